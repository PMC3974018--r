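#' Nearest-neighbor energy parameters
#'
#' Reads a plain-text nearest-neighbor parameter table into an
#' `energy_parameters` object. The bundled compact table (the default) gives
#' stacking free energies for all 36 ordered combinations of canonical pairs,
#' loop-initiation tables to size 30 for hairpin, bulge and internal loops
#' (with logarithmic extrapolation beyond the table), an affine multiloop
#' model, and a terminal AU/GU penalty. All energies are in kcal/mol.
#'
#' The file grammar is documented in the header of
#' `system.file("extdata", "nn_compact.par", package = "hishapes")`:
#' `#` comments, `[section]` headers, and whitespace-separated records.
#'
#' @param file Path to a parameter file. `NULL` (default) loads the bundled
#'   compact table.
#' @return An object of class `energy_parameters`: a list with components
#'   `stack` (6 x 6 matrix indexed by pair type, e.g. `"GC"`), `hairpin`,
#'   `bulge`, `internal` (named numeric vectors by loop size), `ml_offset`,
#'   `ml_branch`, `ml_unpaired`, `terminal_au`, `lxc`, `gas_constant`
#'   (kcal/(mol K)) and `temperature` (K).
#' @examples
#' par <- energy_parameters()
#' par$stack["GC", "GC"]
#' @export
energy_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "nn_compact.par", package = "hishapes")
  }
  if (!file.exists(file)) stop("parameter file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  pair_types <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pair_types, pair_types))
  hairpin <- numeric(0)
  bulge <- numeric(0)
  internal <- numeric(0)
  ml <- c(offset = NA_real_, branch = NA_real_, unpaired = NA_real_)
  misc <- c(terminal_au = NA_real_, lxc = NA_real_,
            gas_constant = NA_real_, temperature = NA_real_)

  section <- ""
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    switch(section,
      stack = {
        if (length(tok) != 3 || !(tok[1] %in% pair_types) ||
            !(tok[2] %in% pair_types)) {
          stop("malformed [stack] record: ", ln)
        }
        stack[tok[1], tok[2]] <- as.numeric(tok[3])
      },
      hairpin = hairpin[tok[1]] <- as.numeric(tok[2]),
      bulge = bulge[tok[1]] <- as.numeric(tok[2]),
      internal = internal[tok[1]] <- as.numeric(tok[2]),
      multiloop = ml[tok[1]] <- as.numeric(tok[2]),
      misc = misc[tok[1]] <- as.numeric(tok[2]),
      stop("record outside any section: ", ln)
    )
  }

  params <- structure(list(
    stack = stack,
    hairpin = hairpin,
    bulge = bulge,
    internal = internal,
    ml_offset = unname(ml["offset"]),
    ml_branch = unname(ml["branch"]),
    ml_unpaired = unname(ml["unpaired"]),
    terminal_au = unname(misc["terminal_au"]),
    lxc = unname(misc["lxc"]),
    gas_constant = unname(misc["gas_constant"]),
    temperature = unname(misc["temperature"])
  ), class = "energy_parameters")
  validate_energy_parameters(params)
  params
}

validate_energy_parameters <- function(p) {
  if (anyNA(p$stack)) stop("incomplete stacking table")
  if (is.na(p$gas_constant) || p$gas_constant <= 0) {
    stop("gas_constant must be positive")
  }
  if (is.na(p$temperature) || p$temperature <= 0) {
    stop("temperature must be positive")
  }
  for (nm in c("hairpin", "bulge", "internal")) {
    sizes <- as.integer(names(p[[nm]]))
    if (length(sizes) == 0 || anyNA(p[[nm]])) stop("empty ", nm, " table")
    lo <- c(hairpin = 3L, bulge = 1L, internal = 2L)[[nm]]
    if (min(sizes) < lo) {
      stop(nm, " table has loop size below the physical minimum ", lo)
    }
    if (!identical(sizes, seq(min(sizes), max(sizes)))) {
      stop(nm, " table must tabulate contiguous loop sizes")
    }
  }
  invisible(p)
}

#' @export
print.energy_parameters <- function(x, ...) {
  cat("Nearest-neighbor energy parameters (kcal/mol)\n")
  cat(sprintf("  stacks: %d entries; hairpin %s..%s; bulge %s..%s; internal %s..%s\n",
              sum(!is.na(x$stack)),
              names(x$hairpin)[1], names(x$hairpin)[length(x$hairpin)],
              names(x$bulge)[1], names(x$bulge)[length(x$bulge)],
              names(x$internal)[1], names(x$internal)[length(x$internal)]))
  cat(sprintf("  multiloop: %.2f + %.2f/branch + %.2f/unpaired; terminal AU/GU %.2f\n",
              x$ml_offset, x$ml_branch, x$ml_unpaired, x$terminal_au))
  cat(sprintf("  kT = %.6f kcal/mol (R = %.7f, T = %.2f K)\n",
              kT(x), x$gas_constant, x$temperature))
  invisible(x)
}

# thermal energy in kcal/mol
kT <- function(params) params$gas_constant * params$temperature

# loop initiation with logarithmic extrapolation beyond the table
loop_initiation <- function(table, size, lxc) {
  sizes <- as.integer(names(table))
  if (size < sizes[1]) stop("loop size ", size, " below tabulated minimum")
  mx <- sizes[length(sizes)]
  if (size <= mx) {
    unname(table[[as.character(size)]])
  } else {
    unname(table[[as.character(mx)]]) + lxc * log(size / mx)
  }
}
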