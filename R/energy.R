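#' Loop decomposition of a secondary structure
#'
#' Decomposes a pseudoknot-free structure into its unique set of loops:
#' exactly one exterior loop, plus one loop per base pair (the loop that pair
#' closes). Every base pair closes exactly one loop and every unpaired base
#' belongs to exactly one loop.
#'
#' @param structure A `secondary_structure` or dot-bracket string.
#' @return Object of class `loop_decomposition`: a list of loops, each a list
#'   with `kind` (`"exterior"`, `"hairpin"`, `"stack"`, `"bulge"`,
#'   `"internal"` or `"multiloop"`), `closing` (the closing pair `(i,j)`, or
#'   `NULL` for the exterior loop), `branches` (2-column matrix of enclosed
#'   helix-opening pairs), `unpaired` (count of unpaired bases in the loop)
#'   and, for bulge/internal loops, `sides` (unpaired counts 5' and 3' of the
#'   branch).
#' @examples
#' decompose_structure("((...))")
#' @export
decompose_structure <- function(structure) {
  s <- validate_structure(structure, nolp = FALSE)
  loops <- pt_loops(s$pt)
  structure(loops, class = "loop_decomposition", n = s$n)
}

# scan one loop interior [from, to]; returns branches matrix and unpaired count
scan_interior <- function(pt, from, to) {
  branches <- NULL
  unpaired <- 0L
  gaps <- integer(0)   # unpaired run lengths between/around branches
  gap <- 0L
  k <- from
  while (k <= to) {
    if (pt[k] > k) {
      branches <- rbind(branches, c(k, pt[k]))
      gaps <- c(gaps, gap)
      gap <- 0L
      k <- pt[k] + 1L
    } else {
      unpaired <- unpaired + 1L
      gap <- gap + 1L
      k <- k + 1L
    }
  }
  gaps <- c(gaps, gap)
  list(branches = branches, unpaired = unpaired, gaps = gaps)
}

pt_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  ext <- scan_interior(pt, 1L, n)
  loops[[1]] <- list(kind = "exterior", closing = NULL,
                     branches = ext$branches, unpaired = ext$unpaired)
  prs <- pairs_from_pt(pt)
  if (nrow(prs)) {
    for (r in seq_len(nrow(prs))) {
      i <- unname(prs[r, 1]); j <- unname(prs[r, 2])
      inn <- scan_interior(pt, i + 1L, j - 1L)
      nb <- if (is.null(inn$branches)) 0L else nrow(inn$branches)
      if (nb == 0L) {
        kind <- "hairpin"
        sides <- NULL
      } else if (nb == 1L) {
        left <- inn$branches[1, 1] - i - 1L
        right <- j - inn$branches[1, 2] - 1L
        sides <- c(left, right)
        kind <- if (left + right == 0L) "stack"
                else if (left == 0L || right == 0L) "bulge"
                else "internal"
      } else {
        kind <- "multiloop"
        sides <- NULL
      }
      loops[[length(loops) + 1L]] <- list(
        kind = kind, closing = c(i, j), branches = inn$branches,
        unpaired = inn$unpaired, sides = sides)
    }
  }
  loops
}

#' @export
print.loop_decomposition <- function(x, ...) {
  cat("Loop decomposition (", length(x), " loops)\n", sep = "")
  for (lp in x) {
    cl <- if (is.null(lp$closing)) "-" else
      paste0("(", lp$closing[1], ",", lp$closing[2], ")")
    nb <- if (is.null(lp$branches)) 0L else nrow(lp$branches)
    cat(sprintf("  %-9s closing %-9s branches %d unpaired %d\n",
                lp$kind, cl, nb, lp$unpaired))
  }
  invisible(x)
}

pair_type <- function(chars, i, j) paste0(chars[i], chars[j])

terminal_penalty <- function(params, type) {
  if (type %in% c("AU", "UA", "GU", "UG")) params$terminal_au else 0
}

# free energy of a single loop under the nearest-neighbor model
loop_energy <- function(loop, chars, pt, params) {
  switch(loop$kind,
    exterior = 0,
    stack = {
      i <- loop$closing[1]; j <- loop$closing[2]
      params$stack[pair_type(chars, i, j),
                   pair_type(chars, i + 1L, j - 1L)]
    },
    hairpin = {
      i <- loop$closing[1]; j <- loop$closing[2]
      loop_initiation(params$hairpin, loop$unpaired, params$lxc) +
        terminal_penalty(params, pair_type(chars, i, j))
    },
    bulge = {
      i <- loop$closing[1]; j <- loop$closing[2]
      b <- loop$branches[1, ]
      loop_initiation(params$bulge, loop$unpaired, params$lxc) +
        terminal_penalty(params, pair_type(chars, i, j)) +
        terminal_penalty(params, pair_type(chars, b[1], b[2]))
    },
    internal = {
      i <- loop$closing[1]; j <- loop$closing[2]
      b <- loop$branches[1, ]
      loop_initiation(params$internal, loop$unpaired, params$lxc) +
        terminal_penalty(params, pair_type(chars, i, j)) +
        terminal_penalty(params, pair_type(chars, b[1], b[2]))
    },
    multiloop = {
      i <- loop$closing[1]; j <- loop$closing[2]
      nb <- nrow(loop$branches)
      e <- params$ml_offset + params$ml_branch * (nb + 1L) +
        params$ml_unpaired * loop$unpaired +
        terminal_penalty(params, pair_type(chars, i, j))
      for (r in seq_len(nb)) {
        e <- e + terminal_penalty(
          params, pair_type(chars, loop$branches[r, 1], loop$branches[r, 2]))
      }
      e
    },
    stop("unknown loop kind: ", loop$kind)
  )
}

# fast path used by enumeration: energy from a pair table
energy_pt <- function(chars, pt, params) {
  loops <- pt_loops(pt)
  e <- 0
  for (lp in loops) e <- e + loop_energy(lp, chars, pt, params)
  e
}

#' Free energy of a secondary structure
#'
#' Sums loop free energies over the unique loop decomposition. The exterior
#' loop contributes 0 kcal/mol.
#'
#' @param seq An `rna_sequence` or sequence string.
#' @param structure A `secondary_structure` or dot-bracket string, compatible
#'   with `seq` (canonical pairs only).
#' @param params `energy_parameters` (default: bundled compact table).
#' @return Free energy in kcal/mol.
#' @examples
#' structure_energy("GGAAACC", "((...))")
#' @export
structure_energy <- function(seq, structure, params = energy_parameters()) {
  sq <- as_rna_sequence(seq)
  s <- validate_structure(structure, seq = sq, nolp = FALSE)
  energy_pt(sq$chars, s$pt, params)
}

#' Energy of a closed substructure
#'
#' Energy of all loops enclosed by (and including the loop closed by) a given
#' base pair. The sum of the top-level closed-substructure energies plus the
#' exterior-loop contribution equals [structure_energy()]; the analogous
#' bookkeeping holds inside multiloops. Used by the strictly-negative filter,
#' whose rule is that closed substructures whose parent loop is the exterior
#' loop or a multiloop must not have positive energy.
#'
#' @inheritParams structure_energy
#' @param closing_pair Integer pair `c(i, j)` present in `structure`, whose
#'   parent loop is the exterior loop or a multiloop.
#' @return Free energy in kcal/mol of the enclosed loops.
#' @export
closed_substructure_energy <- function(seq, structure, closing_pair,
                                       params = energy_parameters()) {
  sq <- as_rna_sequence(seq)
  s <- validate_structure(structure, seq = sq, nolp = FALSE)
  pt <- s$pt
  i <- closing_pair[1]; j <- closing_pair[2]
  if (i < 1 || j > s$n || pt[i] != j) {
    stop("closing pair (", i, ",", j, ") is not a pair of the structure")
  }
  loops <- pt_loops(pt)
  parent_ok <- FALSE
  for (lp in loops) {
    if (lp$kind %in% c("exterior", "multiloop") && !is.null(lp$branches) &&
        any(lp$branches[, 1] == i & lp$branches[, 2] == j)) {
      parent_ok <- TRUE
      break
    }
  }
  if (!parent_ok) {
    stop("parent loop of pair (", i, ",", j,
         ") is neither the exterior loop nor a multiloop")
  }
  closed_energy_pt(sq$chars, pt, loops, i, j, params)
}

# energy of loops whose closing pair lies within [i, j] (loops precomputed)
closed_energy_pt <- function(chars, pt, loops, i, j, params) {
  e <- 0
  for (lp in loops) {
    if (!is.null(lp$closing) && lp$closing[1] >= i && lp$closing[2] <= j) {
      e <- e + loop_energy(lp, chars, pt, params)
    }
  }
  e
}
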