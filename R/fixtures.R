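#' Deterministic random RNA sequences
#'
#' Draws reproducible random sequences with a target GC fraction. Bases are
#' sampled independently with probabilities `gc/2` for each of G and C and
#' `(1-gc)/2` for each of A and U, using R's Mersenne-Twister generator
#' seeded from `seed` (the RNG state of the caller is left untouched).
#'
#' @param n_seqs Number of sequences.
#' @param length Sequence length in nt (`>= 1`).
#' @param gc Target GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed; the same `(spec, seed)` always reproduces the
#'   same sequences.
#' @return List of [rna_sequence()] objects with identifiers recording the
#'   generation spec; attribute `"rng"` names the generator.
#' @examples
#' random_sequences(2, 20, gc = 0.5, seed = 1)
#' @export
random_sequences <- function(n_seqs, length, gc = 0.5, seed = 1) {
  stopifnot(length >= 1, gc >= 0, gc <= 1, n_seqs >= 1)
  out <- with_local_seed(seed, {
    lapply(seq_len(n_seqs), function(s) {
      res <- sample(c("G", "C", "A", "U"), length, replace = TRUE,
                    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
      rna_sequence(paste(res, collapse = ""),
                   id = sprintf("rnd_l%d_gc%g_s%d_%d", length, gc, seed, s))
    })
  })
  attr(out, "rng") <- "Mersenne-Twister/sample"
  out
}

# run code under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

revcomp <- function(chars) rev(chartr("ACGU", "UGCA", chars))

#' Designed bistable sequence
#'
#' Constructs a synthetic sequence with two mutually exclusive helix
#' arrangements of nearly equal energy, a desk-scale stand-in for natural
#' conformational switches. The design is `L AAA M AAA R` with
#' `M = revcomp(L)` and `R` a lightly mutated copy of `L`, so that the
#' central segment can pair either upstream (class 1) or downstream
#' (class 2) but not both. Candidate arms are drawn until (a) the two
#' best non-open hishape classes at level `h` are within 1 kcal/mol of each
#' other, (b) their hishreps are mutually exclusive (no shared pairs), and
#' (c) the kinetically preferred class (smaller direct saddle from the open
#' chain) is not the thermodynamically preferred one -- the operational
#' signature of a bistable switch whose occupancies cross over time.
#'
#' @param arm_length Helix arm length in nt (`>= 4`, default 6).
#' @param seed Integer seed.
#' @param params `energy_parameters`.
#' @param max_tries Bounded number of candidate draws (default 300).
#' @return An [rna_sequence()] with attribute `"classes"` (the two dominant
#'   hishape texts) and `"gap"` (their hishrep energy difference, kcal/mol).
#' @export
bistable_sequence <- function(arm_length = 6, seed = 1,
                              params = energy_parameters(), max_tries = 300) {
  stopifnot(arm_length >= 4)
  for (try in seq_len(max_tries)) {
    arm <- with_local_seed(seed * 1000L + try, {
      sample(c("G", "C", "A", "U"), arm_length, replace = TRUE,
             prob = c(0.4, 0.4, 0.1, 0.1))
    })
    mid <- revcomp(arm)
    right <- arm
    # perturb one downstream position to detune the two stems
    pos <- ((try - 1L) %% arm_length) + 1L
    right[pos] <- c(G = "A", C = "A", A = "G", U = "G")[[right[pos]]]
    sq <- tryCatch(
      rna_sequence(paste(c(arm, "AAA", mid, "AAA", right), collapse = ""),
                   id = sprintf("bistable_a%d_s%d", arm_length, seed)),
      error = function(e) NULL)
    if (is.null(sq)) next

    ok <- tryCatch({
      cls <- classify(sq, level = "h", params = params)
      non_open <- cls[cls$hishape != "[_]", , drop = FALSE]
      if (nrow(non_open) < 2) FALSE else {
        c1 <- non_open[1, ]; c2 <- non_open[2, ]
        gap <- abs(c1$hishrep_energy - c2$hishrep_energy)
        p1 <- structure_pairs(c1$hishrep)
        p2 <- structure_pairs(c2$hishrep)
        exclusive <- !any(paste(p1[, 1], p1[, 2]) %in%
                            paste(p2[, 1], p2[, 2]))
        both_stable <- c1$hishrep_energy < 0 && c2$hishrep_energy < 0
        if (gap <= 1 && exclusive && both_stable) {
          # kinetic preference must oppose thermodynamic preference
          open <- strrep(".", sq$n)
          s1 <- direct_path_bfs(sq, open, c1$hishrep, k = 10, params)$saddle
          s2 <- direct_path_bfs(sq, open, c2$hishrep, k = 10, params)$saddle
          thermo_first <- c1$ensemble_energy < c2$ensemble_energy
          kinetic_first <- s1 < s2
          if (is.finite(s1) && is.finite(s2) && s1 != s2 &&
              (thermo_first != kinetic_first)) {
            attr(sq, "classes") <- c(c1$hishape, c2$hishape)
            attr(sq, "gap") <- gap
            TRUE
          } else FALSE
        } else FALSE
      }
    }, error = function(e) FALSE)
    if (isTRUE(ok)) return(sq)
  }
  stop("no bistable sequence found in ", max_tries, " tries; ",
       "try a different seed or a longer arm_length")
}

#' Fit exponential growth asymptotics
#'
#' Least-squares fit of per-length counts to the abstract-shape growth law
#' `count(n) = a * b^n * n^(-3/2)`, linearized as
#' `log(count) + 1.5 log(n) = log(a) + n log(b)`.
#'
#' @param lengths Sequence lengths `n` (>= 3 distinct points).
#' @param counts Positive counts per length.
#' @return Named numeric vector `c(a, b)`.
#' @examples
#' n <- 20:40
#' growth_curve_fit(n, 2 * 1.5^n * n^(-1.5))
#' @export
growth_curve_fit <- function(lengths, counts) {
  if (length(lengths) != length(counts)) {
    stop("lengths and counts must have equal length")
  }
  if (length(unique(lengths)) < 3) stop("need at least 3 distinct lengths")
  if (any(counts <= 0)) stop("counts must be positive")
  y <- log(counts) + 1.5 * log(lengths)
  fit <- stats::lm(y ~ lengths)
  co <- stats::coef(fit)
  c(a = unname(exp(co[1])), b = unname(exp(co[2])))
}
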