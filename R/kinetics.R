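#' Arrhenius transition rate
#'
#' Rate of the transition out of hishape alpha across the saddle to beta:
#' `r = A * exp(-(dG[alpha,beta] - dG(alpha)) / kT)`, with the barrier
#' `dG[alpha,beta]` an absolute saddle height and `dG(alpha)` the ensemble
#' energy of the departing hishape. The formula is applied literally; rates
#' above `A` are possible when the saddle lies below the ensemble energy.
#'
#' @param barrier Saddle height `dG[alpha,beta]` in kcal/mol.
#' @param ensemble_energy Ensemble energy `dG(alpha)` of the departing state.
#' @param A Arrhenius pre-exponential factor in 1/microsecond (default 1.0).
#' @param params `energy_parameters` supplying `kT`.
#' @return Rate in 1/microsecond.
#' @examples
#' transition_rate(2, 2) # = A
#' @export
transition_rate <- function(barrier, ensemble_energy, A = 1.0,
                            params = energy_parameters()) {
  A * exp(-(barrier - ensemble_energy) / kT(params))
}

#' Build the hishape-level rate matrix
#'
#' Assembles the continuous-time Markov chain generator R over a set of
#' hishape classes: off-diagonals `R[beta, alpha] = transition_rate(
#' dG[alpha,beta], dG(alpha))` and diagonal `R[alpha, alpha] =
#' -sum_{beta != alpha} R[beta, alpha]` so that columns sum to zero. Because
#' barriers are symmetric saddle heights, detailed balance
#' `r_beta_alpha * Z_alpha = r_alpha_beta * Z_beta` holds exactly and the
#' stationary distribution is the Boltzmann distribution over ensemble
#' energies.
#'
#' @param classes A [classify()] result (or data frame with columns
#'   `hishape` and `ensemble_energy`) listing the states.
#' @param barriers Symmetric numeric matrix of saddle heights
#'   `dG[alpha,beta]` in kcal/mol; `Inf` marks a pair known to be
#'   unconnected (zero rate, with a warning), `NA` marks a missing entry
#'   (an error).
#' @inheritParams transition_rate
#' @return Object of class `rate_matrix`: list with `R` (generator,
#'   1/microsecond), `states` (hishape texts), `ensemble_energy` and `pi`
#'   (the Boltzmann stationary distribution over the states).
#' @export
build_rate_matrix <- function(classes, barriers, A = 1.0,
                              params = energy_parameters()) {
  states <- classes$hishape
  g <- classes$ensemble_energy
  ns <- length(states)
  stopifnot(is.matrix(barriers), nrow(barriers) == ns, ncol(barriers) == ns)
  off <- !diag(ns)
  if (any(is.na(barriers[off]))) {
    bad <- which(is.na(barriers) & off, arr.ind = TRUE)[1, ]
    stop("missing barrier for state pair (", states[bad[1]], ", ",
         states[bad[2]], ")")
  }
  if (max(abs(barriers - t(barriers)), na.rm = TRUE) > 1e-9) {
    stop("barrier matrix must be symmetric (saddle heights)")
  }
  ktv <- kT(params)
  R <- matrix(0, ns, ns, dimnames = list(states, states))
  for (a in seq_len(ns)) {
    for (b in seq_len(ns)) {
      if (a == b) next
      if (is.finite(barriers[a, b])) {
        R[b, a] <- A * exp(-(barriers[a, b] - g[a]) / ktv)
      }
    }
  }
  isolated <- which(colSums(R) == 0 & rowSums(R) == 0)
  if (length(isolated) && ns > 1L) {
    warning("states with no finite-barrier connection retained with zero ",
            "rates: ", paste(states[isolated], collapse = ", "))
  }
  diag(R) <- -colSums(R)
  w <- exp(-(g - min(g)) / ktv)
  structure(list(R = R, states = states, ensemble_energy = g,
                 pi = w / sum(w), A = A, kT = ktv),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Hishape CTMC generator (", length(x$states), " states, A = ",
      x$A, " /us)\n", sep = "")
  print(round(x$R, 6))
  invisible(x)
}

#' Propagate the master equation
#'
#' Solves `dp/dt = R p` for the occupancy vector, `p(t) = expm(tR) p(0)`.
#' When the chain satisfies detailed balance with respect to its Boltzmann
#' distribution (the construction of [build_rate_matrix()] guarantees this),
#' the generator is symmetrized as `D^-1 R D` with `D = diag(sqrt(pi))` and
#' propagated through a symmetric eigendecomposition; otherwise a dense
#' matrix exponential (scaling-and-squaring) is used per time point.
#'
#' @param rates A `rate_matrix` from [build_rate_matrix()], or a plain
#'   generator matrix (columns summing to zero).
#' @param p0 Initial probability vector over the states.
#' @param times Increasing vector of non-negative times in microseconds.
#' @return Object of class `occupancy_trajectory`: a data frame with column
#'   `time` and one occupancy column per state.
#' @export
propagate <- function(rates, p0, times) {
  if (inherits(rates, "rate_matrix")) {
    R <- rates$R
    states <- rates$states
    pi <- rates$pi
  } else {
    R <- as.matrix(rates)
    states <- colnames(R)
    if (is.null(states)) states <- paste0("state", seq_len(ncol(R)))
    pi <- NULL
  }
  ns <- ncol(R)
  if (length(p0) != ns) stop("p0 has length ", length(p0), ", expected ", ns)
  if (any(p0 < -1e-12) || abs(sum(p0) - 1) > 1e-9) {
    stop("p0 must be a probability vector (non-negative, summing to 1)")
  }
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop("times must be non-negative and strictly increasing")
  }

  reversible <- FALSE
  if (!is.null(pi) && all(pi > 0)) {
    flux <- R * rep(pi, each = ns)        # flux[b,a] = r_ba * pi_a
    reversible <- max(abs(flux - t(flux))) <= 1e-8 * max(abs(flux), 1e-300)
  }

  P <- matrix(NA_real_, length(times), ns)
  if (reversible) {
    d <- sqrt(pi)
    Rs <- (1 / d) * R * rep(d, each = ns)  # D^-1 R D, symmetric
    Rs <- (Rs + t(Rs)) / 2
    eg <- eigen(Rs, symmetric = TRUE)
    # the generator has one exact zero eigenvalue per connected component;
    # clamp numerically-zero (or spuriously positive) eigenvalues so they
    # are not amplified by exp(lambda * t) at large times
    scale <- max(abs(eg$values), 1e-300)
    eg$values[eg$values > -1e-10 * scale] <- 0
    y0 <- as.numeric(t(eg$vectors) %*% (p0 / d))
    for (it in seq_along(times)) {
      P[it, ] <- d * as.numeric(eg$vectors %*% (exp(eg$values * times[it]) * y0))
    }
  } else {
    for (it in seq_along(times)) {
      Et <- as.matrix(Matrix::expm(Matrix::Matrix(R * times[it])))
      P[it, ] <- as.numeric(Et %*% p0)
    }
  }
  out <- data.frame(time = times, P)
  names(out) <- c("time", states)
  class(out) <- c("occupancy_trajectory", "data.frame")
  attr(out, "p0") <- p0
  attr(out, "states") <- states
  out
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat("Occupancy trajectory: ", nrow(x), " times, ",
      length(attr(x, "states")), " states\n", sep = "")
  show <- unique(round(seq(1, nrow(x), length.out = min(10, nrow(x)))))
  print.data.frame(x[show, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Default logarithmic time grid
#'
#' @param from,to Decades in microseconds (defaults 1e-2 to 1e8).
#' @param length.out Number of points (default 200).
#' @return Log-spaced time vector in microseconds.
#' @export
kinetics_times <- function(from = 1e-2, to = 1e8, length.out = 200) {
  10^seq(log10(from), log10(to), length.out = length.out)
}

#' End-to-end hishape folding kinetics
#'
#' Runs the full pipeline on one sequence: classify the folding space into
#' hishapes, estimate all pairwise barriers between the hishreps of the
#' selected states with [hipath2()], build the Arrhenius rate matrix, and
#' propagate the master equation from a unit initial distribution.
#'
#' The state set consists of the `k_best` classes plus the open chain
#' `"[_]"` and the `initial` hishape (both added if not already selected).
#'
#' @inheritParams classify
#' @param k_best Number of best classes (by hishrep energy) to simulate.
#' @param initial Hishape text of the initially populated state
#'   (default the open chain `"[_]"`).
#' @param times Output times in microseconds (default [kinetics_times()]).
#' @param A Arrhenius prefactor in 1/microsecond (default 1.0).
#' @param width,theta,anchors Passed to [hipath2()].
#' @return An `occupancy_trajectory` with the classification in attribute
#'   `"classification"`, the barrier matrix in `"barriers"` and the
#'   `rate_matrix` in `"rates"`.
#' @export
simulate_kinetics <- function(seq, level = "h", strictly_negative = FALSE,
                              k_best = 25, initial = "[_]",
                              times = kinetics_times(), A = 1.0,
                              width = 10, theta = 1, anchors = "auto",
                              params = energy_parameters(),
                              energy_band = NULL, max_len = 60) {
  sq <- as_rna_sequence(seq)
  space <- enumerate_structures(sq, params = params,
                                energy_band = energy_band, max_len = max_len)
  full <- classify(sq, level = level, strictly_negative = strictly_negative,
                   params = params, space = space)
  if (!initial %in% full$hishape) {
    stop("initial hishape ", initial, " is not a class of this folding ",
         "space; available states: ", paste(full$hishape, collapse = " "))
  }
  sel <- seq_len(min(k_best, nrow(full)))
  sel <- union(sel, match(c("[_]", initial), full$hishape))
  sel <- sel[!is.na(sel)]
  states <- full[sel, , drop = FALSE]

  # anchor classification at level h over the unrestricted space, as the
  # pathway search is defined on the full landscape
  cls_h <- classify(sq, level = "h", params = params, space = space)
  cache <- new.env(parent = emptyenv())
  ns <- nrow(states)
  barriers <- matrix(0, ns, ns, dimnames = list(states$hishape,
                                                states$hishape))
  for (a in seq_len(max(0, ns - 1L))) {
    for (b in seq.int(a + 1L, ns)) {
      fp <- hipath2(sq, states$hishrep[a], states$hishrep[b],
                    width = width, theta = theta, anchors = anchors,
                    params = params, classification = cls_h, cache = cache)
      barriers[a, b] <- barriers[b, a] <- fp$saddle
    }
  }

  rates <- build_rate_matrix(states, barriers, A = A, params = params)
  p0 <- as.numeric(states$hishape == initial)
  traj <- propagate(rates, p0, times)
  attr(traj, "classification") <- states
  attr(traj, "barriers") <- barriers
  attr(traj, "rates") <- rates
  traj
}
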