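ktv <- hishapes:::kT(TOY_PARAMS)

test_that("Arrhenius rates follow the exponential law and invert cleanly", {
  expect_equal(transition_rate(2.5, 2.5), 1.0)
  expect_equal(transition_rate(ktv * log(2), 0), 0.5)
  set.seed(71)
  for (rep in 1:10) {
    barrier <- runif(1, -3, 8)
    g <- runif(1, -5, 2)
    r <- transition_rate(barrier, g, A = 2)
    expect_equal(-ktv * log(r / 2) + g, barrier, tolerance = 1e-9)
  }
})

two_state_classes <- function(g1, g2) {
  structure(data.frame(hishape = c("[5]", "[9]"),
                       ensemble_energy = c(g1, g2)),
            class = c("hishape_classification", "data.frame"))
}

test_that("rate matrices are conservative generators with detailed balance", {
  cls <- two_state_classes(-1, -1)
  B <- matrix(c(0, 2, 2, 0), 2, 2)
  rm <- build_rate_matrix(cls, B)
  expect_equal(rm$R[2, 1], rm$R[1, 2])   # equal ensemble energies
  expect_equal(colSums(rm$R), c("[5]" = 0, "[9]" = 0), tolerance = 1e-12)

  # detailed balance r_ba * exp(-dG(a)/kT) = r_ab * exp(-dG(b)/kT)
  cls3 <- structure(data.frame(hishape = c("[a]", "[b]", "[c]"),
                               ensemble_energy = c(-2, -1.2, 0.3)),
                    class = c("hishape_classification", "data.frame"))
  B3 <- matrix(c(0, 1.5, 2.5, 1.5, 0, 1.1, 2.5, 1.1, 0), 3, 3)
  rm3 <- build_rate_matrix(cls3, B3)
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    expect_equal(rm3$R[b, a] * exp(-cls3$ensemble_energy[a] / ktv),
                 rm3$R[a, b] * exp(-cls3$ensemble_energy[b] / ktv),
                 tolerance = 1e-12)
  }

  B_na <- B; B_na[1, 2] <- B_na[2, 1] <- NA
  expect_error(build_rate_matrix(cls, B_na), "missing barrier")
  B_inf <- matrix(Inf, 2, 2); diag(B_inf) <- 0
  expect_warning(build_rate_matrix(cls, B_inf), "zero")
  expect_error(build_rate_matrix(cls, matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("propagation conserves probability and matches closed forms", {
  cls <- two_state_classes(-1, -1)
  B0 <- matrix(0, 2, 2)
  rmz <- build_rate_matrix(cls, B0)
  rmz$R[] <- 0
  traj <- suppressWarnings(propagate(rmz, c(0.3, 0.7), c(1, 10, 100)))
  expect_equal(unname(as.matrix(traj[, -1])),
               matrix(c(0.3, 0.7), 3, 2, byrow = TRUE))

  # 2-state analytic relaxation: p1(t) = pi1 + (p1(0) - pi1) exp(-(r12+r21) t)
  cls2 <- two_state_classes(-1.7, -0.4)
  B <- matrix(c(0, 1.9, 1.9, 0), 2, 2)
  rm <- build_rate_matrix(cls2, B)
  r21 <- rm$R[2, 1]; r12 <- rm$R[1, 2]
  times <- c(0.01, 0.1, 1, 10, 100)
  traj <- propagate(rm, c(1, 0), times)
  pi1 <- r12 / (r12 + r21)
  expect_equal(traj[["[5]"]], pi1 + (1 - pi1) * exp(-(r12 + r21) * times),
               tolerance = 1e-9)
  expect_equal(rowSums(traj[, -1]), rep(1, length(times)), tolerance = 1e-9)

  expect_error(propagate(rm, c(0.5, 0.6), times), "probability")
  expect_error(propagate(rm, c(1, 0), c(2, 1)), "increasing")
})

test_that("both propagation backends agree with a dense matrix exponential", {
  cls3 <- structure(data.frame(hishape = c("[a]", "[b]", "[c]"),
                               ensemble_energy = c(-2, -1.2, 0.3)),
                    class = c("hishape_classification", "data.frame"))
  B3 <- matrix(c(0, 1.5, 2.5, 1.5, 0, 1.1, 2.5, 1.1, 0), 3, 3)
  rm3 <- build_rate_matrix(cls3, B3)
  p0 <- c(1, 0, 0)
  times <- 10^seq(-2, 4, length.out = 20)
  traj <- propagate(rm3, p0, times)          # symmetrized eigen route
  plain <- propagate(rm3$R, p0, times)       # scaling-and-squaring route
  for (it in seq_along(times)) {
    ref <- as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(
      rm3$R * times[it]))) %*% p0)
    expect_equal(as.numeric(as.matrix(traj[it, -1])), ref, tolerance = 1e-8)
    expect_equal(as.numeric(as.matrix(plain[it, -1])), ref, tolerance = 1e-8)
  }
})

test_that("end-to-end kinetics relaxes to the Boltzmann distribution", {
  # single-class sequence: occupancy pinned at 1
  traj0 <- simulate_kinetics("AAAA", times = c(1, 100))
  expect_equal(unname(as.matrix(traj0[, -1])), matrix(1, 2, 1))

  bs <- bistable_sequence(arm_length = 6, seed = 1)
  traj <- simulate_kinetics(bs, k_best = Inf)
  cls <- attr(traj, "classification")
  occ <- as.matrix(traj[, -1])
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
  expect_gte(min(occ), -1e-12)
  expect_equal(as.numeric(occ[nrow(occ), ]), cls$probability,
               tolerance = 1e-6)

  # total variation distance to equilibrium decays monotonically
  tv <- apply(occ, 1, function(p) sum(abs(p - cls$probability)) / 2)
  expect_true(all(diff(tv) <= 1e-10))
})

test_that("restricting to strictly negative hishapes is internally consistent", {
  bs <- bistable_sequence(arm_length = 6, seed = 1)
  trajsn <- simulate_kinetics(bs, k_best = Inf, strictly_negative = TRUE)
  clssn <- classify(bs, strictly_negative = TRUE)
  states <- attr(trajsn, "states")
  expect_equal(as.numeric(as.matrix(trajsn[nrow(trajsn), -1])),
               clssn$probability[match(states, clssn$hishape)],
               tolerance = 1e-6)
})

test_that("unknown initial hishapes are rejected with the available states", {
  expect_error(simulate_kinetics("GGAAACC", initial = "[9]"),
               "available states")
})
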