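mk_moments <- function(Mu, Ms, Mss = Ms^2, Mus = Mu * Ms) {
  structure(list(Mu = Mu, Ms = Ms, Mss = Mss, Mus = Mus), class = "moments")
}

test_that("exact proportionality is recovered by both estimators", {
  set.seed(1)
  Ms <- cbind(runif(80, 0, 10))
  Mu <- 2 * Ms
  # counting-identity second moments keep the stochastic block consistent
  mom <- mk_moments(Mu, Ms, Mss = Ms^2 + Ms, Mus = Mu * Ms)
  for (mode in c("steady_state", "stochastic")) {
    fit <- fit_gamma(mom, mode)
    expect_equal(fit$gamma, 2, tolerance = 1e-10)
    expect_true(fit$valid)
  }
})

test_that("degenerate genes are flagged invalid, never silently zero", {
  Ms <- cbind(rep(0, 20), runif(20))
  Mu <- cbind(rep(0, 20), -2 * Ms[, 2])
  fit <- fit_gamma(mk_moments(Mu, Ms), "steady_state")
  expect_false(fit$valid[1])
  expect_match(fit$reason[1], "all-zero")
  expect_false(fit$valid[2])
  expect_match(fit$reason[2], "non-positive")
})

test_that("velocity is the residual from the steady-state line", {
  Ms <- cbind(c(1, 2, 4))
  Mu <- cbind(c(1, 1, 2))
  fit <- fit_gamma(mk_moments(Mu, Ms), "steady_state", c(0.2, 0.7))
  V <- compute_velocity(mk_moments(Mu, Ms), fit)
  expect_equal(V$V, Mu - fit$gamma * Ms, ignore_attr = TRUE)
  # a cell exactly on the line has zero residual
  Mu2 <- cbind(c(0.5, 1, 2)); Ms2 <- cbind(c(1, 2, 4))
  fit2 <- fit_gamma(mk_moments(Mu2, Ms2), "steady_state")
  V2 <- compute_velocity(mk_moments(Mu2, Ms2), fit2)
  expect_equal(max(abs(V2$V)), 0, tolerance = 1e-12)

  # gene-count mismatch is a contract error
  expect_error(compute_velocity(mk_moments(Mu2[, c(1, 1)], Ms2[, c(1, 1)]), fit2),
               "contract")
})

test_that("scaling both layers by c leaves gamma unchanged and scales V by c", {
  # exact for the first-moment (steady-state) estimator; the stochastic
  # estimator's counting-identity block is intentionally scale-dependent
  v <- small_velocity()
  c0 <- 3.7
  mom2 <- mk_moments(v$mom$Mu * c0, v$mom$Ms * c0,
                     v$mom$Mss * c0^2, v$mom$Mus * c0^2)
  fit1 <- fit_gamma(v$mom, "steady_state")
  fit2 <- fit_gamma(mom2, "steady_state")
  ok <- fit1$valid & fit2$valid
  expect_equal(fit2$gamma[ok], fit1$gamma[ok], tolerance = 1e-8)
  V1 <- compute_velocity(v$mom, fit1)
  V2 <- compute_velocity(mom2, fit2)
  expect_equal(V2$V[, ok], c0 * V1$V[, ok], tolerance = 1e-8)
})

test_that("steady-state and stochastic modes agree on noise-free equilibrium data", {
  set.seed(9)
  alpha <- rexp(200, 0.2) + 0.5
  gam <- 0.45
  Mu <- cbind(alpha)           # u* = alpha / beta
  Ms <- cbind(alpha / gam)     # s* = alpha / gamma
  # second moments satisfying the Poisson counting identity make the
  # second-moment equation exactly consistent with the first
  mom <- mk_moments(Mu, Ms, Mss = Ms^2 + Ms, Mus = Mu * Ms)
  fs <- fit_gamma(mom, "steady_state")
  fx <- fit_gamma(mom, "stochastic")
  expect_equal(fs$gamma, gam, tolerance = 1e-10)
  expect_lt(abs(fx$gamma - fs$gamma) / fs$gamma, 0.05)
})

test_that("gamma is recovered from a Poisson-noise equilibrium cohort", {
  cfg <- sim_config(n_genes = 30, n_dynamic_genes = 0, n_de_genes = 0,
                    n_subjects_per_group = 5, n_cells_per_subject = 200,
                    cell_types = "excitatory", phase = "equilibrium",
                    gamma = c(0.3, runif(29, 0.2, 1)), seed = 21)
  ds <- generate_cohort(cfg)
  norm <- normalize_counts(ds$counts, "velocity_layers")
  mom <- neighbor_moments(norm$S, norm$U, n_pcs = 10, k = 50)
  for (mode in c("steady_state", "stochastic")) {
    fit <- fit_gamma(mom, mode)
    expect_true(fit$valid[1])
    expect_lt(abs(fit$gamma[1] - 0.3) / 0.3, 0.1)
  }
})

test_that("estimated velocity signs follow the kinetic ground truth", {
  v <- small_velocity()
  vt <- true_velocity(v$ds)
  idx <- which(v$ds$truth$labels == "null" & v$fit$valid)
  agree <- vapply(idx, function(j) {
    big <- abs(vt[, j]) > 0.1 * max(abs(vt[, j]))
    mean(sign(v$V$V[big, j]) == sign(vt[big, j]))
  }, numeric(1))
  expect_gt(mean(agree), 0.9)
})

test_that("velocity gene ranking matches the Welch formula and flags signal", {
  set.seed(4)
  n <- 60
  types <- rep(c("a", "b", "c"), each = 20)
  V <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  V[types == "b", 3] <- V[types == "b", 3] + 5

  rk <- rank_velocity_genes(V, types)
  # direct Welch formula on extracted vectors
  x <- V[types == "b", 3]; y <- V[types != "b", 3]
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(rk$t[rk$cell_type == "b" & rk$gene == "g3"], tw, tolerance = 1e-12)
  expect_equal(rk$rank[rk$cell_type == "b" & rk$gene == "g3"], 1)

  # constructed zero-variance signal still lands on top
  V2 <- matrix(0, n, 2, dimnames = list(NULL, c("flat", "hit")))
  V2[types == "a", 2] <- 1
  rk2 <- rank_velocity_genes(V2, types)
  expect_equal(rk2$gene[rk2$cell_type == "a" & rk2$rank == 1], "hit")

  expect_error(rank_velocity_genes(V, rep("a", n)), "2 cell types")
})
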