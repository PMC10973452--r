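test_that("subject means aggregate cells per type with absence giving NaN", {
  cells <- data.frame(barcode = paste0("b", 1:5),
                      subject_id = c("s1", "s1", "s2", "s2", "s2"),
                      cell_type = c("excitatory", "excitatory", "excitatory",
                                    "microglia", "microglia"))
  V <- rbind(1, 3, 5, 2, 4) %*% t(c(1, 1))
  sgm <- subject_mean_velocity(V, cells)
  expect_equal(unname(sgm$excitatory$mean["s1", ]), c(2, 2))   # mean(1, 3)
  expect_equal(unname(sgm$excitatory$mean["s2", ]), c(5, 5))   # single cell
  expect_true(all(is.nan(sgm$microglia$mean["s1", ])))         # lacks the type
  expect_equal(unname(sgm$microglia$n_cells["s1"]), 0L)
  expect_equal(unname(sgm$microglia$mean["s2", ]), c(3, 3))
})

test_that("partial Spearman reduces to Spearman and kills perfect confounding", {
  set.seed(31)
  x <- rnorm(100); y <- x + rnorm(100)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_lt(ps$p, 1e-4)

  # y identical to a covariate: residualizing removes all signal
  z <- rnorm(100)
  ps2 <- partial_spearman(x, z, covariates = data.frame(z = z))
  expect_lt(abs(ps2$rho), 1e-8)

  expect_match(partial_spearman(rnorm(3), rnorm(3),
                                covariates = data.frame(a = rnorm(3)))$reason,
               "insufficient")
})

test_that("partial Spearman matches an independent rank/QR/Pearson oracle", {
  oracle <- function(x, y, Z) {
    rx <- rank(x); ry <- rank(y)
    D <- cbind(1, apply(as.matrix(Z), 2, rank))
    qx <- qr.resid(qr(D), rx); qy <- qr.resid(qr(D), ry)
    rho <- cor(qx, qy)
    n <- length(x); k <- ncol(as.matrix(Z))
    tv <- rho * sqrt((n - 2 - k) / (1 - rho^2))
    list(rho = rho, p = 2 * pt(-abs(tv), n - 2 - k))
  }
  set.seed(55)
  for (i in 1:25) {
    n <- 30
    x <- rnorm(n) + sample(0:1, n, TRUE)          # ties in ranks
    y <- 0.4 * x + rnorm(n)
    Z <- data.frame(a = rnorm(n), b = runif(n))
    got <- partial_spearman(x, y, Z)
    want <- oracle(x, y, Z)
    expect_equal(got$rho, want$rho, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("rho is invariant under monotone transforms of either variable", {
  set.seed(9)
  x <- rexp(25); y <- rnorm(25); Z <- data.frame(a = rnorm(25))
  base <- partial_spearman(x, y, Z)
  expect_equal(partial_spearman(log(x), y, Z)$rho, base$rho, tolerance = 1e-12)
  expect_equal(partial_spearman(x, exp(y), Z)$rho, base$rho, tolerance = 1e-12)
})

test_that("planted trait couplings surface as top associations", {
  cfg <- sim_config(n_genes = 80, n_dynamic_genes = 8, n_de_genes = 0,
                    n_subjects_per_group = 12, n_cells_per_subject = 60,
                    cell_types = "excitatory", trait_noise = 0.3, seed = 23)
  ds <- generate_cohort(cfg)
  sgm <- subject_mean_velocity(true_velocity(ds), ds$cells,
                               subjects = ds$subjects$subject_id)
  ta <- trait_association(sgm, ds$subjects, traits = "np", alpha = 0.001)
  tab <- ta$table[order(ta$table$p), ]
  planted <- sprintf("gene%04d", ds$truth$trait_coupling$np$gene)
  expect_lte(match(planted, tab$gene), 2)
  expect_lt(tab$p_fwer[match(planted, tab$gene)], 0.001)

  # Holm within family: single-gene family has p_fwer = p
  one <- list(excitatory = list(mean = sgm$excitatory$mean[, 1, drop = FALSE],
                                n_cells = sgm$excitatory$n_cells))
  ta1 <- trait_association(one, ds$subjects, traits = "np")
  expect_equal(ta1$table$p_fwer, ta1$table$p)
  # Holm dominates Bonferroni and is bounded below by p
  expect_true(all(ta$table$p_fwer <= pmin(nrow(ta$table) * ta$table$p, 1) + 1e-12))
  expect_true(all(ta$table$p_fwer >= ta$table$p - 1e-12))
})

test_that("recovery strengthens with the coupling weight", {
  # traits built directly with fixed absolute noise so the weight matters
  cfg <- sim_config(n_genes = 60, n_dynamic_genes = 6, n_de_genes = 0,
                    n_subjects_per_group = 10, n_cells_per_subject = 50,
                    cell_types = "excitatory", seed = 37)
  ds <- generate_cohort(cfg)
  sgm <- subject_mean_velocity(true_velocity(ds), ds$cells,
                               subjects = ds$subjects$subject_id)
  m_g <- sgm$excitatory$mean[, 1]
  set.seed(2)
  noise <- rnorm(length(m_g), 0, sd(m_g))
  meta <- ds$subjects
  pvals <- vapply(c(0.25, 1, 4), function(w) {
    meta$np <- w * m_g[meta$subject_id] + noise
    ta <- trait_association(sgm, meta, traits = "np")
    ta$table$p[ta$table$gene == "gene0001"]
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})

test_that("an independent trait yields no FWER-significant genes", {
  set.seed(44)
  hits <- replicate(10, {
    n_subj <- 20
    sgm <- list(excitatory = list(
      mean = matrix(rnorm(n_subj * 300), n_subj,
                    dimnames = list(paste0("s", 1:n_subj), paste0("g", 1:300))),
      n_cells = stats::setNames(rep(10L, n_subj), paste0("s", 1:n_subj))))
    meta <- data.frame(subject_id = paste0("s", 1:n_subj), group = "AD",
                       age = rnorm(n_subj, 85), sex = sample(c("F", "M"), n_subj, TRUE),
                       education = rnorm(n_subj, 18), pmi = rexp(n_subj, 1 / 7),
                       np = rnorm(n_subj))
    ta <- trait_association(sgm, meta, traits = "np", alpha = 0.001)
    sum(ta$table$significant)
  })
  expect_gte(mean(hits == 0), 0.9)
})
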