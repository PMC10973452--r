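test_that("fold changes follow the documented sign rules", {
  v <- cbind(a = c(2, 2, 1, 1), b = c(1, 3, 1, 3), c = c(0.2, 0.2, -0.2, -0.2),
             d = c(-2, -2, -1, -1))
  g <- factor(c("ctrl", "ctrl", "AD", "AD"), levels = c("ctrl", "AD"))
  fc <- group_fold_change(v, g)
  expect_equal(fc$log2fc[1], -1)                   # means 1 vs 2
  expect_equal(fc$log2fc[2], 0)                    # equal means
  expect_true(fc$sign_discordant[3])               # +0.2 vs -0.2
  expect_true(is.na(fc$log2fc[3]))
  expect_equal(fc$log2fc[4], -1)                   # both negative: magnitudes
  expect_false(fc$sign_discordant[4])
  expect_error(group_fold_change(v, factor(rep("a", 4))), "two levels")
})

test_that("all-equal values give U = n1*n2/2 and p = 1", {
  vals <- matrix(1, 24, 3)
  grp <- rep(c("ctrl", "AD"), each = 12)
  subj <- rep(paste0("s", 1:6), each = 4)
  res <- wilcoxon_permutation(vals, grp, subj, n_perm = 99, seed = 1)
  expect_equal(res$u_stat, rep(12 * 12 / 2, 3))
  expect_equal(res$p_emp, rep(1, 3))
})

test_that("Monte-Carlo permutation null converges to the exact enumeration", {
  # 4 subjects, 2 per group: C(4,2) = 6 equally likely reassignments
  set.seed(8)
  n_per <- 10
  subj <- rep(paste0("s", 1:4), each = n_per)
  grp <- rep(c("a", "a", "b", "b"), each = n_per)
  x <- rnorm(40) + rep(c(1.2, 0, 0.3, 0.1), each = n_per)

  # exact oracle: enumerate all subject reassignments
  combs <- combn(4, 2)
  devs <- apply(combs, 2, function(pick) {
    in_a <- subj %in% paste0("s", pick)
    u <- u_stat_oracle(x, in_a)
    abs(u - sum(in_a) * sum(!in_a) / 2)
  })
  u_obs <- u_stat_oracle(x, grp == "a")
  d_obs <- abs(u_obs - 400 / 2)
  p_exact_limit <- mean(devs >= d_obs - 1e-12)

  res <- wilcoxon_permutation(x, grp, subj, n_perm = 6000, seed = 42)
  expect_equal(res$u_stat, u_obs)
  # add-one Monte-Carlo estimate converges to the enumeration value
  expect_lt(abs(res$p_emp - p_exact_limit), 0.03)
})

test_that("permutation p is deterministic given the seed and rank-invariant", {
  set.seed(12)
  x <- matrix(rnorm(60 * 4), 60, 4)
  grp <- rep(c("a", "b"), each = 30)
  subj <- rep(paste0("s", 1:6), each = 10)
  r1 <- wilcoxon_permutation(x, grp, subj, n_perm = 200, seed = 7)
  r2 <- wilcoxon_permutation(x, grp, subj, n_perm = 200, seed = 7)
  expect_identical(r1$p_emp, r2$p_emp)
  # U is invariant under strictly monotone transforms
  r3 <- wilcoxon_permutation(exp(x), grp, subj, n_perm = 200, seed = 7)
  expect_identical(r1$u_stat, r3$u_stat)
  expect_identical(r1$p_emp, r3$p_emp)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.7), 0.7)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
})

test_that("significance calls apply both thresholds, honouring discordance", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    q = c(0.01, 0.04, 0.06, 0.2, 0.01, 0.03),
                    log2fc = c(0.3, 0.1, 0.5, 0.3, 0.26, 0.24),
                    sign_discordant = FALSE)
  out <- call_significant(tab)
  expect_equal(out$gene, c("g1", "g5"))
  # discordant rows pass the fold-change gate
  tab$sign_discordant[2] <- TRUE
  expect_equal(call_significant(tab)$gene, c("g1", "g2", "g5"))
  expect_equal(nrow(call_significant(tab[0, ])), 0)
})

test_that("planted kinetic effects are called and null genes stay controlled", {
  # per-subject moment smoothing keeps subject-level exchangeability; the
  # planted fraction is kept small (10 of 500) so size-normalization does
  # not redistribute the group effect into null genes, and 12 subjects
  # per group keep the permutation floor below what BH needs
  cfg <- sim_config(n_genes = 500, n_dynamic_genes = 10, n_de_genes = 0,
                    n_subjects_per_group = 12, n_cells_per_subject = 100,
                    cell_types = "excitatory", group_effect_gamma = 2,
                    time_mode = "independent", seed = 55)
  ds <- generate_cohort(cfg)
  norm <- normalize_counts(ds$counts, "velocity_layers")
  mom <- neighbor_moments(norm$S, norm$U, n_pcs = 30, k = 30,
                          by = ds$cells$subject_id)
  V <- compute_velocity(mom, fit_gamma(mom, "stochastic"))
  tab <- differential_table(V$V, ds$cells, "velocity", n_perm = 2000, seed = 56)
  truth <- ds$truth$labels[match(tab$gene, ds$counts$features$id)]
  called <- tab$gene %in% call_significant(tab)$gene
  expect_equal(sum(called & truth == "dynamic"), 10)
  expect_lte(sum(called & truth == "null"), 5)
})

test_that("length-bias check behaves at the boundaries and under dependence", {
  lens <- c(100, 200, 400, 800, 1600)
  expect_warning(r <- length_bias_check(rep(3, 5), lens), "constant")
  expect_true(r$undefined)
  r2 <- length_bias_check(2 * lens + 5, lens)
  expect_equal(r2$correlation, 1, tolerance = 1e-12)
  expect_error(length_bias_check(1:3, c(1, -1, 2)), "> 0")

  # independent statistics and lengths: correlation near zero almost always
  set.seed(30)
  hits <- replicate(60, {
    r <- length_bias_check(rnorm(1000), rexp(1000) * 1e4 + 500)
    abs(r$correlation) < 0.08 & r$p > 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("differential_table integrates the pieces per cell type", {
  set.seed(5)
  n <- 80
  cells <- data.frame(
    barcode = paste0("b", 1:n),
    subject_id = rep(paste0("s", 1:8), each = 10),
    cell_type = rep(c("excitatory", "astrocyte"), n / 2),
    group = rep(c("control", "AD"), each = n / 2)
  )
  vals <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  vals[cells$group == "AD", 1] <- vals[cells$group == "AD", 1] + 4
  tab <- differential_table(vals, cells, "velocity", n_perm = 300, seed = 3)
  expect_setequal(unique(tab$cell_type), c("excitatory", "astrocyte"))
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$p_emp > 0 & tab$p_emp <= 1))
  # q-values computed within each cell type family
  for (tp in c("excitatory", "astrocyte")) {
    sub <- tab[tab$cell_type == tp, ]
    expect_equal(sub$q, fdr_adjust(sub$p_emp))
  }
  # with 4 subjects per group the two-sided permutation floor is ~2/C(8,4)
  g1 <- tab[tab$gene == "g1", ]
  expect_true(all(g1$p_emp <= 0.05))
})
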