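#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-subject, multi-cell-type single-nucleus cohort generated
#' from the transcription-splicing-degradation kinetic model. Genes fall into
#' three truth classes:
#' \describe{
#'   \item{dynamic}{cells traverse the induction/repression trajectory; the
#'     affected group's degradation rate gamma is multiplied by
#'     `group_effect_gamma`, so the two groups differ in kinetics (velocity)
#'     only.}
#'   \item{de}{constitutively expressed: cells sit at the kinetic steady
#'     state, where expected velocity is zero in both groups; the affected
#'     group's transcription rate alpha is multiplied by
#'     `group_effect_alpha`, so the groups differ in expression only.}
#'   \item{null}{trajectory genes with identical kinetics in both groups.}
#' }
#'
#' The splicing rate beta is fixed to 1 for all genes (only gamma/beta is
#' identifiable from unspliced/spliced ratios); per-cell latent times are
#' uniform on `[0, t_max]` and each gene observes them through its own
#' random phase offset (mod the `2 * t_switch` cycle), so both kinetic
#' phases are populated and genes are desynchronized.
#' Subject heterogeneity enters as independent log-normal multipliers of
#' alpha per (subject, gene) (`subject_alpha_sd`), which induces the
#' within-subject correlation of cells that subject-level permutation
#' testing must respect. Neuropathology traits are linear combinations of
#' the subject-mean true velocity of designated genes plus Gaussian noise.
#'
#' @param n_genes total number of genes (default 200).
#' @param n_dynamic_genes,n_de_genes number of dynamic / DE genes
#'   (their sum must not exceed `n_genes`).
#' @param n_subjects_per_group subjects per group (default 24, the cohort
#'   size of a balanced postmortem study arm).
#' @param n_cells_per_subject cells per subject (default 100).
#' @param cell_types character vector of cell-type labels (default the six
#'   major cortical types).
#' @param groups two group labels; the second is the affected group.
#' @param group_effect_gamma multiplicative factor (> 0) applied to gamma of
#'   dynamic genes in the affected group (default 2).
#' @param group_effect_alpha multiplicative factor (> 0) applied to alpha of
#'   DE genes in the affected group (default 2).
#' @param trait_coupling named list: for each trait, a data.frame with
#'   columns `gene` (index or name) and `weight`. `NULL` (default) couples
#'   each of the four traits (np, nft, amyloid, tangles) to one distinct
#'   dynamic gene with weight 0.8.
#' @param trait_noise trait noise standard deviation, as a fraction of the
#'   across-subject standard deviation of the coupled signal (default 0.5).
#' @param noise counting-noise family: `list(family = "poisson")` (default)
#'   or `list(family = "nb", dispersion = d)` with NB variance
#'   `mu + d * mu^2`.
#' @param subject_alpha_sd sdlog of the per-(subject, gene) log-normal
#'   alpha multiplier (default 0.1).
#' @param type_alpha_sd sdlog of the per-(gene, cell type) log-normal alpha
#'   multiplier creating cell-type-specific dynamics (default 0.3).
#' @param cell_size_sd sdlog of the per-cell log-normal capture-efficiency
#'   factor applied to both layers (default 0.1); removed by per-cell
#'   normalization.
#' @param t_switch latent time of the induction-to-repression switch
#'   (default 8; with beta = 1 the trajectory then essentially reaches both
#'   steady states, the regime the steady-state estimator assumes for
#'   extreme-quantile cells).
#' @param t_max width of the latent-time window cells are drawn from,
#'   uniform on `[0, t_max]` (default `1.5 * t_switch`). A window narrower
#'   than the full `2 * t_switch` cycle mimics a tissue snapshot that does
#'   not sample a closed kinetic cycle uniformly: the net drift left over
#'   is a non-zero mean velocity whose size depends on gamma, which is
#'   what group comparisons detect.
#' @param time_mode `"shared"` (default) or `"independent"`. Shared: one
#'   latent time per cell, read by every gene through its phase offset —
#'   cells progress coherently, the regime embedding/field analyses
#'   assume, but gene-level statistics are then correlated through each
#'   subject's time draw. Independent: every (cell, gene) pair draws its
#'   own phase (asynchronous transcriptional bursting), making null genes
#'   statistically independent — the regime for gene-level calibration
#'   studies.
#' @param phase `"trajectory"` (default) or `"equilibrium"`; in equilibrium
#'   mode every gene is at steady state and cells spread along the
#'   steady-state line through independent per-(cell, gene) log-normal
#'   activity factors (sdlog 0.5) — expression fluctuation around steady
#'   state — the regime used for slope-recovery experiments.
#' @param gamma optional length-`n_genes` vector of true gamma/beta values
#'   (default drawn uniformly from [0.2, 1]).
#' @param seed integer seed; fixed seed implies identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_dynamic_genes = 20, n_de_genes = 20,
                       n_subjects_per_group = 24, n_cells_per_subject = 100,
                       cell_types = c("excitatory", "inhibitory", "astrocyte",
                                      "microglia", "oligodendrocyte", "OPC"),
                       groups = c("control", "AD"),
                       group_effect_gamma = 2, group_effect_alpha = 2,
                       trait_coupling = NULL, trait_noise = 0.5,
                       noise = list(family = "poisson"),
                       subject_alpha_sd = 0.1, type_alpha_sd = 0.3,
                       cell_size_sd = 0.1, t_switch = 8, t_max = NULL,
                       time_mode = c("shared", "independent"),
                       phase = c("trajectory", "equilibrium"),
                       gamma = NULL, seed = 1L) {
  phase <- match.arg(phase)
  time_mode <- match.arg(time_mode)
  if (n_genes < 1 || n_subjects_per_group < 1 || n_cells_per_subject < 1)
    stop("infeasible config: need at least one gene, subject and cell")
  if (n_dynamic_genes + n_de_genes > n_genes)
    stop("infeasible config: n_dynamic_genes + n_de_genes exceeds n_genes")
  if (group_effect_gamma <= 0 || group_effect_alpha <= 0)
    stop("infeasible config: group effect factors must be > 0")
  if (length(groups) != 2) stop("infeasible config: exactly two groups required")
  if (!is.null(gamma) && (length(gamma) != n_genes || any(gamma <= 0)))
    stop("infeasible config: gamma must be a positive vector of length n_genes")
  if (!noise$family %in% c("poisson", "nb"))
    stop("infeasible config: noise family must be 'poisson' or 'nb'")
  if (is.null(t_max)) t_max <- 1.5 * t_switch
  if (t_max <= 0 || t_max > 2 * t_switch)
    stop("infeasible config: t_max must lie in (0, 2 * t_switch]")
  structure(list(
    n_genes = n_genes, n_dynamic_genes = n_dynamic_genes, n_de_genes = n_de_genes,
    n_subjects_per_group = n_subjects_per_group,
    n_cells_per_subject = n_cells_per_subject,
    cell_types = cell_types, groups = groups,
    group_effect_gamma = group_effect_gamma, group_effect_alpha = group_effect_alpha,
    trait_coupling = trait_coupling, trait_noise = trait_noise, noise = noise,
    subject_alpha_sd = subject_alpha_sd, type_alpha_sd = type_alpha_sd,
    cell_size_sd = cell_size_sd, t_switch = t_switch, t_max = t_max,
    time_mode = time_mode, phase = phase,
    gamma = gamma, seed = as.integer(seed)
  ), class = "sim_config")
}

# vectorised closed form over cells (alpha varies per cell, rates scalar)
.expected_us <- function(alpha, beta, gamma, t, t_switch) {
  u <- s <- numeric(length(t))
  ind <- t <= t_switch
  if (any(ind)) {
    r <- .kinetics_closed_form(alpha[ind], beta, gamma, t[ind], 0, 0)
    u[ind] <- r$u; s[ind] <- r$s
  }
  if (any(!ind)) {
    sw <- .kinetics_closed_form(alpha[!ind], beta, gamma, t_switch, 0, 0)
    # repression: alpha = 0 from the switch state; u0 varies per cell
    tau <- t[!ind] - t_switch
    eb <- exp(-beta * tau); eg <- exp(-gamma * tau)
    dif <- if (abs(gamma - beta) < 1e-10 * max(gamma, beta)) -tau * eb
           else (eg - eb) / (gamma - beta)
    u[!ind] <- sw$u * eb
    s[!ind] <- sw$s * eg + (0 - beta * sw$u) * dif
  }
  list(u = u, s = s)
}

#' Generate a synthetic multi-subject cohort with known kinetic ground truth
#'
#' Draws subjects, cells, per-gene kinetic parameters and spliced/unspliced
#' counts according to a [sim_config()]. See that help page for the
#' generative model.
#'
#' @param config a [sim_config()] object.
#' @return A `synthetic_dataset` list with components
#'   \describe{
#'     \item{counts}{`count_layers`: sparse spliced `S` and unspliced `U`
#'       cells x genes matrices plus `barcodes` and `features`.}
#'     \item{cells}{per-cell annotation (barcode, subject_id, cell_type, group).}
#'     \item{subjects}{per-subject metadata (group, age, sex, education, pmi,
#'       and traits np, nft, amyloid, tangles).}
#'     \item{truth}{gene labels, per-group true kinetic parameters, per-cell
#'       latent time, the per-cell x gene expected velocity matrix
#'       `velocity_true`, and all sampled multipliers.}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  G <- config$n_genes
  n_subj <- 2L * config$n_subjects_per_group
  n_cells <- n_subj * config$n_cells_per_subject

  ## gene-level truth
  labels <- rep("null", G)
  if (config$n_dynamic_genes > 0) labels[seq_len(config$n_dynamic_genes)] <- "dynamic"
  if (config$n_de_genes > 0)
    labels[config$n_dynamic_genes + seq_len(config$n_de_genes)] <- "de"
  gene_ids <- sprintf("gene%04d", seq_len(G))
  gamma0 <- if (is.null(config$gamma)) stats::runif(G, 0.2, 1) else config$gamma
  alpha0 <- exp(stats::rnorm(G, log(5), 0.5))
  beta <- 1

  grp_aff <- config$groups[2]
  params <- lapply(config$groups, function(g) {
    gam <- gamma0
    alp <- alpha0
    if (g == grp_aff) {
      gam[labels == "dynamic"] <- gam[labels == "dynamic"] * config$group_effect_gamma
      alp[labels == "de"] <- alp[labels == "de"] * config$group_effect_alpha
    }
    data.frame(gene = gene_ids, alpha = alp, beta = beta, gamma = gam,
               t_switch = config$t_switch)
  })
  names(params) <- config$groups

  ## subjects
  subject_id <- sprintf("subj%03d", seq_len(n_subj))
  group <- rep(config$groups, each = config$n_subjects_per_group)
  sex <- unlist(lapply(config$groups, function(g) {
    n <- config$n_subjects_per_group
    sample(rep(c("F", "M"), length.out = n))
  }))
  subjects <- data.frame(
    subject_id = subject_id, group = group,
    age = round(stats::rnorm(n_subj, 86, 4), 1), sex = sex,
    education = round(stats::rnorm(n_subj, 18, 2.5), 1),
    pmi = round(stats::rgamma(n_subj, shape = 4, rate = 4 / 7), 2),
    stringsAsFactors = FALSE
  )

  ## cells
  barcode <- sprintf("bc%06d", seq_len(n_cells))
  cell_subject <- rep(subject_id, each = config$n_cells_per_subject)
  cell_group <- rep(group, each = config$n_cells_per_subject)
  cell_type <- sample(config$cell_types, n_cells, replace = TRUE)
  latent_time <- stats::runif(n_cells, 0, config$t_max)
  cells <- data.frame(barcode = barcode, subject_id = cell_subject,
                      cell_type = cell_type, group = cell_group,
                      stringsAsFactors = FALSE)

  ## multiplicative effects
  type_alpha <- matrix(exp(stats::rnorm(G * length(config$cell_types),
                                        0, config$type_alpha_sd)),
                       nrow = G, dimnames = list(gene_ids, config$cell_types))
  subject_alpha <- matrix(exp(stats::rnorm(n_subj * G, 0, config$subject_alpha_sd)),
                          nrow = n_subj, dimnames = list(subject_id, gene_ids))
  size_factor <- exp(stats::rnorm(n_cells, 0, config$cell_size_sd))
  # equilibrium mode: per-(cell, gene) log-normal activity spreads cells
  # along each gene's steady-state line; a factor shared across genes
  # would be removed by per-cell size normalization and leave no spread
  activity <- if (config$phase == "equilibrium")
    matrix(exp(stats::rnorm(n_cells * G, 0, 0.5)), n_cells, G)
  else matrix(1, 1, 1)

  subj_idx <- match(cell_subject, subject_id)
  type_idx <- match(cell_type, config$cell_types)

  # genes are desynchronized by a per-gene phase offset: genes in a real
  # cell do not switch in unison, and synchronizing them would make the
  # per-cell totals track the kinetic phase instead of capture efficiency.
  # Designated dynamic genes get offsets placing their sampled window where
  # the trajectory leaves a net drift: a gene whose window balances to zero
  # drift has no observable dynamic difference to label as ground truth.
  gene_offset <- stats::runif(G, 0, 2 * config$t_switch)
  is_dyn <- labels == "dynamic"
  gene_offset[is_dyn] <- stats::runif(sum(is_dyn), 0.5 * config$t_switch,
                                      0.875 * config$t_switch)
  time_ind <- if (config$time_mode == "independent")
    matrix(stats::runif(n_cells * G, 0, config$t_max), n_cells, G)

  EU <- ES <- Vtrue <- matrix(0, n_cells, G,
                              dimnames = list(barcode, gene_ids))
  for (g in seq_len(G)) {
    steady <- config$phase == "equilibrium" || labels[g] == "de"
    for (grp in config$groups) {
      cg <- which(cell_group == grp)
      p <- params[[grp]]
      a_eff <- p$alpha[g] * type_alpha[g, type_idx[cg]] *
        subject_alpha[cbind(subj_idx[cg], g)]
      if (config$phase == "equilibrium") a_eff <- a_eff * activity[cg, g]
      gam <- p$gamma[g]
      if (steady) {
        EU[cg, g] <- a_eff / beta
        ES[cg, g] <- a_eff / gam
        # Vtrue stays 0: beta*u - gamma*s vanishes at steady state
      } else {
        tcell <- if (config$time_mode == "independent") time_ind[cg, g]
                 else latent_time[cg]
        tg <- (tcell + gene_offset[g]) %% (2 * config$t_switch)
        r <- .expected_us(a_eff, beta, gam, tg, config$t_switch)
        EU[cg, g] <- r$u
        ES[cg, g] <- r$s
        Vtrue[cg, g] <- beta * r$u - gam * r$s
      }
    }
  }

  ## counts
  mu_u <- EU * size_factor
  mu_s <- ES * size_factor
  draw <- function(mu) {
    x <- if (config$noise$family == "poisson") stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), mu = mu, size = 1 / config$noise$dispersion)
    matrix(x, nrow(mu), ncol(mu))
  }
  S <- draw(mu_s)
  U <- draw(mu_u)

  ## traits: weighted subject-mean true velocity of coupled genes + noise
  coupling <- config$trait_coupling
  if (is.null(coupling)) {
    dyn <- which(labels == "dynamic")
    traits <- c("np", "nft", "amyloid", "tangles")
    coupling <- list()
    if (length(dyn) > 0) {
      picks <- rep(dyn, length.out = length(traits))
      for (i in seq_along(traits))
        coupling[[traits[i]]] <- data.frame(gene = picks[i], weight = 0.8)
    } else {
      for (tr in traits) coupling[[tr]] <- data.frame(gene = integer(), weight = numeric())
    }
  }
  # trait noise scales with the pooled within-group signal sd: pathology
  # severity differs between groups by construction, but the association
  # analysis runs within a group, so that is the variation the noise must
  # be commensurate with for couplings to be recoverable yet noisy
  subj_mean_v <- apply(Vtrue, 2, function(v) tapply(v, subj_idx, mean))
  for (tr in names(coupling)) {
    cp <- coupling[[tr]]
    gi <- if (is.character(cp$gene)) match(cp$gene, gene_ids) else cp$gene
    sig <- if (nrow(cp) > 0)
      as.vector(subj_mean_v[, gi, drop = FALSE] %*% cp$weight) else numeric(n_subj)
    s_w <- sqrt(mean(tapply(sig, group, stats::var)))
    if (!is.finite(s_w) || s_w == 0) s_w <- 1e-6
    subjects[[tr]] <- sig + stats::rnorm(n_subj, 0, config$trait_noise * s_w)
  }

  features <- data.frame(id = gene_ids, symbol = toupper(gene_ids),
                         length = sample(500:200000, G, replace = TRUE),
                         stringsAsFactors = FALSE)
  counts <- count_layers(S = Matrix::Matrix(S, sparse = TRUE),
                         U = Matrix::Matrix(U, sparse = TRUE),
                         barcodes = barcode, features = features)

  structure(list(
    counts = counts, cells = cells, subjects = subjects,
    truth = list(labels = labels, params = params, latent_time = latent_time,
                 gene_offset = gene_offset,
                 velocity_true = Vtrue, expected_u = EU, expected_s = ES,
                 type_alpha = type_alpha, subject_alpha = subject_alpha,
                 size_factor = size_factor, activity = activity,
                 trait_coupling = coupling, config = config)
  ), class = "synthetic_dataset")
}

# minimal Matrix-Market coordinate writer for integer count matrices;
# Matrix::writeMM emits a "real" header, but counts are declared integer here.
.write_mtx_integer <- function(m, path) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  tm <- Matrix::summary(m)  # 1-based triplets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(tm)), con)
  if (nrow(tm) > 0)
    writeLines(sprintf("%d %d %d", tm$i, tm$j, as.integer(tm$x)), con)
  invisible(path)
}

#' Write a synthetic dataset to disk in exchange formats
#'
#' Emits `spliced.mtx` and `unspliced.mtx` (Matrix-Market coordinate,
#' 1-based indices, integer general), `barcodes.tsv`, `features.tsv`,
#' `cells.tsv`, `subjects.tsv` and `truth.json`. [read_matrices()] on the
#' output directory recovers the count layers exactly. `truth.json` holds
#' the per-gene labels, per-group kinetic parameters, per-cell latent times
#' and trait couplings; the dense expected-value matrices stay in the
#' in-memory object only.
#'
#' @param ds a `synthetic_dataset` from [generate_cohort()].
#' @param directory output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, directory) {
  if (!inherits(ds, "synthetic_dataset")) stop("ds must be a synthetic_dataset")
  if (!dir.exists(directory) && !dir.create(directory, recursive = TRUE))
    stop("cannot create directory: ", directory)
  fp <- function(x) file.path(directory, x)
  .write_mtx_integer(ds$counts$S, fp("spliced.mtx"))
  .write_mtx_integer(ds$counts$U, fp("unspliced.mtx"))
  writeLines(ds$counts$barcodes, fp("barcodes.tsv"))
  utils::write.table(ds$counts$features, fp("features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$cells, fp("cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$subjects, fp("subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  jsonlite::write_json(list(
    labels = truth$labels,
    genes = ds$counts$features$id,
    params = truth$params,
    latent_time = truth$latent_time,
    trait_coupling = truth$trait_coupling,
    seed = truth$config$seed
  ), fp("truth.json"), auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(directory)
}

#' Expected (noise-free) velocity matrix of a synthetic dataset
#'
#' @param ds a `synthetic_dataset`.
#' @return cells x genes matrix of true expected velocities beta*u - gamma*s.
#' @export
true_velocity <- function(ds) {
  if (!inherits(ds, "synthetic_dataset")) stop("ds must be a synthetic_dataset")
  ds$truth$velocity_true
}
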