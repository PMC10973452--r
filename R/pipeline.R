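#' Assemble a pipeline configuration
#'
#' Collects stage parameters for [run_pipeline()]. Any element can be
#' overridden; defaults run the full analysis on a synthetic cohort.
#'
#' @param out_dir output directory for stage results and the manifest.
#' @param seed master seed; stage seeds derive from it.
#' @param simulate list of [sim_config()] arguments (used when `input_dir`
#'   is `NULL`).
#' @param input_dir optional directory with user data in the layout of
#'   [write_dataset()] (including `cells.tsv` and `subjects.tsv`).
#' @param exclude_types cell types dropped during harmonization.
#' @param velocity list: `k`, `n_pcs`, `mode`, `quantile_pair`,
#'   `per_subject` (restrict moment smoothing to each subject's own cells;
#'   default FALSE, i.e. cells pooled across subjects).
#' @param differential list: `n_perm`, `q_thresh`, `fc_thresh`,
#'   `stratify_by` (`NULL` or `"sex"`).
#' @param fields list: `grid_size`, `z_thresh`.
#' @param assoc list: `traits`, `covariates`, `alpha`, `group`.
#' @param overlap list: `enabled` plus [sim_config()] overrides for the
#'   replication cohort.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("velodelta_run_"), seed = 1,
                            simulate = list(), input_dir = NULL,
                            exclude_types = character(),
                            velocity = list(), differential = list(),
                            fields = list(), assoc = list(),
                            overlap = list(enabled = FALSE)) {
  merge_defaults <- function(x, d) { d[names(x)] <- x; d }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
    input_dir = input_dir, exclude_types = exclude_types,
    velocity = merge_defaults(velocity, list(k = 100, n_pcs = 30,
                                             mode = "stochastic",
                                             quantile_pair = c(0.05, 0.95),
                                             per_subject = FALSE)),
    differential = merge_defaults(differential,
                                  list(n_perm = 5000, q_thresh = 0.05,
                                       fc_thresh = 0.25, stratify_by = NULL)),
    fields = merge_defaults(fields, list(grid_size = 50, z_thresh = 1.96)),
    assoc = merge_defaults(assoc, list(traits = c("np", "nft", "amyloid", "tangles"),
                                       covariates = c("age", "sex", "education", "pmi"),
                                       alpha = 0.001, group = NULL)),
    overlap = merge_defaults(overlap, list(enabled = FALSE))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    call_txt <- paste(deparse(conditionCall(e)), collapse = " ")
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         if (nzchar(call_txt) && call_txt != "NULL") paste0(" [in ", call_txt, "]"),
         call. = FALSE)
  })
}

#' Run the differential RNA-velocity pipeline end to end
#'
#' Executes: data (simulate or ingest) -> preprocess (harmonize,
#' normalize) -> velocity (moments, gamma fit, velocity matrix, gene
#' ranking) -> differential velocity and expression (subject-level
#' permutation tests, optionally stratified by sex) -> cell speed and
#' residual velocity fields -> trait association -> optional cross-dataset
#' overlap against a replication cohort. Stage outputs are written as
#' TSV/JSON under `out_dir` and a manifest records parameters, seeds and
#' per-file checksums; a rerun with the same config and seed reproduces
#' identical checksums.
#'
#' @param config a [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x) file.path(config$out_dir, x)
  wtsv <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                             quote = FALSE, row.names = FALSE)

  ## data
  ds <- .stage("data", {
    if (is.null(config$input_dir)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      generate_cohort(do.call(sim_config, sim_args))
    } else {
      counts <- read_matrices(config$input_dir)
      cells <- utils::read.table(file.path(config$input_dir, "cells.tsv"),
                                 sep = "\t", header = TRUE, stringsAsFactors = FALSE)
      subjects <- utils::read.table(file.path(config$input_dir, "subjects.tsv"),
                                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
      list(counts = counts, cells = cells, subjects = subjects, truth = NULL)
    }
  })

  ## preprocess
  prep <- .stage("preprocess", {
    h <- harmonize(ds$counts, ds$cells, exclude_types = config$exclude_types)
    norm <- normalize_counts(h$counts, "velocity_layers")
    cells <- h$cells[!(h$cells$barcode %in% norm$dropped), , drop = FALSE]
    expr <- normalize_counts(h$counts, "expression")
    expr <- expr[cells$barcode, , drop = FALSE]
    list(norm = norm, expr = expr, cells = cells)
  })

  ## velocity
  vel <- .stage("velocity", {
    vc <- config$velocity
    mom <- neighbor_moments(prep$norm$S, prep$norm$U, n_pcs = vc$n_pcs, k = vc$k,
                            by = if (isTRUE(vc$per_subject))
                              prep$cells$subject_id)
    fit <- fit_gamma(mom, mode = vc$mode, quantile_pair = vc$quantile_pair)
    V <- compute_velocity(mom, fit)
    ranking <- rank_velocity_genes(V, prep$cells$cell_type)
    wtsv(ranking, "velocity_gene_ranking.tsv")
    wtsv(data.frame(gene = fit$genes, gamma = fit$gamma, r2 = fit$r2,
                    valid = fit$valid), "gamma_fit.tsv")
    list(moments = mom, fit = fit, V = V, ranking = ranking)
  })

  ## differential (velocity and expression)
  dc <- config$differential
  run_diff <- function(values, cells, metric, seed, tag) {
    tab <- differential_table(values, cells, metric = metric,
                              n_perm = dc$n_perm, seed = seed,
                              q_thresh = dc$q_thresh, fc_thresh = dc$fc_thresh)
    wtsv(tab, paste0("differential_", metric, tag, ".tsv"))
    sig <- call_significant(tab, dc$q_thresh, dc$fc_thresh)
    for (tp in unique(sig$cell_type))
      writeLines(sig$gene[sig$cell_type == tp],
                 out(paste0("significant_", metric, tag, "_", tp, ".txt")))
    tab
  }
  diff <- .stage("differential", {
    strata <- stats::setNames(list(rep(TRUE, nrow(prep$cells))), "")
    if (!is.null(dc$stratify_by)) {
      svals <- ds$subjects[[dc$stratify_by]][match(prep$cells$subject_id,
                                                   ds$subjects$subject_id)]
      strata <- lapply(stats::setNames(unique(svals), paste0("_", unique(svals))),
                       function(v) svals == v)
    }
    res <- list()
    for (si in seq_along(strata)) {
      nm <- names(strata)[si]
      sel <- strata[[si]]
      res[[paste0("velocity", nm)]] <-
        run_diff(vel$V$V[sel, , drop = FALSE], prep$cells[sel, , drop = FALSE],
                 "velocity", config$seed + 1L, nm)
      res[[paste0("expression", nm)]] <-
        run_diff(prep$expr[sel, , drop = FALSE], prep$cells[sel, , drop = FALSE],
                 "expression", config$seed + 2L, nm)
    }
    res
  })

  ## fields and speed
  fld <- .stage("fields", {
    coords <- vel$moments$pcs[, 1:2, drop = FALSE]  # PCA-2D fallback embedding
    grp <- factor(prep$cells$group, levels = unique(prep$cells$group))
    speeds <- cell_speed(vel$V)
    speed_tests <- lapply(stats::setNames(nm = unique(prep$cells$cell_type)),
                          function(tp) {
      sel <- prep$cells$cell_type == tp
      compare_speed(speeds[sel], grp[sel])
    })
    wtsv(data.frame(cell_type = names(speed_tests),
                    median_a = vapply(speed_tests, `[[`, 1, "median_a"),
                    median_b = vapply(speed_tests, `[[`, 1, "median_b"),
                    p = vapply(speed_tests, `[[`, 1, "wilcoxon_p")),
         "speed_tests.tsv")
    emb <- lapply(levels(grp), function(g) {
      sel <- grp == g
      embed_velocity(vel$V$V[sel, , drop = FALSE],
                     vel$moments$Ms[sel, , drop = FALSE],
                     coords[sel, , drop = FALSE],
                     .knn_index(coords[sel, , drop = FALSE],
                                min(15, sum(sel) - 1)))
    })
    fg <- residual_field(emb[[1]], emb[[2]],
                         grid_size = config$fields$grid_size,
                         z_thresh = config$fields$z_thresh)
    wtsv(data.frame(fg$grid_coords, z = fg$z, mask = fg$mask), "residual_field.tsv")
    list(speeds = speeds, speed_tests = speed_tests, grid = fg)
  })

  ## trait association
  assoc <- .stage("association", {
    sgm <- subject_mean_velocity(vel$V, prep$cells,
                                 subjects = ds$subjects$subject_id)
    ta <- trait_association(sgm, ds$subjects, traits = config$assoc$traits,
                            covariates = config$assoc$covariates,
                            alpha = config$assoc$alpha,
                            group = config$assoc$group)
    wtsv(ta$table, "trait_association.tsv")
    ta
  })

  ## optional cross-dataset overlap
  ovl <- NULL
  if (isTRUE(config$overlap$enabled)) {
    ovl <- .stage("overlap", {
      rep_args <- config$overlap
      rep_args$enabled <- NULL
      if (is.null(rep_args$seed)) rep_args$seed <- config$seed + 1000L
      ds2 <- generate_cohort(do.call(sim_config, rep_args))
      norm2 <- normalize_counts(ds2$counts, "velocity_layers")
      cells2 <- ds2$cells[!(ds2$cells$barcode %in% norm2$dropped), , drop = FALSE]
      mom2 <- neighbor_moments(norm2$S, norm2$U, n_pcs = config$velocity$n_pcs,
                               k = config$velocity$k)
      V2 <- compute_velocity(mom2, fit_gamma(mom2, mode = config$velocity$mode))
      tab2 <- differential_table(V2$V, cells2, metric = "velocity",
                                 n_perm = dc$n_perm, seed = config$seed + 3L,
                                 q_thresh = dc$q_thresh, fc_thresh = dc$fc_thresh)
      tab1 <- diff$velocity
      res <- list()
      for (tp in intersect(unique(tab1$cell_type), unique(tab2$cell_type))) {
        uni <- intersect(tab1$gene[tab1$cell_type == tp],
                         tab2$gene[tab2$cell_type == tp])
        res[[tp]] <- fisher_overlap(
          intersect(tab1$gene[tab1$cell_type == tp & tab1$significant], uni),
          intersect(tab2$gene[tab2$cell_type == tp & tab2$significant], uni),
          uni)
      }
      summ <- summarize_overlap(res)
      jsonlite::write_json(list(per_cell_type = lapply(res, unclass),
                                summary = summ),
                           out("overlap.json"), auto_unbox = TRUE, digits = NA)
      list(per_cell_type = res, summary = summ)
    })
  }

  ## manifest
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("velodelta")),
    seed = config$seed,
    parameters = unclass(config)[c("velocity", "differential", "fields", "assoc")],
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, prep = prep, velocity = vel, differential = diff,
                 fields = fld, association = assoc, overlap = ovl,
                 manifest = manifest, out_dir = config$out_dir))
}
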