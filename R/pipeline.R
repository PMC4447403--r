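#' Validate a pipeline configuration
#'
#' Checks types, ranges and referenced input files before any computation.
#'
#' @param config named list (see [run_pipeline()]) or a path to a JSON or
#'   YAML file holding one.
#' @return the normalized configuration list, invisibly classed
#'   `em_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_input("yaml package required to read YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_input("config must be a list or file path")
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop_input("config$seed (integer) is required")
  if (is.null(config$out_dir)) stop_input("config$out_dir is required")
  for (f in c("matrix_tsv", "samples_csv", "cohort_csv", "cq_csv",
              "wells_csv", "assays_csv")) {
    for (sect in c("clone", "cohort", "plate")) {
      p <- config[[sect]][[f]]
      if (!is.null(p) && !file.exists(p))
        stop_input("config$", sect, "$", f, " does not exist: ", p)
    }
  }
  config$signature <- config$signature %||% list()
  config$signature$n_per_direction <-
    config$signature$n_per_direction %||% 30L
  config$signature$k_em <- config$signature$k_em %||%
    min(30L, config$signature$n_per_direction)
  config$signature$alpha <- config$signature$alpha %||% 0.01
  config$permutation <- config$permutation %||% list()
  config$permutation$n_perm <- config$permutation$n_perm %||% 99L
  config$singlecell <- config$singlecell %||% list()
  config$singlecell$fallback <- config$singlecell$fallback %||% 24
  structure(config, class = c("em_config", "list"))
}

#' Run the full E/M analysis pipeline
#'
#' Orchestrates: clone-matrix acquisition (synthetic or from TSV) ->
#' array normalization -> differential expression -> E/M/EM signature
#' composition -> cohort survival evaluation -> random-gene-set
#' permutation -> single-cell Cq processing, state-space projection,
#' co-expression counts and cross-match test. Per-stage tables are
#' written under `out_dir` together with a consolidated JSON report;
#' every random draw is derived from `config$seed`, so a rerun with the
#' same configuration reproduces the report byte for byte.
#'
#' @param config configuration list or file path; see [validate_config()].
#'   Recognized sections (all optional beyond `seed` and `out_dir`):
#'   `clone` (either `matrix_tsv` + `samples_csv` + `group_e`/`group_m`, or
#'   generator arguments for [generate_clone_matrix()]), `signature`
#'   (`n_per_direction`, `k_em`, `alpha`), `cohort` (either `cohort_csv`
#'   or arguments for [generate_cohort()], e.g. `n_patients`, `beta`),
#'   `survival` (`endpoint`, `subtype`), `permutation` (`n_perm`),
#'   `plate` (either `cq_csv` + `wells_csv` or arguments for
#'   [generate_cq_plate()]), `singlecell` (`fallback`, `compare` = two
#'   group labels).
#' @return the report list (also written to `out_dir/report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("emstate")),
                 seed = as.integer(cfg$seed))

  ## --- signatures arm -------------------------------------------------
  clone <- cfg$clone %||% list()
  if (!is.null(clone$matrix_tsv)) {
    mat <- read_expression_matrix(clone$matrix_tsv, clone$samples_csv)
    group_e <- clone$group_e %||% "Eclone"
    group_m <- clone$group_m %||% "Mclone"
  } else {
    gen <- do.call(generate_clone_matrix,
                   c(clone[intersect(names(clone),
                                     names(formals(generate_clone_matrix)))],
                     list(seed = child_seed(cfg$seed, 1))))
    mat <- gen$matrix
    group_e <- "Eclone"; group_m <- "Mclone"
  }
  mat <- normalize_arrays(mat, reference_groups = c(group_e, group_m))
  diff <- derive_differential_genes(mat, group_e, group_m,
                                    alpha = cfg$signature$alpha)
  sigs <- rank_signature(diff, cfg$signature$n_per_direction, cap = TRUE)
  k_em <- min(cfg$signature$k_em, sigs$E$k_e, sigs$M$k_m)
  em_sig <- compose_em_signature(sigs$E, sigs$M, k_em)
  write_gmt(list(sigs$E, sigs$M, em_sig),
            file.path(cfg$out_dir, "signatures.gmt"))
  write_signature_csv(em_sig, file.path(cfg$out_dir, "em_signature.csv"))
  report$signatures <- list(n_e = sigs$E$k_e, n_m = sigs$M$k_m,
                            em_size = nrow(em_sig$members),
                            n_significant = sum(diff$significant))

  ## --- survival arm ---------------------------------------------------
  chrt <- cfg$cohort %||% list()
  if (!is.null(chrt$cohort_csv)) {
    cohort <- read_cohort(chrt$cohort_csv)
  } else {
    gen <- do.call(generate_cohort,
                   c(list(n_patients = chrt$n_patients %||% 300,
                          signature = em_sig,
                          beta = chrt$beta %||% 0.5),
                     chrt[intersect(names(chrt),
                                    setdiff(names(formals(generate_cohort)),
                                            c("n_patients", "signature",
                                              "beta", "seed")))],
                     list(seed = child_seed(cfg$seed, 2))))
    cohort <- gen$cohort
  }
  surv_cfg <- cfg$survival %||% list()
  fit <- evaluate_signature_survival(cohort, em_sig,
                                     endpoint = surv_cfg$endpoint,
                                     subtype = surv_cfg$subtype)
  report$survival <- fit[c("hr", "ci_low", "ci_high", "logrank_chi2",
                           "logrank_p", "cutoff", "n_high", "n_low")]
  perm <- permutation_null(cohort, em_sig,
                           n_perm = cfg$permutation$n_perm,
                           seed = child_seed(cfg$seed, 3),
                           endpoint = surv_cfg$endpoint,
                           subtype = surv_cfg$subtype)
  write.csv(perm$null_stats, file.path(cfg$out_dir, "permutation_null.csv"),
            row.names = FALSE)
  report$permutation <- list(n_perm = perm$n_perm,
                             permuted_p = perm$permuted_p)

  ## --- single-cell arm ------------------------------------------------
  pl <- cfg$plate %||% list()
  if (!is.null(pl$cq_csv)) {
    plate <- read_cq_plate(pl$cq_csv, pl$wells_csv, pl$assays_csv)
  } else {
    gen <- do.call(generate_cq_plate,
                   c(pl[intersect(names(pl),
                                  setdiff(names(formals(generate_cq_plate)),
                                          "seed"))],
                     list(seed = child_seed(cfg$seed, 4))))
    plate <- gen$plate
  }
  profile <- process_cq_plate(plate, fallback = cfg$singlecell$fallback)
  state <- project_em_state(profile)
  write.csv(state, file.path(cfg$out_dir, "state_space.csv"),
            row.names = FALSE)
  compare <- cfg$singlecell$compare %||% {
    gr <- unique(state$group)
    if (length(gr) >= 2L) gr[1:2] else NULL
  }
  counts <- count_coexpressing(profile)
  report$singlecell <- list(n_cells = counts$n_cells,
                            coexpressing = counts$coexpressing,
                            exclusive_e = counts$exclusive_e,
                            exclusive_m = counts$exclusive_m,
                            silent = counts$silent)
  if (!is.null(compare)) {
    sub <- state[state$group %in% compare, , drop = FALSE]
    cm <- crossmatch_test(as.matrix(sub[, c("mean_e", "mean_m")]),
                          sub$group)
    mwu_e <- mann_whitney_u(sub$mean_e[sub$group == compare[1L]],
                            sub$mean_e[sub$group == compare[2L]])
    mwu_m <- mann_whitney_u(sub$mean_m[sub$group == compare[1L]],
                            sub$mean_m[sub$group == compare[2L]])
    report$singlecell$comparison <- list(
      groups = compare, crossmatch_a1 = cm$a1, crossmatch_p = cm$p,
      mwu_p_mean_e = mwu_e$p, mwu_p_mean_m = mwu_m$p)
  }
  pca <- pca_cells(profile$normalized[profile$single_cell, , drop = FALSE])
  write.csv(data.frame(cell_id = state$cell_id,
                       pca$scores[, 1:2, drop = FALSE]),
            file.path(cfg$out_dir, "pca_scores.csv"), row.names = FALSE)
  report$singlecell$pc1_variance <- pca$variance_fraction[1L]

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
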