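#' Default single-cell E and M marker panels
#'
#' The 10 epithelial and 7 mesenchymal genes profiled on the single-cell
#' qPCR chips; both panels can be overridden wherever they are used.
#'
#' @return list with character vectors `E` and `M`.
#' @export
em_panels <- function() {
  list(E = c("CDH1", "CD24", "EPCAM", "IL1B", "KRT5", "LCN2", "TP63",
             "TRAIL", "SLPI", "S100A8"),
       M = c("ABCA6", "DCN", "IL1R1", "PCOLCE", "WNT5A", "VIM", "ZEB2"))
}

#' Construct a single-cell qPCR Cq plate
#'
#' @param cq numeric matrix of raw quantification-cycle values, wells in
#'   rows (rownames = well ids), assays in columns (colnames = gene ids);
#'   `NA` marks no amplification.
#' @param wells data.frame with one row per well: `well_id`, `group`
#'   (annotation label), `cells` (cells per well: 1 or 100; 0 for NTC),
#'   `ntc` (logical, no-template control).
#' @param assays optional data.frame with `gene` and `panel`
#'   (`"E"`/`"M"`/`"other"`); defaults to [em_panels()] membership.
#' @return object of class `cq_plate`.
#' @export
cq_plate <- function(cq, wells, assays = NULL) {
  if (!is.matrix(cq) || is.null(rownames(cq)) || is.null(colnames(cq)))
    stop_input("`cq` must be a matrix with well and assay names")
  if (any(cq <= 0, na.rm = TRUE)) stop_input("Cq values must be positive")
  need <- c("well_id", "group", "cells", "ntc")
  if (!all(need %in% names(wells)))
    stop_input("wells must have columns ", paste(need, collapse = ", "))
  if (!setequal(wells$well_id, rownames(cq)))
    stop_input("wells$well_id must match the Cq rownames")
  wells <- wells[match(rownames(cq), wells$well_id), , drop = FALSE]
  if (is.null(assays)) {
    p <- em_panels()
    assays <- data.frame(gene = colnames(cq),
                         panel = ifelse(colnames(cq) %in% p$E, "E",
                                        ifelse(colnames(cq) %in% p$M, "M",
                                               "other")),
                         stringsAsFactors = FALSE)
  }
  if (!setequal(assays$gene, colnames(cq)))
    stop_input("assays$gene must match the Cq colnames")
  assays <- assays[match(colnames(cq), assays$gene), , drop = FALSE]
  structure(list(cq = cq, wells = wells, assays = assays),
            class = "cq_plate")
}

#' @export
print.cq_plate <- function(x, ...) {
  cat(sprintf("<cq_plate> %d wells x %d assays (%d NTC wells, %.0f%% detected)\n",
              nrow(x$cq), ncol(x$cq), sum(x$wells$ntc),
              100 * mean(!is.na(x$cq))))
  invisible(x)
}

#' Read a Cq plate from wide CSV files
#'
#' The Cq CSV has wells in rows (first column = well id) and assays in
#' columns; empty cells mean no amplification. Companion CSVs give the
#' well metadata and, optionally, the assay panel assignment.
#'
#' @param cq_csv,wells_csv,assays_csv file paths (`assays_csv` optional).
#' @return a [cq_plate()].
#' @export
read_cq_plate <- function(cq_csv, wells_csv, assays_csv = NULL) {
  tab <- read.csv(cq_csv, check.names = FALSE, stringsAsFactors = FALSE)
  cq <- as.matrix(tab[, -1L, drop = FALSE])
  mode(cq) <- "numeric"
  rownames(cq) <- as.character(tab[[1L]])
  wells <- read.csv(wells_csv, stringsAsFactors = FALSE)
  wells$ntc <- as.logical(wells$ntc)
  assays <- if (!is.null(assays_csv)) read.csv(assays_csv,
                                               stringsAsFactors = FALSE)
  cq_plate(cq, wells, assays)
}

#' Write a Cq plate to wide CSV files
#'
#' @param plate a [cq_plate()].
#' @param cq_csv,wells_csv,assays_csv output paths.
#' @return invisibly, `plate`.
#' @export
write_cq_plate <- function(plate, cq_csv, wells_csv, assays_csv = NULL) {
  stopifnot(inherits(plate, "cq_plate"))
  out <- data.frame(well_id = rownames(plate$cq), plate$cq,
                    check.names = FALSE)
  write.csv(out, cq_csv, row.names = FALSE, quote = FALSE, na = "")
  write.csv(plate$wells, wells_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(assays_csv))
    write.csv(plate$assays, assays_csv, row.names = FALSE, quote = FALSE)
  invisible(plate)
}

#' Estimate the per-assay background cycle from NTC wells
#'
#' The background `C_bg` of an assay is the smallest Cq observed across
#' that assay's no-template-control wells (the most conservative
#' contamination/primer-dimer level); assays whose NTCs never amplified
#' fall back to a global detection limit.
#'
#' @param plate a [cq_plate()].
#' @param fallback global background Cq for assays without NTC
#'   amplification (and for plates without NTC wells).
#' @return named numeric vector of per-assay `C_bg`.
#' @export
estimate_background <- function(plate, fallback = 24) {
  stopifnot(inherits(plate, "cq_plate"))
  ntc <- plate$cq[plate$wells$ntc, , drop = FALSE]
  if (nrow(ntc) == 0L && is.null(fallback))
    stop_input("no NTC wells and no fallback background configured")
  bg <- apply(ntc, 2L, function(v) if (all(is.na(v))) NA_real_
                                   else min(v, na.rm = TRUE))
  if (nrow(ntc) == 0L) bg <- rep(NA_real_, ncol(plate$cq))
  if (anyNA(bg)) {
    if (is.null(fallback))
      stop_input("assays without NTC amplification and no fallback configured")
    bg[is.na(bg)] <- fallback
  }
  setNames(as.numeric(bg), colnames(plate$cq))
}

#' Transform Cq values to linear expression above background
#'
#' `expression = 2^(C_bg - C_q)` for detected reactions with
#' `C_q < C_bg`; reactions at or beyond background, and wells with no
#' amplification, are set to 0.
#'
#' @param plate a [cq_plate()].
#' @param background named per-assay `C_bg`, e.g. from
#'   [estimate_background()].
#' @return numeric matrix (wells x assays) of linear expression values.
#' @export
cq_to_expression <- function(plate, background) {
  stopifnot(inherits(plate, "cq_plate"))
  if (!all(colnames(plate$cq) %in% names(background)))
    stop_input("background must cover every assay")
  bg <- background[colnames(plate$cq)]
  lin <- 2^sweep(-plate$cq, 2L, bg, `+`)  # 2^(C_bg - C_q)
  not_detected <- is.na(plate$cq) | sweep(plate$cq, 2L, bg, `>=`)
  not_detected[is.na(not_detected)] <- TRUE
  lin[not_detected] <- 0
  lin
}

#' Normalize expression to the per-gene maximum over single cells
#'
#' Each gene is divided by its maximum linear expression across the
#' single-cell wells only; pooled (100-cell) wells are normalized by the
#' same factor, so they may exceed 1. Genes undetected in every single
#' cell stay 0.
#'
#' @param linear numeric matrix (wells x assays) of linear expression.
#' @param single_cell_mask logical per well, `TRUE` for single-cell wells.
#' @return matrix of normalized values, in `[0, 1]` for single cells.
#' @export
normalize_per_gene_max <- function(linear, single_cell_mask) {
  if (!any(single_cell_mask)) stop_input("need at least one single-cell well")
  mx <- apply(linear[single_cell_mask, , drop = FALSE], 2L, max)
  mx[mx == 0] <- 1  # all-zero gene: leave at 0 without dividing by 0
  sweep(linear, 2L, mx, `/`)
}

#' Process a raw Cq plate into a normalized expression profile
#'
#' Convenience chain: [estimate_background()], [cq_to_expression()],
#' [normalize_per_gene_max()]; NTC wells are dropped from the output.
#'
#' @param plate a [cq_plate()].
#' @param fallback global background Cq (see [estimate_background()]).
#' @return object of class `cell_profile`: list with `background`,
#'   `linear`, `normalized` (both wells x assays, NTC wells removed),
#'   `wells` (metadata without NTCs), `assays`, `single_cell` (logical
#'   mask).
#' @export
process_cq_plate <- function(plate, fallback = 24) {
  stopifnot(inherits(plate, "cq_plate"))
  bg <- estimate_background(plate, fallback = fallback)
  lin <- cq_to_expression(plate, bg)
  keep <- !plate$wells$ntc
  lin <- lin[keep, , drop = FALSE]
  wells <- plate$wells[keep, , drop = FALSE]
  single <- wells$cells == 1
  norm <- normalize_per_gene_max(lin, single)
  structure(list(background = bg, linear = lin, normalized = norm,
                 wells = wells, assays = plate$assays,
                 single_cell = single),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("<cell_profile> %d wells (%d single cells) x %d assays\n",
              nrow(x$normalized), sum(x$single_cell), ncol(x$normalized)))
  invisible(x)
}

#' Project cells into the E-M state space
#'
#' For each single cell, averages the normalized expression over the E
#' panel (`mean_e`) and over the M panel (`mean_m`), giving the cell's
#' position in the two-dimensional E-M state space; cells near the
#' diagonal with both means high are hybrid E/M.
#'
#' @param profile a `cell_profile` from [process_cq_plate()].
#' @param e_panel,m_panel marker gene panels (default [em_panels()]).
#' @return data.frame with `cell_id`, `mean_e`, `mean_m`, `group`, one row
#'   per single cell.
#' @export
project_em_state <- function(profile, e_panel = em_panels()$E,
                             m_panel = em_panels()$M) {
  stopifnot(inherits(profile, "cell_profile"))
  if (length(e_panel) == 0L || length(m_panel) == 0L)
    stop_input("panels must be non-empty")
  if (length(intersect(e_panel, m_panel)))
    stop_input("panels must be disjoint")
  missing <- setdiff(c(e_panel, m_panel), colnames(profile$normalized))
  if (length(missing))
    stop_input("panel genes absent from the plate: ",
               paste(missing, collapse = ", "))
  norm <- profile$normalized[profile$single_cell, , drop = FALSE]
  wells <- profile$wells[profile$single_cell, , drop = FALSE]
  data.frame(cell_id = wells$well_id,
             mean_e = rowMeans(norm[, e_panel, drop = FALSE]),
             mean_m = rowMeans(norm[, m_panel, drop = FALSE]),
             group = wells$group, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Count cells co-expressing, exclusively expressing, or silent
#'
#' A cell co-expresses when at least one E-panel gene and at least one
#' M-panel gene are detected (normalized value > 0); it is exclusive-E /
#' exclusive-M when only one panel is detected, and silent when neither is.
#'
#' @inheritParams project_em_state
#' @param groups optional subset of annotation groups to count (default:
#'   all single cells).
#' @return list with `n_cells`, `coexpressing`, `exclusive_e`,
#'   `exclusive_m`, `silent`, and `per_gene_detection` (matrix of detected
#'   cell counts per gene and group).
#' @export
count_coexpressing <- function(profile, e_panel = em_panels()$E,
                               m_panel = em_panels()$M, groups = NULL) {
  stopifnot(inherits(profile, "cell_profile"))
  norm <- profile$normalized[profile$single_cell, , drop = FALSE]
  wells <- profile$wells[profile$single_cell, , drop = FALSE]
  if (!is.null(groups)) {
    keep <- wells$group %in% groups
    norm <- norm[keep, , drop = FALSE]
    wells <- wells[keep, , drop = FALSE]
  }
  det_e <- rowSums(norm[, e_panel, drop = FALSE] > 0) > 0
  det_m <- rowSums(norm[, m_panel, drop = FALSE] > 0) > 0
  per_gene <- t(vapply(
    c(e_panel, m_panel),
    function(g) tapply(norm[, g] > 0, wells$group, sum),
    tapply(norm[, 1L] > 0, wells$group, sum)))
  list(n_cells = nrow(norm),
       coexpressing = sum(det_e & det_m),
       exclusive_e = sum(det_e & !det_m),
       exclusive_m = sum(det_m & !det_e),
       silent = sum(!det_e & !det_m),
       per_gene_detection = per_gene)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact when both samples have at most 20 values and no ties cross the
#' samples; otherwise the tie-corrected normal approximation with
#' continuity correction. Used to compare E-panel (or M-panel) aggregate
#' expression between cell groups.
#'
#' @param x,y numeric samples.
#' @return list with `u` (statistic for `x`), `p`, `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop_input("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(list(u = length(x) * length(y) / 2, p = 1, exact = TRUE))
  }
  exact <- length(x) <= 20L && length(y) <= 20L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Standardized PCA of single-cell profiles
#'
#' Centers every gene to mean zero and unit variance, then computes the
#' principal components by singular-value decomposition. Zero-variance
#' genes are dropped with a warning. Loadings are sign-fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix, cells x genes (e.g. `profile$normalized`).
#' @return list with `scores` (cells x PCs), `loadings` (genes x PCs),
#'   `variance_fraction`.
#' @export
pca_cells <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_input("need at least 2 cells")
  v <- apply(x, 2L, var)
  if (sum(v > 0) < 2L) stop_input("fewer than 2 genes with nonzero variance")
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  list(scores = sweep(pc$x, 2L, flip, `*`),
       loadings = sweep(pc$rotation, 2L, flip, `*`),
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2))
}

#' Pairwise Pearson correlation between samples or cells
#'
#' Correlates observations (rows) across a gene subset, optionally
#' averaging the correlations within and between annotation blocks (the
#' "correlation average" of grouped heat maps). Self-correlations are
#' excluded from block averages.
#'
#' @param x numeric matrix, observations x genes.
#' @param genes optional gene subset.
#' @param blocks optional annotation label per observation.
#' @return list with `r` (observation x observation correlation matrix)
#'   and, when `blocks` is given, `block_r` (block x block average r).
#' @export
correlation_matrix <- function(x, genes = NULL, blocks = NULL) {
  x <- as.matrix(x)
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_input("need >= 2 observations and >= 2 features")
  sds <- apply(x, 1L, sd)
  if (any(sds == 0))
    warning("zero-variance observation(s): correlations reported as NA")
  r <- suppressWarnings(cor(t(x)))
  diag(r) <- 1
  out <- list(r = r)
  if (!is.null(blocks)) {
    blocks <- as.character(blocks)
    lev <- unique(blocks)
    br <- matrix(NA_real_, length(lev), length(lev),
                 dimnames = list(lev, lev))
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      sub <- r[blocks == lev[i], blocks == lev[j], drop = FALSE]
      if (i == j) {
        vals <- sub[upper.tri(sub)]
        br[i, j] <- if (length(vals)) mean(vals, na.rm = TRUE) else 1
      } else {
        br[i, j] <- mean(sub, na.rm = TRUE)
      }
    }
    out$block_r <- br
  }
  out
}
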