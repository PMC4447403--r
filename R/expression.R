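#' Construct a clone-labelled expression matrix
#'
#' Bundles a log2 expression matrix (genes x samples) with one group label
#' per sample. This is the input container for array normalization and
#' differential expression between morphological clone groups.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames). All values must be finite.
#' @param groups character (or factor) vector of group tags, one per sample;
#'   either named by sample id or in column order.
#' @return an object of class `em_matrix`: a list with elements `values` and
#'   `groups` (named character vector).
#' @examples
#' m <- expression_matrix(
#'   matrix(rnorm(20), 5, 4,
#'          dimnames = list(paste0("g", 1:5), paste0("s", 1:4))),
#'   c(s1 = "E", s2 = "E", s3 = "M", s4 = "M"))
#' m
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) < 1L ||
      ncol(values) < 1L)
    stop_input("`values` must be a non-empty numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_input("gene ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_input("sample ids (colnames) must be present and unique")
  if (!all(is.finite(values)))
    stop_input("all expression values must be finite")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop_input("need exactly one group tag per sample")
  if (is.null(names(groups))) {
    names(groups) <- colnames(values)
  } else if (!setequal(names(groups), colnames(values))) {
    stop_input("group names do not match sample ids")
  }
  groups <- groups[colnames(values)]
  if (anyNA(groups)) stop_input("group tags must not be missing")
  structure(list(values = values, groups = groups), class = "em_matrix")
}

#' @export
print.em_matrix <- function(x, ...) {
  cat(sprintf("<em_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an expression matrix with a sample sheet
#'
#' Expects a TSV whose first column holds gene ids and whose header holds
#' sample ids, plus a companion CSV with columns `sample_id` and `group`.
#'
#' @param matrix_tsv path to the expression TSV.
#' @param samples_csv path to the sample sheet CSV.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_tsv, samples_csv) {
  tab <- read.csv(matrix_tsv, sep = "\t", check.names = FALSE)
  if (ncol(tab) < 2L) stop_input("expression TSV needs gene id + >=1 sample")
  genes <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- genes
  sheet <- read.csv(samples_csv, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop_input("sample sheet must have columns sample_id, group")
  expression_matrix(values, setNames(sheet$group, sheet$sample_id))
}

#' Write an expression matrix and its sample sheet
#'
#' @param x an [expression_matrix()].
#' @param matrix_tsv,samples_csv output paths.
#' @return invisibly, `x`.
#' @export
write_expression_matrix <- function(x, matrix_tsv, samples_csv) {
  stopifnot(inherits(x, "em_matrix"))
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE)
  write.table(out, matrix_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(data.frame(sample_id = colnames(x$values), group = x$groups),
            samples_csv, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Normalize arrays by central tendency and, optionally, a reference group
#'
#' First shifts every sample so its median is zero (central tendency);
#' then, when `reference_groups` is supplied, expresses every value relative
#' to the per-gene mean of the samples in those groups, so the reference
#' level sits at zero per gene.
#'
#' @param x an [expression_matrix()].
#' @param reference_groups optional character vector of group tags defining
#'   the reference (e.g. the E and M clone groups together, so values are
#'   relative to the intermediate expression between them).
#' @return an [expression_matrix()] with normalized values.
#' @export
normalize_arrays <- function(x, reference_groups = NULL) {
  stopifnot(inherits(x, "em_matrix"))
  v <- x$values
  v <- sweep(v, 2L, apply(v, 2L, median), `-`)
  if (!is.null(reference_groups)) {
    sel <- x$groups %in% reference_groups
    if (!any(sel))
      stop_input("no samples belong to the requested reference groups")
    ref <- rowMeans(v[, sel, drop = FALSE])
    v <- sweep(v, 1L, ref, `-`)
  }
  expression_matrix(v, x$groups)
}
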