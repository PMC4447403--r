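#' Moderated differential expression between two clone groups
#'
#' Per-gene two-sample comparison with a simple empirical-Bayes variance
#' moderation: the pooled within-group variance of each gene is shrunk
#' towards the mean variance across genes (`prior_df` pseudo-degrees of
#' freedom), and the moderated t statistic is referred to a t distribution
#' with `prior_df + n - 2` degrees of freedom. The effect size is the
#' difference of group means on the log2 scale, positive when the gene is
#' higher in `group_e`.
#'
#' @param x an [expression_matrix()].
#' @param group_e,group_m group tags to compare (effect = E minus M).
#' @param alpha significance threshold on the (adjusted) p-value.
#' @param prior_df prior degrees of freedom of the variance moderation.
#' @param adjust use Benjamini-Hochberg adjusted p-values for the
#'   significance flag (`TRUE`, default) or raw p-values.
#' @return a data.frame of class `em_diff`, rows sorted significant-first
#'   and by decreasing `|effect_size|` within the significant set, with
#'   columns `gene`, `effect_size`, `t`, `p`, `p_adj`, `significant` and
#'   attributes `group_e`, `group_m`, `alpha`.
#' @seealso [rank_signature()] for turning the result into E/M signatures.
#' @export
derive_differential_genes <- function(x, group_e, group_m, alpha = 0.01,
                                      prior_df = 4, adjust = TRUE) {
  stopifnot(inherits(x, "em_matrix"))
  e <- x$groups == group_e
  m <- x$groups == group_m
  n1 <- sum(e); n2 <- sum(m)
  if (n1 < 2L || n2 < 2L)
    stop_input("need at least 2 samples per group (got ", n1, " vs ", n2, ")")
  ve <- x$values[, e, drop = FALSE]
  vm <- x$values[, m, drop = FALSE]
  effect <- rowMeans(ve) - rowMeans(vm)
  df_res <- n1 + n2 - 2L
  s2 <- (rowSums((ve - rowMeans(ve))^2) + rowSums((vm - rowMeans(vm))^2)) /
    df_res
  s2_prior <- mean(s2)
  s2_mod <- (prior_df * s2_prior + df_res * s2) / (prior_df + df_res)
  tstat <- effect / sqrt(s2_mod * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = prior_df + df_res)
  p_adj <- p.adjust(p, method = "BH")
  signif <- (if (adjust) p_adj else p) < alpha
  out <- data.frame(gene = rownames(x$values), effect_size = effect,
                    t = tstat, p = p, p_adj = p_adj, significant = signif,
                    row.names = NULL, stringsAsFactors = FALSE)
  # significant genes first, by |effect| descending; ties by smaller p then id
  ord <- order(!out$significant, -abs(out$effect_size), out$p, out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_e") <- group_e
  attr(out, "group_m") <- group_m
  attr(out, "alpha") <- alpha
  class(out) <- c("em_diff", "data.frame")
  out
}

#' Construct a gene signature
#'
#' @param name signature label.
#' @param members data.frame with columns `gene`, `direction` (`"E"` or
#'   `"M"`), `rank` (contiguous from 1 within each direction) and
#'   `effect_size`.
#' @return an object of class `em_signature` with fields `name`, `members`,
#'   `k_e`, `k_m`.
#' @export
gene_signature <- function(name, members) {
  need <- c("gene", "direction", "rank", "effect_size")
  if (!all(need %in% names(members)))
    stop_input("members must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(members$gene)) stop_input("duplicate gene ids in signature")
  if (!all(members$direction %in% c("E", "M")))
    stop_input("direction must be 'E' or 'M'")
  for (d in c("E", "M")) {
    r <- sort(members$rank[members$direction == d])
    if (length(r) && !identical(as.integer(r), seq_along(r)))
      stop_input("ranks must be contiguous from 1 within direction ", d)
  }
  structure(list(name = name,
                 members = members[order(members$direction, members$rank),
                                   need, drop = FALSE],
                 k_e = sum(members$direction == "E"),
                 k_m = sum(members$direction == "M")),
            class = "em_signature")
}

#' @export
print.em_signature <- function(x, ...) {
  cat(sprintf("<em_signature> %s: %d genes (E %d, M %d)\n",
              x$name, nrow(x$members), x$k_e, x$k_m))
  invisible(x)
}

#' Gene ids of a signature
#'
#' @param signature an [gene_signature()].
#' @param direction optionally restrict to `"E"` or `"M"` members.
#' @return character vector of gene ids in rank order.
#' @export
signature_genes <- function(signature, direction = NULL) {
  stopifnot(inherits(signature, "em_signature"))
  m <- signature$members
  if (!is.null(direction)) m <- m[m$direction == direction, , drop = FALSE]
  m$gene[order(m$rank)]
}

#' Rank the most extreme differentially expressed genes into E/M signatures
#'
#' The E signature takes the `n_per_direction` significant genes with the
#' largest positive effect sizes, the M signature the largest negative ones
#' (both in decreasing `|effect_size|` order).
#'
#' @param diff an `em_diff` result from [derive_differential_genes()].
#' @param n_per_direction genes requested per direction.
#' @param cap if `TRUE`, cap at the number of qualifying genes instead of
#'   raising a shortage error.
#' @return list with elements `E` and `M`, each an [gene_signature()].
#' @export
rank_signature <- function(diff, n_per_direction, cap = FALSE) {
  stopifnot(inherits(diff, "em_diff"))
  if (n_per_direction < 0) stop_input("`n_per_direction` must be >= 0")
  sig <- diff[diff$significant, , drop = FALSE]
  one <- function(dirname, sel, sign_label) {
    sub <- sig[sel, , drop = FALSE]
    n_take <- n_per_direction
    if (nrow(sub) < n_per_direction) {
      if (!cap)
        stop_input(sprintf(
          "only %d qualifying genes in the %s direction (requested %d)",
          nrow(sub), dirname, n_per_direction))
      n_take <- nrow(sub)
    }
    sub <- head(sub, n_take)
    gene_signature(sprintf("%s_top%d", dirname, n_take),
                   data.frame(gene = sub$gene,
                              direction = rep(sign_label, nrow(sub)),
                              rank = seq_len(nrow(sub)),
                              effect_size = sub$effect_size,
                              stringsAsFactors = FALSE))
  }
  list(E = one("E", sig$effect_size > 0, "E"),
       M = one("M", sig$effect_size < 0, "M"))
}

#' Compose a combined EM signature from the top E and top M genes
#'
#' @param sig_e,sig_m E and M signatures from [rank_signature()].
#' @param k genes taken from each input (output has `2 * k` members).
#' @return an [gene_signature()] with `k_e = k_m = k`.
#' @examples
#' # a 60-gene EM signature from the 30 most extreme genes per direction
#' # compose_em_signature(sigs$E, sigs$M, k = 30)
#' @export
compose_em_signature <- function(sig_e, sig_m, k) {
  stopifnot(inherits(sig_e, "em_signature"), inherits(sig_m, "em_signature"))
  if (k > nrow(sig_e$members) || k > nrow(sig_m$members))
    stop_input("k = ", k, " exceeds an input signature size (",
               nrow(sig_e$members), " E, ", nrow(sig_m$members), " M)")
  take <- function(s) s$members[s$members$rank <= k, , drop = FALSE]
  gene_signature(sprintf("EM_top%d", 2L * k), rbind(take(sig_e), take(sig_m)))
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' Direction tags are recovered from a `direction=E,M,...` description field
#' when present; otherwise all members are tagged `"E"`.
#'
#' @param path GMT file path.
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop_input("malformed GMT line: ", substr(ln, 1, 40))
    genes <- f[-(1:2)]
    dirs <- rep("E", length(genes))
    if (grepl("^direction=", f[2L])) {
      d <- strsplit(sub("^direction=", "", f[2L]), ",", fixed = TRUE)[[1L]]
      if (length(d) == length(genes)) dirs <- d
    }
    members <- do.call(rbind, lapply(c("E", "M"), function(dd) {
      g <- genes[dirs == dd]
      if (!length(g)) return(NULL)
      data.frame(gene = g, direction = dd, rank = seq_along(g),
                 effect_size = NA_real_, stringsAsFactors = FALSE)
    }))
    gene_signature(f[1L], members)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write gene signatures to a GMT file
#'
#' Members are written in rank order (E before M); the description field
#' encodes the direction tags so [read_gmt()] round-trips them.
#'
#' @param signatures a single [gene_signature()] or a list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "em_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    m <- s$members[order(s$members$direction, s$members$rank), , drop = FALSE]
    paste(c(s$name, paste0("direction=", paste(m$direction, collapse = ",")),
            m$gene), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write the detailed per-gene signature table
#'
#' @param signature an [gene_signature()].
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
write_signature_csv <- function(signature, path) {
  stopifnot(inherits(signature, "em_signature"))
  write.csv(signature$members, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
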