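#' Exact minimum-weight perfect matching
#'
#' Pairs all units so that the total within-pair distance is minimal, using
#' an exact blossom (primal-dual) algorithm on the complete graph. This is
#' the matching underlying the cross-match test.
#'
#' @param d symmetric numeric distance matrix (or a `dist` object) over an
#'   even number of units.
#' @return list with `pairs` (two-column integer matrix of matched unit
#'   indices) and `total` (sum of matched distances).
#' @export
min_weight_perfect_matching <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_input("`d` must be a square distance matrix")
  n <- nrow(d)
  if (n %% 2L != 0L) stop_input("number of units must be even")
  m <- mwpm_cpp(d)
  i <- which(m > seq_len(n))
  pairs <- cbind(i, m[i])
  dimnames(pairs) <- NULL
  list(pairs = pairs, total = sum(d[pairs]))
}

# null probability mass of A1 for one value (log scale internally)
crossmatch_mass <- function(a1, n_total, n_group1) {
  n2 <- n_total - n_group1
  a0 <- (n_group1 - a1) / 2
  a2 <- (n2 - a1) / 2
  if (a0 < 0 || a2 < 0 || a0 != floor(a0) || a2 != floor(a2)) return(0)
  exp(a1 * log(2) + lfactorial(n_total / 2) -
        lchoose(n_total, n_group1) - lfactorial(a0) - lfactorial(a1) -
        lfactorial(a2))
}

#' Exact null distribution of the cross-match count
#'
#' Distribution of the number of cross-group pairs `A1` in a fixed perfect
#' matching of `n_total` units when `n_group1` group labels are assigned
#' uniformly at random.
#'
#' @param n_total total number of matched units (even).
#' @param n_group1 size of group 1.
#' @return data.frame with columns `a1`, `prob`, `cum` (lower-tail
#'   cumulative probability), covering all achievable `a1`.
#' @export
crossmatch_null_distribution <- function(n_total, n_group1) {
  if (n_total %% 2L != 0L) stop_input("`n_total` must be even")
  if (n_group1 < 0 || n_group1 > n_total)
    stop_input("`n_group1` out of range")
  a1 <- seq(n_group1 %% 2L, min(n_group1, n_total - n_group1), by = 2L)
  prob <- vapply(a1, crossmatch_mass, 0, n_total = n_total,
                 n_group1 = n_group1)
  data.frame(a1 = a1, prob = prob, cum = cumsum(prob))
}

#' Exact lower-tail p-value of the cross-match test
#'
#' `P(A1 <= a1)` under the permutation null of group labels for a fixed
#' perfect matching. Small cross-match counts indicate separation of the
#' two groups.
#'
#' @param a1 observed number of cross-group pairs.
#' @param n_total total number of matched units (even).
#' @param n_group1 size of group 1.
#' @return the exact p-value.
#' @examples
#' crossmatch_null_pvalue(0, 4, 2)  # 1/3
#' @export
crossmatch_null_pvalue <- function(a1, n_total, n_group1) {
  dist <- crossmatch_null_distribution(n_total, n_group1)
  if (!a1 %in% dist$a1)
    stop_input("a1 = ", a1, " is impossible for groups of ", n_group1,
               " and ", n_total - n_group1, " (parity)")
  dist$cum[dist$a1 == a1]
}

#' Cross-match test for separation of two groups
#'
#' Builds the pairwise distance matrix over all units, computes the exact
#' minimum-weight perfect matching of the complete graph, counts the pairs
#' joining different groups (`a1`), and reports the exact lower-tail
#' permutation p-value given the fixed matching. An odd total is handled by
#' adding a phantom unit farther from every real unit than any observed
#' distance; the phantom's partner is discarded before counting and the
#' null uses the reduced even count.
#'
#' @param x numeric matrix of unit coordinates (units x features), e.g. the
#'   `(mean_e, mean_m)` columns of [project_em_state()]; or a precomputed
#'   `dist`/square distance matrix.
#' @param labels group label per unit (exactly two distinct values).
#' @param distance `"euclidean"` on the coordinates, or `"rank"` (each
#'   feature rank-transformed first).
#' @return object of class `em_crossmatch`: list with `a1`, `pairs`
#'   (matched unit ids), `n_total`, `n_group1`, `p`, `null` (the exact null
#'   distribution), `dropped` (unit removed by phantom matching, if any).
#' @export
crossmatch_test <- function(x, labels, distance = c("euclidean", "rank")) {
  distance <- match.arg(distance)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop_input("`labels` must have exactly two groups")
  if (min(table(labels)) < 2L) stop_input("need >= 2 units per group")
  if (inherits(x, "dist")) {
    d <- as.matrix(x)
  } else if (is.matrix(x) && nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x)))) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (distance == "rank") x <- apply(x, 2L, rank)
    d <- as.matrix(dist(x))
  }
  n <- nrow(d)
  if (length(labels) != n) stop_input("one label per unit required")
  ids <- rownames(d) %||% as.character(seq_len(n))
  if (all(d[upper.tri(d)] == 0))
    warning("all pairwise distances are zero; matching is arbitrary")
  dropped <- NULL
  if (n %% 2L == 1L) {
    far <- max(d) + 1
    d <- rbind(cbind(d, far), c(rep(far, n), 0))
    mw <- min_weight_perfect_matching(d)
    phantom <- n + 1L
    hit <- mw$pairs[rowSums(mw$pairs == phantom) > 0L, ]
    dropped_idx <- setdiff(hit, phantom)
    dropped <- ids[dropped_idx]
    keep_pairs <- mw$pairs[rowSums(mw$pairs == phantom) == 0L, , drop = FALSE]
    use_labels <- labels[-dropped_idx]
    pairs <- keep_pairs
    n_eff <- n - 1L
    n1 <- sum(use_labels == lev[1L])
  } else {
    mw <- min_weight_perfect_matching(d)
    pairs <- mw$pairs
    n_eff <- n
    n1 <- sum(labels == lev[1L])
  }
  a1 <- sum(labels[pairs[, 1L]] != labels[pairs[, 2L]])
  p <- crossmatch_null_pvalue(a1, n_eff, n1)
  structure(list(a1 = a1,
                 pairs = cbind(ids[pairs[, 1L]], ids[pairs[, 2L]]),
                 n_total = n_eff, n_group1 = n1, p = p,
                 null = crossmatch_null_distribution(n_eff, n1),
                 dropped = dropped,
                 method = "closed-form"),
            class = "em_crossmatch")
}

#' @export
print.em_crossmatch <- function(x, ...) {
  cat(sprintf("<em_crossmatch> a1 = %d cross-group pairs of %d units, p = %.4g\n",
              x$a1, x$n_total, x$p))
  invisible(x)
}
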