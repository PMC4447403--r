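# Independent oracles used across the suite.

# Exact minimum-weight perfect matching cost by bitmask dynamic programming
# (feasible up to ~16 units). Independent of the blossom implementation.
dp_min_pm_cost <- function(D) {
  n <- nrow(D)
  stopifnot(n %% 2 == 0, n <= 16)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(S) {
    if (S == 0L) return(0)
    key <- as.character(S)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    i <- 0L
    while (!bitwAnd(S, bitwShiftL(1L, i))) i <- i + 1L
    S2 <- bitwAnd(S, bitwNot(bitwShiftL(1L, i)))
    best <- Inf
    for (j in seq.int(i + 1L, n - 1L)) {
      if (bitwAnd(S2, bitwShiftL(1L, j))) {
        cost <- D[i + 1L, j + 1L] + rec(bitwAnd(S2, bitwNot(bitwShiftL(1L, j))))
        if (cost < best) best <- cost
      }
    }
    memo[[key]] <- best
    best
  }
  rec(bitwShiftL(1L, n) - 1L)
}

# Exhaustive lower-tail p of the cross-match count for a fixed matching
# of pairs (1,2), (3,4), ...: enumerate every labeling of n_group1 units.
enum_crossmatch_p <- function(a1, n_total, n_group1) {
  pairs <- matrix(seq_len(n_total), ncol = 2, byrow = TRUE)
  labelings <- utils::combn(n_total, n_group1)
  a1_all <- apply(labelings, 2, function(g1) {
    lab <- seq_len(n_total) %in% g1
    sum(lab[pairs[, 1]] != lab[pairs[, 2]])
  })
  mean(a1_all <= a1)
}

# a tiny deterministic cq_plate for unit tests
toy_plate <- function() {
  cq <- rbind(
    c(20, 22, NA),   # single cell 1
    c(18, NA, 23),   # single cell 2
    c(12, 14, 15),   # 100-cell pool
    c(26, NA, NA),   # NTC: assay a amplifies late, others never
    c(28, NA, NA))   # NTC
  dimnames(cq) <- list(c("w1", "w2", "pool1", "ntc1", "ntc2"),
                       c("a", "b", "c"))
  wells <- data.frame(
    well_id = rownames(cq),
    group = c("grp1", "grp1", "pool", "NTC", "NTC"),
    cells = c(1L, 1L, 100L, 0L, 0L),
    ntc = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  assays <- data.frame(gene = c("a", "b", "c"),
                       panel = c("E", "E", "M"), stringsAsFactors = FALSE)
  cq_plate(cq, wells, assays)
}
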