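make_planted <- function(seed = 11, noise_sd = 0.5, n_genes = 1000) {
  generate_clone_matrix(n_genes = n_genes, n_e = 6, n_m = 4, n_planted = 30,
                        effect_size = 3, noise_sd = noise_sd, seed = seed)
}

test_that("planted differential genes are recovered as ranked signatures", {
  g <- make_planted()
  d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  sigs <- rank_signature(d, 30)
  expect_setequal(signature_genes(sigs$E), g$truth$e_up)
  expect_setequal(signature_genes(sigs$M), g$truth$m_up)
  expect_true(all(d$significant[d$gene %in% c(g$truth$e_up, g$truth$m_up)]))
})

test_that("planted genes rank top-30 by effect size across replicate seeds", {
  for (seed in 1:10) {
    g <- make_planted(seed = seed)
    d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
    top_e <- d$gene[order(-d$effect_size)][1:30]
    top_m <- d$gene[order(d$effect_size)][1:30]
    expect_setequal(top_e, g$truth$e_up)
    expect_setequal(top_m, g$truth$m_up)
  }
})

test_that("null data yields essentially no adjusted discoveries", {
  g <- generate_clone_matrix(n_genes = 1000, n_e = 6, n_m = 4,
                             n_planted = 1, effect_size = 0, seed = 21)
  d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  expect_lte(sum(d$significant), 1)
})

test_that("unadjusted false-positive count is near alpha * n_genes", {
  counts <- vapply(1:5, function(s) {
    g <- generate_clone_matrix(n_genes = 1000, n_e = 6, n_m = 4,
                               n_planted = 1, effect_size = 0, seed = 100 + s)
    d <- derive_differential_genes(g$matrix, "Eclone", "Mclone",
                                   alpha = 0.01, adjust = FALSE)
    sum(d$significant)
  }, 0)
  expect_gt(mean(counts), 1)    # some false positives do occur
  expect_lt(mean(counts), 40)   # but on the order of alpha * n
})

test_that("swapping the group labels negates effects and keeps p-values", {
  g <- make_planted(seed = 3)
  d1 <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  d2 <- derive_differential_genes(g$matrix, "Mclone", "Eclone")
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d2$effect_size, -d1$effect_size)
  expect_equal(d2$p, d1$p)
})

test_that("effect sign convention is positive when higher in the E group", {
  v <- matrix(c(10, 10, 10, 2, 2, 2, 5, 5, 5, 5, 5, 5), nrow = 2,
              byrow = TRUE,
              dimnames = list(c("up_in_e", "flat"), paste0("s", 1:6)))
  m <- expression_matrix(v, setNames(rep(c("E", "M"), each = 3),
                                     colnames(v)))
  d <- derive_differential_genes(m, "E", "M")
  expect_gt(d$effect_size[d$gene == "up_in_e"], 0)
})

test_that("moderated effects and ranking agree with limma", {
  g <- make_planted(seed = 7)
  d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  design <- cbind(1, g$matrix$groups == "Eclone")
  fit <- limma::eBayes(limma::lmFit(g$matrix$values, design))
  lim <- data.frame(gene = rownames(fit$coefficients),
                    logfc = fit$coefficients[, 2], t = fit$t[, 2])
  merged <- merge(d, lim, by = "gene")
  # effect sizes are both group-mean differences -> identical
  expect_equal(merged$effect_size, merged$logfc, tolerance = 1e-10)
  # moderated t statistics are not identical but strongly rank-concordant
  expect_gt(cor(rank(abs(merged$t.x)), rank(abs(merged$t.y))), 0.98)
})

test_that("rank_signature enforces shortage, emptiness and forced sets", {
  g <- make_planted(seed = 13)
  d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  expect_error(rank_signature(d, 150), "qualifying genes")
  capped <- rank_signature(d, 150, cap = TRUE)
  expect_lte(capped$E$k_e, 150)

  empty <- rank_signature(d, 0)
  expect_identical(nrow(empty$E$members), 0L)

  n_e <- sum(d$significant & d$effect_size > 0)
  n_m <- sum(d$significant & d$effect_size < 0)
  forced <- rank_signature(d, min(n_e, n_m))
  expect_identical(forced$E$members$effect_size,
                   sort(forced$E$members$effect_size, decreasing = TRUE))
})

test_that("EM composition keeps directions and sizes", {
  g <- make_planted(seed = 17)
  d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  sigs <- rank_signature(d, 30)
  em60 <- compose_em_signature(sigs$E, sigs$M, 30)
  expect_identical(nrow(em60$members), 60L)
  expect_identical(c(em60$k_e, em60$k_m), c(30L, 30L))
  em24 <- compose_em_signature(sigs$E, sigs$M, 12)
  expect_identical(nrow(em24$members), 24L)
  expect_error(compose_em_signature(sigs$E, sigs$M, 31), "exceeds")
  # k equal to the full inputs = union of both signatures
  full <- compose_em_signature(sigs$E, sigs$M, 30)
  expect_setequal(signature_genes(full),
                  c(signature_genes(sigs$E), signature_genes(sigs$M)))
})

test_that("signatures round-trip through GMT and write deterministically", {
  g <- make_planted(seed = 19)
  d <- derive_differential_genes(g$matrix, "Eclone", "Mclone")
  sigs <- rank_signature(d, 20)
  em <- compose_em_signature(sigs$E, sigs$M, 10)
  f1 <- withr::local_tempfile(fileext = ".gmt")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(list(sigs$E, em), f1)
  write_gmt(list(sigs$E, em), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_gmt(f1)
  expect_setequal(signature_genes(back[[em$name]], "E"),
                  signature_genes(em, "E"))
  expect_setequal(signature_genes(back[[em$name]], "M"),
                  signature_genes(em, "M"))
})
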