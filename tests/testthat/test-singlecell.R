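test_that("background is the minimum NTC Cq per assay, with fallback", {
  plate <- toy_plate()
  bg <- estimate_background(plate, fallback = 24)
  expect_equal(unname(bg["a"]), 26)   # min of NTC Cq 26, 28
  expect_equal(unname(bg["b"]), 24)   # NTC never amplified -> fallback
  expect_equal(unname(bg["c"]), 24)
  expect_length(bg, ncol(plate$cq))
  no_ntc <- cq_plate(plate$cq[1:3, ], plate$wells[1:3, ], plate$assays)
  expect_error(estimate_background(no_ntc, fallback = NULL), "no NTC")
})

test_that("Cq transforms to linear expression with background truncation", {
  plate <- toy_plate()
  bg <- c(a = 24, b = 24, c = 24)
  lin <- cq_to_expression(plate, bg)
  expect_equal(lin["w1", "a"], 16)       # 2^(24-20)
  expect_equal(lin["w1", "c"], 0)        # missing -> 0
  expect_equal(unname(lin["ntc1", "a"]), 0)  # Cq 26 >= bg 24 -> 0
  bg2 <- c(a = 20, b = 24, c = 24)
  expect_equal(cq_to_expression(plate, bg2)["w1", "a"], 0)  # Cq == bg -> 0
})

test_that("per-gene max normalization uses single cells only", {
  expect_equal(normalize_per_gene_max(matrix(c(2, 8, 4), 3, 1), rep(TRUE, 3)),
               matrix(c(0.25, 1, 0.5), 3, 1))
  # all-zero gene stays zero without division errors
  expect_true(all(normalize_per_gene_max(matrix(0, 3, 1), rep(TRUE, 3)) == 0))
  # a single cell normalizes to 1
  expect_equal(as.vector(normalize_per_gene_max(matrix(5, 1, 1), TRUE)), 1)
  # pooled wells are excluded from the max but scaled by the same factor
  lin <- matrix(c(2, 4, 40), 3, 1)
  norm <- normalize_per_gene_max(lin, c(TRUE, TRUE, FALSE))
  expect_equal(as.vector(norm), c(0.5, 1, 10))
})

test_that("normalizing an already-normalized profile is the identity", {
  gen <- generate_cq_plate(n_e = 8, n_m = 8, n_pool = 0, seed = 9)
  prof <- process_cq_plate(gen$plate)
  again <- normalize_per_gene_max(prof$normalized, prof$single_cell)
  expect_equal(again, prof$normalized)
})

test_that("cells project to panel means in the E-M state space", {
  plate <- toy_plate()
  prof <- process_cq_plate(plate, fallback = 24)
  st <- project_em_state(prof, e_panel = c("a", "b"), m_panel = "c")
  expect_identical(nrow(st), 2L)          # single cells only
  lin <- prof$linear[1:2, ]
  norm <- prof$normalized[1:2, ]
  expect_equal(st$mean_e, unname(rowMeans(norm[, c("a", "b")])))
  expect_true(all(st$mean_e >= 0 & st$mean_e <= 1))
  expect_error(project_em_state(prof, e_panel = c("a", "nope"),
                                m_panel = "c"), "nope")
  expect_error(project_em_state(prof, e_panel = "a", m_panel = "a"),
               "disjoint")
})

test_that("hybrid cells sit on the state-space diagonal", {
  gen <- generate_cq_plate(n_e = 16, n_hybrid = 16, n_m = 16, seed = 15)
  prof <- process_cq_plate(gen$plate)
  st <- project_em_state(prof)
  means <- aggregate(st[, c("mean_e", "mean_m")], list(group = st$group),
                     mean)
  rownames(means) <- means$group
  # hybrids express E genes above the M state's E level, and M genes above
  # the E state's M level
  expect_gt(means["hybrid", "mean_e"], means["M", "mean_e"])
  expect_gt(means["hybrid", "mean_m"], means["E", "mean_m"])
})

test_that("co-expression counting distinguishes promiscuous E from exclusive M", {
  gen <- generate_cq_plate(n_e = 24, n_m = 24, seed = 3)
  prof <- process_cq_plate(gen$plate)
  ce <- count_coexpressing(prof, groups = "E")
  cm <- count_coexpressing(prof, groups = "M")
  expect_identical(ce$n_cells, 24L)
  expect_gte(ce$coexpressing, 20)          # E cells co-express E and M genes
  expect_gte(cm$exclusive_m, 20)           # M cells are exclusively M
  expect_identical(ce$coexpressing + ce$exclusive_e + ce$exclusive_m +
                     ce$silent, ce$n_cells)
  # a fully silent cell is counted as silent
  prof0 <- prof
  prof0$normalized[1, ] <- 0
  c0 <- count_coexpressing(prof0, groups = "E")
  expect_gte(c0$silent, 1)
})

test_that("Mann-Whitney U handles exact, tied and degenerate cases", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  mw <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(mw$u), 0)
  expect_equal(mw$p, 0.1)       # 2 * 1/20 extreme orderings
  expect_true(mw$exact)
  expect_warning(tied <- mann_whitney_u(c(1, 1), c(1, 1)), "tied")
  expect_equal(tied$p, 1)
})

test_that("standardized PCA captures collinear data on one component", {
  x <- cbind(1:10, (1:10) * 2)
  pc <- pca_cells(x)
  expect_equal(pc$variance_fraction[1], 1)
  # deterministic on rerun
  pc2 <- pca_cells(x)
  expect_identical(pc$scores, pc2$scores)
})

test_that("PCA loadings separate the E panel from the M panel by sign", {
  gen <- generate_cq_plate(n_e = 20, n_m = 20, n_pool = 0, seed = 23)
  prof <- process_cq_plate(gen$plate)
  pc <- suppressWarnings(
    pca_cells(prof$normalized[prof$single_cell, , drop = FALSE]))
  panels <- em_panels()
  found <- FALSE
  for (k in 1:2) {
    l <- pc$loadings[, k]
    me <- mean(l[intersect(names(l), panels$E)])
    mm <- mean(l[intersect(names(l), panels$M)])
    if (sign(me) != sign(mm) && abs(me) > 0.1 && abs(mm) > 0.1) found <- TRUE
  }
  expect_true(found)
})

test_that("correlation matrices recover planted block structure", {
  expect_equal(correlation_matrix(rbind(1:5, 1:5 * 2))$r[1, 2], 1)
  expect_equal(correlation_matrix(rbind(1:5, -(1:5)))$r[1, 2], -1)
  set.seed(66)
  base <- rnorm(50)
  x <- rbind(t(replicate(4, base + rnorm(50, 0, 0.3))),
             t(replicate(4, -base + rnorm(50, 0, 0.3))))
  cm <- correlation_matrix(x, blocks = rep(c("E", "M"), each = 4))
  expect_gt(cm$block_r["E", "E"], 0.5)
  expect_gt(cm$block_r["M", "M"], 0.5)
  expect_lt(cm$block_r["E", "M"], -0.5)
})

test_that("Cq plates round-trip through wide CSV files", {
  gen <- generate_cq_plate(n_e = 6, n_m = 6, n_pool = 1, seed = 31)
  cqf <- withr::local_tempfile(fileext = ".csv")
  wf <- withr::local_tempfile(fileext = ".csv")
  af <- withr::local_tempfile(fileext = ".csv")
  write_cq_plate(gen$plate, cqf, wf, af)
  back <- read_cq_plate(cqf, wf, af)
  expect_equal(back$cq, gen$plate$cq, tolerance = 1e-10)
  expect_identical(back$wells$ntc, gen$plate$wells$ntc)
})
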