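test_that("count normalization follows pseudocount + c * scale / total", {
  expect_equal(normalize_counts(c(10, 40), engine_params(pseudocount = 0, scale = 100)),
               c(20, 80))
  expect_equal(normalize_counts(c(1, 1), engine_params(pseudocount = 0, scale = 10)),
               c(5, 5))
  expect_equal(normalize_counts(c(10, 40), engine_params(pseudocount = 5, scale = 100)),
               c(25, 85))
  expect_error(normalize_counts(c(0, 0)), class = "value_error")
})

test_that("guide log2 fold changes are log2 ratios of normalized counts", {
  lib <- compose_library(1, 0, 0, 2)
  m <- matrix(c(10, 40, 40, 10), 2,
              dimnames = list(lib$guide_id, c("ctrl", "trt")))
  tab <- count_table(m, lib)
  cs <- contrast_spec("trt_vs_ctrl", "ctrl", "trt")
  st <- guide_log2fc(tab, cs, engine_params(pseudocount = 5, scale = 100))
  # normalized: ctrl (25, 85), trt (85, 25)
  expect_equal(st$norm_ctrl, c(25, 85))
  expect_equal(st$fc, c(log2(85 / 25), log2(25 / 85)))
  expect_equal(st$fc[1], 1.7655, tolerance = 1e-4)

  # identical columns -> fc exactly 0
  m2 <- matrix(c(10, 40, 10, 40), 2,
               dimnames = list(lib$guide_id, c("ctrl", "trt")))
  st2 <- guide_log2fc(count_table(m2, lib), cs, engine_params())
  expect_equal(st2$fc, c(0, 0))

  # doubling treated counts leaves proportions, hence fc, unchanged (pc = 0)
  m3 <- m2; m3[, "trt"] <- m3[, "trt"] * 2L
  st3 <- guide_log2fc(count_table(m3, lib), cs, engine_params(pseudocount = 0))
  expect_equal(st3$fc, st2$fc)

  expect_error(guide_log2fc(tab, contrast_spec("x", "ctrl", "nope")),
               class = "invalid_parameter")
})

test_that("empirical-Bayes std uses the rank window with clamping and floor", {
  lib <- compose_library(1, 0, 0, 2)
  cs <- contrast_spec("c", "ctrl", "trt")

  # 2 guides with fc (-1, +1): sample sd of {-1, 1} = sqrt(2) for both
  # (ctrl proportions 2/3:1/3, trt 1/3:2/3 -> ratios 1/2 and 2)
  m <- matrix(c(200, 100, 100, 200), 2,
              dimnames = list(lib$guide_id, c("ctrl", "trt")))
  st <- eb_std(guide_log2fc(count_table(m, lib), cs,
                            engine_params(pseudocount = 0, scale = 300)),
               engine_params(pseudocount = 0, scale = 300, window = 1))
  expect_equal(st$fc, c(-1, 1))
  expect_equal(st$std, c(sqrt(2), sqrt(2)))
  expect_equal(st$z, c(-1, 1) / sqrt(2))

  # all fc equal -> window sd 0 -> floored at min_std
  m2 <- matrix(c(10, 40, 10, 40), 2,
               dimnames = list(lib$guide_id, c("ctrl", "trt")))
  st2 <- eb_std(guide_log2fc(count_table(m2, lib), cs, engine_params()),
                engine_params(window = 1, min_std = 1e-6))
  expect_equal(st2$std, c(1e-6, 1e-6))

  expect_error(eb_std(st[1, , drop = FALSE]), class = "invalid_parameter")
})

test_that("window boundaries clamp to the table edges", {
  # 10 guides, w = 3: the rank-1 guide's window spans ranks 1-4
  lib10 <- compose_library(5, 0, 0, 2)
  set.seed(42)
  ctrl <- sort(sample(100:1000, 10), decreasing = TRUE)
  trt <- sample(100:1000, 10)
  m <- matrix(c(ctrl, trt), 10, dimnames = list(lib10$guide_id, c("ctrl", "trt")))
  tab <- count_table(m, lib10)
  p <- engine_params(pseudocount = 0, window = 3)
  st <- eb_std(guide_log2fc(tab, contrast_spec("c", "ctrl", "trt"), p), p)
  ord <- order(-st$norm_ctrl, st$guide_id, method = "radix")
  fc_sorted <- st$fc[ord]
  expect_equal(st$std[ord[1]], max(sd(fc_sorted[1:4]), 1e-6))
  expect_equal(st$std[ord[10]], max(sd(fc_sorted[7:10]), 1e-6))
  expect_equal(st$std[ord[5]], max(sd(fc_sorted[2:8]), 1e-6))
})

test_that("gene aggregation sums z, scales by sqrt(numObs) and re-standardizes", {
  st <- data.frame(
    guide_id = sprintf("g%02d", 1:12),
    unit = rep(c("A", "B", "C"), each = 4),
    pair = 1L,
    z = c(1, 1, 1, 1, 0, 0, 0, 0, -1, -1, -1, -1),
    stringsAsFactors = FALSE)
  res <- gene_scores(st)
  a <- res[res$unit == "A", ]
  expect_equal(a$sumZ, 4)
  expect_equal(a$numObs, 4)
  # raw score before re-standardization: 4 / sqrt(4) = 2
  expect_equal(a$sumZ / sqrt(a$numObs), 2)
  expect_equal(mean(res$normZ), 0, tolerance = 1e-9)
  expect_equal(sd(res$normZ), 1, tolerance = 1e-9)
  expect_equal(res$p_left + res$p_right, rep(1, 3))
  # rank follows ascending normZ
  expect_equal(res$unit[res$rank == 1], "C")
})

test_that("BH adjustment matches the step-up enumeration oracle", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("run_contrast matches the independent straight-line oracle", {
  # 50 guides / 10 genes, every field within 1e-9
  lib <- compose_library(10, 0, 10, 4)  # 40 targeting + 10 ntc = 50 guides
  tab <- random_count_table(lib, seed = 21)
  cs <- contrast_spec("trt_vs_ctrl", "ctrl", "trt")
  for (w in c(3, 10, 50)) {
    p <- engine_params(window = w)
    got <- run_contrast(tab, cs, p)
    want <- oracle_run_contrast(tab, "ctrl", "trt", window = min(w, 50))
    expect_equal(got$unit, want$unit)
    for (col in c("numObs", "sumZ", "normZ", "p_left", "p_right",
                  "fdr_left", "fdr_right")) {
      expect_lt(max(abs(got[[col]] - want[[col]])), 1e-9)
    }
  }
})

test_that("scores are invariant to guide row order", {
  lib <- small_library()
  tab <- random_count_table(lib, seed = 31)
  cs <- contrast_spec("c", "ctrl", "trt")
  res1 <- run_contrast(tab, cs)
  perm <- with_seed_test(5, sample(nrow(tab)))
  tab2 <- tab[perm, , drop = FALSE]
  class(tab2) <- class(tab)
  res2 <- run_contrast(tab2, cs)
  expect_equal(res1, res2)
})

test_that("degenerate contrasts (treated identical to control) give normZ 0", {
  lib <- small_library()
  tab <- random_count_table(lib, seed = 41)
  tab$trt <- tab$ctrl
  class(tab) <- c("count_table", "data.frame")
  res <- run_contrast(tab, contrast_spec("c", "ctrl", "trt"))
  expect_true(all(res$normZ == 0))
  expect_true(all(res$p_left == 0.5))
})

test_that("normZ is invariant to per-sample scaling when pseudocount is 0", {
  lib <- small_library()
  tab <- random_count_table(lib, seed = 51)
  p <- engine_params(pseudocount = 0)
  res1 <- run_contrast(tab, contrast_spec("c", "ctrl", "trt"), p)
  tab2 <- tab
  tab2$trt <- tab2$trt * 7L
  class(tab2) <- class(tab)
  res2 <- run_contrast(tab2, contrast_spec("c", "ctrl", "trt"), p)
  expect_equal(res1$normZ, res2$normZ, tolerance = 1e-12)
})

test_that("p_left decreases in normZ and fdr never undercuts p", {
  sim <- study_screen(seed = 61, n_target = 50, n_essential = 5, n_ntc = 40)
  res <- run_contrast(sim$table, contrast_spec("c", "T0", "DMSO"))
  # depletion p-value grows with normZ: the most depleted gene is the most
  # significant in the left tail
  o <- order(res$normZ)
  expect_true(all(diff(res$p_left[o]) >= 0))
  expect_true(all(diff(res$p_left[o])[diff(res$normZ[o]) > 0] > 0))
  expect_true(all(res$fdr_left >= res$p_left))
  expect_true(all(res$fdr_right >= res$p_right))
  expect_true(all(res$p_left > 0 & res$p_left < 1))
})

test_that("null screens yield calibrated left-tail p-values", {
  sim <- study_screen(seed = 71)  # all effects zero, study-scale library
  res <- run_contrast(sim$table, contrast_spec("c", "T0", "DMSO"))
  frac <- mean(res$p_left < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})
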