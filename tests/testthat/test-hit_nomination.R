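# minimal hand-built score tables for rule-level tests
mk_scores <- function(genes, normZ, fdr_left = rep(0.5, length(genes))) {
  structure(list(scores = data.frame(
    gene = genes, mean_normZ = normZ,
    p_left = pnorm(normZ), p_right = 1 - pnorm(normZ),
    fdr_left = fdr_left, fdr_right = 1 - fdr_left,
    stringsAsFactors = FALSE)), class = "averaged_score_table")
}

two_line_scores <- function(fit1, fit2, ola1, fdr1 = 0.5) {
  list(
    L1 = list(DMSO_vs_T0 = mk_scores("G1", fit1),
              OLA_vs_DMSO = mk_scores("G1", ola1, fdr1)),
    L2 = list(DMSO_vs_T0 = mk_scores("G1", fit2),
              OLA_vs_DMSO = mk_scores("G1", 0))
  )
}

test_that("the nomination rule combines fitness window and drug threshold", {
  # neutral fitness in both lines, strong drug depletion in one -> nominated
  h <- nominate_hits(two_line_scores(0.2, -0.3, -2.5),
                     "DMSO_vs_T0", "OLA_vs_DMSO")
  expect_true(h$nominated[h$gene == "G1"])

  # fitness outside the window in one line -> never nominated
  h2 <- nominate_hits(two_line_scores(-1.5, 0.0, -2.5),
                      "DMSO_vs_T0", "OLA_vs_DMSO")
  expect_false(h2$nominated[h2$gene == "G1"])

  # fitness exactly -1.0 sits inside the closed window
  h3 <- nominate_hits(two_line_scores(-1.0, 0.0, -2.5),
                      "DMSO_vs_T0", "OLA_vs_DMSO")
  expect_true(h3$nominated[h3$gene == "G1"])

  # drug normZ exactly -1 fails the strict threshold
  h4 <- nominate_hits(two_line_scores(0, 0, -1.0),
                      "DMSO_vs_T0", "OLA_vs_DMSO")
  expect_false(h4$nominated[h4$gene == "G1"])
})

test_that("FDR acts as a flag by default and as a gate on request", {
  sc <- two_line_scores(0, 0, -2.5, fdr1 = 0.5)
  h <- nominate_hits(sc, "DMSO_vs_T0", "OLA_vs_DMSO")
  expect_true(h$nominated)
  expect_false(h$fdr_pass)

  h2 <- nominate_hits(sc, "DMSO_vs_T0", "OLA_vs_DMSO",
                      nomination_criteria(require_fdr = TRUE))
  expect_false(h2$nominated)

  sc3 <- two_line_scores(0, 0, -2.5, fdr1 = 0.05)
  h3 <- nominate_hits(sc3, "DMSO_vs_T0", "OLA_vs_DMSO",
                      nomination_criteria(require_fdr = TRUE))
  expect_true(h3$nominated)
  expect_true(h3$fdr_pass)
})

test_that("genes without a fitness score are unevaluable, not nominated", {
  sc <- list(L1 = list(DMSO_vs_T0 = mk_scores("G1", 0),
                       OLA_vs_DMSO = mk_scores(c("G1", "G2"), c(-2.5, -2.5))))
  h <- nominate_hits(sc, "DMSO_vs_T0", "OLA_vs_DMSO")
  expect_true(h$nominated[h$gene == "G1"])
  expect_false(h$nominated[h$gene == "G2"])
  expect_true(h$unevaluable[h$gene == "G2"])
  expect_equal(h$criteria_met[h$gene == "G2"], "unevaluable")

  # a missing fitness contrast altogether is an error
  expect_error(nominate_hits(list(L1 = list(OLA_vs_DMSO = mk_scores("G1", -3))),
                             "DMSO_vs_T0", "OLA_vs_DMSO"),
               class = "invalid_parameter")
})

test_that("nomination is monotone in the driving scores", {
  set.seed(2)
  for (i in 1:20) {
    fit <- runif(2, -2, 2)
    drug <- runif(1, -3, 1)
    h <- nominate_hits(two_line_scores(fit[1], fit[2], drug),
                       "DMSO_vs_T0", "OLA_vs_DMSO")$nominated
    # lowering drug normZ never un-nominates
    h_lower <- nominate_hits(two_line_scores(fit[1], fit[2], drug - 1),
                             "DMSO_vs_T0", "OLA_vs_DMSO")$nominated
    # moving fitness toward 0 never un-nominates
    h_center <- nominate_hits(two_line_scores(fit[1] / 2, fit[2] / 2, drug),
                              "DMSO_vs_T0", "OLA_vs_DMSO")$nominated
    if (h) {
      expect_true(h_lower)
      expect_true(h_center)
    }
  }
})

test_that("guide concordance counts depleted guides", {
  lib <- compose_library(2, 0, 0, 4)
  cs <- contrast_spec("c", "ctrl", "trt")
  m <- matrix(0L, 8, 2, dimnames = list(lib$guide_id, c("ctrl", "trt")))
  m[, "ctrl"] <- 100L
  # gene 1: all 4 guides depleted; gene 2: 2 of 4 (equal column totals)
  m[, "trt"] <- c(50L, 60L, 70L, 80L, 150L, 90L, 60L, 240L)
  m[, "ctrl"] <- c(100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L)
  tab <- count_table(m, lib)
  p0 <- engine_params(pseudocount = 0)
  expect_equal(guide_concordance(tab, cs, "TGT0001", p0), 1.0)
  expect_equal(guide_concordance(tab, cs, "TGT0002", p0), 0.5)
  # no guide depleted
  m2 <- m; m2[, "trt"] <- 300L
  expect_equal(guide_concordance(count_table(m2, lib), cs, "TGT0001", p0), 0.0)
  expect_error(guide_concordance(tab, cs, "NOPE", p0),
               class = "invalid_parameter")
})

test_that("known sensitizers are flagged case-insensitively", {
  sc <- list(L1 = list(DMSO_vs_T0 = mk_scores(c("BRCA1", "brca1x", "xrcc1"),
                                              c(0, 0, 0)),
                       OLA_vs_DMSO = mk_scores(c("BRCA1", "brca1x", "xrcc1"),
                                               c(-2, -2, -2))))
  known <- c("CHD1L", "BRCA1", "MUS81", "RNASEH2A", "XRCC1")
  h <- nominate_hits(sc, "DMSO_vs_T0", "OLA_vs_DMSO", known_genes = known)
  expect_true(h$known_sensitizer[h$gene == "BRCA1"])
  expect_true(h$known_sensitizer[h$gene == "xrcc1"])
  expect_false(h$known_sensitizer[h$gene == "brca1x"])
  h2 <- annotate_known(h, character())
  expect_false(any(h2$known_sensitizer))
})
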