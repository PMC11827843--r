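test_that("essential-gene exclusion removes exactly the excluded categories", {
  lib <- compose_library(356, 63, 324, 4)
  tab <- random_count_table(lib, seed = 1)
  out <- exclude_essentials(tab, resampling_params())
  expect_equal(nrow(out), 1748)  # 2000 - 63 * 4
  expect_false(any(out$category == "essential"))
  # guide order preserved
  expect_equal(out$guide_id, tab$guide_id[tab$category != "essential"])

  # nothing to exclude -> identity
  ntab <- random_count_table(compose_library(3, 0, 8, 4), seed = 2)
  expect_equal(exclude_essentials(ntab, resampling_params()), ntab)

  # excluding everything is an error
  expect_error(
    exclude_essentials(tab, resampling_params(
      excluded_categories = c("target", "essential", "ntc"))),
    class = "invalid_parameter")
})

test_that("NTC aggregation partitions guides into groups of group_size", {
  ids <- sprintf("NTC%04d", 1:324)
  map <- aggregate_ntc(ids, 4, seed = 11)
  expect_equal(length(map), 324)
  expect_equal(length(unique(map)), 81)
  expect_true(all(table(map) == 4))
  expect_setequal(names(map), ids)
  # seeded determinism
  expect_identical(aggregate_ntc(ids, 4, seed = 11), map)
  expect_false(identical(aggregate_ntc(ids, 4, seed = 12), map))

  # remainder guides dropped with a warning
  expect_warning(map10 <- aggregate_ntc(ids[1:10], 4, seed = 1),
                 "2 NTC guide")
  expect_equal(length(map10), 8)
  expect_equal(length(unique(map10)), 2)

  expect_error(aggregate_ntc(ids[1:3], 4, seed = 1),
               class = "invalid_parameter")
})

test_that("different repetitions use different aggregations", {
  s1 <- vapply(1:50, function(k) child_seed_test(42, k), integer(1))
  s2 <- vapply(1:50, function(k) child_seed_test(43, k), integer(1))
  expect_false(anyDuplicated(s1) > 0)
  expect_equal(length(intersect(s1, s2)), 0)
})

test_that("a single repetition reproduces a direct scoring run exactly", {
  sim <- study_screen(seed = 5, n_target = 30, n_essential = 5, n_ntc = 24)
  cs <- contrast_spec("DMSO_vs_T0", "T0", "DMSO")
  rp <- resampling_params(n_rep = 1, seed = 77)
  avg <- resampled_scores(sim$table, cs, engine_params(), rp)

  # rebuild the rep-1 table by hand and score it once
  base <- exclude_essentials(sim$table, rp)
  ntc_ids <- base$guide_id[base$category == "ntc"]
  map <- aggregate_ntc(ntc_ids, 4, seed = child_seed_test(77, 1))
  tab1 <- base
  hit <- match(tab1$guide_id, names(map))
  tab1$gene[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  class(tab1) <- class(base)
  direct <- run_contrast(tab1, cs, engine_params())

  real <- direct[!startsWith(direct$unit, "NTC_PG_"), ]
  expect_identical(avg$scores$mean_normZ[match(real$unit, avg$scores$gene)],
                   real$normZ)
  # averaged normZ equals the mean of the per-rep trace by definition
  expect_equal(avg$scores$mean_normZ,
               rowMeans(avg$trace)[avg$scores$gene], ignore_attr = TRUE)
})

test_that("resampled output is bit-reproducible and respects the budget", {
  sim <- study_screen(seed = 6, n_target = 20, n_essential = 3, n_ntc = 16)
  cs <- contrast_spec("c", "T0", "DMSO")
  a <- resampled_scores(sim$table, cs, engine_params(),
                        resampling_params(n_rep = 5, seed = 3))
  b <- resampled_scores(sim$table, cs, engine_params(),
                        resampling_params(n_rep = 5, seed = 3))
  expect_identical(a$scores, b$scores)
  expect_identical(a$trace, b$trace)
  expect_error(
    resampled_scores(sim$table, cs, engine_params(),
                     resampling_params(n_rep = 5, seed = 3, max_cells = 10)),
    class = "budget_error")
  expect_error(
    resampled_scores(random_count_table(compose_library(4, 0, 0, 4), seed = 2),
                     contrast_spec("c", "ctrl", "trt"), engine_params(),
                     resampling_params(seed = 1)),
    class = "invalid_parameter")
})

test_that("averaging across repetitions shrinks the score variance", {
  # the same simulated table scored under >= 20 different master seeds:
  # sd across seeds of the 25-rep average < sd of a single-rep score
  sim <- study_screen(seed = 9, n_target = 25, n_essential = 4, n_ntc = 40)
  cs <- contrast_spec("c", "T0", "DMSO")
  seeds <- 101:124
  single <- avg25 <- matrix(NA_real_, 25, length(seeds))
  for (i in seq_along(seeds)) {
    r1 <- resampled_scores(sim$table, cs, engine_params(),
                           resampling_params(n_rep = 1, seed = seeds[i]))
    r25 <- resampled_scores(sim$table, cs, engine_params(),
                            resampling_params(n_rep = 25, seed = seeds[i]))
    tgt <- grep("^TGT", r1$scores$gene)
    single[, i] <- r1$scores$mean_normZ[order(r1$scores$gene)][
      grepl("^TGT", sort(r1$scores$gene))]
    avg25[, i] <- r25$scores$mean_normZ[order(r25$scores$gene)][
      grepl("^TGT", sort(r25$scores$gene))]
  }
  sd_single <- mean(apply(single, 1, sd))
  sd_avg <- mean(apply(avg25, 1, sd))
  expect_lt(sd_avg, sd_single)
})

test_that("NTC pseudogenes stay near zero on null screens", {
  sim <- study_screen(seed = 13)  # study-scale, all effects zero
  cs <- contrast_spec("DMSO_vs_T0", "T0", "DMSO")
  avg <- resampled_scores(sim$table, cs, engine_params(),
                          resampling_params(n_rep = 20, seed = 17))
  expect_true(all(abs(avg$ntc$mean_normZ) < 0.2))
  expect_lt(mean(abs(avg$scores$mean_normZ) > 3), 0.01)
})
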