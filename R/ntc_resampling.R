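# NTC-pseudogene resampling wrapper around the scorer.
#
# The null for a custom library with many non-targeting controls: exclude
# essential genes from the count table, randomly aggregate NTC guides into
# groups of 4 treated as single genes, score, repeat 100 times with fresh
# aggregations, and average each real gene's normZ over the repetitions.
# P-values come from the averaged z via the standard normal and are
# BH-corrected per tail over real genes. The averaged statistic is
# conservative (its variance is below 1 because only the NTC aggregation
# changes between repetitions); this is documented, not corrected.

#' Resampling parameters
#'
#' @param group_size NTC guides per pseudogene (default 4).
#' @param n_rep number of random aggregations (default 100).
#' @param seed master seed; repetition k derives its own child seed through
#'   a fixed counter-based rule, so results are order-insensitive and
#'   bit-reproducible.
#' @param excluded_categories guide categories removed before scoring
#'   (default `"essential"`).
#' @param max_cells budget guard: `n_rep * guides * samples` may not exceed
#'   this (default 5e8).
#' @return a list of class `resampling_params`.
#' @export
resampling_params <- function(group_size = 4, n_rep = 100, seed = 1,
                              excluded_categories = "essential",
                              max_cells = 5e8) {
  stopifnot(group_size >= 1, n_rep >= 1)
  structure(list(group_size = as.integer(group_size),
                 n_rep = as.integer(n_rep), seed = as.integer(seed),
                 excluded_categories = excluded_categories,
                 max_cells = max_cells),
            class = "resampling_params")
}

#' Remove excluded guide categories from a count table
#'
#' @param table a `count_table` (annotated with categories).
#' @param params a `resampling_params`; its `excluded_categories` rows are
#'   dropped, guide order otherwise preserved.
#' @return the filtered `count_table`.
#' @export
exclude_essentials <- function(table, params = resampling_params()) {
  keep <- !(table$category %in% params$excluded_categories)
  if (!any(keep)) {
    sk_stop("invalid_parameter", "exclusion would remove every guide")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Randomly aggregate NTC guides into pseudogenes
#'
#' Draws a uniformly random partition: the ids are shuffled and consecutive
#' blocks of `group_size` become pseudogenes `NTC_PG_0001`, ... If the
#' number of ids is not divisible by `group_size`, the remainder guides are
#' dropped from that repetition with a warning.
#'
#' @param ntc_guide_ids NTC guide ids (at least `group_size` of them).
#' @param group_size guides per pseudogene.
#' @param seed integer seed for the shuffle.
#' @return named character vector: names are guide ids (those kept), values
#'   the assigned pseudogene labels.
#' @export
aggregate_ntc <- function(ntc_guide_ids, group_size = 4, seed) {
  n <- length(ntc_guide_ids)
  if (n < group_size) {
    sk_stop("invalid_parameter", "fewer NTC guides than one group")
  }
  shuffled <- with_seed(seed, sample(ntc_guide_ids))
  n_groups <- n %/% group_size
  rem <- n - n_groups * group_size
  if (rem > 0) {
    warning(sprintf("%d NTC guide(s) dropped from this aggregation (remainder of %d / %d)",
                    rem, n, group_size))
    shuffled <- shuffled[seq_len(n_groups * group_size)]
  }
  labels <- sprintf("NTC_PG_%04d", rep(seq_len(n_groups), each = group_size))
  stats::setNames(labels, shuffled)
}

#' Resampled, averaged normZ scores for one contrast
#'
#' For each repetition k = 1..n_rep: exclude the configured categories,
#' relabel NTC guides by a fresh random aggregation (child seed derived
#' from the master seed and k), score the contrast, and record every real
#' gene's normZ. Real genes are then reported with the arithmetic mean of
#' their per-repetition normZ, `p_left = pnorm(mean normZ)`,
#' `p_right = 1 - p_left`, and BH FDR per tail over real genes only. NTC
#' pseudogenes change membership between repetitions, so they are reported
#' as per-repetition diagnostics rather than averaged.
#'
#' @param table a `count_table` containing NTC guides.
#' @param contrast a `contrast_spec`.
#' @param engine an `engine_params`.
#' @param params a `resampling_params` (carries the master seed).
#' @return an `averaged_score_table`: list with `scores` (data.frame
#'   `gene`, `mean_normZ`, `p_left`, `p_right`, `fdr_left`, `fdr_right`),
#'   `trace` (genes x n_rep matrix of per-repetition normZ), `ntc`
#'   (per-repetition pseudogene diagnostics: mean, sd, fraction beyond
#'   |normZ| > 1.645), `label`, `params`, `warnings`.
#' @export
resampled_scores <- function(table, contrast, engine = engine_params(),
                             params = resampling_params()) {
  ntc_ids <- table$guide_id[table$category == "ntc"]
  if (!length(ntc_ids)) {
    sk_stop("invalid_parameter", "table contains no NTC guides")
  }
  base <- exclude_essentials(table, params)
  cells <- as.numeric(params$n_rep) * nrow(base) * length(count_samples(base))
  if (cells > params$max_cells) {
    sk_stop("budget_error", sprintf(
      "resampling budget exceeded: %g cells > %g", cells, params$max_cells))
  }
  ntc_ids <- base$guide_id[base$category == "ntc"]
  is_ntc <- base$category == "ntc"
  real_genes <- sort(unique(base$gene[!is_ntc]))
  warns <- character()

  trace <- matrix(NA_real_, length(real_genes), params$n_rep,
                  dimnames = list(real_genes, NULL))
  ntc_diag <- vector("list", params$n_rep)
  for (k in seq_len(params$n_rep)) {
    ck <- child_seed(params$seed, k)
    map <- withCallingHandlers(
      aggregate_ntc(ntc_ids, params$group_size, ck),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tab_k <- base
    hit <- match(tab_k$guide_id, names(map))
    # NTC guides not in the partition (remainder) are dropped this rep
    keep <- !is_ntc | !is.na(hit)
    tab_k$gene[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    tab_k <- tab_k[keep, , drop = FALSE]
    class(tab_k) <- class(base)
    res <- run_contrast(tab_k, contrast, engine)
    is_pg <- startsWith(res$unit, "NTC_PG_")
    trace[res$unit[!is_pg], k] <- res$normZ[!is_pg]
    pg <- res$normZ[is_pg]
    ntc_diag[[k]] <- data.frame(
      rep = k, n_pseudogenes = sum(is_pg),
      mean_normZ = mean(pg), sd_normZ = stats::sd(pg),
      q05_normZ = unname(stats::quantile(pg, 0.05)),
      q95_normZ = unname(stats::quantile(pg, 0.95)),
      frac_beyond_1.645 = mean(abs(pg) > 1.645))
  }
  mean_nz <- rowMeans(trace)
  p_left <- .clamp_p(stats::pnorm(mean_nz))
  p_right <- 1 - p_left
  scores <- data.frame(
    gene = real_genes, mean_normZ = mean_nz,
    p_left = p_left, p_right = p_right,
    fdr_left = stats::p.adjust(p_left, method = "BH"),
    fdr_right = stats::p.adjust(p_right, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
  scores <- scores[order(scores$mean_normZ, scores$gene, method = "radix"), ]
  rownames(scores) <- NULL
  structure(list(scores = scores, trace = trace,
                 ntc = do.call(rbind, ntc_diag),
                 label = contrast$label, params = params,
                 warnings = unique(warns)),
            class = "averaged_score_table")
}

#' Write an averaged score table to TSV
#'
#' Columns: GENE, MEAN_NORMZ, P_LEFT, P_RIGHT, FDR_LEFT, FDR_RIGHT.
#' @param avg an `averaged_score_table`.
#' @param path output path.
#' @param trace_path optional path for the per-repetition normZ trace TSV.
#' @export
write_averaged_scores <- function(avg, path, trace_path = NULL) {
  out <- avg$scores
  colnames(out) <- c("GENE", "MEAN_NORMZ", "P_LEFT", "P_RIGHT",
                     "FDR_LEFT", "FDR_RIGHT")
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(trace_path)) {
    tr <- data.frame(GENE = rownames(avg$trace), avg$trace,
                     check.names = FALSE)
    colnames(tr)[-1] <- paste0("REP", seq_len(ncol(avg$trace)))
    utils::write.table(format(tr, digits = 15, trim = TRUE, scientific = FALSE),
                       trace_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
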