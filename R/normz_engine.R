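# Core scorer: guide-level fold-change z-scores with a rank-window
# empirical-Bayes standard deviation, summed per gene and re-standardized
# into normZ, with one-tailed normal p-values and BH FDR per tail.
#
# The algorithm is fixed here: pseudocount 5, per-sample normalization to
# 1e7 reads, empirical-Bayes std over a +/- w rank window on guides sorted
# by normalized control count (w = min(500, max(50, floor(n/4))); the
# common fixed 500 would span a quarter of a 2,000-guide custom library, so
# the cap adapts to keep the window local), sample sd with denominator
# n - 1, std floor 1e-6. Internal self-consistency and the brute-force
# oracle in the tests are the contract; numerical parity with any external
# tool version is not claimed.

#' Define a contrast between control and treated samples
#'
#' @param label contrast name, e.g. `"OLA_vs_DMSO"`.
#' @param control_samples,treated_samples sample ids; non-empty, disjoint.
#' @param paired if `TRUE`, the k-th control is paired with the k-th treated
#'   sample (lists must have equal length); if `FALSE` every control is
#'   paired with every treated sample. With single columns per arm (this
#'   study's design) the two are identical.
#' @return a list of class `contrast_spec`.
#' @export
contrast_spec <- function(label, control_samples, treated_samples, paired = FALSE) {
  if (!length(control_samples) || !length(treated_samples)) {
    sk_stop("invalid_parameter", "control and treated sample lists must be non-empty")
  }
  if (length(intersect(control_samples, treated_samples))) {
    sk_stop("invalid_parameter", "control and treated samples must be disjoint")
  }
  if (paired && length(control_samples) != length(treated_samples)) {
    sk_stop("invalid_parameter", "paired contrasts need equal-length sample lists")
  }
  structure(list(label = label,
                 control_samples = as.character(control_samples),
                 treated_samples = as.character(treated_samples),
                 paired = isTRUE(paired)),
            class = "contrast_spec")
}

#' Scoring parameters
#'
#' @param pseudocount added to every normalized count (default 5).
#' @param scale per-sample normalization target in reads (default 1e7).
#' @param window empirical-Bayes half-window in ranks; `NULL` (default)
#'   resolves to `min(500, max(50, floor(n_guides / 4)))` at scoring time.
#' @param min_std floor on the empirical-Bayes standard deviation
#'   (default 1e-6), keeping every z finite.
#' @return a list of class `engine_params`.
#' @export
engine_params <- function(pseudocount = 5, scale = 1e7, window = NULL,
                          min_std = 1e-6) {
  stopifnot(pseudocount >= 0, scale > 0, min_std > 0,
            is.null(window) || (window >= 1 && window == floor(window)))
  structure(list(pseudocount = pseudocount, scale = scale,
                 window = window, min_std = min_std),
            class = "engine_params")
}

.resolve_window <- function(params, n_guides) {
  w <- params$window
  if (is.null(w)) w <- min(500, max(50, floor(n_guides / 4)))
  min(w, n_guides)
}

#' Normalize a column of read counts
#'
#' `c'_i = pseudocount + c_i * scale / sum(c)`.
#'
#' @param column nonnegative integer counts with a positive total.
#' @param params an `engine_params`.
#' @return numeric vector of normalized counts.
#' @export
normalize_counts <- function(column, params = engine_params()) {
  tot <- sum(column)
  if (tot <= 0) sk_stop("value_error", "cannot normalize an all-zero column")
  params$pseudocount + column * params$scale / tot
}

# expand a contrast into (control, treated) column pairs
.contrast_pairs <- function(contrast) {
  if (contrast$paired) {
    data.frame(control = contrast$control_samples,
               treated = contrast$treated_samples,
               stringsAsFactors = FALSE)
  } else {
    expand.grid(control = contrast$control_samples,
                treated = contrast$treated_samples,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
}

#' Guide-level log2 fold changes for a contrast
#'
#' Normalizes the contrast's sample columns and computes, for every
#' (control, treated) pair, `fc = log2(normalized treated / normalized
#' control)` per guide.
#'
#' @param table a `count_table`.
#' @param contrast a `contrast_spec`.
#' @param params an `engine_params`.
#' @return a `guide_stats` data.frame: `guide_id`, `unit` (gene), `pair`,
#'   `norm_ctrl`, `norm_trt`, `fc`.
#' @export
guide_log2fc <- function(table, contrast, params = engine_params()) {
  cols <- c(contrast$control_samples, contrast$treated_samples)
  missing <- setdiff(cols, count_samples(table))
  if (length(missing)) {
    sk_stop("invalid_parameter", paste0(
      "contrast samples missing from table: ", paste(missing, collapse = ", ")))
  }
  norm <- lapply(table[cols], normalize_counts, params = params)
  pairs <- .contrast_pairs(contrast)
  n <- nrow(table)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    nc <- norm[[pairs$control[k]]]
    nt <- norm[[pairs$treated[k]]]
    data.frame(guide_id = table$guide_id, unit = table$gene,
               pair = k, norm_ctrl = nc, norm_trt = nt,
               fc = log2(nt / nc), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("guide_stats", "data.frame")
  out
}

#' Empirical-Bayes standard deviation of guide fold changes
#'
#' Within each (control, treated) pair, guides are sorted by normalized
#' control count descending (ties broken by guide_id, C-locale); the guide
#' at rank r receives the sample standard deviation (denominator n - 1) of
#' the fold changes at ranks [max(1, r - w), min(N, r + w)], floored at
#' `min_std`. Fills `std` and `z = fc / std`.
#'
#' @param stats a `guide_stats` from [guide_log2fc()].
#' @param params an `engine_params`.
#' @return the `guide_stats` with `std` and `z` columns filled.
#' @export
eb_std <- function(stats, params = engine_params()) {
  n_guides <- length(unique(stats$guide_id))
  if (n_guides < 2) sk_stop("invalid_parameter", "need at least 2 guides")
  w <- .resolve_window(params, n_guides)
  stats$std <- NA_real_
  for (k in unique(stats$pair)) {
    idx <- which(stats$pair == k)
    nc <- stats$norm_ctrl[idx]
    gid <- stats$guide_id[idx]
    ord <- order(-nc, gid, method = "radix")
    fc <- stats$fc[idx][ord]
    N <- length(fc)
    r <- seq_len(N)
    lo <- pmax(1L, r - w)
    hi <- pmin(N, r + w)
    cs1 <- cumsum(fc)
    cs2 <- cumsum(fc * fc)
    s1 <- cs1[hi] - c(0, cs1)[lo]
    s2 <- cs2[hi] - c(0, cs2)[lo]
    nw <- hi - lo + 1
    v <- (s2 - s1 * s1 / nw) / (nw - 1)
    sd_w <- sqrt(pmax(v, 0))
    stats$std[idx[ord]] <- pmax(sd_w, params$min_std)
  }
  stats$z <- stats$fc / stats$std
  stats
}

.clamp_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)

#' Aggregate guide z-scores into gene-level normZ scores
#'
#' Per unit (gene or NTC pseudogene): `sumZ` is the sum of z over its
#' guide-pair observations, the raw score is `sumZ / sqrt(numObs)`, and
#' normZ re-standardizes the raw scores to mean 0 / sd 1 across units.
#' One-tailed p-values come from the standard normal (left tail = depletion
#' / sensitizer, right tail = enrichment / suppressor); BH FDR is computed
#' within each tail separately, over all scored units, because the two
#' tails are separate hypothesis families. If the raw scores are constant
#' across units (degenerate input, e.g. treated identical to control) all
#' normZ are set to 0 and p to 0.5.
#'
#' @param stats a `guide_stats` with `z` filled.
#' @param gene_mapping optional named character vector guide_id -> unit;
#'   defaults to the `unit` column. Guides absent from the mapping are
#'   excluded with a warning.
#' @return a `gene_score_table`: `unit`, `numObs`, `sumZ`, `normZ`,
#'   `p_left`, `p_right`, `fdr_left`, `fdr_right`, `rank` (ascending
#'   normZ), sorted by rank.
#' @export
gene_scores <- function(stats, gene_mapping = NULL) {
  if (!is.null(gene_mapping)) {
    unit <- unname(gene_mapping[stats$guide_id])
    drop <- is.na(unit)
    if (any(drop)) {
      warning(sprintf("%d guide observations without a unit mapping excluded",
                      sum(drop)))
      stats <- stats[!drop, , drop = FALSE]
      unit <- unit[!drop]
    }
    stats$unit <- unit
  }
  if (!nrow(stats)) sk_stop("invalid_parameter", "no scored observations")
  sums <- rowsum(stats$z, stats$unit)
  units <- rownames(sums)
  n_obs <- as.vector(rowsum(rep(1L, nrow(stats)), stats$unit))
  sumZ <- as.vector(sums)
  raw <- sumZ / sqrt(n_obs)
  s <- stats::sd(raw)
  if (length(raw) < 2 || !is.finite(s) || s == 0) {
    normZ <- rep(0, length(raw))
    p_left <- rep(0.5, length(raw))
  } else {
    normZ <- (raw - mean(raw)) / s
    p_left <- .clamp_p(stats::pnorm(normZ))
  }
  p_right <- 1 - p_left
  out <- data.frame(unit = units, numObs = n_obs, sumZ = sumZ, normZ = normZ,
                    p_left = p_left, p_right = p_right,
                    fdr_left = stats::p.adjust(p_left, method = "BH"),
                    fdr_right = stats::p.adjust(p_right, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$normZ, out$unit, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Score one contrast end to end
#'
#' Composition: normalize counts, guide log2 fold changes, empirical-Bayes
#' std, z, gene-level normZ. Deterministic for fixed inputs and invariant
#' to guide row order.
#'
#' @param table a `count_table`.
#' @param contrast a `contrast_spec`.
#' @param params an `engine_params`.
#' @return a `gene_score_table`.
#' @export
run_contrast <- function(table, contrast, params = engine_params()) {
  stats <- guide_log2fc(table, contrast, params)
  stats <- eb_std(stats, params)
  gene_scores(stats)
}

#' Write a gene score table to TSV
#'
#' Columns: UNIT, NUMOBS, SUMZ, NORMZ, P_LEFT, P_RIGHT, FDR_LEFT,
#' FDR_RIGHT, RANK.
#' @param scores a `gene_score_table`.
#' @param path output path.
#' @export
write_gene_scores <- function(scores, path) {
  out <- scores[, c("unit", "numObs", "sumZ", "normZ", "p_left", "p_right",
                    "fdr_left", "fdr_right", "rank")]
  colnames(out) <- c("UNIT", "NUMOBS", "SUMZ", "NORMZ", "P_LEFT", "P_RIGHT",
                     "FDR_LEFT", "FDR_RIGHT", "RANK")
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
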