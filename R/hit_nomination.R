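# Hit nomination: combine the fitness contrast (vehicle vs T0) with the
# drug contrasts (drug vs vehicle) across cell lines.
#
# A gene is nominated as a sensitizer when its fitness normZ lies in the
# closed window [-1, +1] in every cell line where it is measured (the gene
# is not itself a fitness gene) AND its drug normZ is strictly below -1 in
# at least one (cell line, drug). FDR < 0.1 is an annotation flag by
# default, not a gate, because published workflows combine it loosely with
# a by-eye consistency check of the per-guide counts; `require_fdr = TRUE`
# turns it into a hard gate.

#' Nomination criteria
#'
#' @param fitness_window closed interval on the fitness-contrast normZ
#'   (default `c(-1, 1)`); boundary values are inside.
#' @param drug_threshold strict upper bound on the drug-contrast normZ
#'   (default -1).
#' @param min_cell_lines minimum number of cell lines in which the drug
#'   criterion must fire (default 1).
#' @param fdr_max FDR annotation/gate level (default 0.1).
#' @param require_fdr if `TRUE`, `fdr_left < fdr_max` becomes a gate on the
#'   qualifying drug contrasts instead of a flag.
#' @return a list of class `nomination_criteria`.
#' @export
nomination_criteria <- function(fitness_window = c(-1, 1), drug_threshold = -1,
                                min_cell_lines = 1, fdr_max = 0.1,
                                require_fdr = FALSE) {
  stopifnot(length(fitness_window) == 2, fitness_window[1] < fitness_window[2],
            drug_threshold < fitness_window[2], min_cell_lines >= 1)
  structure(list(fitness_window = fitness_window,
                 drug_threshold = drug_threshold,
                 min_cell_lines = as.integer(min_cell_lines),
                 fdr_max = fdr_max, require_fdr = isTRUE(require_fdr)),
            class = "nomination_criteria")
}

.score_frame <- function(x) {
  if (inherits(x, "averaged_score_table")) {
    data.frame(gene = x$scores$gene, normZ = x$scores$mean_normZ,
               fdr_left = x$scores$fdr_left, stringsAsFactors = FALSE)
  } else if (inherits(x, "gene_score_table")) {
    data.frame(gene = x$unit, normZ = x$normZ, fdr_left = x$fdr_left,
               stringsAsFactors = FALSE)
  } else {
    sk_stop("invalid_parameter", "scores must be averaged_score_table or gene_score_table")
  }
}

#' Nominate sensitizer hits across cell lines
#'
#' @param scores nested list: `scores[[cell_line]][[contrast_label]]` is an
#'   `averaged_score_table` (or `gene_score_table`). Every cell line must
#'   carry the fitness contrast, and at least one drug contrast must be
#'   present overall.
#' @param fitness_label contrast label of the fitness (vehicle vs T0)
#'   comparison.
#' @param drug_labels contrast labels of the drug comparisons.
#' @param criteria a `nomination_criteria`.
#' @param known_genes optional character vector of previously reported
#'   sensitizers, matched case-insensitively.
#' @return a `hit_call_table` data.frame: `gene`, `nominated`,
#'   `unevaluable`, `criteria_met`, `n_lines_drug_hit`, `fdr_pass`,
#'   `known_sensitizer`, plus `normZ_<line>_<label>` / `fdr_<line>_<label>`
#'   columns for every score table supplied.
#' @export
nominate_hits <- function(scores, fitness_label, drug_labels,
                          criteria = nomination_criteria(),
                          known_genes = NULL) {
  lines <- names(scores)
  if (is.null(lines) || !length(lines)) {
    sk_stop("invalid_parameter", "scores must be a named list keyed by cell line")
  }
  for (cl in lines) {
    if (!fitness_label %in% names(scores[[cl]])) {
      sk_stop("invalid_parameter", paste0(
        "cell line ", cl, " lacks the fitness contrast '", fitness_label, "'"))
    }
  }
  if (!any(vapply(scores, function(s) any(drug_labels %in% names(s)), logical(1)))) {
    sk_stop("invalid_parameter", "no drug contrast present in scores")
  }

  frames <- list()
  for (cl in lines) {
    for (lab in names(scores[[cl]])) {
      frames[[paste(cl, lab, sep = "_")]] <- .score_frame(scores[[cl]][[lab]])
    }
  }
  genes <- sort(unique(unlist(lapply(frames, `[[`, "gene"))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(frames)) {
    idx <- match(genes, frames[[nm]]$gene)
    out[[paste0("normZ_", nm)]] <- frames[[nm]]$normZ[idx]
    out[[paste0("fdr_", nm)]] <- frames[[nm]]$fdr_left[idx]
  }

  lo <- criteria$fitness_window[1]; hi <- criteria$fitness_window[2]
  fit_cols <- paste0("normZ_", lines, "_", fitness_label)
  fit_mat <- as.matrix(out[, fit_cols, drop = FALSE])
  measured <- !is.na(fit_mat)
  fit_ok_mat <- fit_mat >= lo & fit_mat <= hi
  fitness_pass <- apply(fit_ok_mat | !measured, 1, all) & rowSums(measured) > 0
  unevaluable <- rowSums(measured) == 0

  n_lines_hit <- integer(length(genes))
  fdr_pass <- logical(length(genes))
  for (cl in lines) {
    labs <- intersect(drug_labels, names(scores[[cl]]))
    if (!length(labs)) next
    nz <- as.matrix(out[, paste0("normZ_", cl, "_", labs), drop = FALSE])
    fd <- as.matrix(out[, paste0("fdr_", cl, "_", labs), drop = FALSE])
    hit <- nz < criteria$drug_threshold & !is.na(nz)
    hit_fdr <- hit & fd < criteria$fdr_max & !is.na(fd)
    line_hit <- if (criteria$require_fdr) hit_fdr else hit
    n_lines_hit <- n_lines_hit + as.integer(apply(line_hit, 1, any))
    fdr_pass <- fdr_pass | apply(hit_fdr, 1, any)
  }
  drug_pass <- n_lines_hit >= criteria$min_cell_lines

  nominated <- fitness_pass & drug_pass & !unevaluable
  crit <- character(length(genes))
  crit[fitness_pass] <- "fitness_window"
  crit[drug_pass] <- trimws(paste(crit[drug_pass], "drug_normZ"))
  crit[fdr_pass] <- trimws(paste(crit[fdr_pass], "fdr"))
  crit[unevaluable] <- "unevaluable"

  out$nominated <- nominated
  out$unevaluable <- unevaluable
  out$criteria_met <- gsub(" ", ";", crit)
  out$n_lines_drug_hit <- n_lines_hit
  out$fdr_pass <- fdr_pass
  out$known_sensitizer <- FALSE
  class(out) <- c("hit_call_table", "data.frame")
  if (!is.null(known_genes)) out <- annotate_known(out, known_genes)
  out
}

#' Fraction of a gene's guides depleted under treatment
#'
#' Quantitative stand-in for the by-eye consistency check of per-guide
#' count plots: the fraction of the gene's (guide, pair) observations with
#' normalized treated count strictly below normalized control count.
#'
#' @param table a `count_table`.
#' @param contrast a `contrast_spec`.
#' @param gene gene id present in the table.
#' @param params an `engine_params`.
#' @return a fraction in [0, 1].
#' @export
guide_concordance <- function(table, contrast, gene,
                              params = engine_params()) {
  if (!gene %in% table$gene) {
    sk_stop("invalid_parameter", paste0("unknown gene: ", gene))
  }
  stats <- guide_log2fc(table, contrast, params)
  stats <- stats[stats$unit == gene, , drop = FALSE]
  mean(stats$norm_trt < stats$norm_ctrl)
}

#' Flag known sensitizers in a hit table
#'
#' @param hits a `hit_call_table`.
#' @param known_genes character vector of known sensitizer symbols; matched
#'   case-insensitively (symbol tables are uppercase, user data varies).
#' @return the `hit_call_table` with `known_sensitizer` filled.
#' @export
annotate_known <- function(hits, known_genes) {
  hits$known_sensitizer <- toupper(hits$gene) %in% toupper(known_genes)
  hits
}

#' Write a hit table to TSV
#' @param hits a `hit_call_table`.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  out <- hits
  score_cols <- grep("^(normZ|fdr)_", colnames(out), value = TRUE)
  front <- c("gene", "nominated", "criteria_met", "n_lines_drug_hit",
             "fdr_pass", "known_sensitizer", "unevaluable")
  out <- out[, c(front, score_cols)]
  colnames(out)[seq_along(front)] <- toupper(front)
  colnames(out)[1] <- "GENE"
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
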