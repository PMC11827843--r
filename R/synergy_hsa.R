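# Highest-single-agent (HSA) drug synergy scoring for two-drug dose
# matrices of % viability.
#
# For each combination cell (both doses > 0), the HSA excess is the
# combination's % inhibition minus the better of the two single agents at
# the same doses; the synergy score is the arithmetic mean of the excess
# over the combination grid, in percentage points. Scores above +10 are
# called synergistic, below -10 antagonistic, otherwise additive. Replicate
# matrices are averaged before scoring. No baseline correction or
# dose-response smoothing is applied.

#' Build a dose-response viability matrix
#'
#' @param doses_a,doses_b ascending concentrations, each starting at 0
#'   (the single-agent axis).
#' @param viability numeric matrix of % viability indexed
#'   `[dose_a, dose_b]`; `viability[1, 1]` is the untreated reference.
#'   Values above 100 are allowed. Pass a list of matrices to average
#'   replicates.
#' @param drug_a,drug_b drug names.
#' @param units_a,units_b concentration units (annotation only).
#' @return a list of class `dose_matrix`.
#' @export
dose_matrix <- function(doses_a, doses_b, viability,
                        drug_a = "drug_A", drug_b = "drug_B",
                        units_a = "uM", units_b = "uM") {
  if (is.list(viability)) {
    viability <- Reduce(`+`, lapply(viability, as.matrix)) / length(viability)
  }
  viability <- as.matrix(viability)
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    sk_stop("invalid_parameter", "dose vectors must start at 0")
  }
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0)) {
    sk_stop("invalid_parameter", "dose vectors must be strictly increasing")
  }
  if (!identical(dim(viability), c(length(doses_a), length(doses_b)))) {
    sk_stop("invalid_parameter", "viability matrix must be length(doses_a) x length(doses_b)")
  }
  dimnames(viability) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 viability = viability, drug_a = drug_a, drug_b = drug_b,
                 units_a = units_a, units_b = units_b),
            class = "dose_matrix")
}

#' Convert % viability to % inhibition
#'
#' `inhibition = 100 - viability`; no clamping, so viability above 100
#' yields negative inhibition.
#'
#' @param v % viability (vector or matrix).
#' @return % inhibition of the same shape.
#' @export
inhibition_from_viability <- function(v) 100 - v

#' HSA excess matrix
#'
#' For every combination cell (a > 0, b > 0):
#' `excess = I(a, b) - max(I(a, 0), I(0, b))` with I = % inhibition.
#'
#' @param m a `dose_matrix`.
#' @return numeric matrix of excess inhibition over the combination cells,
#'   in percentage points.
#' @export
hsa_excess <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  I <- inhibition_from_viability(m$viability)
  if (nrow(I) < 2 || ncol(I) < 2) {
    sk_stop("invalid_parameter", "need single-agent rows/columns and at least one combination cell")
  }
  single_a <- I[-1, 1]   # drug A alone at each a > 0
  single_b <- I[1, -1]   # drug B alone at each b > 0
  combo <- I[-1, -1, drop = FALSE]
  best_single <- pmax(matrix(single_a, nrow(combo), ncol(combo)),
                      matrix(single_b, nrow(combo), ncol(combo), byrow = TRUE))
  ex <- combo - best_single
  dimnames(ex) <- list(m$doses_a[-1], m$doses_b[-1])
  ex
}

#' HSA synergy score
#'
#' @param m a `dose_matrix`.
#' @return a `synergy_result`: list with `excess` (matrix), `score` (mean
#'   excess, percentage points) and `classification` (`"synergistic"` if
#'   score > 10, `"antagonistic"` if score < -10, else `"additive"`).
#' @export
hsa_score <- function(m) {
  ex <- hsa_excess(m)
  score <- mean(ex)
  cls <- if (score > 10) "synergistic" else if (score < -10) "antagonistic" else "additive"
  structure(list(excess = ex, score = score, classification = cls,
                 drug_a = m$drug_a, drug_b = m$drug_b),
            class = "synergy_result")
}

#' Read a dose matrix from CSV
#'
#' Layout: first row and first column hold the doses (0 first); the body is
#' % viability (or % inhibition with `value = "inhibition"`; it is
#' converted back to viability internally).
#'
#' @param path CSV path.
#' @param value `"viability"` (default) or `"inhibition"`.
#' @param drug_a,drug_b drug names.
#' @return a `dose_matrix`.
#' @export
read_dose_matrix <- function(path, value = c("viability", "inhibition"),
                             drug_a = "drug_A", drug_b = "drug_B") {
  value <- match.arg(value)
  raw <- as.matrix(utils::read.csv(path, header = FALSE))
  doses_a <- as.numeric(raw[-1, 1])
  doses_b <- as.numeric(raw[1, -1])
  body <- matrix(as.numeric(raw[-1, -1]), length(doses_a), length(doses_b))
  if (value == "inhibition") body <- 100 - body
  dose_matrix(doses_a, doses_b, body, drug_a = drug_a, drug_b = drug_b)
}
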