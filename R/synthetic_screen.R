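# Synthetic screen generator.
#
# Emulates the statistical structure a pooled dropout screen hands to the
# scorer: lognormal plasmid-pool skew, per-guide efficiency attenuation,
# exponential growth over D population doublings with per-gene fitness and
# drug-sensitization effects, compositional renormalization, and
# gamma-Poisson (negative binomial) sequencing noise. Infection (MOI ~ 0.3)
# and selection are not modeled mechanistically; the baseline skew and the
# Beta efficiency absorb their effect, since downstream statistics only see
# counts.

#' Construct an effect model for screen simulation
#'
#' @param fitness named numeric: log2 abundance change per population
#'   doubling for each gene (0 = neutral, negative = essential). Genes not
#'   named default to 0; NTC guides are always neutral.
#' @param sensitization named list, one element per drug arm, each a named
#'   numeric of additional log2/doubling effects under that drug
#'   (negative = sensitizer). May be empty.
#' @param doublings named numeric: population doublings per non-T0 arm
#'   (default 15 for a vehicle arm named `DMSO`). Names define the arms of
#'   the simulated screen; an arm whose name matches a `sensitization`
#'   element is a drug arm, any other is vehicle-like.
#' @param coverage expected sequencing reads per guide (default 300; the
#'   expected column total is `coverage * n_guides`).
#' @param dispersion gamma-Poisson dispersion theta (variance
#'   `mu + mu^2/theta`), default 100.
#' @param efficiency_alpha,efficiency_beta Beta parameters for per-guide
#'   efficiency u in [0,1] (defaults 5, 1: most guides near fully active).
#' @param baseline_sigma sd of the natural-log initial guide abundance
#'   (lognormal library skew), default 0.5.
#' @return a list of class `effect_model`.
#' @export
effect_model <- function(fitness = numeric(),
                         sensitization = list(),
                         doublings = c(DMSO = 15),
                         coverage = 300,
                         dispersion = 100,
                         efficiency_alpha = 5,
                         efficiency_beta = 1,
                         baseline_sigma = 0.5) {
  stopifnot(all(doublings > 0), coverage > 0, dispersion > 0,
            efficiency_alpha > 0, efficiency_beta > 0, baseline_sigma >= 0)
  if (length(sensitization) && is.null(names(sensitization))) {
    sk_stop("invalid_parameter", "sensitization must be a named list (one element per drug)")
  }
  structure(list(
    fitness = fitness,
    sensitization = sensitization,
    doublings = doublings,
    coverage = coverage,
    dispersion = dispersion,
    efficiency_alpha = efficiency_alpha,
    efficiency_beta = efficiency_beta,
    baseline_sigma = baseline_sigma
  ), class = "effect_model")
}

# fitness/sensitization lookup with default 0; ntc guides are always neutral
.gene_effect <- function(map, genes) {
  e <- rep(0, length(genes))
  hit <- match(genes, names(map))
  e[!is.na(hit)] <- map[hit[!is.na(hit)]]
  e
}

#' Simulate a pooled CRISPR dropout screen
#'
#' Draws, per guide, an efficiency u ~ Beta(alpha, beta) and a baseline
#' abundance b ~ LogNormal(0, baseline_sigma); initial proportions are
#' proportional to b. For each arm with doublings D the per-guide log2
#' effect is `u * (fitness + sensitization[drug])`; final proportions are
#' `p * 2^(D * effect)` renormalized over the library (compositional
#' closure: dropout of essentials inflates the remaining guides, as in a
#' real screen). Observed counts are gamma-Poisson around
#' `coverage * n_guides * proportion`. The T0 column uses the initial
#' proportions.
#'
#' @param library a `library_design`.
#' @param model an `effect_model`; all genes it names must be in the library.
#' @param seed mandatory integer seed; the same (library, model, seed) always
#'   reproduces the same counts bit for bit.
#' @param cell_line label recorded in the sample sheet (default "LINE1").
#' @return a `simulated_screen`: list with `table` (a `count_table` with
#'   columns T0 then one per arm), `samples` (a `sample_sheet`), `truth`
#'   (per-gene class and effect sizes), `guide_truth` (per-guide u and
#'   baseline), `seed`, `model`.
#' @export
simulate_screen <- function(library, model, seed, cell_line = "LINE1") {
  if (missing(seed)) {
    sk_stop("invalid_parameter", "simulate_screen requires an explicit seed")
  }
  stopifnot(inherits(model, "effect_model"))
  named_genes <- unique(c(names(model$fitness),
                          unlist(lapply(model$sensitization, names))))
  unknown <- setdiff(named_genes, library$gene)
  if (length(unknown)) {
    sk_stop("consistency_error", paste0(
      "model references genes absent from the library: ",
      paste(utils::head(unknown, 5), collapse = ", ")))
  }
  n <- nrow(library)
  if (n == 0) sk_stop("invalid_parameter", "empty library")
  arms <- names(model$doublings)
  depth <- model$coverage * n

  f <- .gene_effect(model$fitness, library$gene)
  f[library$category == "ntc"] <- 0

  draw <- with_seed(seed, {
    u <- stats::rbeta(n, model$efficiency_alpha, model$efficiency_beta)
    b <- stats::rlnorm(n, 0, model$baseline_sigma)
    p0 <- b / sum(b)
    cols <- list(T0 = stats::rnbinom(n, mu = depth * p0, size = model$dispersion))
    for (arm in arms) {
      s <- if (arm %in% names(model$sensitization)) {
        .gene_effect(model$sensitization[[arm]], library$gene)
      } else rep(0, n)
      s[library$category == "ntc"] <- 0
      eff <- u * (f + s)
      w <- p0 * 2^(model$doublings[[arm]] * eff)
      p <- w / sum(w)
      cols[[arm]] <- stats::rnbinom(n, mu = depth * p, size = model$dispersion)
    }
    list(u = u, b = b, counts = do.call(cbind, cols))
  })
  m <- draw$counts
  rownames(m) <- library$guide_id
  tab <- count_table(m, library)

  arm_kind <- ifelse(arms %in% names(model$sensitization), "drug", "vehicle")
  ss <- sample_sheet(
    sample_id = c("T0", arms),
    arm = c("T0", arm_kind),
    cell_line = cell_line,
    drug_name = c(NA, ifelse(arm_kind == "drug", arms, NA)),
    replicate = 1L
  )
  sim <- structure(list(
    table = tab, samples = ss,
    guide_truth = data.frame(guide_id = library$guide_id, gene = library$gene,
                             category = library$category,
                             efficiency = draw$u, baseline = draw$b,
                             stringsAsFactors = FALSE),
    seed = as.integer(seed), model = model, cell_line = cell_line
  ), class = "simulated_screen")
  sim$truth <- truth_labels(sim)
  sim
}

#' Expected pre-renormalization log2 fold change of a guide
#'
#' Test helper: the expected log2 fold change of a guide versus T0, before
#' compositional renormalization, is `D * u * (fitness + sensitization)`.
#'
#' @param model an `effect_model`.
#' @param gene gene identifier.
#' @param arm arm name (must appear in `model$doublings`).
#' @param u guide efficiency in [0, 1] (default 1).
#' @return expected log2 fold change (a single number).
#' @export
expected_log2fc <- function(model, gene, arm, u = 1) {
  if (!arm %in% names(model$doublings)) {
    sk_stop("invalid_parameter", paste0("unknown arm: ", arm))
  }
  f <- .gene_effect(model$fitness, gene)
  s <- if (arm %in% names(model$sensitization)) {
    .gene_effect(model$sensitization[[arm]], gene)
  } else 0
  unname(model$doublings[[arm]] * u * (f + s))
}

#' Truth labels of a simulated screen
#'
#' One row per gene (NTC guides are their own units). Classes follow the
#' effect signs: negative fitness = essential; otherwise negative
#' sensitization under any drug = sensitizer, positive = suppressor; NTC
#' guides are `ntc`; everything else neutral.
#'
#' @param sim a `simulated_screen`.
#' @return data.frame: `gene`, `category`, `class`, `fitness`, one
#'   `sens_<drug>` column per drug arm.
#' @export
truth_labels <- function(sim) {
  lib <- sim$guide_truth
  genes <- unique(lib[, c("gene", "category")])
  model <- sim$model
  f <- .gene_effect(model$fitness, genes$gene)
  f[genes$category == "ntc"] <- 0
  out <- data.frame(gene = genes$gene, category = genes$category,
                    fitness = f, stringsAsFactors = FALSE)
  drugs <- names(model$sensitization)
  smat <- matrix(0, nrow(out), length(drugs),
                 dimnames = list(NULL, if (length(drugs)) paste0("sens_", drugs)))
  for (d in seq_along(drugs)) {
    s <- .gene_effect(model$sensitization[[drugs[d]]], genes$gene)
    s[genes$category == "ntc"] <- 0
    smat[, d] <- s
  }
  any_neg <- if (length(drugs)) apply(smat < 0, 1, any) else rep(FALSE, nrow(out))
  any_pos <- if (length(drugs)) apply(smat > 0, 1, any) else rep(FALSE, nrow(out))
  cls <- rep("neutral", nrow(out))
  cls[any_pos] <- "suppressor"
  cls[any_neg] <- "sensitizer"
  cls[out$fitness < 0] <- "essential"
  cls[out$category == "ntc"] <- "ntc"
  out$class <- cls
  cbind(out[, c("gene", "category", "class", "fitness")], smat)
}
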