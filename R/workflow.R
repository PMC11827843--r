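# End-to-end orchestration: simulate (or ingest) a screen, score every
# (cell line, contrast) with the NTC-resampling wrapper, nominate hits,
# and write TSV outputs plus a YAML run manifest. One master seed drives
# the simulation and all resampling through the counter-based child-seed
# rule, so a run is fully determined by (config, seed).

.known_config_keys <- c("seed", "output_dir", "simulate", "inputs",
                        "contrasts", "engine", "resampling", "nomination")

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) sk_stop("config_error", "config must be a list or YAML path")
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    sk_stop("config_error", paste0("unknown config key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  if (is.null(config$contrasts)) sk_stop("config_error", "config key 'contrasts' is required")
  roles <- vapply(config$contrasts, function(x) x$role %||% "drug", character(1))
  if (sum(roles == "fitness") != 1L) {
    sk_stop("config_error", "config must define exactly one contrast with role 'fitness'")
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    sk_stop("config_error", "config needs either 'simulate' or 'inputs'")
  }
  if (!is.null(config$simulate) && is.null(config$seed)) {
    sk_stop("config_error", "config key 'seed' is mandatory when simulating")
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build an effect_model from the simulate: block of a config
.model_from_config <- function(sim_cfg, library) {
  mc <- sim_cfg$model %||% list()
  doublings <- unlist(mc$doublings %||% list(DMSO = 15))
  fitness <- unlist(mc$fitness) %||% numeric()
  sens <- lapply(mc$sensitization %||% list(), unlist)
  # shorthand: apply one fitness value to every essential gene in the library
  if (!is.null(mc$essential_fitness)) {
    ess <- unique(library$gene[library$category == "essential"])
    fitness <- c(fitness, stats::setNames(rep(mc$essential_fitness, length(ess)), ess))
  }
  # shorthand: make the first n_genes target genes sensitizers under listed drugs
  if (!is.null(mc$sensitizers)) {
    sc <- mc$sensitizers
    tgt <- unique(library$gene[library$category == "target"])
    picked <- utils::head(tgt, sc$n_genes %||% 0)
    for (d in sc$drugs %||% character()) {
      sens[[d]] <- c(sens[[d]] %||% numeric(),
                     stats::setNames(rep(sc$effect %||% -0.5, length(picked)), picked))
    }
  }
  effect_model(
    fitness = fitness, sensitization = sens, doublings = doublings,
    coverage = mc$coverage %||% 300, dispersion = mc$dispersion %||% 100,
    efficiency_alpha = mc$efficiency_alpha %||% 5,
    efficiency_beta = mc$efficiency_beta %||% 1,
    baseline_sigma = mc$baseline_sigma %||% 0.5)
}

#' Run the full screen analysis from one configuration
#'
#' Stages: simulate or ingest count tables per cell line, score every
#' configured contrast with [resampled_scores()], nominate hits with
#' [nominate_hits()], and write score TSVs, the hit TSV, and a YAML
#' manifest recording seeds, parameters, warnings and md5 digests of every
#' output. Running the same config and seed twice produces byte-identical
#' outputs.
#'
#' @param config a list or path to a YAML file. Keys: `seed`, `output_dir`,
#'   `simulate` (library/model/cell_lines) or `inputs` (per-cell-line
#'   counts/library/samples paths), `contrasts` (each with `label`,
#'   `control`, `treated`, `role` = fitness/drug, optional `exclude`),
#'   optional `engine`, `resampling`, `nomination` blocks.
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, a list with `scores` (nested cell line -> label ->
#'   `averaged_score_table`), `hits` (`hit_call_table`), `tables` (the
#'   count tables), `manifest` and `paths`.
#' @export
run_screen_analysis <- function(config, output_dir = NULL) {
  t_start <- proc.time()[["elapsed"]]
  config <- .read_config(config)
  out_dir <- output_dir %||% config$output_dir %||% sk_stop("config_error", "no output_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  eng_cfg <- config$engine %||% list()
  engine <- engine_params(pseudocount = eng_cfg$pseudocount %||% 5,
                          scale = eng_cfg$scale %||% 1e7,
                          window = eng_cfg$window,
                          min_std = eng_cfg$min_std %||% 1e-6)
  rs_cfg <- config$resampling %||% list()
  timings <- list(); warns <- character()

  # --- acquire count tables -------------------------------------------------
  tables <- list()
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    lc <- sc$library %||% list()
    library <- compose_library(lc$n_target_genes %||% 356,
                               lc$n_essential_genes %||% 63,
                               lc$n_ntc_guides %||% 324,
                               lc$guides_per_gene %||% 4)
    model <- .model_from_config(sc, library)
    cell_lines <- sc$cell_lines %||% "LINE1"
    for (i in seq_along(cell_lines)) {
      sim <- simulate_screen(library, model, seed = child_seed(seed, 900000 + i),
                             cell_line = cell_lines[[i]])
      tables[[cell_lines[[i]]]] <- sim$table
    }
  } else {
    for (inp in config$inputs) {
      lib <- read_library(inp$library)
      ss <- if (!is.null(inp$samples)) read_sample_sheet(inp$samples) else NULL
      tables[[inp$cell_line]] <- read_count_table(inp$counts, lib, ss)
    }
  }
  timings$acquire <- proc.time()[["elapsed"]] - t_start

  # --- score contrasts ------------------------------------------------------
  t_score <- proc.time()[["elapsed"]]
  scores <- list()
  paths <- character()
  labels <- vapply(config$contrasts, `[[`, character(1), "label")
  for (li in seq_along(tables)) {
    cl <- names(tables)[li]
    scores[[cl]] <- list()
    for (ci in seq_along(config$contrasts)) {
      cc <- config$contrasts[[ci]]
      contrast <- contrast_spec(cc$label, cc$control, cc$treated)
      # drug contrasts exclude essentials; the fitness (vehicle vs T0)
      # contrast keeps them by default, so essential dropout anchors the
      # normZ scale genes are judged against
      default_exclude <- if (identical(cc$role %||% "drug", "fitness"))
        character(0) else "essential"
      rp <- resampling_params(
        group_size = rs_cfg$group_size %||% 4,
        n_rep = rs_cfg$n_rep %||% 100,
        seed = child_seed(seed, 1000 * li + ci),
        excluded_categories = as.character(unlist(
          cc$exclude %||% rs_cfg$exclude %||% default_exclude)))
      avg <- resampled_scores(tables[[cl]], contrast, engine, rp)
      warns <- c(warns, avg$warnings)
      scores[[cl]][[cc$label]] <- avg
      p <- file.path(out_dir, sprintf("scores_%s_%s.tsv", cl, cc$label))
      write_averaged_scores(avg, p)
      paths <- c(paths, p)
    }
  }
  timings$score <- proc.time()[["elapsed"]] - t_score

  # --- nominate -------------------------------------------------------------
  t_nom <- proc.time()[["elapsed"]]
  roles <- vapply(config$contrasts, function(x) x$role %||% "drug", character(1))
  fitness_label <- labels[roles == "fitness"]
  drug_labels <- labels[roles == "drug"]
  nom_cfg <- config$nomination %||% list()
  criteria <- nomination_criteria(
    fitness_window = unlist(nom_cfg$fitness_window %||% c(-1, 1)),
    drug_threshold = nom_cfg$drug_threshold %||% -1,
    min_cell_lines = nom_cfg$min_cell_lines %||% 1,
    fdr_max = nom_cfg$fdr_max %||% 0.1,
    require_fdr = nom_cfg$require_fdr %||% FALSE)
  known <- nom_cfg$known_genes %||% character()
  hits <- nominate_hits(scores, fitness_label, drug_labels, criteria, known)
  hit_path <- file.path(out_dir, "hits.tsv")
  write_hits(hits, hit_path)
  paths <- c(paths, hit_path)
  timings$nominate <- proc.time()[["elapsed"]] - t_nom

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    seed = as.integer(seed),
    engine = engine[!vapply(engine, is.null, logical(1))],
    resampling = list(group_size = rs_cfg$group_size %||% 4,
                      n_rep = rs_cfg$n_rep %||% 100),
    contrasts = config$contrasts,
    cell_lines = names(tables),
    warnings = unique(warns),
    timings_sec = lapply(timings, function(x) round(x, 3)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(scores = scores, hits = hits, tables = tables,
                 manifest = manifest,
                 paths = c(paths, manifest_path)))
}

#' Scatter plot of drug-contrast vs fitness-contrast normZ
#'
#' The classic two-axis hit view: fitness (vehicle vs T0) normZ on x, drug
#' (drug vs vehicle) normZ on y, dashed guides at +/-1 on both axes.
#'
#' @param fitness,drug `averaged_score_table`s (or `gene_score_table`s)
#'   sharing at least one gene.
#' @param out image path (.png/.svg/.pdf); the plot is also returned.
#' @param highlight optional character vector of genes to label.
#' @return the ggplot object, invisibly after saving.
#' @export
plot_normz_scatter <- function(fitness, drug, out = NULL, highlight = NULL) {
  f <- .score_frame(fitness); d <- .score_frame(drug)
  shared <- intersect(f$gene, d$gene)
  if (!length(shared)) sk_stop("invalid_parameter", "fitness and drug tables share no genes")
  df <- data.frame(gene = shared,
                   fitness_normZ = f$normZ[match(shared, f$gene)],
                   drug_normZ = d$normZ[match(shared, d$gene)])
  df$highlight <- df$gene %in% (highlight %||% character())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = fitness_normZ, y = drug_normZ)) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = highlight),
                        show.legend = FALSE, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "normZ (vehicle vs T0)", y = "normZ (drug vs vehicle)") +
    ggplot2::theme_classic()
  if (!is.null(out)) ggplot2::ggsave(out, p, width = 5, height = 5, dpi = 150)
  invisible(p)
}
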