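# Library design, sample sheets, count tables: composition, I/O, validation.
#
# A library design is a data.frame with columns guide_id, gene, category
# (one of "target", "essential", "ntc") plus attributes. NTC guides carry a
# per-guide reserved gene label (their own guide_id) so that each NTC guide
# stays an independent unit until the resampling step aggregates them.

GUIDE_CATEGORIES <- c("target", "essential", "ntc")

#' Compose a synthetic sgRNA library design
#'
#' Builds the guide -> gene -> category catalogue of a custom pooled library:
#' `n_target_genes + n_essential_genes` genes carrying `guides_per_gene`
#' guides each, plus `n_ntc_guides` non-targeting control guides. Naming is
#' deterministic (`TGT0001_g1`, `ESS0001_g1`, `NTC0001`), so two calls with
#' the same arguments give identical designs.
#'
#' @param n_target_genes number of target genes.
#' @param n_essential_genes number of essential (positive-control) genes.
#' @param n_ntc_guides number of non-targeting control guides.
#' @param guides_per_gene guides per target/essential gene (default 4).
#' @return a `library_design`: data.frame with columns `guide_id`, `gene`,
#'   `category`; attributes `guides_per_gene` and `counts` (per-category
#'   guide totals).
#' @examples
#' lib <- compose_library(356, 63, 324, 4)
#' sum(lib$category != "ntc")  # 1676 gene-targeting guides
#' @export
compose_library <- function(n_target_genes, n_essential_genes, n_ntc_guides,
                            guides_per_gene = 4) {
  args <- c(n_target_genes, n_essential_genes, n_ntc_guides, guides_per_gene)
  if (any(!is.finite(args)) || any(args < 0) || any(args != floor(args))) {
    sk_stop("invalid_parameter", "all library composition arguments must be nonnegative integers")
  }
  if (guides_per_gene < 1) {
    sk_stop("invalid_parameter", "'guides_per_gene' must be >= 1")
  }
  mk_genes <- function(prefix, n) {
    if (n == 0) return(NULL)
    genes <- sprintf("%s%04d", prefix, seq_len(n))
    data.frame(
      guide_id = paste0(rep(genes, each = guides_per_gene), "_g",
                        rep(seq_len(guides_per_gene), times = n)),
      gene = rep(genes, each = guides_per_gene),
      stringsAsFactors = FALSE
    )
  }
  tgt <- mk_genes("TGT", n_target_genes)
  ess <- mk_genes("ESS", n_essential_genes)
  ntc <- if (n_ntc_guides > 0) {
    ids <- sprintf("NTC%04d", seq_len(n_ntc_guides))
    data.frame(guide_id = ids, gene = ids, stringsAsFactors = FALSE)
  } else NULL
  design <- rbind(
    if (!is.null(tgt)) cbind(tgt, category = "target"),
    if (!is.null(ess)) cbind(ess, category = "essential"),
    if (!is.null(ntc)) cbind(ntc, category = "ntc")
  )
  if (is.null(design)) {
    design <- data.frame(guide_id = character(), gene = character(),
                         category = character(), stringsAsFactors = FALSE)
  }
  rownames(design) <- NULL
  attr(design, "guides_per_gene") <- as.integer(guides_per_gene)
  attr(design, "counts") <- c(
    target = as.integer(n_target_genes * guides_per_gene),
    essential = as.integer(n_essential_genes * guides_per_gene),
    ntc = as.integer(n_ntc_guides)
  )
  class(design) <- c("library_design", "data.frame")
  design
}

#' Build a sample sheet
#'
#' @param sample_id unique sample identifiers.
#' @param arm one of `"T0"`, `"vehicle"`, `"drug"` per sample.
#' @param cell_line cell line per sample.
#' @param drug_name drug per sample; must be given exactly for `arm == "drug"`.
#' @param replicate positive integer replicate index.
#' @return data.frame with class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, arm, cell_line,
                         drug_name = NA_character_, replicate = 1L) {
  ss <- data.frame(sample_id = as.character(sample_id),
                   arm = as.character(arm),
                   cell_line = as.character(cell_line),
                   drug_name = as.character(drug_name),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ss$sample_id)) {
    sk_stop("invalid_parameter", "sample_ids must be unique")
  }
  if (!all(ss$arm %in% c("T0", "vehicle", "drug"))) {
    sk_stop("invalid_parameter", "arm must be one of T0, vehicle, drug")
  }
  bad <- (ss$arm == "drug") != (!is.na(ss$drug_name) & nzchar(ss$drug_name))
  if (any(bad)) {
    sk_stop("invalid_parameter", "drug_name must be present iff arm == 'drug'")
  }
  if (any(ss$replicate < 1L)) {
    sk_stop("invalid_parameter", "replicate indices must be >= 1")
  }
  class(ss) <- c("sample_sheet", "data.frame")
  ss
}

#' Assemble a validated count table
#'
#' @param counts integer matrix, guides x samples; rownames are guide ids.
#' @param library a `library_design` the guides must belong to.
#' @return a `count_table`: data.frame with `guide_id`, `gene`, `category`
#'   annotation columns followed by one integer column per sample.
#' @export
count_table <- function(counts, library) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    sk_stop("format_error", "count matrix must have guide ids as rownames")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    sk_stop("value_error", "counts must be nonnegative integers")
  }
  if (anyDuplicated(rownames(counts))) {
    sk_stop("consistency_error", "duplicate guide rows in count matrix")
  }
  missing <- setdiff(rownames(counts), library$guide_id)
  if (length(missing)) {
    sk_stop("consistency_error", paste0(
      "guides absent from library: ", paste(utils::head(missing, 5), collapse = ", ")))
  }
  idx <- match(rownames(counts), library$guide_id)
  tab <- data.frame(guide_id = rownames(counts),
                    gene = library$gene[idx],
                    category = library$category[idx],
                    stringsAsFactors = FALSE)
  storage.mode(counts) <- "integer"
  tab <- cbind(tab, as.data.frame(counts))
  rownames(tab) <- NULL
  class(tab) <- c("count_table", "data.frame")
  tab
}

#' Sample columns of a count table
#' @param table a `count_table`.
#' @return character vector of sample column names.
#' @export
count_samples <- function(table) {
  setdiff(colnames(table), c("guide_id", "gene", "category"))
}

#' Extract the integer count matrix from a count table
#' @param table a `count_table`.
#' @return integer matrix with guide ids as rownames.
#' @export
count_matrix <- function(table) {
  m <- as.matrix(table[, count_samples(table), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- table$guide_id
  m
}

#' Write a count table to a tab-delimited file
#'
#' Format: header `GUIDE<TAB>GENE<TAB><sample1>...`, UTF-8, no index column.
#' @param table a `count_table`.
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  out <- table[, c("guide_id", "gene", count_samples(table))]
  colnames(out)[1:2] <- c("GUIDE", "GENE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited count table
#'
#' Expects header `GUIDE<TAB>GENE<TAB><sample columns>`; rows are validated
#' against the declared library design and coerced to integer counts. Row
#' order is preserved.
#'
#' @param path file path.
#' @param library a `library_design`.
#' @param samples optional `sample_sheet`; when given, the file's sample
#'   columns must match its sample ids.
#' @return a `count_table`.
#' @export
read_count_table <- function(path, library, samples = NULL) {
  if (!file.exists(path)) sk_stop("format_error", paste0("file not found: ", path))
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("GUIDE", "GENE") %in% colnames(raw)[1:2])) {
    sk_stop("format_error", "count table must start with GUIDE and GENE columns")
  }
  samp_cols <- setdiff(colnames(raw), c("GUIDE", "GENE"))
  if (!length(samp_cols)) sk_stop("format_error", "count table has no sample columns")
  num <- suppressWarnings(
    vapply(raw[samp_cols], function(x) as.numeric(x), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(raw$GUIDE, samp_cols))
  if (any(is.na(num)) || any(num < 0) || any(num != floor(num))) {
    sk_stop("value_error", "counts must be nonnegative integers")
  }
  tab <- count_table(num, library)
  if (!is.null(samples)) {
    if (!setequal(samp_cols, samples$sample_id)) {
      sk_stop("consistency_error", "sample columns do not match the sample sheet")
    }
  }
  tab
}

#' Read a tab-delimited library annotation
#'
#' Format: `GUIDE<TAB>GENE<TAB>CATEGORY`, CATEGORY in target/essential/ntc.
#' @param path file path.
#' @return a `library_design`.
#' @export
read_library <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("GUIDE", "GENE", "CATEGORY") %in% colnames(raw))) {
    sk_stop("format_error", "library file needs GUIDE, GENE, CATEGORY columns")
  }
  if (!all(raw$CATEGORY %in% GUIDE_CATEGORIES)) {
    sk_stop("value_error", "CATEGORY must be target, essential or ntc")
  }
  design <- data.frame(guide_id = raw$GUIDE, gene = raw$GENE,
                       category = raw$CATEGORY, stringsAsFactors = FALSE)
  attr(design, "counts") <- c(
    target = sum(design$category == "target"),
    essential = sum(design$category == "essential"),
    ntc = sum(design$category == "ntc"))
  class(design) <- c("library_design", "data.frame")
  design
}

#' Write a library annotation TSV
#' @param library a `library_design`.
#' @param path output path.
#' @export
write_library <- function(library, path) {
  out <- data.frame(GUIDE = library$guide_id, GENE = library$gene,
                    CATEGORY = library$category)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Format: `SAMPLE<TAB>ARM<TAB>CELL_LINE<TAB>DRUG<TAB>REPLICATE`.
#' @param path file path.
#' @return a `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("SAMPLE", "ARM", "CELL_LINE", "DRUG", "REPLICATE")
  if (!all(need %in% colnames(raw))) {
    sk_stop("format_error", "sample sheet needs SAMPLE, ARM, CELL_LINE, DRUG, REPLICATE")
  }
  sample_sheet(raw$SAMPLE, raw$ARM, raw$CELL_LINE, raw$DRUG, raw$REPLICATE)
}

#' Write a sample sheet TSV
#' @param samples a `sample_sheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- data.frame(SAMPLE = samples$sample_id, ARM = samples$arm,
                    CELL_LINE = samples$cell_line, DRUG = samples$drug_name,
                    REPLICATE = samples$replicate)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a screen count table against its sample sheet
#'
#' Returns violations rather than raising: duplicate guide ids, sample
#' columns unknown to the sample sheet, genes whose guides mix categories,
#' and all-zero guides (flagged, never removed -- dropping them would change
#' the normZ re-standardization).
#'
#' @param table a `count_table`.
#' @param samples a `sample_sheet`.
#' @return data.frame with columns `type`, `item`, `detail`; zero rows when
#'   the screen is valid.
#' @export
validate_screen <- function(table, samples) {
  v <- list()
  add <- function(type, item, detail) {
    v[[length(v) + 1L]] <<- data.frame(type = type, item = item,
                                       detail = detail, stringsAsFactors = FALSE)
  }
  dup <- unique(table$guide_id[duplicated(table$guide_id)])
  for (g in dup) add("duplicate_guide", g, "guide_id appears more than once")
  unk <- setdiff(count_samples(table), samples$sample_id)
  for (s in unk) add("unknown_sample", s, "column not in sample sheet")
  miss <- setdiff(samples$sample_id, count_samples(table))
  for (s in miss) add("missing_sample", s, "sample sheet entry without a count column")
  cats <- tapply(table$category, table$gene, function(x) length(unique(x)))
  for (g in names(cats)[cats > 1L]) {
    add("category_inconsistency", g, "guides of one gene carry mixed categories")
  }
  m <- as.matrix(table[, count_samples(table), drop = FALSE])
  zero <- table$guide_id[rowSums(m) == 0]
  for (g in zero) add("all_zero_guide", g, "zero counts in every sample (flagged, retained)")
  if (!length(v)) {
    return(data.frame(type = character(), item = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
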