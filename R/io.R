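#' Read a gene-by-sample count matrix with its design and organism map
#'
#' Reads a TSV count table (first column gene ids, remaining columns one per
#' sample), a design TSV (`sample_id`, `generation`, `replicate`; generation
#' order is taken from order of first appearance in the file) and an
#' optional organism TSV (`gene_id`, `organism` with values host/symbiont).
#'
#' @param path Count TSV path.
#' @param design_path Design TSV path.
#' @param organism_path Optional organism-map TSV path; when absent all
#'   genes are labelled host.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design_path, organism_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a gene column plus samples")
  genes <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  # column-wise validation so the error names the offending cell
  for (j in seq_len(ncol(counts))) {
    col <- suppressWarnings(as.numeric(counts[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop("invalid count '", counts[bad[1], j], "' at gene '",
           genes[bad[1]], "', sample '", colnames(counts)[j], "'")
    counts[, j] <- col
  }
  storage.mode(counts) <- "double"
  rownames(counts) <- genes

  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  organism <- NULL
  if (!is.null(organism_path)) {
    om <- utils::read.delim(organism_path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "organism") %in% names(om)))
      stop("organism map needs columns gene_id, organism")
    organism <- stats::setNames(om$organism, om$gene_id)
  }
  count_matrix(counts, design, organism)
}

#' Write a count matrix and its side tables
#'
#' Writes `counts.tsv`, `design.tsv` and `organisms.tsv` under `dir` in the
#' formats [read_counts()] expects, so a write/read round trip reproduces
#' the object exactly.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "counts.tsv")
  dp <- file.path(dir, "design.tsv")
  op <- file.path(dir, "organisms.tsv")
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- cm$design
  des$generation <- as.character(des$generation)
  # keep declared generation order readable by order of first appearance
  des <- des[order(match(des$generation, levels(cm$design$generation))), ]
  utils::write.table(des, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cm$organism), organism = cm$organism),
    op, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cp, design = dp, organisms = op))
}

#' Read microscopy section measurements
#'
#' CSV columns: `genotype_id`, `generation`, `tiller_id`, `section_index`,
#' `hyphal_count`, `diameters` (semicolon-separated values in micrometers;
#' typically a subsample of 40-50 hyphae per section), `vascular_hyphae`.
#'
#' @param path CSV path.
#' @return Data frame of class `section_measurements` with a list column
#'   `diameters_um` holding per-hypha diameters.
#' @export
read_sections <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype_id", "generation", "tiller_id", "section_index",
            "hyphal_count", "diameters", "vascular_hyphae")
  if (!all(need %in% names(tab)))
    stop("sections CSV needs columns: ", paste(need, collapse = ", "))
  diam <- lapply(strsplit(as.character(tab$diameters), ";", fixed = TRUE),
                 function(v) as.numeric(v[nzchar(v)]))
  for (i in seq_len(nrow(tab))) {
    row_id <- paste0("genotype '", tab$genotype_id[i], "' section ",
                     tab$section_index[i])
    if (tab$hyphal_count[i] < 0 || tab$vascular_hyphae[i] < 0)
      stop("negative hyphal count at ", row_id)
    if (tab$vascular_hyphae[i] > tab$hyphal_count[i])
      stop("vascular_hyphae exceeds hyphal_count at ", row_id)
    if (!(tab$section_index[i] %in% 1:3))
      stop("section_index outside 1..3 at ", row_id)
    d <- diam[[i]]
    if (length(d) && (any(!is.finite(d)) || any(d <= 0)))
      stop("non-positive or non-finite diameter at ", row_id)
    if (!length(d) && tab$hyphal_count[i] > 0)
      warning("no diameters recorded for ", row_id,
              " despite hyphal_count > 0; record kept")
  }
  out <- data.frame(
    genotype_id = as.character(tab$genotype_id),
    generation = as.character(tab$generation),
    tiller_id = as.character(tab$tiller_id),
    section_index = as.integer(tab$section_index),
    hyphal_count = as.integer(tab$hyphal_count),
    vascular_hyphae = as.integer(tab$vascular_hyphae),
    stringsAsFactors = FALSE)
  out$diameters_um <- diam
  class(out) <- c("section_measurements", "data.frame")
  out
}

#' Write section measurements to CSV
#'
#' Inverse of [read_sections()]; diameters are serialized as a
#' semicolon-separated field.
#'
#' @param sections Data frame from [read_sections()] or
#'   [simulate_sections()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sections <- function(sections, path) {
  tab <- data.frame(
    genotype_id = sections$genotype_id,
    generation = sections$generation,
    tiller_id = sections$tiller_id,
    section_index = sections$section_index,
    hyphal_count = sections$hyphal_count,
    diameters = vapply(sections$diameters_um,
                       function(d) paste(format(d, trim = TRUE,
                                                digits = 15),
                                         collapse = ";"), ""),
    vascular_hyphae = sections$vascular_hyphae)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read seed-transmission test records
#'
#' CSV columns: `generation`, `n_tested`, `n_infected`, `selected`
#' (whether the parents of that generation were selected for endophyte
#' infection).
#'
#' @param path CSV path.
#' @return Data frame of class `transmission_records`.
#' @export
read_transmission <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("generation", "n_tested", "n_infected", "selected")
  if (!all(need %in% names(tab)))
    stop("transmission CSV needs columns: ", paste(need, collapse = ", "))
  bad <- which(tab$n_infected < 0 | tab$n_infected > tab$n_tested |
                 tab$n_tested < 1)
  if (length(bad))
    stop("n_infected outside [0, n_tested] at generation ",
         tab$generation[bad[1]])
  tab$selected <- as.logical(tab$selected)
  class(tab) <- c("transmission_records", "data.frame")
  tab
}

#' Read tillering time series
#'
#' CSV columns: `genotype_id`, `generation`, `day`, `tiller_count`.
#' Decreases of tiller count within a genotype raise a warning (counting
#' noise), never an error.
#'
#' @param path CSV path.
#' @return Data frame of class `tiller_records`.
#' @export
read_tillering <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype_id", "generation", "day", "tiller_count")
  if (!all(need %in% names(tab)))
    stop("tillering CSV needs columns: ", paste(need, collapse = ", "))
  if (any(tab$tiller_count < 1)) stop("tiller_count must be positive")
  if (any(tab$day < 0)) stop("day must be non-negative")
  for (g in unique(tab$genotype_id)) {
    sub <- tab[tab$genotype_id == g, ]
    sub <- sub[order(sub$day), ]
    if (is.unsorted(sub$tiller_count))
      warning("tiller_count decreases within genotype '", g,
              "' (kept; likely counting noise)")
  }
  class(tab) <- c("tiller_records", "data.frame")
  tab
}
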