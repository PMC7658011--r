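#' Construct a dual-organism count matrix
#'
#' Bundles gene-level read counts with the sample design (ordered
#' generations, replicates) and a gene-to-organism map distinguishing host
#' (plant) from symbiont (fungal endophyte) genes. This is the input
#' container for normalization, trend detection and read-share partitioning.
#'
#' @param counts Integer matrix of non-negative read counts, genes in rows
#'   (unique rownames required), samples in columns (colnames required).
#' @param design Data frame with columns `sample_id`, `generation`,
#'   `replicate`; one row per sample column. `generation` may be a factor,
#'   in which case its level order is taken as the generation order;
#'   otherwise order of first appearance is used (never lexical sort, so
#'   e.g. "G10" can follow "G9").
#' @param organism Named character vector mapping gene ids to `"host"` or
#'   `"symbiont"`. Genes absent from the map default to `"host"` with a
#'   warning.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `design` (with `generation` as an ordered factor) and
#'   `organism` (named character, one entry per gene).
#' @seealso [read_counts()], [normalize_rpm()], [trend_test()],
#'   [symbiont_share()]
#' @export
count_matrix <- function(counts, design, organism = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count (negative, non-integer or missing) at gene '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "double"

  design <- as.data.frame(design)
  need <- c("sample_id", "generation", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  missing_design <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_design))
    stop("sample column missing from design: ",
         paste(missing_design, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  gen_levels <- if (is.factor(design$generation)) {
    levels(design$generation)
  } else {
    unique(as.character(design$generation))
  }
  design$generation <- factor(as.character(design$generation),
                              levels = gen_levels, ordered = TRUE)
  design$replicate <- as.integer(design$replicate)
  if (any(is.na(design$replicate)) || any(design$replicate < 1))
    stop("replicate must be a positive integer")
  if (anyDuplicated(design[, c("generation", "replicate")]))
    stop("(generation, replicate) pairs must be unique")

  genes <- rownames(counts)
  org <- rep("host", length(genes))
  names(org) <- genes
  if (!is.null(organism)) {
    organism <- vapply(organism, as.character, "")
    unknown <- setdiff(organism, c("host", "symbiont"))
    if (length(unknown))
      stop("organism labels must be 'host' or 'symbiont', got: ",
           paste(unknown, collapse = ", "))
    hit <- intersect(genes, names(organism))
    org[hit] <- organism[hit]
    unmapped <- setdiff(genes, names(organism))
    if (length(unmapped))
      warning(length(unmapped),
              " gene(s) absent from organism map, labelled 'host': ",
              paste(utils::head(unmapped, 5), collapse = ", "),
              if (length(unmapped) > 5) ", ..." else "")
  }

  libsize <- colSums(counts)
  if (any(libsize <= 0))
    stop("zero library size in sample: ",
         paste(colnames(counts)[libsize <= 0], collapse = ", "))

  structure(list(counts = counts, design = design, organism = org),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  n_sym <- sum(x$organism == "symbiont")
  cat("count_matrix: ", nrow(x$counts), " genes (",
      nrow(x$counts) - n_sym, " host, ", n_sym, " symbiont) x ",
      ncol(x$counts), " samples\n", sep = "")
  cat("generations:",
      paste(levels(x$design$generation), collapse = " < "), "\n")
  cat("library sizes:",
      paste(format(colSums(x$counts), big.mark = ","), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Group structure of an ordered-generation design
#'
#' Splits sample ids by generation, in the declared generation order.
#' The group sizes (n1, ..., nk) define the combinatorial null for the
#' monotone-separation trend test.
#'
#' @param design Design data frame as stored in a [count_matrix()].
#' @return Named list of character vectors of sample ids, one per
#'   generation, in generation order.
#' @export
group_design <- function(design) {
  gens <- levels(design$generation)
  groups <- lapply(gens, function(g)
    design$sample_id[design$generation == g])
  names(groups) <- gens
  if (length(groups) < 2) stop("need at least 2 generations")
  if (any(lengths(groups) < 1)) stop("every generation needs >= 1 sample")
  groups
}
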