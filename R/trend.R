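## Monotone-separation trend detection with a combinatorial chance null.
##
## A gene is called "down" when every replicate value of each later
## generation lies strictly below every replicate value of the preceding
## generation (max of later group < min of earlier group at every adjacent
## boundary); "up" is the mirror. Under exchangeable continuous values the
## chance probability of full separation is prod(nj!)/N! per direction.

# Vectorized separation calls over the rows of a values matrix.
# group_cols: list of column-index vectors in generation order.
# Returns list(direction = character, tied = logical).
.separation_calls <- function(values, group_cols) {
  k <- length(group_cols)
  gmin <- lapply(group_cols, function(idx)
    do.call(pmin, lapply(idx, function(j) values[, j])))
  gmax <- lapply(group_cols, function(idx)
    do.call(pmax, lapply(idx, function(j) values[, j])))
  n <- nrow(values)
  strict_down <- strict_up <- weak_down <- weak_up <- rep(TRUE, n)
  for (j in seq_len(k - 1)) {
    strict_down <- strict_down & (gmax[[j + 1]] < gmin[[j]])
    weak_down   <- weak_down   & (gmax[[j + 1]] <= gmin[[j]])
    strict_up   <- strict_up   & (gmin[[j + 1]] > gmax[[j]])
    weak_up     <- weak_up     & (gmin[[j + 1]] >= gmax[[j]])
  }
  direction <- rep("none", n)
  direction[strict_down] <- "down"
  direction[strict_up] <- "up"
  tied <- (direction == "none") & (weak_down | weak_up)
  list(direction = direction, tied = tied)
}

#' Call strictly monotone expression trends across ordered generations
#'
#' For every gene, tests whether all replicate values of each later
#' generation lie strictly below (direction `down`) or strictly above
#' (`up`) all replicate values of the preceding generation, for every
#' adjacent pair in the declared generation order. Equality at any group
#' boundary defeats separation: such genes are called `none` with
#' `tied = TRUE` when a non-strict ordering would otherwise separate.
#' The call depends only on within-gene value ranks, so it is invariant
#' under any strictly increasing transform (e.g. [log_median_center()]
#' at a fixed pseudocount).
#'
#' @param em An `expression_matrix` (or a plain numeric matrix, in which
#'   case `groups` is required).
#' @param groups Optional named list of sample-id (or column-index)
#'   vectors in generation order; defaults to [group_design()] of the
#'   design carried by `em`.
#' @param direction `"both"`, `"down"` or `"up"`: which calls to retain
#'   (others are reported as `none`).
#' @return Data frame with columns `gene_id`, `direction`
#'   (down/up/none) and `tied`.
#' @export
detect_monotone <- function(em, groups = NULL,
                            direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  values <- if (inherits(em, "expression_matrix")) em$values else
    as.matrix(em)
  if (is.null(groups)) {
    if (!inherits(em, "expression_matrix"))
      stop("groups must be given for a plain matrix")
    groups <- group_design(em$design)
  }
  group_cols <- lapply(groups, function(ids) {
    idx <- if (is.numeric(ids)) as.integer(ids) else
      match(ids, colnames(values))
    if (any(is.na(idx))) stop("design sample missing from matrix: ",
                              paste(ids[is.na(idx)], collapse = ", "))
    idx
  })
  sep <- .separation_calls(values, group_cols)
  if (direction != "both") {
    drop <- sep$direction != direction & sep$direction != "none"
    sep$direction[drop] <- "none"
  }
  data.frame(gene_id = rownames(values), direction = sep$direction,
             tied = sep$tied, stringsAsFactors = FALSE)
}

#' Chance probability of full monotone separation
#'
#' For exchangeable continuous values in k ordered groups of sizes
#' n1, ..., nk (N = sum nj), the probability that the groups fully
#' separate in the declared order is `prod(nj!) / N!`; the probability of
#' separation in either direction is twice that. For the 3x3x3 replicate
#' design this gives 1/840 for both directions.
#'
#' @param group_sizes Positive integer group sizes.
#' @param directions `"both"` (increase or decrease) or `"one"`.
#' @return The null probability.
#' @export
null_probability <- function(group_sizes, directions = c("both", "one")) {
  directions <- match.arg(directions)
  if (length(group_sizes) < 2) stop("need at least 2 groups")
  if (any(group_sizes < 1)) stop("every group size must be >= 1")
  p1 <- exp(sum(lfactorial(group_sizes)) - lfactorial(sum(group_sizes)))
  if (directions == "both") 2 * p1 else p1
}

#' Permutation oracle for the separation null probability
#'
#' Shuffles the expression values of every gene across the group labels
#' independently, `n_perm` times, and recounts full separations. Serves
#' as an empirical check on [null_probability()]; for continuous data the
#' estimate converges to the analytic value, while ties in the data pull
#' it below (ties defeat separation).
#'
#' @param em `expression_matrix` or numeric matrix of values.
#' @param groups As in [detect_monotone()].
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer RNG seed.
#' @param direction `"both"`, `"down"` or `"up"`.
#' @return List with `p_hat` (mean separation frequency over gene x
#'   permutation trials), `se` (binomial Monte-Carlo standard error),
#'   `n_trials`.
#' @export
permutation_null <- function(em, groups = NULL, n_perm = 10000,
                             seed = 1L,
                             direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  values <- if (inherits(em, "expression_matrix")) em$values else
    as.matrix(em)
  if (is.null(groups)) groups <- group_design(em$design)
  group_cols <- lapply(groups, function(ids) {
    if (is.numeric(ids)) as.integer(ids) else match(ids, colnames(values))
  })
  n <- ncol(values)
  g <- nrow(values)
  set.seed(seed)
  hits <- 0
  trials <- 0
  # rows are gene x permutation trials; process in chunks to bound memory
  chunk <- max(1L, min(n_perm, as.integer(2e6 / n / g) + 1L))
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    big <- values[rep(seq_len(g), b), , drop = FALSE]
    keys <- matrix(stats::runif(length(big)), nrow = nrow(big))
    ord <- order(row(keys), keys)          # random order within each row
    shuffled <- matrix(big[ord], ncol = n, byrow = TRUE)
    sep <- .separation_calls(shuffled, group_cols)
    hit <- if (direction == "both") sep$direction != "none" else
      sep$direction == direction
    hits <- hits + sum(hit)
    trials <- trials + nrow(big)
    done <- done + b
  }
  p_hat <- hits / trials
  list(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / trials),
       n_trials = trials)
}

#' Expected number of monotone genes under the chance null
#'
#' @param m_tested Number of genes entering the test.
#' @param p_null Per-gene null probability from [null_probability()].
#' @return `m_tested * p_null`.
#' @export
expected_count <- function(m_tested, p_null) {
  if (m_tested < 0) stop("m_tested must be >= 0")
  m_tested * p_null
}

#' z-test for an excess of monotone genes over the chance expectation
#'
#' Tests whether the observed count of fully separated genes exceeds the
#' chance expectation, using the Poisson-variance normal approximation
#' `z = (observed - expected) / sqrt(expected)` with a one-sided upper
#' tail (an excess of rare events is the alternative of interest).
#'
#' @param observed Observed count of monotone genes.
#' @param expected Expected count under the null; must be > 0.
#' @return List with `excess`, `z` and `p_value`.
#' @export
excess_test <- function(observed, expected) {
  if (!is.finite(expected) || expected <= 0)
    stop("expected must be > 0")
  z <- (observed - expected) / sqrt(expected)
  list(excess = observed - expected, z = z,
       p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Exact two-sided confidence interval for an observed count
#'
#' Garwood's exact Poisson interval via chi-square quantiles:
#' `low = qchisq(alpha/2, 2c)/2`, `high = qchisq(1 - alpha/2, 2c + 2)/2`
#' (low = 0 when c = 0). A Clopper-Pearson exact binomial interval on
#' `count / m_tested`, rescaled back to counts, is available as an
#' alternative; for gene universes of 10^4 or more the two agree to well
#' under one count. `round_to` rounds both bounds for report display
#' (e.g. `round_to = 10` for comparison with interval bounds quoted to
#' the nearest ten).
#'
#' @param count Non-negative observed count.
#' @param level Confidence level in (0, 1).
#' @param method `"poisson"` (Garwood, default) or `"binomial"`
#'   (Clopper-Pearson; requires `m_tested`).
#' @param m_tested Gene universe size for the binomial method.
#' @param round_to Optional rounding unit for the returned bounds.
#' @return Numeric vector `c(low, high)`.
#' @export
exact_count_ci <- function(count, level = 0.95,
                           method = c("poisson", "binomial"),
                           m_tested = NULL, round_to = NULL) {
  method <- match.arg(method)
  if (count < 0 || count != round(count))
    stop("count must be a non-negative integer")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  alpha <- 1 - level
  if (method == "poisson") {
    low <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
    high <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  } else {
    if (is.null(m_tested) || m_tested < count)
      stop("binomial method needs m_tested >= count")
    ci <- stats::binom.test(count, m_tested,
                            conf.level = level)$conf.int
    low <- ci[1] * m_tested
    high <- ci[2] * m_tested
  }
  out <- c(low = low, high = high)
  if (!is.null(round_to)) out <- round(out / round_to) * round_to
  out
}

#' Intersect monotone genes with an external significant-gene list
#'
#' The differential-expression analysis itself (e.g. an edgeR fit at a
#' chosen FDR) is performed outside this package; its significant gene
#' ids are consumed here as a plain set and intersected with the monotone
#' calls. Input and output sizes are reported via `message()`.
#'
#' @param monotone_ids Character vector of monotone gene ids.
#' @param significant_ids Character vector of significant gene ids.
#' @return Character vector of gene ids in both sets.
#' @export
intersect_significant <- function(monotone_ids, significant_ids) {
  out <- intersect(monotone_ids, significant_ids)
  message("intersect_significant: ", length(unique(monotone_ids)),
          " monotone x ", length(unique(significant_ids)),
          " significant -> ", length(out), " genes")
  out
}

#' Share of reads assigned to the symbiont
#'
#' Per-sample fraction of total reads mapping to symbiont genes, with
#' per-generation means. A stable share across generations despite
#' declining hyphal biomass indicates increased fungal transcriptional
#' activity per hypha.
#'
#' @param cm A [count_matrix()] with an organism map.
#' @return List of class `symbiont_share` with `per_sample` (data frame:
#'   sample_id, generation, share) and `per_generation` (named means).
#' @export
symbiont_share <- function(cm) {
  sym <- cm$organism[rownames(cm$counts)] == "symbiont"
  tot <- colSums(cm$counts)
  sh <- if (any(sym)) colSums(cm$counts[sym, , drop = FALSE]) / tot else
    stats::setNames(rep(0, ncol(cm$counts)), colnames(cm$counts))
  per_sample <- data.frame(sample_id = colnames(cm$counts),
                           generation = cm$design$generation,
                           share = as.numeric(sh),
                           stringsAsFactors = FALSE)
  per_generation <- tapply(per_sample$share, per_sample$generation, mean)
  structure(list(per_sample = per_sample,
                 per_generation = per_generation[
                   levels(cm$design$generation)]),
            class = "symbiont_share")
}

#' @export
print.symbiont_share <- function(x, digits = 4, ...) {
  cat("symbiont read share by generation:\n")
  print(round(x$per_generation, digits))
  invisible(x)
}

#' Monotone-trend excess test across ordered generations
#'
#' The package's central analysis. Normalizes a dual-organism count
#' matrix to RPM (library size over all genes), restricts to genes of one
#' organism with nonzero total count (the tested universe `m_tested`),
#' calls strictly monotone trends with [detect_monotone()], and compares
#' the observed number of trending genes with the combinatorial chance
#' expectation `m_tested * p_null` via the one-sided Poisson-variance
#' z-test, attaching a Garwood exact confidence interval for the observed
#' count. Detection operates on RPM values; as the detector is
#' rank-based, any strictly increasing per-sample-monotone transform
#' (log, median centering) yields identical calls.
#'
#' @param cm A [count_matrix()].
#' @param direction `"both"` (default; the chance expectation covers a
#'   consistent increase or decrease), `"down"` or `"up"`.
#' @param organism Which gene set to test: `"host"` (default) or
#'   `"symbiont"`.
#' @param m_tested Override for the tested-universe size used in the
#'   expectation; defaults to the number of organism genes with nonzero
#'   total count.
#' @param level Confidence level for the exact count interval.
#' @return Object of class `trend_test`: list with `calls` (per-gene
#'   data frame), `m_tested`, `observed_down`, `observed_up`, `observed`
#'   (count entering the excess test), `n_tied`, `p_null_one`,
#'   `p_null_both`, `p_null_used`, `expected`, `excess`, `z`, `p_value`,
#'   `ci` (low, high), `group_sizes`, `direction`, `organism`, `level`.
#' @seealso [summary.trend_test()], [intersect_significant()],
#'   [symbiont_share()]
#' @export
trend_test <- function(cm, direction = c("both", "down", "up"),
                       organism = c("host", "symbiont"),
                       m_tested = NULL, level = 0.95) {
  direction <- match.arg(direction)
  organism <- match.arg(organism)
  em <- normalize_rpm(cm)
  keep <- cm$organism[rownames(cm$counts)] == organism &
    rowSums(cm$counts) > 0
  if (!any(keep)) stop("no ", organism, " genes with nonzero counts")
  values <- em$values[keep, , drop = FALSE]
  groups <- group_design(cm$design)
  calls <- detect_monotone(values, groups = groups, direction = "both")
  if (is.null(m_tested)) m_tested <- nrow(values)

  observed_down <- sum(calls$direction == "down")
  observed_up <- sum(calls$direction == "up")
  p1 <- null_probability(lengths(groups), "one")
  p2 <- null_probability(lengths(groups), "both")
  if (direction == "both") {
    observed <- observed_down + observed_up
    p_used <- p2
  } else {
    observed <- if (direction == "down") observed_down else observed_up
    p_used <- p1
  }
  expected <- expected_count(m_tested, p_used)
  et <- excess_test(observed, expected)
  ci <- exact_count_ci(observed, level = level)

  structure(list(
    calls = calls, m_tested = m_tested, observed_down = observed_down,
    observed_up = observed_up, observed = observed,
    n_tied = sum(calls$tied), p_null_one = p1, p_null_both = p2,
    p_null_used = p_used, expected = expected, excess = et$excess,
    z = et$z, p_value = et$p_value, ci = ci,
    group_sizes = lengths(groups), direction = direction,
    organism = organism, level = level), class = "trend_test")
}

#' @export
print.trend_test <- function(x, digits = 4, ...) {
  cat("\n\tMonotone-separation trend test (", x$organism,
      " genes, direction = ", x$direction, ")\n\n", sep = "")
  cat("design: groups of size (",
      paste(x$group_sizes, collapse = ", "), "), null p = ",
      format(x$p_null_used, digits = digits),
      " (", if (x$direction == "both") "both directions" else
        "one direction", ")\n", sep = "")
  cat("genes tested: ", x$m_tested, "\n", sep = "")
  cat("observed monotone: ", x$observed, " (down ", x$observed_down,
      ", up ", x$observed_up, "; ties defeated ", x$n_tied, ")\n",
      sep = "")
  cat("expected by chance: ", format(x$expected, digits = digits),
      ",  excess: ", format(x$excess, digits = digits), "\n", sep = "")
  cat("z = ", format(x$z, digits = digits), ",  one-sided p-value ",
      format.pval(x$p_value, digits = digits), "\n", sep = "")
  cat(100 * x$level, "% exact CI for the observed count: [",
      format(x$ci[["low"]], digits = digits), ", ",
      format(x$ci[["high"]], digits = digits), "]\n\n", sep = "")
  invisible(x)
}

#' Summarize a trend test as a one-row data frame
#'
#' @param object A `trend_test` object.
#' @param ... Unused.
#' @return One-row data frame with the test's headline numbers
#'   (m_tested, observed, expected, excess, z, p_value, ci_low, ci_high).
#' @export
summary.trend_test <- function(object, ...) {
  data.frame(m_tested = object$m_tested, observed = object$observed,
             observed_down = object$observed_down,
             observed_up = object$observed_up,
             expected = object$expected, excess = object$excess,
             z = object$z, p_value = object$p_value,
             ci_low = object$ci[["low"]], ci_high = object$ci[["high"]])
}
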