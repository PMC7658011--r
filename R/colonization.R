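#' Per-section colonization morphometry
#'
#' Converts raw section measurements into per-section summaries: mean
#' hyphal diameter, mean hyphal cross-sectional area and the biovolume
#' index (mean area x hyphal count, in um^2 x hyphae), a proxy for fungal
#' biomass in the section. Hyphae are modelled as circular in cross
#' section. By default the area is the mean of per-hypha areas
#' `mean(pi * (d/2)^2)`; the area of the mean diameter
#' `pi * (mean(d)/2)^2` is available as an alternative (Jensen's
#' inequality makes it smaller whenever diameters vary).
#'
#' @param sections `section_measurements` data frame from
#'   [read_sections()] or [simulate_sections()].
#' @param area_method `"mean_area"` (default) or
#'   `"area_of_mean_diameter"`.
#' @return Data frame with `genotype_id`, `generation`, `section_index`,
#'   `hyphal_count`, `vascular_hyphae`, `mean_diameter_um`,
#'   `mean_area_um2`, `biovolume_index`. Zero-count sections get
#'   biovolume 0 and missing diameter/area.
#' @export
summarize_sections <- function(sections,
                               area_method = c("mean_area",
                                               "area_of_mean_diameter")) {
  area_method <- match.arg(area_method)
  n <- nrow(sections)
  mean_d <- mean_a <- biov <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sections$diameters_um[[i]]
    cnt <- sections$hyphal_count[i]
    if (cnt == 0) {
      biov[i] <- 0
      next
    }
    if (length(d)) {
      mean_d[i] <- mean(d)
      mean_a[i] <- if (area_method == "mean_area")
        mean(pi * (d / 2)^2) else pi * (mean(d) / 2)^2
      biov[i] <- mean_a[i] * cnt
    }
  }
  data.frame(genotype_id = sections$genotype_id,
             generation = sections$generation,
             section_index = sections$section_index,
             hyphal_count = sections$hyphal_count,
             vascular_hyphae = sections$vascular_hyphae,
             mean_diameter_um = mean_d, mean_area_um2 = mean_a,
             biovolume_index = biov, stringsAsFactors = FALSE)
}

#' Per-genotype colonization summary
#'
#' Averages per-section count, diameter and biovolume index over each
#' genotype's sections (unweighted; diameter means ignore zero-count
#' sections, whose diameter is undefined). These genotype means are the
#' unit of the downstream rank tests and percent-change comparisons.
#'
#' @param section_summaries Output of [summarize_sections()].
#' @return Data frame with one row per genotype: `genotype_id`,
#'   `generation`, `n_sections`, `mean_count`, `mean_diameter_um`,
#'   `mean_biovolume_index`.
#' @export
genotype_summary <- function(section_summaries) {
  key <- unique(section_summaries[, c("genotype_id", "generation")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sub <- section_summaries[
      section_summaries$genotype_id == key$genotype_id[i], , drop = FALSE]
    if (nrow(sub) == 1)
      warning("genotype '", key$genotype_id[i],
              "' has a single section; summary equals that section")
    data.frame(genotype_id = key$genotype_id[i],
               generation = key$generation[i],
               n_sections = nrow(sub),
               mean_count = mean(sub$hyphal_count),
               mean_diameter_um = if (all(is.na(sub$mean_diameter_um)))
                 NA_real_ else mean(sub$mean_diameter_um, na.rm = TRUE),
               mean_biovolume_index = mean(sub$biovolume_index),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.group_summaries <- function(groups) {
  t(vapply(groups, function(v)
    c(n = length(v), mean = mean(v), median = stats::median(v),
      min = min(v), max = max(v)), numeric(5)))
}

#' Kruskal-Wallis rank comparison across generations
#'
#' Rank test on one value per genotype (the genotype means from
#' [genotype_summary()]), with the standard tie correction, as
#' implemented in `stats::kruskal.test`. `H = 0`, `p = 1` when all values
#' are identical.
#'
#' @param groups Named list of numeric vectors, one per generation.
#' @return Object of class `generation_comparison`: `statistic_name`,
#'   `statistic` (H), `df` (k - 1), `p_value`, `group_summaries`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 1)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    stat <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    stat <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(statistic_name = "Kruskal-Wallis H", statistic = stat,
                 df = length(groups) - 1, p_value = p,
                 group_summaries = .group_summaries(groups)),
            class = "generation_comparison")
}

#' @export
print.generation_comparison <- function(x, digits = 4, ...) {
  cat(x$statistic_name, " = ", format(x$statistic, digits = digits),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = digits),
      "\n", sep = "")
  print(round(x$group_summaries, digits))
  if (!is.null(x$frequencies)) {
    cat("per-group frequency:\n")
    print(signif(x$frequencies, digits))
  }
  invisible(x)
}

#' Chi-square test of vascular-bundle colonization frequency
#'
#' Pools hyphal counts per generation and tests homogeneity of the
#' vascular-bundle colonization frequency (vascular vs non-vascular
#' hyphae) across generations with Pearson's chi-square statistic
#' (no continuity correction), df = k - 1. Warns when any expected cell
#' is below 5 (the frequencies involved are typically very low).
#' Generations with zero total hyphae are excluded with a warning.
#'
#' @param sections `section_measurements` data frame.
#' @return `generation_comparison` with an extra `frequencies` element
#'   (named per-generation vascular frequency) and `table` (k x 2 counts).
#' @export
vascular_chi_square <- function(sections) {
  gens <- unique(sections$generation)
  tot <- vapply(gens, function(g)
    sum(sections$hyphal_count[sections$generation == g]), 0)
  vas <- vapply(gens, function(g)
    sum(sections$vascular_hyphae[sections$generation == g]), 0)
  drop <- tot == 0
  if (any(drop)) {
    warning("generation(s) with zero total hyphae excluded: ",
            paste(gens[drop], collapse = ", "))
    gens <- gens[!drop]; tot <- tot[!drop]; vas <- vas[!drop]
  }
  if (length(gens) < 2) stop("need at least 2 generations with hyphae")
  tab <- cbind(vascular = vas, other = tot - vas)
  rownames(tab) <- gens
  freq <- vas / tot
  names(freq) <- gens
  if (all(vas == 0) || all(vas == tot)) {
    # degenerate table: one column all zero, no heterogeneity to test
    stat <- 0; p <- 1; expected <- tab
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
    expected <- ct$expected
  }
  if (any(expected < 5))
    warning("expected cell count below 5; chi-square approximation ",
            "is coarse at these low frequencies")
  structure(list(statistic_name = "Pearson chi-square",
                 statistic = stat, df = length(gens) - 1, p_value = p,
                 group_summaries = cbind(n = tot, vascular = vas),
                 frequencies = freq, table = tab),
            class = "generation_comparison")
}

#' Percent decline between generation means
#'
#' Decline from the baseline (first) generation to each later one:
#' `(mean_baseline - mean_later) / mean_baseline * 100`. Negative values
#' indicate an increase.
#'
#' @param means Named numeric vector of per-generation means in
#'   generation order (e.g. generation means of genotype mean biovolume).
#' @return Data frame with `pair` (e.g. `"G2->G9"`) and
#'   `percent_decline`.
#' @export
percent_change <- function(means) {
  if (length(means) < 2) stop("need at least 2 generations")
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  base <- means[[1]]
  if (!is.finite(base) || base <= 0) stop("baseline mean must be > 0")
  later <- seq_along(means)[-1]
  data.frame(pair = paste0(names(means)[1], "->", names(means)[later]),
             percent_decline = (base - unname(means[later])) / base * 100,
             stringsAsFactors = FALSE)
}

#' Seed-transmission rates with exact binomial intervals
#'
#' Per-generation infection rate `n_infected / n_tested` with the
#' Clopper-Pearson exact interval.
#'
#' @param records `transmission_records` data frame.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `generation`, `n_tested`, `n_infected`,
#'   `selected`, `rate`, `ci_low`, `ci_high` (rates as proportions).
#' @export
transmission_estimate <- function(records, level = 0.95) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  ci <- t(vapply(seq_len(nrow(records)), function(i)
    stats::binom.test(records$n_infected[i], records$n_tested[i],
                      conf.level = level)$conf.int, numeric(2)))
  data.frame(generation = records$generation,
             n_tested = records$n_tested,
             n_infected = records$n_infected,
             selected = records$selected,
             rate = records$n_infected / records$n_tested,
             ci_low = ci[, 1], ci_high = ci[, 2])
}

#' Tillering growth curves and generation comparison
#'
#' Averages tiller counts per genotype and day, then per generation and
#' day (mean of genotype means); reports the day each genotype first
#' exceeded its initial tiller count (first daughter tiller; missing if
#' counts never increase); and compares generations by a Kruskal-Wallis
#' test on per-genotype final counts.
#'
#' @param records `tiller_records` data frame.
#' @return List of class `tillering_curve`: `curve` (generation, day,
#'   mean_count), `first_daughter` (genotype_id, generation, day -- NA if
#'   never), `comparison` ([kruskal_wallis()] result, or NULL with a
#'   single generation).
#' @export
tillering_curve <- function(records) {
  geno_day <- stats::aggregate(tiller_count ~ genotype_id + generation +
                                 day, data = records, FUN = mean)
  curve <- stats::aggregate(tiller_count ~ generation + day,
                            data = geno_day, FUN = mean)
  names(curve)[names(curve) == "tiller_count"] <- "mean_count"
  curve <- curve[order(curve$generation, curve$day), ]
  rownames(curve) <- NULL

  genos <- unique(geno_day[, c("genotype_id", "generation")])
  fd <- vapply(seq_len(nrow(genos)), function(i) {
    sub <- geno_day[geno_day$genotype_id == genos$genotype_id[i], ]
    sub <- sub[order(sub$day), ]
    up <- which(sub$tiller_count > sub$tiller_count[1])
    if (length(up)) sub$day[up[1]] else NA_real_
  }, 0)
  first_daughter <- data.frame(genos, day = fd, stringsAsFactors = FALSE)

  comparison <- NULL
  if (length(unique(records$generation)) >= 2) {
    finals <- vapply(seq_len(nrow(genos)), function(i) {
      sub <- geno_day[geno_day$genotype_id == genos$genotype_id[i], ]
      sub$tiller_count[which.max(sub$day)]
    }, 0)
    comparison <- kruskal_wallis(split(finals, genos$generation))
  }
  structure(list(curve = curve, first_daughter = first_daughter,
                 comparison = comparison), class = "tillering_curve")
}

#' @export
print.tillering_curve <- function(x, ...) {
  cat("tillering curve over", length(unique(x$curve$generation)),
      "generation(s),", length(unique(x$curve$day)), "time points\n")
  if (!is.null(x$comparison)) {
    cat("final-count comparison: ")
    print(x$comparison)
  }
  invisible(x)
}
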