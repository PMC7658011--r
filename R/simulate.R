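## Synthetic-data generators. Each emulates one input stream of the
## analysis: pooled-replicate dual-organism RNA-seq counts with planted
## monotone trends, microscopy section morphometry, a selective
## open-pollination seed maintenance program, and tillering time series.
## Fixing `seed` fixes every output bit-for-bit.

#' Simulate a dual-organism RNA-seq count matrix with planted trends
#'
#' Gene mean expression levels are drawn log-normally; a fraction
#' `frac_monotone_down` of host genes is planted with geometrically
#' declining generation means (mu, mu*delta, mu*delta^2, ...). Counts are
#' drawn negative-binomially (variance mu + dispersion * mu^2; Poisson at
#' dispersion 0) with per-sample expected totals equal to `library_size`.
#' Symbiont gene means are scaled so the expected symbiont read share
#' matches `symbiont_share_target`; symbiont expression is constant
#' across generations (the fungal transcriptome carries no planted
#' trend). Ground-truth planted gene ids are returned separately and are
#' never written into the data.
#'
#' @param n_host_genes,n_symbiont_genes Gene counts (defaults 13440 host,
#'   300 symbiont).
#' @param generations Named integer vector: replicate count per
#'   generation, in generation order (default `c(G2=3, G6=3, G9=3)`).
#' @param mean_log_expression,sdlog_expression Log-normal location and
#'   spread of relative gene means.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param frac_monotone_down Fraction of host genes planted with a
#'   declining trend.
#' @param decline_factor Per-generation-step multiplier delta in (0, 1)
#'   for planted genes.
#' @param symbiont_share_target Expected fraction of reads from symbiont
#'   genes (default 0.003).
#' @param library_size Expected reads per sample.
#' @param seed Integer RNG seed.
#' @return List with `cm` (a [count_matrix()]) and `truth` (character
#'   vector of planted monotone-down gene ids).
#' @export
simulate_counts <- function(n_host_genes = 13440, n_symbiont_genes = 300,
                            generations = c(G2 = 3, G6 = 3, G9 = 3),
                            mean_log_expression = 6,
                            sdlog_expression = 1, dispersion = 0.1,
                            frac_monotone_down = 0, decline_factor = 0.5,
                            symbiont_share_target = 0.003,
                            library_size = 16e6, seed = 1L) {
  stopifnot(n_host_genes >= 1, n_symbiont_genes >= 0,
            length(generations) >= 2, all(generations >= 1),
            dispersion >= 0, frac_monotone_down >= 0,
            frac_monotone_down <= 1, decline_factor > 0,
            decline_factor < 1, symbiont_share_target > 0,
            symbiont_share_target < 1, library_size > 0)
  set.seed(seed)
  k <- length(generations)
  gens <- names(generations)
  if (is.null(gens)) stop("generations must be named with labels")

  host_ids <- sprintf("host_%05d", seq_len(n_host_genes))
  sym_ids <- if (n_symbiont_genes > 0)
    sprintf("sym_%04d", seq_len(n_symbiont_genes)) else character(0)

  host_mu <- exp(stats::rnorm(n_host_genes, mean_log_expression,
                              sdlog_expression))
  n_planted <- round(frac_monotone_down * n_host_genes)
  if (frac_monotone_down > 0 && n_planted < 1)
    warning("frac_monotone_down * n_host_genes < 1: no genes planted")
  truth <- if (n_planted > 0)
    sort(sample(host_ids, n_planted)) else character(0)

  # per-generation host means: planted genes decline geometrically
  host_gen_mu <- matrix(host_mu, n_host_genes, k)
  rownames(host_gen_mu) <- host_ids
  if (n_planted > 0)
    for (i in seq_len(k))
      host_gen_mu[truth, i] <- host_mu[match(truth, host_ids)] *
        decline_factor^(i - 1)

  sym_gen_mu <- NULL
  if (n_symbiont_genes > 0) {
    sym_mu <- exp(stats::rnorm(n_symbiont_genes, mean_log_expression,
                               sdlog_expression))
    target_sum <- symbiont_share_target / (1 - symbiont_share_target) *
      mean(colSums(host_gen_mu))
    sym_mu <- sym_mu * target_sum / sum(sym_mu)
    sym_gen_mu <- matrix(sym_mu, n_symbiont_genes, k)
    rownames(sym_gen_mu) <- sym_ids
  }
  gen_mu <- rbind(host_gen_mu, sym_gen_mu)

  sample_ids <- unlist(lapply(seq_len(k), function(i)
    paste0(gens[i], "_r", seq_len(generations[i]))))
  counts <- matrix(0, nrow(gen_mu), length(sample_ids),
                   dimnames = list(rownames(gen_mu), sample_ids))
  col <- 0
  for (i in seq_len(k)) {
    mu <- gen_mu[, i] / sum(gen_mu[, i]) * library_size
    for (r in seq_len(generations[i])) {
      col <- col + 1
      counts[, col] <- if (dispersion > 0)
        stats::rnbinom(nrow(gen_mu), mu = mu, size = 1 / dispersion)
      else stats::rpois(nrow(gen_mu), mu)
    }
  }
  design <- data.frame(
    sample_id = sample_ids,
    generation = factor(rep(gens, generations), levels = gens),
    replicate = unlist(lapply(generations, seq_len)),
    stringsAsFactors = FALSE)
  organism <- stats::setNames(
    c(rep("host", n_host_genes), rep("symbiont", n_symbiont_genes)),
    c(host_ids, sym_ids))
  list(cm = count_matrix(counts, design, organism), truth = truth)
}

#' Simulate microscopy section measurements
#'
#' Per-section hyphal counts are drawn negative-binomially around
#' per-generation means (deterministic at `count_dispersion = 0`);
#' per-hypha diameters are normal truncated at zero, with at most
#' `max_measured` hyphae measured per section (a 40-50 hypha subsample
#' when counts exceed it, mirroring routine morphometry practice);
#' vascular-bundle hyphal counts are binomial in the section count.
#' Defaults emulate a declining colonization series: generation mean
#' counts 250/180/62.5 (a 75% count drop) and mean diameters
#' 2.00/1.93/1.75 um, giving generation biovolume means near the ratio
#' 100:67:19.
#'
#' @param genotypes_per_generation Named integer vector of genotypes per
#'   generation in generation order (default `c(G2=9, G6=10, G9=8)`).
#' @param sections_per_genotype Sections cut per genotype (default 3).
#' @param count_mean Named per-generation mean hyphal count.
#' @param count_dispersion NB dispersion for counts; 0 = deterministic.
#' @param diameter_mean_um,diameter_sd_um Per-generation diameter mean
#'   (named) and common standard deviation, in micrometers.
#' @param vascular_rate Named per-generation probability that a hypha
#'   sits in a vascular bundle.
#' @param max_measured Maximum hyphae measured for diameter per section.
#' @param seed Integer RNG seed.
#' @return `section_measurements` data frame (see [read_sections()]).
#' @export
simulate_sections <- function(
    genotypes_per_generation = c(G2 = 9, G6 = 10, G9 = 8),
    sections_per_genotype = 3,
    count_mean = c(G2 = 250, G6 = 180, G9 = 62.5),
    count_dispersion = 0.02,
    diameter_mean_um = c(G2 = 2.0, G6 = 1.93, G9 = 1.75),
    diameter_sd_um = 0.2,
    vascular_rate = c(G2 = 0.0004, G6 = 0.0023, G9 = 0.0030),
    max_measured = 50, seed = 1L) {
  gens <- names(genotypes_per_generation)
  stopifnot(!is.null(gens), all(count_mean[gens] > 0),
            all(vascular_rate[gens] >= 0), all(vascular_rate[gens] <= 1),
            all(diameter_mean_um[gens] > 0), diameter_sd_um >= 0,
            count_dispersion >= 0, sections_per_genotype >= 1)
  set.seed(seed)
  rows <- list()
  for (g in gens) {
    for (p in seq_len(genotypes_per_generation[[g]])) {
      gid <- paste0(g, "_p", p)
      for (s in seq_len(sections_per_genotype)) {
        count <- if (count_dispersion > 0)
          stats::rnbinom(1, mu = count_mean[[g]],
                         size = 1 / count_dispersion)
        else round(count_mean[[g]])
        n_meas <- min(count,
                      if (count > max_measured)
                        sample(seq(max_measured - 10, max_measured), 1)
                      else count)
        d <- numeric(0)
        if (n_meas > 0) {
          d <- stats::rnorm(n_meas, diameter_mean_um[[g]], diameter_sd_um)
          while (any(d <= 0))            # truncate at zero
            d[d <= 0] <- stats::rnorm(sum(d <= 0), diameter_mean_um[[g]],
                                      diameter_sd_um)
        }
        vasc <- stats::rbinom(1, count, vascular_rate[[g]])
        rows[[length(rows) + 1]] <- list(
          genotype_id = gid, generation = g, tiller_id = paste0(gid, "_t1"),
          section_index = s, hyphal_count = as.integer(count),
          vascular_hyphae = as.integer(vasc), diameters_um = d)
      }
    }
  }
  out <- data.frame(
    genotype_id = vapply(rows, `[[`, "", "genotype_id"),
    generation = vapply(rows, `[[`, "", "generation"),
    tiller_id = vapply(rows, `[[`, "", "tiller_id"),
    section_index = vapply(rows, `[[`, 0L, "section_index"),
    hyphal_count = vapply(rows, `[[`, 0L, "hyphal_count"),
    vascular_hyphae = vapply(rows, `[[`, 0L, "vascular_hyphae"),
    stringsAsFactors = FALSE)
  out$diameters_um <- lapply(rows, `[[`, "diameters_um")
  class(out) <- c("section_measurements", "data.frame")
  out
}

#' Simulate a selective seed maintenance program
#'
#' Each plant carries a seed-transmission probability tau, Beta-distributed
#' across the founder population. Every generation, offspring are produced
#' by open pollination of the parent pool; each offspring inherits the
#' endophyte with probability equal to its seed parent's tau, and its own
#' tau is `h * tau_parent + (1 - h) * fresh_draw` with heritability `h`.
#' The parent pool of a selected generation is restricted to infected
#' plants of the previous generation (the selection that drives
#' transmission rates upward when tau is heritable); generations listed in
#' `unselected_generations` are derived without regard to infection
#' status.
#'
#' @param n_generations Number of generations (default 9).
#' @param n_parents Founder population size (default 38).
#' @param tau_mean,tau_concentration Beta distribution of tau across
#'   founders: mean and concentration (a+b); low concentration means wide
#'   plant-to-plant variation in transmission ability.
#' @param heritability_of_tau In `[0, 1]`; 0 resets every offspring's tau
#'   to a fresh population draw (selection then has no cumulative effect).
#' @param unselected_generations Generations whose parents were not
#'   selected for infection (default `c(3, 5)`).
#' @param n_tested_per_generation Offspring tested per generation.
#' @param seed Integer RNG seed.
#' @return `transmission_records` data frame: `generation`, `n_tested`,
#'   `n_infected`, `selected`.
#' @export
simulate_maintenance_program <- function(
    n_generations = 9, n_parents = 38, tau_mean = 0.76,
    tau_concentration = 2, heritability_of_tau = 1,
    unselected_generations = c(3, 5), n_tested_per_generation = 200,
    seed = 1L) {
  stopifnot(n_generations >= 1, n_parents >= 1, tau_mean > 0,
            tau_mean < 1, tau_concentration > 0,
            heritability_of_tau >= 0, heritability_of_tau <= 1,
            n_tested_per_generation >= 1)
  set.seed(seed)
  a <- tau_mean * tau_concentration
  b <- (1 - tau_mean) * tau_concentration
  h <- heritability_of_tau
  pool_tau <- stats::rbeta(n_parents, a, b)   # founders, all infected
  n_off <- n_tested_per_generation
  rec <- vector("list", n_generations)
  for (g in seq_len(n_generations)) {
    selected <- !(g %in% unselected_generations)
    parent <- sample(seq_along(pool_tau), n_off, replace = TRUE)
    infected <- stats::rbinom(n_off, 1, pool_tau[parent]) == 1
    child_tau <- h * pool_tau[parent] +
      (1 - h) * stats::rbeta(n_off, a, b)
    rec[[g]] <- data.frame(generation = g, n_tested = n_off,
                           n_infected = sum(infected),
                           selected = selected)
    # parents of the NEXT generation: infected offspring unless that
    # generation is propagated without regard to infection status
    next_selected <- !((g + 1) %in% unselected_generations)
    pool_tau <- if (next_selected && any(infected))
      child_tau[infected] else child_tau
  }
  out <- do.call(rbind, rec)
  class(out) <- c("transmission_records", "data.frame")
  out
}

#' Simulate tillering time series
#'
#' Geometric tiller growth from three initial tillers, counted every two
#' days, with multiplicative log-normal observation noise:
#' `count(day) = round(3 * (1 + rate)^(day / 2) * exp(eps))`. With
#' `noise_sd = 0` the closed form `round(3 * (1 + rate)^(day / 2))` is
#' returned exactly.
#'
#' @param genotypes Number of genotypes (default 13).
#' @param days Last observation day; counts recorded on days 0, 2, ...
#' @param rate Per-count-interval (2-day) growth rate; 0 keeps counts
#'   constant at 3.
#' @param noise_sd Log-scale observation noise standard deviation.
#' @param generation Generation label attached to all records.
#' @param seed Integer RNG seed.
#' @return `tiller_records` data frame: `genotype_id`, `generation`,
#'   `day`, `tiller_count`.
#' @export
simulate_tillering <- function(genotypes = 13, days = 30, rate = 0.14,
                               noise_sd = 0.05, generation = "G2",
                               seed = 1L) {
  stopifnot(genotypes >= 1, days >= 0, rate >= 0, noise_sd >= 0)
  set.seed(seed)
  day <- seq(0, days, by = 2)
  rec <- lapply(seq_len(genotypes), function(p) {
    latent <- 3 * (1 + rate)^(day / 2)
    if (noise_sd > 0)
      latent <- latent * exp(stats::rnorm(length(day), 0, noise_sd))
    data.frame(genotype_id = paste0(generation, "_p", p),
               generation = generation, day = day,
               tiller_count = pmax(1L, as.integer(round(latent))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  class(out) <- c("tiller_records", "data.frame")
  out
}
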