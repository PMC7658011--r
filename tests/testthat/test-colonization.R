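test_that("section summaries compute per-hypha areas and biovolume", {
  s <- section_row(count = 100, diameters = rep(2, 40))
  ss <- summarize_sections(s)
  expect_equal(ss$mean_area_um2, pi, tolerance = 1e-12)
  expect_equal(ss$biovolume_index, 100 * pi, tolerance = 1e-12)
  expect_equal(round(ss$biovolume_index, 2), 314.16)

  # areas are averaged per hypha, not computed from the mean diameter
  s2 <- section_row(count = 2, diameters = c(1, 3))
  ss2 <- summarize_sections(s2)
  expect_equal(ss2$mean_area_um2, 1.25 * pi, tolerance = 1e-12)
  alt <- summarize_sections(s2, area_method = "area_of_mean_diameter")
  expect_equal(alt$mean_area_um2, pi)       # pi * (2/2)^2, Jensen gap

  # zero-count sections: biovolume 0, diameter missing
  s0 <- section_row(count = 0, diameters = numeric(0))
  ss0 <- summarize_sections(s0)
  expect_equal(ss0$biovolume_index, 0)
  expect_true(is.na(ss0$mean_diameter_um))
})

test_that("biovolume is permutation-invariant and scales quadratically", {
  d <- c(1.2, 2.5, 1.9, 2.1, 1.4)
  a <- summarize_sections(section_row(count = 50, diameters = d))
  b <- summarize_sections(section_row(count = 50, diameters = rev(d)))
  expect_equal(a$biovolume_index, b$biovolume_index)
  for (c_ in c(0.5, 2, 3)) {
    sc <- summarize_sections(section_row(count = 50, diameters = c_ * d))
    expect_equal(sc$biovolume_index, c_^2 * a$biovolume_index,
                 tolerance = 1e-12)
  }
})

test_that("genotype summaries average sections and handle degenerate input", {
  secs <- bind_sections(
    section_row("g1", section = 1, count = 100, diameters = c(2, 2)),
    section_row("g1", section = 2, count = 110, diameters = c(2, 2)),
    section_row("g1", section = 3, count = 120, diameters = c(2, 2)))
  gs <- genotype_summary(summarize_sections(secs))
  expect_equal(gs$mean_count, 110)
  expect_equal(gs$n_sections, 3)

  one <- section_row("g2", section = 1, count = 50, diameters = c(2))
  expect_warning(g1 <- genotype_summary(summarize_sections(one)),
                 "single section")
  expect_equal(g1$mean_count, 50)

  # diameter mean ignores zero-count sections
  mix <- bind_sections(
    section_row("g3", section = 1, count = 10, diameters = c(3, 3)),
    section_row("g3", section = 2, count = 0, diameters = numeric(0)))
  gm <- genotype_summary(summarize_sections(mix))
  expect_equal(gm$mean_diameter_um, 3)
  expect_equal(gm$mean_biovolume_index,
               mean(c(10 * pi * 1.5^2, 0)))
})

test_that("Kruskal-Wallis wrapper matches the rank formula and handles ties", {
  kw <- kruskal_wallis(list(G2 = c(1, 2, 3), G6 = c(4, 5, 6),
                            G9 = c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # independent route: hand-computed H with tie correction
  hand_H <- function(groups) {
    x <- unlist(groups); N <- length(x); r <- rank(x)
    nj <- lengths(groups)
    rbar <- tapply(r, rep(seq_along(groups), nj), mean)
    H <- 12 / (N * (N + 1)) * sum(nj * (rbar - (N + 1) / 2)^2)
    t_ <- table(x)
    H / (1 - sum(t_^3 - t_) / (N^3 - N))
  }
  set.seed(15)
  for (i in 1:5) {
    g <- list(a = round(rnorm(6), 1), b = round(rnorm(5), 1),
              c = round(rnorm(7), 1))
    expect_equal(kruskal_wallis(g)$statistic, unname(hand_H(g)),
                 tolerance = 1e-12)
  }

  ident <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  same <- kruskal_wallis(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(same$p_value, 1)
})

test_that("Kruskal-Wallis chi-square p tracks a brute-force permutation p", {
  set.seed(19)
  groups <- list(a = c(2.1, 3.4, 1.8), b = c(3.0, 4.2, 5.1),
                 c = c(4.8, 3.9, 6.0))
  obs <- kruskal_wallis(groups)
  x <- unlist(groups)
  lab <- rep(1:3, lengths(groups))
  perm_H <- replicate(4000, {
    xl <- split(x[sample(length(x))], lab)
    kruskal_wallis(xl)$statistic
  })
  p_perm <- mean(perm_H >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.05)
})

test_that("vascular chi-square reproduces the 2x2 closed form and frequencies", {
  secs <- bind_sections(
    section_row("g1", "G2", count = 100, vascular = 10,
                diameters = c(2)),
    section_row("g2", "G6", count = 100, vascular = 20,
                diameters = c(2)))
  vc <- vascular_chi_square(secs)
  # N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  expect_equal(vc$statistic, 200 * (10 * 80 - 90 * 20)^2 /
                 (100 * 100 * 30 * 170), tolerance = 1e-12)
  expect_equal(round(vc$statistic, 4), 3.9216)
  expect_equal(vc$df, 1)

  # toy table consistent with frequencies 0.04%, 0.23%, 0.30%
  secs3 <- bind_sections(
    section_row("g1", "G2", count = 2500, vascular = 1, diameters = 2),
    section_row("g2", "G6", count = 2600, vascular = 6, diameters = 2),
    section_row("g3", "G9", count = 2700, vascular = 8, diameters = 2))
  vc3 <- suppressWarnings(vascular_chi_square(secs3))
  expect_equal(unname(vc3$frequencies),
               c(1 / 2500, 6 / 2600, 8 / 2700))
  expect_equal(round(100 * unname(vc3$frequencies), 2),
               c(0.04, 0.23, 0.30))
  # pooled frequency lies between per-generation extremes
  pooled <- sum(secs3$vascular_hyphae) / sum(secs3$hyphal_count)
  expect_true(pooled >= min(vc3$frequencies) &&
                pooled <= max(vc3$frequencies))

  # equal frequencies give a null statistic
  eq <- bind_sections(
    section_row("g1", "G2", count = 100, vascular = 10, diameters = 2),
    section_row("g2", "G6", count = 200, vascular = 20, diameters = 2))
  vceq <- suppressWarnings(vascular_chi_square(eq))
  expect_equal(vceq$statistic, 0)
  expect_equal(vceq$p_value, 1)
})

test_that("percent change mirrors the printed decline arithmetic", {
  pc <- percent_change(c(G2 = 100, G6 = 67, G9 = 19))
  expect_equal(pc$pair, c("G2->G6", "G2->G9"))
  expect_equal(pc$percent_decline, c(33, 81))
  expect_equal(percent_change(c(a = 5, b = 5))$percent_decline, 0)
  expect_error(percent_change(c(a = 0, b = 1)), "baseline")
})

test_that("transmission estimates use exact binomial intervals", {
  recs <- data.frame(generation = c(1, 2, 3),
                     n_tested = c(50, 10, 10),
                     n_infected = c(38, 0, 10),
                     selected = TRUE)
  est <- transmission_estimate(recs)
  expect_equal(est$rate, c(0.76, 0, 1))
  expect_equal(est$ci_low[1], 0.6183093, tolerance = 1e-6)
  expect_equal(est$ci_high[1], 0.8693901, tolerance = 1e-6)
  expect_equal(est$ci_high[2], 0.3084971, tolerance = 1e-6)
  expect_equal(est$ci_low[3], 0.6915029, tolerance = 1e-6)
  expect_equal(est$ci_low[3], 1 - est$ci_high[2])   # symmetry
})

test_that("transmission intervals attain nominal coverage", {
  set.seed(23)
  p <- 0.76
  draws <- rbinom(1500, 50, p)
  recs <- data.frame(generation = seq_along(draws), n_tested = 50,
                     n_infected = draws, selected = TRUE)
  est <- transmission_estimate(recs)
  expect_gte(mean(est$ci_low <= p & p <= est$ci_high), 0.95)
})

test_that("tillering curves, first-daughter times and rank test behave", {
  # constant counts: no daughter tiller ever appears
  flat <- simulate_tillering(genotypes = 3, days = 10, rate = 0,
                             noise_sd = 0, generation = "G2", seed = 1)
  tc <- tillering_curve(flat)
  expect_true(all(is.na(tc$first_daughter$day)))
  expect_null(tc$comparison)

  # two identical generations: rank test cannot separate them
  a <- simulate_tillering(genotypes = 4, days = 12, rate = 0.3,
                          noise_sd = 0, generation = "G2", seed = 2)
  b <- simulate_tillering(genotypes = 4, days = 12, rate = 0.3,
                          noise_sd = 0, generation = "G9", seed = 2)
  tc2 <- tillering_curve(rbind(a, b))
  expect_equal(tc2$comparison$p_value, 1)
  # growth from 3 tillers means the first increase day is recorded
  expect_true(all(!is.na(tc2$first_daughter$day)))

  # equal growth rates across generations: mostly non-significant
  ps <- vapply(1:10, function(s) {
    g1 <- simulate_tillering(genotypes = 8, days = 20, rate = 0.15,
                             generation = "G2", seed = s)
    g2 <- simulate_tillering(genotypes = 8, days = 20, rate = 0.15,
                             generation = "G9", seed = s + 100)
    tillering_curve(rbind(g1, g2))$comparison$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})
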