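# symbiotrend

Quantitative analyses for tracking **co-adaptation in grass–endophyte
symbioses** across the generations of a seed maintenance program.

Artificial associations between a pasture grass (e.g. *Lolium perenne*)
and a selected seed-transmitted *Epichloë* endophyte strain have not
co-evolved, so both partners are expected to adapt over the serial
seed-propagation cycles that maintain the association. `symbiotrend`
implements the statistics used to detect such changes from three data
streams collected at ordered generations (e.g. G2 < G6 < G9):

* **Transcriptome trends.** A gene shows a *monotone-separation trend*
  when every replicate RPM value of each later generation lies strictly
  below (or above) every replicate value of the preceding generation.
  For k ordered groups with replicate sizes n₁,…,n_k (N = Σnⱼ) of
  exchangeable continuous values, the chance probability of full
  separation is

      p₁ = (∏ⱼ nⱼ!) / N!   per direction,   p = 2·p₁ both directions,

  i.e. p = 1/840 for the 3×3×3 replicate design. With m genes tested,
  the expected chance count is E = m·p, and the observed count O is
  tested for excess with the Poisson-variance z-test
  z = (O − E)/√E (one-sided upper tail), accompanied by Garwood's exact
  Poisson confidence interval for O
  (low = ½χ²(α/2, 2O), high = ½χ²(1−α/2, 2O+2)).
  A permutation oracle (`permutation_null()`) verifies the analytic
  null empirically. Supporting steps: whole-library RPM normalization,
  TMM scaling factors, log₂ median centering, symbiont read-share
  partitioning for dual-organism (host + fungus) count matrices.
* **Colonization morphometry.** Per-section hyphal counts and diameters
  become a biovolume index (mean hyphal cross-sectional area
  `mean(π(d/2)²)` × hyphal count, μm²·hyphae), averaged per genotype,
  compared across generations by Kruskal–Wallis rank tests and percent
  declines; vascular-bundle colonization frequency is compared by a
  Pearson chi-square on the pooled vascular/non-vascular table.
* **Transmission and growth.** Per-generation seed-transmission rates
  with Clopper–Pearson exact intervals, and tillering growth curves
  with first-daughter-tiller times.

Every input stream has a synthetic generator
(`simulate_counts()`, `simulate_sections()`,
`simulate_maintenance_program()`, `simulate_tillering()`) with ground
truth returned separately, so the whole pipeline is testable without
any external data.

## Worked example

```r
library(symbiotrend)

## dual-organism count matrix: 13,440 host + 300 symbiont genes,
## 3 generations x 3 replicates, 1% of host genes planted with a
## geometric decline (factor 0.2 per generation step)
sim <- simulate_counts(frac_monotone_down = 0.01, decline_factor = 0.2,
                       dispersion = 0.05, seed = 7)
trend_test(sim$cm)
#> 	Monotone-separation trend test (host genes, direction = both)
#>
#> design: groups of size (3, 3, 3), null p = 0.00119 (both directions)
#> genes tested: 13440
#> observed monotone: 147 (down 143, up 4; ties defeated 0)
#> expected by chance: 16,  excess: 131
#> z = 32.75,  one-sided p-value < 2.2e-16
#> 95% exact CI for the observed count: [124.2, 172.8]

symbiont_share(sim$cm)
#> symbiont read share by generation:
#>    G2    G6    G9
#> 0.003 0.003 0.003
```

The observed 147 monotone genes (134 planted plus chance calls) far
exceed the 16 expected by chance out of 13,440 tested (z = 32.75); the
symbiont contributes a stable ≈0.3% of reads in every generation.

```r
## colonization: 9/10/8 genotypes, 3 sections each, declining counts
## and diameters (defaults emulate generation biovolume ratio 100:67:19)
secs <- simulate_sections(seed = 1)
gs <- genotype_summary(summarize_sections(secs))
means <- tapply(gs$mean_biovolume_index, gs$generation, mean)
percent_change(means[c("G2", "G6", "G9")])
#>     pair percent_decline
#> 1 G2->G6        33.21987
#> 2 G2->G9        81.94993
kruskal_wallis(split(gs$mean_biovolume_index, gs$generation))
#> Kruskal-Wallis H = 23.07, df = 2, p = 9.775e-06
```

The biovolume index declines by 33% (G2→G6) and 82% (G2→G9), and the
generations differ strongly by the rank test — the signature of an
endophyte whose biomass concentration is being selected downward while
seed transmission stays high:

```r
prog <- simulate_maintenance_program(seed = 1)   # 9 generations,
round(transmission_estimate(prog)$rate, 3)       # selection off at G3, G5
#> [1] 0.725 0.795 0.775 0.845 0.880 0.890 0.895 0.950 0.940
```

A thin command-line front end over the same functions is installed at
`inst/scripts/symbiotrend` (subcommands `simulate`, `trend`,
`colonize`, `transmit`).

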