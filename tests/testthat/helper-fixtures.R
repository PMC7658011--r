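# Small fixtures built in code.

toy_design <- function(gens = c("G2", "G6", "G9"), reps = 3) {
  data.frame(
    sample_id = paste0(rep(gens, each = reps), "_r", seq_len(reps)),
    generation = factor(rep(gens, each = reps), levels = gens),
    replicate = rep(seq_len(reps), length(gens)),
    stringsAsFactors = FALSE)
}

# gene x sample count matrix with named generation means per gene
toy_cm <- function(gene_means, gens = c("G2", "G6", "G9"), reps = 3,
                   organism = NULL) {
  design <- toy_design(gens, reps)
  counts <- t(vapply(gene_means, function(m)
    rep(m, each = reps), numeric(length(gens) * reps)))
  dimnames(counts) <- list(names(gene_means), design$sample_id)
  count_matrix(counts, design, organism)
}

# one section-measurement row in the read_sections() layout
section_row <- function(genotype = "g1", generation = "G2",
                        section = 1L, count = 10L, diameters = c(2, 2),
                        vascular = 0L) {
  out <- data.frame(genotype_id = genotype, generation = generation,
                    tiller_id = paste0(genotype, "_t1"),
                    section_index = as.integer(section),
                    hyphal_count = as.integer(count),
                    vascular_hyphae = as.integer(vascular),
                    stringsAsFactors = FALSE)
  out$diameters_um <- list(diameters)
  class(out) <- c("section_measurements", "data.frame")
  out
}

bind_sections <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("section_measurements", "data.frame")
  out
}
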