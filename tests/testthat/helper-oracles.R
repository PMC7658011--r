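# Brute-force enumeration oracle: probability that k ordered groups of
# the given sizes fully separate (either direction) when distinct ranks
# are assigned at random. Independent of the package's analytic formula.
enumerate_separation_p <- function(sizes) {
  N <- sum(sizes)
  # enumerate assignments of ranks to groups as ordered set partitions
  assignments <- function(avail, sizes) {
    if (!length(sizes)) return(list(list()))
    first <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (g1 in first)
      for (rest in assignments(setdiff(avail, g1), sizes[-1]))
        out[[length(out) + 1]] <- c(list(g1), rest)
    out
  }
  sep <- 0
  all_assign <- assignments(seq_len(N), sizes)
  for (a in all_assign) {
    down <- all(vapply(seq_len(length(a) - 1), function(j)
      max(a[[j + 1]]) < min(a[[j]]), TRUE))
    up <- all(vapply(seq_len(length(a) - 1), function(j)
      min(a[[j + 1]]) > max(a[[j]]), TRUE))
    sep <- sep + (down || up)
  }
  c(p = sep / length(all_assign), n_sep = sep,
    n_total = length(all_assign))
}
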