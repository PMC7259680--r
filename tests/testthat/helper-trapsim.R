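# Shared fixtures: tiny deterministic genomes and hand-placed individuals.

default_layout <- genome_layout()

# a 2 x 1 Mb toy genome for fast unit tests
toy_layout <- genome_layout(chromosome_mb = c(1, 1), recombination_cm_mb = 4)

# an individual from explicit global positions (sorted automatically)
make_individual <- function(h1 = integer(0), h2 = integer(0)) {
  list(h1 = sort(as.integer(h1)), h2 = sort(as.integer(h2)))
}

# population object wrapper around hand-built individuals
make_population <- function(individuals, config) {
  st <- trapsim:::cpp_population_stats(individuals, trapsim:::engine_cfg(config))
  structure(
    list(individuals = individuals, fitness = st$fitness,
         cluster_insertions = st$cluster_insertions, generation = 0L),
    class = "population"
  )
}

# all insertion positions present in a population, with multiplicity
all_positions <- function(population) {
  unlist(lapply(population$individuals, function(i) c(i$h1, i$h2)),
         use.names = FALSE)
}

# brute-force two-sided Wilcoxon rank-sum p-value by complete enumeration of
# all assignments of the pooled ranks to group 1 (valid without ties)
enumerate_wilcoxon_p <- function(g1, g2) {
  n1 <- length(g1)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
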