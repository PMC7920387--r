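# Independent oracles used across test files.

# KS connectivity score recomputed from the empirical-CDF definition of the
# two one-sided KS statistics between the position set and the uniform grid
# 1..n, instead of the max-over-p formula used by the implementation.
ks_oracle <- function(positions, n) {
  m <- length(positions)
  if (m == 0) return(0)
  ecdf_at <- function(v) sum(positions <= v) / m
  grid <- seq_len(n)
  a <- max(vapply(grid, function(v) ecdf_at(v) - v / n, numeric(1)))
  b <- max(vapply(grid, function(v) v / n - ecdf_at(v - 1), numeric(1)))
  if (abs(a - b) <= 1e-12) 0 else if (a > b) a else -b
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# query subsets of a small universe (pathway = first `pathway_size` labels).
hyper_oracle <- function(overlap, query_size, pathway_size, universe_size) {
  stopifnot(universe_size <= 12)
  subsets <- utils::combn(universe_size, query_size)
  mean(apply(subsets, 2, function(s) sum(s <= pathway_size) >= overlap))
}

# Random strictly-increasing position vector for property tests.
random_positions <- function(m, n) sort(sample.int(n, m))

make_ks_input <- function(positions, n) {
  structure(list(m = length(positions), positions = positions, n = n),
            class = "KSInput")
}

make_signature <- function(id, up, down) {
  structure(list(pathway_id = id, up_genes = up, down_genes = down),
            class = "PathwaySignature")
}

make_result <- function(drug, ts, k = 1) {
  structure(list(drug_name = drug, k = k, ts = ts, records = NULL),
            class = "TherapeuticResult")
}
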