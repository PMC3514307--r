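# Shared fixtures built in code.

GT <- c("AA", "Aa", "aa")

snp_a_counts <- function() {
  matrix(c(95, 1, 0,
           1, 90, 0,
           0, 3, 23), 3, 3, byrow = TRUE, dimnames = list(GT, GT))
}

snp_b_counts <- function() {
  matrix(c(96, 15, 0,
           2, 87, 1,
           0, 14, 32), 3, 3, byrow = TRUE, dimnames = list(GT, GT))
}

# Expand a 3x3 count matrix (rows observed, cols gold) into paired calls;
# as.vector(counts) runs column-major, i.e. observed AA..aa within each
# gold genotype.
expand_pairs <- function(counts, locus_id = "L1") {
  gold <- rep(rep(GT, each = 3), as.vector(counts))
  obs <- rep(rep(GT, times = 3), as.vector(counts))
  n <- sum(counts)
  data.frame(subject_id = sprintf("v%04d", seq_len(n)),
             locus_id = locus_id, gold_call = gold, observed_call = obs,
             stringsAsFactors = FALSE)
}

# Small case-control dataset from genotype count vectors (AA, Aa, aa).
counts_dataset <- function(cases, controls, locus = "L1") {
  make_fixture_dataset(list(cases = cases, controls = controls),
                       locus = locus)
}
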