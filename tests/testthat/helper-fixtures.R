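# Shared fixtures, built in code at test time.

toy_counts <- function() {
  m <- matrix(c(2, 3,
                0, 5,
                7, 1), nrow = 3, byrow = TRUE)
  rownames(m) <- c("otu_a", "otu_b", "otu_c")
  colnames(m) <- c("s1", "s2")
  m
}

toy_table <- function() otu_table(toy_counts())

write_toy_tsv <- function(path = tempfile(fileext = ".tsv")) {
  write_otu_table(toy_table(), path)
  path
}

# small power-law community as an abundance vector
small_community <- function(alpha = 0.7, n = 500, seed = 42) {
  abundance_vector(sad_sample(power_law(alpha), n, seed = seed))
}

# independent oracle: brute-force zeta sums to M with the Euler-Maclaurin
# tail remainder M^(1-s)/(s-1) + M^(-s)/2
brute_zeta <- function(s, M = 1e6) {
  x <- seq_len(M)
  sum(x^(-s)) + M^(1 - s) / (s - 1) + M^(-s) / 2
}
brute_reads_per_species <- function(alpha) brute_zeta(alpha) / brute_zeta(1 + alpha)
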