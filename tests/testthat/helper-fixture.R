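# Shared small simulation reused across test files (built once per run).
.radicl_test_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.radicl_test_env$sim)) {
    cfg <- sim_config(seed = 42, n_contacts = 2000, dup_rate = 0.1,
                      rrna_rate = 0.05, seq_error_rate = 0)
    .radicl_test_env$sim <- simulate_library(cfg)
  }
  .radicl_test_env$sim
}

small_anatomy <- function() {
  read_anatomy(small_sim()$fixture$config$barcodes)
}

# extraction records of the shared sim, cached
small_records <- function() {
  if (is.null(.radicl_test_env$records)) {
    sim <- small_sim()
    .radicl_test_env$records <- extract_tags(sim$reads, small_anatomy())
  }
  .radicl_test_env$records
}

# brute-force occurrence count of a tag (both strands) in a genome given
# as a character vector of chromosome sequences
brute_force_hits <- function(tag, chrom_seqs) {
  count_in <- function(pat, subj) {
    hits <- gregexpr(pat, subj, fixed = TRUE)[[1]]
    sum(hits > 0)
  }
  total <- 0L
  for (s in chrom_seqs) {
    total <- total + count_in(tag, s) +
      count_in(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(tag))), s)
  }
  total
}

# brute-force upper-tail binomial probability by exact pmf summation
# (log-space terms, independent of stats::pbinom)
binom_tail_oracle <- function(k, N, P) {
  if (k <= 0) return(1)
  i <- k:N
  sum(exp(lchoose(N, i) + i * log(P) + (N - i) * log1p(-P)))
}

# definitional BH step-up: sort ascending, q(i) = min_{j >= i} p(j) * m / j
# capped at 1, returned in input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, (m / i) * ps[i])
    q[i] <- min(running, 1)
  }
  q[order(o)]
}

# minimal annotated-pairs constructor for significance/profile tests
fake_pairs <- function(rna_gene, dna_bin, rna_bin = dna_bin, ...) {
  df <- data.frame(rna_gene = rna_gene, dna_bin = dna_bin,
                   rna_bin = rna_bin, stringsAsFactors = FALSE, ...)
  class(df) <- c("contact_pairs", "data.frame")
  df
}
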