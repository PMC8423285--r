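# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings, where the package relies on it)
# so that implementation and check stay independent.

# Reverse complement by explicit character lookup.
revcomp_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Codon counts by explicit substring walking.
codon_counts_oracle <- function(seqs) {
  counts <- integer(0)
  for (s in seqs) {
    starts <- seq(1, nchar(s) - 2, by = 3)
    for (cd in substring(s, starts, starts + 2)) {
      counts[cd] <- (if (is.na(counts[cd])) 0L else counts[cd]) + 1L
    }
  }
  counts
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# assignments of the pooled sample to the first group (tie-free data only).
# U = number of (a, b) pairs with a > b; the null distribution of U is
# symmetric about n_a * n_b / 2.
mwu_exact_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n_a <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  n_tot <- length(us)
  lo <- min(u_obs, n_a * length(b) - u_obs)
  hi <- max(u_obs, n_a * length(b) - u_obs)
  min(1, (sum(us <= lo) + sum(us >= hi)) / n_tot)
}

# Paired t-test, closed form.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# Random ACGT string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a GFF3 file from raw body lines.
local_gff <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".gff3", .local_envir = env)
  writeLines(c("##gff-version 3", lines), path)
  path
}

local_fasta <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  writeLines(lines, path)
  path
}
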