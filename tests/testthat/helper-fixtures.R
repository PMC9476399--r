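# Small in-code fixtures shared across tests.

# Beads counts chosen so the observed proportions are exact round numbers:
# lib sizes 1000 each, peptide "a" proportions (0.1, 0.2, 0.3).
toy_beads_matrix <- function() {
  counts <- rbind(a = c(100, 200, 300),
                  b = c(900, 800, 700))
  colnames(counts) <- paste0("beads_", 1:3)
  phip_counts(counts, roles = rep("beads", 3))
}

# A plate with known proportions and one serum column.
toy_plate <- function(serum_counts = c(150, 850)) {
  counts <- cbind(rbind(a = c(100, 200, 300), b = c(900, 800, 700)),
                  serum_counts)
  colnames(counts) <- c(paste0("beads_", 1:3), "serum_1")
  phip_counts(counts, roles = c(rep("beads", 3), "serum"))
}

# Hand-built BeadsPrior for direct sampler tests.
manual_prior <- function(peptide_ids, mu0, sigma2_0) {
  sh <- beta_shapes_from_moments(mu0, sigma2_0)
  g <- apply_guard(sh$a, sh$b)
  structure(list(peptide_id = peptide_ids, mu0 = mu0, sigma2_0 = sigma2_0,
                 a0 = g$a, b0 = g$b, method = "true",
                 fallback = rep(FALSE, length(mu0))),
            class = "BeadsPrior")
}

# Build a PeptideCountMatrix with explicitly chosen library sizes by adding
# one filler peptide that absorbs the remaining reads per sample.
matrix_with_lib_sizes <- function(counts, roles, lib_sizes) {
  filler <- lib_sizes - colSums(counts)
  stopifnot(all(filler >= 0))
  phip_counts(rbind(counts, zzz_filler = filler), roles = roles)
}

# Conditional binomial doubletail oracle for the exact test at dispersion
# zero with equal library sizes: given the peptide's total count across all
# samples, the serum count is Binomial(total, n_serum / n_total) under the
# null, and the two-sided p-value sums the probabilities of all outcomes no
# more likely than the observed one (exactly tied outcomes are accumulated
# in ascending-probability order, stable in the outcome index).
binom_doubletail_oracle <- function(beads_counts, serum_count, n_beads_samples) {
  yb <- sum(beads_counts)
  tot <- yb + serum_count
  pr <- dbinom(0:tot, tot, n_beads_samples / (n_beads_samples + 1))
  o <- order(pr)
  cumsum(pr[o])[order(o)][yb + 1]
}
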