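# Synthetic-data generation: a fully synthetic beads-only prior emulating
# the statistical structure of real PhIP-Seq plates, and a plate simulator
# following the hierarchical generative model.

default_fc_bins <- function() {
  cbind(lower = c(1, 2, 4, 8, 16), upper = c(2, 4, 8, 16, 32))
}

bin_label <- function(bins) sprintf("(%g,%g]", bins[, 1], bins[, 2])

#' Generate a synthetic beads-only prior
#'
#' Emulates the two dominant features of mock IP read counts on real
#' PhIP-Seq plates: a strongly peptide-dependent background, with mean
#' read-pull proportions spanning orders of magnitude (a heavy-tailed
#' log-normal across peptides, normalized to sum to one), and
#' larger-than-binomial between-sample variability. Each peptide's
#' between-sample variance is \eqn{\sigma^2_{i0} = \tau_i \mu_{i0}^2} with a
#' Gamma-distributed squared coefficient of variation \eqn{\tau_i} plus an
#' abundance-dependent floor \code{1 / (mu * floor_reads)}, which both
#' mirrors the elevated relative variability of rarely-pulled peptides and
#' keeps every peptide overdispersed relative to binomial sampling at
#' million-read library sizes. Shapes follow by moment matching and the
#' \code{a >= 1} guard.
#'
#' @param P Number of peptides (>= 2).
#' @param seed Integer RNG seed; identical seeds give identical priors.
#' @param mu_sdlog Log-scale standard deviation of the peptide background
#'   spread (default 1.5, i.e. about 4 orders of magnitude between the 1st
#'   and 99th percentile).
#' @param disp_shape,disp_rate Gamma shape and rate of the peptide-specific
#'   squared coefficient of variation (default mean 0.05, i.e. a typical
#'   between-mock-IP coefficient of variation around 22%).
#' @param floor_reads Scale of the abundance-dependent dispersion floor in
#'   reads (default \code{5e5}).
#' @return A \code{BeadsPrior} with \code{method = "true"}.
#' @export
generate_beads_prior <- function(P, seed = NULL, mu_sdlog = 1.5,
                                 disp_shape = 4, disp_rate = 80,
                                 floor_reads = 5e5) {
  if (P < 2) argument_error("P must be at least 2")
  if (mu_sdlog <= 0 || disp_shape <= 0 || disp_rate <= 0 || floor_reads <= 0)
    argument_error("spread parameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::rlnorm(P, meanlog = 0, sdlog = mu_sdlog)
  mu <- mu / sum(mu)
  tau <- stats::rgamma(P, disp_shape, rate = disp_rate) + 1 / (mu * floor_reads)
  s2 <- tau * mu^2
  # the Beta variance bound sigma2 < mu(1-mu) only binds for extreme spreads
  cap <- 0.9 * mu * (1 - mu)
  s2 <- pmin(s2, cap)
  sh <- beta_shapes_from_moments(mu, s2)
  g <- apply_guard(sh$a, sh$b)
  structure(list(peptide_id = sprintf("pep_%05d", seq_len(P)), mu0 = mu,
                 sigma2_0 = s2, a0 = g$a, b0 = g$b, method = "true",
                 fallback = rep(FALSE, P)),
            class = "BeadsPrior")
}

#' Sample plan for a simulated plate
#'
#' The default matches a realistic plate layout: 8 beads-only samples and
#' 12 serum columns, of which one is a beads-only sample run as an actual
#' sample (a built-in null) and two form a technical-replicate pair (same
#' enrichment parameters, fresh count noise).
#'
#' @param n_beads Number of beads-only columns (>= 2).
#' @param n_serum Number of serum columns.
#' @param n_null How many serum columns are beads-run-as-sample nulls
#'   (attenuation 1, no enriched peptides).
#' @param n_replicate_pairs How many technical-replicate pairs among the
#'   remaining serum columns.
#' @param n_enriched Enriched peptides per (non-null) serum column,
#'   divided equally over the fold-change bins.
#' @param fc_bins Two-column matrix of fold-change bin bounds (open-closed
#'   intervals); defaults to (1,2], (2,4], (4,8], (8,16], (16,32].
#' @param lib_size_range Library sizes are drawn uniformly from this range
#'   (default 1e6 to 2e6 reads).
#' @return A \code{sim_design} list.
#' @export
sim_design <- function(n_beads = 8, n_serum = 12, n_null = 1,
                       n_replicate_pairs = 1, n_enriched = 50,
                       fc_bins = default_fc_bins(),
                       lib_size_range = c(1e6, 2e6)) {
  if (n_beads < 2) argument_error("need at least 2 beads-only samples")
  if (n_null + 2 * n_replicate_pairs > n_serum)
    argument_error("null and replicate columns exceed the serum column count")
  if (n_enriched %% nrow(fc_bins) != 0)
    argument_error("n_enriched must be divisible by the number of fold-change bins")
  structure(list(n_beads = n_beads, n_serum = n_serum, n_null = n_null,
                 n_replicate_pairs = n_replicate_pairs,
                 n_enriched = n_enriched, fc_bins = fc_bins,
                 lib_size_range = lib_size_range),
            class = "sim_design")
}

#' Simulate a PhIP-Seq plate from a beads-only prior
#'
#' Draws one plate from the hierarchical generative model. Per serum column
#' \code{j}: an attenuation constant \code{c_j ~ Beta(a_c, b_c)} (1 for
#' beads-only and null columns), a uniform random set of enriched peptides
#' with fold changes drawn uniformly within each bin, then per peptide a
#' pull probability \code{theta_ij ~ Beta} with mean
#' \code{c_j * phi_ij * mu_i0} and the beads-only variance, and finally
#' counts \code{Y_ij ~ Binomial(n_j, theta_ij)}. Technical replicates reuse
#' the same \code{(Z, phi, c)} parameters with fresh \code{theta} and count
#' noise.
#'
#' @param prior A \code{BeadsPrior} (typically from
#'   \code{\link{generate_beads_prior}}, or estimated from a real plate).
#' @param design A \code{\link{sim_design}}.
#' @param config A \code{\link{beer_config}} supplying the attenuation
#'   prior \code{(a_c, b_c)} used to draw serum attenuation constants.
#' @param seed Integer RNG seed.
#' @return List with \code{matrix} (a \code{\link{phip_counts}} object;
#'   beads columns \code{beads_1...}, serum columns \code{serum_1...}) and
#'   \code{truth} (a \code{SimTruth}: binary matrix \code{Z}, fold-change
#'   matrix \code{phi} (1 where not enriched), bin-label matrix \code{bin},
#'   per-column \code{c_true}, \code{is_null}, and \code{replicate_of}).
#' @export
simulate_dataset <- function(prior, design = sim_design(),
                             config = beer_config(), seed = NULL) {
  stopifnot(inherits(prior, "BeadsPrior"), inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  P <- length(prior$peptide_id)
  if (design$n_enriched > P)
    argument_error("more enriched peptides requested than peptides available")
  mu0 <- prior$mu0
  s2 <- prior$sigma2_0
  nb <- design$n_beads
  ns <- design$n_serum
  bins <- design$fc_bins
  per_bin <- design$n_enriched / nrow(bins)

  sample_ids <- c(sprintf("beads_%d", seq_len(nb)),
                  sprintf("serum_%d", seq_len(ns)))
  roles <- c(rep("beads", nb), rep("serum", ns))
  lib <- round(stats::runif(nb + ns, design$lib_size_range[1],
                            design$lib_size_range[2]))

  # serum column parameter sets: nulls first, then replicate pairs sharing
  # one set, then independent columns
  is_null <- c(rep(TRUE, design$n_null), rep(FALSE, ns - design$n_null))
  replicate_of <- rep(NA_character_, ns)
  param_of <- seq_len(ns)
  if (design$n_replicate_pairs > 0) {
    free <- which(!is_null)
    for (r in seq_len(design$n_replicate_pairs)) {
      a <- free[2 * r - 1]; b <- free[2 * r]
      param_of[b] <- a
      replicate_of[b] <- sprintf("serum_%d", a)
    }
  }

  Z <- matrix(0L, P, ns, dimnames = list(prior$peptide_id,
                                         sprintf("serum_%d", seq_len(ns))))
  phi <- matrix(1, P, ns, dimnames = dimnames(Z))
  bin <- matrix(NA_character_, P, ns, dimnames = dimnames(Z))
  c_true <- rep(1, ns)

  for (j in seq_len(ns)) {
    if (is_null[j]) next
    if (param_of[j] != j) {        # technical replicate: copy parameters
      Z[, j] <- Z[, param_of[j]]
      phi[, j] <- phi[, param_of[j]]
      bin[, j] <- bin[, param_of[j]]
      c_true[j] <- c_true[param_of[j]]
      next
    }
    c_true[j] <- stats::rbeta(1, config$a_c, config$b_c)
    sel <- sample.int(P, design$n_enriched)
    Z[sel, j] <- 1L
    labs <- bin_label(bins)
    for (bb in seq_len(nrow(bins))) {
      idx <- sel[((bb - 1) * per_bin + 1):(bb * per_bin)]
      phi[idx, j] <- stats::runif(per_bin, bins[bb, 1], bins[bb, 2])
      bin[idx, j] <- labs[bb]
    }
  }

  counts <- matrix(0, P, nb + ns, dimnames = list(prior$peptide_id, sample_ids))
  for (k in seq_len(nb + ns)) {
    if (k <= nb) {
      mean_k <- mu0
    } else {
      j <- k - nb
      mean_k <- c_true[j] * phi[, j] * mu0
    }
    if (any(mean_k >= 1)) {
      warning("model mean clipped below 1 for ", sum(mean_k >= 1), " peptide(s)")
      mean_k <- pmin(mean_k, 1 - 1e-6)
    }
    sh <- model_shapes(mean_k, s2)
    theta <- stats::rbeta(P, sh$a, sh$b)
    counts[, k] <- stats::rbinom(P, lib[k], theta)
  }

  truth <- structure(list(Z = Z, phi = phi, bin = bin, c_true = c_true,
                          is_null = is_null, replicate_of = replicate_of,
                          serum_ids = sprintf("serum_%d", seq_len(ns))),
                     class = "SimTruth")
  list(matrix = phip_counts(counts, roles), truth = truth)
}
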