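#' Bayesian enrichment analysis of serum samples against beads-only controls
#'
#' The full pipeline for each requested sample: estimate the beads-only
#' prior, remove super-enriched peptides (initial fold change above the
#' configured threshold), re-estimate the prior on the filtered counts with
#' recomputed library sizes, run the Gibbs sampler, and assemble per-peptide
#' posterior summaries with the excluded peptides re-inserted at posterior
#' probability 1.
#'
#' @param m A \code{\link{phip_counts}} object with at least 2 beads-only
#'   samples.
#' @param serum Sample ids to analyse; defaults to every serum sample.
#' @param prior_method Beads-prior estimation route passed to
#'   \code{\link{estimate_beads_prior}} (default the empirical-Bayes
#'   dispersion-derived \code{"edger"} route).
#' @param config A \code{\link{beer_config}}.
#' @param prior Optional \code{BeadsPrior} to use instead of estimating one
#'   (e.g. the true simulation parameters); it is then used as-is for both
#'   the pre-filter and the chain.
#' @param seed Optional integer seed set once before the first chain; with
#'   the same seed, config, and input the result is reproducible.
#' @return A data frame with one row per peptide and analysed sample:
#'   \code{peptide_id}, \code{sample_id}, \code{post_prob},
#'   \code{phi_hat}, \code{excluded_flag}. Per-sample attenuation and
#'   enrichment-proportion posterior means are attached as the
#'   \code{"run_info"} attribute.
#' @examples
#' \donttest{
#' prior <- generate_beads_prior(200, seed = 7)
#' sim <- simulate_dataset(prior, design = sim_design(n_beads = 4,
#'   n_serum = 1, n_null = 0, n_replicate_pairs = 0), seed = 7)
#' cfg <- beer_config(n_iter = 500, n_burn = 100)
#' res <- run_beer(sim$matrix, config = cfg, seed = 1)
#' table(called = call_enriched(res), true = as.logical(sim$truth$Z[, 1]))
#' }
#' @export
run_beer <- function(m, serum = serum_ids(m),
                     prior_method = c("edger", "mom", "mle"),
                     config = beer_config(), prior = NULL, seed = NULL) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  prior_method <- match.arg(prior_method)
  if (!is.null(seed)) set.seed(seed) else if (!is.null(config$seed))
    set.seed(config$seed)

  full_prior <- if (is.null(prior)) estimate_beads_prior(m, prior_method)
                else prior
  rows <- vector("list", length(serum))
  info <- vector("list", length(serum))
  for (k in seq_along(serum)) {
    s <- serum[k]
    pf <- prefilter_super_enriched(m, full_prior, s,
                                   threshold = config$prefilter_threshold)
    sub_prior <- if (is.null(prior)) {
      if (nrow(pf$excluded)) estimate_beads_prior(pf$matrix, prior_method)
      else full_prior
    } else align_prior(prior, pf$matrix)
    fit <- run_mcmc(pf$matrix, sub_prior, config, s, excluded = pf$excluded)
    rows[[k]] <- fit$summary
    info[[k]] <- data.frame(sample_id = s, c_hat = fit$c_hat,
                            pi_hat = fit$pi_hat,
                            n_excluded = nrow(pf$excluded))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "run_info") <- do.call(rbind, info)
  out
}

#' Round-robin false-positive assessment on beads-only samples
#'
#' Each beads-only sample is held out in turn and analysed as if it were a
#' serum sample against the remaining mock IPs. Since mock IPs contain no
#' antibody input, every enrichment call is a false positive; well-behaved
#' methods should produce none (or almost none).
#'
#' @param m A \code{\link{phip_counts}} object with at least 3 beads-only
#'   samples.
#' @param method \code{"beer"} (posterior probability > \code{cutoff}) or
#'   \code{"nb"} (negative-binomial exact test, one-sided BH at
#'   \code{alpha}).
#' @param config A \code{\link{beer_config}} (used for \code{"beer"}).
#' @param cutoff Posterior-probability cutoff for \code{"beer"} calls.
#' @param alpha FDR level for \code{"nb"} calls.
#' @param prior_method Beads-prior route for \code{"beer"}.
#' @param seed Optional seed (BEER chains only).
#' @return Named integer vector: false-positive calls per held-out beads
#'   sample.
#' @export
round_robin_fp <- function(m, method = c("beer", "nb"),
                           config = beer_config(), cutoff = 0.5,
                           alpha = 0.05,
                           prior_method = c("edger", "mom", "mle"),
                           seed = NULL) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  method <- match.arg(method)
  prior_method <- match.arg(prior_method)
  jb <- beads_ids(m)
  if (length(jb) < 3)
    data_error("round-robin requires at least 3 beads-only samples")
  if (!is.null(seed)) set.seed(seed)
  fp <- stats::setNames(integer(length(jb)), jb)
  for (b in jb) {
    held <- leave_one_beads_out(m, b)
    if (method == "beer") {
      res <- run_beer(held, serum = b, prior_method = prior_method,
                      config = config)
      fp[b] <- sum(call_enriched(res, cutoff))
    } else {
      mb <- phip_counts(held$counts[, setdiff(jb, b), drop = FALSE],
                        roles = rep("beads", length(jb) - 1L))
      disp <- estimate_dispersions(mb, groups = rep("beads", length(jb) - 1L))
      res <- nb_exact_test(held, disp, serum = b, alpha = alpha)
      fp[b] <- sum(res$called)
    }
  }
  fp
}
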