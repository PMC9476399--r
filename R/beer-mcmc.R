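# Gibbs sampler for the Beta-Binomial spike-and-slab enrichment model.
#
# Model for one serum sample j with library size n and peptide counts Y_i:
#   Y_i | theta_i           ~ Binomial(n, theta_i)
#   theta_i | c, phi_i      ~ Beta(f_a(c phi_i mu_i0, s2_i0),
#                                  f_b(c phi_i mu_i0, s2_i0))
#   c                       ~ Beta(a_c, b_c)
#   phi_i | Z_i             ~ (1 - Z_i) * 1 + Z_i * (phi_min + Gamma(a_phi, b_phi))
#   Z_i | pi                ~ Bernoulli(pi)
#   pi                      ~ Beta(a_pi, b_pi)
# with (mu_i0, s2_i0) the moments of the guarded beads-only prior
# Beta(a_i0, b_i0).
#
# Update scheme (all peptides vectorized; peptides are conditionally
# independent given c and pi):
#   1. (Z_i, phi_i): Metropolis-Hastings flip with theta integrated out via
#      the Beta-Binomial marginal; the fold change of a proposed enrichment
#      is drawn from its prior slab, so the slab density cancels in the
#      acceptance ratio. Currently-enriched peptides additionally get a
#      multiplicative random-walk refinement of phi.
#   2. theta_i: conjugate draw from Beta(a_i + Y_i, b_i + n - Y_i).
#   3. c: slice sampling (stepping out + shrinkage) on its full
#      conditional within (0, 1).
#   4. pi: conjugate draw from Beta(a_pi + sum(Z), b_pi + P - sum(Z)).
# Because (Z, phi) is drawn from the theta-marginalized conditional and
# theta is refreshed immediately afterwards, the joint stationary
# distribution is preserved (partially collapsed Gibbs).

# Beta shapes at an elevated mean with the beads-only variance retained.
# Means are clipped into the open unit interval; where the variance is
# infeasible at the elevated mean (only possible for means near 1) the
# mean-preserving a = 1 guard is substituted.
model_shapes <- function(mean, s2) {
  mu <- clip(mean, 1e-12, 1 - 1e-6)
  a <- mu^2 * (1 - mu) / s2 - mu
  bad <- !(a > 0) | !is.finite(a)
  if (any(bad)) a[bad] <- 1
  list(a = a, b = a * (1 / mu - 1))
}

# log Beta-Binomial marginal of Y | n, shapes (binomial coefficient omitted
# -- it cancels in every ratio we form).
log_bb <- function(a, b, Y, n) lbeta(a + Y, b + n - Y) - lbeta(a, b)

# Univariate slice sampler with stepping out and shrinkage (Neal 2003),
# constrained to (lower, upper).
slice_sample <- function(x0, logf, w = 0.02, max_steps = 50,
                         lower = 0, upper = 1) {
  y <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1)
  L <- max(lower + 1e-12, x0 - w * u)
  R <- min(upper - 1e-12, L + w)
  k <- max_steps
  while (k > 0 && L > lower + 1e-12 && logf(L) > y) {
    L <- max(lower + 1e-12, L - w); k <- k - 1
  }
  k <- max_steps
  while (k > 0 && R < upper - 1e-12 && logf(R) > y) {
    R <- min(upper - 1e-12, R + w); k <- k - 1
  }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-14) return(x0)
  }
}

#' Run the Gibbs sampler for one serum sample
#'
#' Samples the spike-and-slab Beta-Binomial hierarchy for one serum (or
#' held-out mock IP) sample against the plug-in beads-only prior, and
#' returns ergodic means over the post-burn-in iterations. The beads-only
#' columns are not resampled: their information enters solely through the
#' guarded plug-in shapes \code{(a0, b0)} (empirical Bayes).
#'
#' Expects the super-enriched pre-filter to have been applied already (see
#' \code{\link{prefilter_super_enriched}}); pass its record through
#' \code{excluded} so the removed peptides are re-inserted into the summary
#' with posterior probability 1. \code{\link{run_beer}} wires these steps
#' together.
#'
#' @param m A \code{\link{phip_counts}} object (post pre-filter).
#' @param prior A \code{BeadsPrior} for the peptides of \code{m}, guarded
#'   (\code{a0 >= 1}).
#' @param config A \code{\link{beer_config}}.
#' @param serum Sample id to analyse.
#' @param excluded Optional data frame (\code{peptide_id},
#'   \code{phi_init}) of pre-filtered peptides.
#' @param fix Named list for diagnostics: any of \code{Z}, \code{phi},
#'   \code{c}, \code{pi} given here is held fixed at the supplied value and
#'   its update is skipped.
#' @param keep_draws Retain the per-iteration draws of \code{c} and
#'   \code{pi} (attribute \code{draws}).
#' @return A \code{PosteriorSummary}: list with \code{summary} (data frame
#'   \code{peptide_id}, \code{sample_id}, \code{post_prob},
#'   \code{phi_hat}, \code{excluded_flag}), scalars \code{c_hat} and
#'   \code{pi_hat}, the \code{excluded} record, and per-peptide
#'   \code{theta_mean}/\code{theta_var} diagnostics. \code{phi_hat} is the
#'   posterior mean fold change conditional on enrichment (1 for peptides
#'   never sampled as enriched); excluded peptides carry
#'   \code{post_prob = 1} and their initial fold-change estimate.
#' @export
run_mcmc <- function(m, prior, config = beer_config(), serum,
                     excluded = NULL, fix = list(), keep_draws = FALSE) {
  stopifnot(inherits(m, "PeptideCountMatrix"), inherits(config, "BeerConfig"))
  prior <- align_prior(prior, m)
  if (any(prior$a0 < 1 - 1e-9))
    argument_error("prior must be guarded (a0 >= 1); see apply_guard()")
  init <- initialize_chain(m, prior, serum)

  Y <- m$counts[, serum]
  n <- m$samples[serum, "lib_size"]
  P <- length(Y)
  mom <- beta_moments(prior$a0, prior$b0)
  mu0 <- mom$mu
  s2 <- mom$sigma2

  theta <- init$theta
  Z <- init$Z
  phi <- init$phi
  cc <- init$c
  pi <- init$pi
  phi_min <- config$phi_min
  rw_sd <- 0.3

  fix_z <- !is.null(fix$Z)
  fix_phi <- !is.null(fix$phi)
  fix_c <- !is.null(fix$c)
  fix_pi <- !is.null(fix$pi)
  if (fix_z) Z <- rep_len(as.integer(fix$Z), P)
  if (fix_phi) phi <- rep_len(as.numeric(fix$phi), P)
  if (fix_c) cc <- fix$c
  if (fix_pi) pi <- fix$pi

  n_tot <- config$n_burn + config$n_iter
  sum_Z <- numeric(P)
  sum_phi <- numeric(P)   # accumulated over iterations with Z = 1
  cnt_Z <- numeric(P)
  sum_theta <- numeric(P)
  sum_theta2 <- numeric(P)
  sum_c <- 0
  sum_pi <- 0
  draws <- if (keep_draws) list(c = numeric(config$n_iter),
                                pi = numeric(config$n_iter)) else NULL

  logpost_c <- function(x) {
    sh <- model_shapes(x * phi * mu0, s2)
    stats::dbeta(x, config$a_c, config$b_c, log = TRUE) +
      sum(stats::dbeta(theta, sh$a, sh$b, log = TRUE))
  }

  for (it in seq_len(n_tot)) {
    if (!fix_z) {
      # --- joint (Z, phi) flip with theta collapsed -----------------------
      sh_cur <- model_shapes(cc * phi * mu0, s2)
      ll_cur <- log_bb(sh_cur$a, sh_cur$b, Y, n)
      is0 <- Z == 0L
      phi_prop <- phi
      phi_prop[is0] <- phi_min + stats::rgamma(sum(is0), config$a_phi,
                                               rate = config$b_phi)
      prop_mean <- cc * mu0
      prop_mean[is0] <- cc * phi_prop[is0] * mu0[is0]
      sh_prop <- model_shapes(prop_mean, s2)
      ll_prop <- log_bb(sh_prop$a, sh_prop$b, Y, n)
      log_odds <- log(pi) - log1p(-pi)
      log_alpha <- ifelse(is0,
                          ll_prop - ll_cur + log_odds,
                          ll_prop - ll_cur - log_odds)
      acc <- log(stats::runif(P)) < log_alpha
      Z[acc] <- 1L - Z[acc]
      phi[acc & is0] <- phi_prop[acc & is0]
      phi[acc & !is0] <- 1
      if (fix_phi) phi <- rep_len(as.numeric(fix$phi), P)

      # --- random-walk refinement of phi for enriched peptides ------------
      if (!fix_phi && any(Z == 1L)) {
        e <- which(Z == 1L)
        delta <- phi[e] - phi_min
        delta_new <- delta * exp(stats::rnorm(length(e), 0, rw_sd))
        sh_old <- model_shapes(cc * phi[e] * mu0[e], s2[e])
        sh_new <- model_shapes(cc * (phi_min + delta_new) * mu0[e], s2[e])
        la <- log_bb(sh_new$a, sh_new$b, Y[e], n) -
          log_bb(sh_old$a, sh_old$b, Y[e], n) +
          stats::dgamma(delta_new, config$a_phi, rate = config$b_phi, log = TRUE) -
          stats::dgamma(delta, config$a_phi, rate = config$b_phi, log = TRUE) +
          log(delta_new) - log(delta)
        acc2 <- log(stats::runif(length(e))) < la
        phi[e[acc2]] <- phi_min + delta_new[acc2]
      }
    }

    # --- conjugate theta update ------------------------------------------
    sh <- model_shapes(cc * phi * mu0, s2)
    theta <- clip(stats::rbeta(P, sh$a + Y, sh$b + n - Y), 1e-12, 1 - 1e-12)

    # --- slice update of the attenuation constant ------------------------
    if (!fix_c) cc <- slice_sample(cc, logpost_c)

    # --- conjugate pi update ---------------------------------------------
    if (!fix_pi) {
      s <- sum(Z)
      pi <- stats::rbeta(1, config$a_pi + s, config$b_pi + P - s)
      pi <- clip(pi, 1e-12, 1 - 1e-12)
    }

    if (it > config$n_burn) {
      sum_Z <- sum_Z + Z
      on <- Z == 1L
      sum_phi[on] <- sum_phi[on] + phi[on]
      cnt_Z <- cnt_Z + Z
      sum_theta <- sum_theta + theta
      sum_theta2 <- sum_theta2 + theta^2
      sum_c <- sum_c + cc
      sum_pi <- sum_pi + pi
      if (keep_draws) {
        draws$c[it - config$n_burn] <- cc
        draws$pi[it - config$n_burn] <- pi
      }
    }
  }

  ni <- config$n_iter
  post_prob <- sum_Z / ni
  phi_hat <- ifelse(cnt_Z > 0, sum_phi / pmax(cnt_Z, 1), 1)
  summary <- data.frame(peptide_id = rownames(m$counts),
                        sample_id = serum,
                        post_prob = post_prob,
                        phi_hat = phi_hat,
                        excluded_flag = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(excluded) && nrow(excluded)) {
    summary <- rbind(summary,
                     data.frame(peptide_id = excluded$peptide_id,
                                sample_id = serum,
                                post_prob = 1,
                                phi_hat = excluded$phi_init,
                                excluded_flag = TRUE,
                                stringsAsFactors = FALSE))
  }
  out <- structure(list(summary = summary,
                        c_hat = sum_c / ni,
                        pi_hat = sum_pi / ni,
                        excluded = excluded,
                        theta_mean = sum_theta / ni,
                        theta_var = sum_theta2 / ni - (sum_theta / ni)^2,
                        config = config),
                   class = "PosteriorSummary")
  if (keep_draws) attr(out, "draws") <- draws
  out
}

#' @export
print.PosteriorSummary <- function(x, ...) {
  cat(sprintf(paste0("PosteriorSummary for %s: %d peptides, %d excluded, ",
                     "%d with post_prob > 0.5\n  c_hat %.3f, pi_hat %.4f\n"),
              x$summary$sample_id[1], nrow(x$summary),
              sum(x$summary$excluded_flag),
              sum(x$summary$post_prob > 0.5), x$c_hat, x$pi_hat))
  invisible(x)
}

#' Call enriched peptides from a posterior summary
#'
#' @param s A \code{PosteriorSummary} or its \code{summary} data frame.
#' @param cutoff Posterior-probability cutoff in (0, 1); the conventional
#'   choice is 0.5. Pre-filtered (super-enriched) peptides carry posterior
#'   probability 1 and are therefore always called.
#' @return Logical vector aligned with the summary rows.
#' @export
call_enriched <- function(s, cutoff = 0.5) {
  if (inherits(s, "PosteriorSummary")) s <- s$summary
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff >= 1)
    argument_error("cutoff must lie in (0, 1)")
  s$post_prob > cutoff | s$excluded_flag
}
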