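#' Beta shape parameters from a mean and variance
#'
#' Moment matching for the Beta distribution: given a mean \eqn{\mu} and
#' variance \eqn{\sigma^2}, returns the shapes
#' \deqn{a = \mu^2(1-\mu)/\sigma^2 - \mu, \qquad b = a(1/\mu - 1).}
#' This parameterization is used both to build beads-only prior
#' distributions from estimated moments and, inside the hierarchical model,
#' to move a peptide's background Beta to an elevated mean under enrichment
#' while retaining its beads-only variance.
#'
#' @param mu Mean in (0, 1). Vectorized.
#' @param sigma2 Variance, with \code{0 < sigma2 < mu * (1 - mu)}.
#' @return A list with numeric components \code{a} and \code{b}.
#' @seealso \code{\link{beta_moments}} for the inverse map.
#' @export
beta_shapes_from_moments <- function(mu, sigma2) {
  if (any(mu <= 0 | mu >= 1)) argument_error("mu must lie strictly in (0, 1)")
  if (any(sigma2 <= 0)) argument_error("sigma2 must be positive")
  if (any(sigma2 >= mu * (1 - mu)))
    phip_error("phip_infeasible_moments_error",
               "sigma2 must be smaller than mu * (1 - mu) for a Beta distribution")
  a <- mu^2 * (1 - mu) / sigma2 - mu
  list(a = a, b = a * (1 / mu - 1))
}

#' Mean and variance of a Beta distribution
#'
#' @param a,b Positive shape parameters. Vectorized.
#' @return A list with components \code{mu} and \code{sigma2}.
#' @export
beta_moments <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) argument_error("shape parameters must be positive")
  s <- a + b
  list(mu = a / s, sigma2 = a * b / (s^2 * (s + 1)))
}

#' Lower-bound guard on the first Beta shape parameter
#'
#' Beta shapes can be read as pseudo-counts of successes (\code{a}) and
#' failures (\code{b}). Values of \code{a} below 1 arise for rarely-pulled
#' peptides and destabilize the posterior sampler, so \code{a} is floored at
#' 1 and \code{b} is recomputed to preserve the mean \eqn{a/(a+b)}:
#' \code{b' = a' * (1/mu - 1)}. Shapes with \code{a >= 1} pass through
#' unchanged.
#'
#' @param a,b Positive shapes. Vectorized.
#' @return A list with guarded components \code{a} (all \code{>= 1}) and
#'   \code{b}.
#' @export
apply_guard <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) argument_error("shape parameters must be positive")
  mu <- a / (a + b)
  low <- a < 1
  a2 <- ifelse(low, 1, a)
  b2 <- ifelse(low, a2 * (1 / mu - 1), b)
  list(a = a2, b = b2)
}

# Assemble a BeadsPrior from per-peptide moments, applying the degenerate
# fallbacks and the a >= 1 guard. mu/sigma2 may contain NA or infeasible
# entries; these get the documented substitutes:
#   * mu <= 0 (all-zero peptide): mu = 1 / (2 * mean beads library size)
#   * sigma2 <= 0 or sigma2 >= mu(1-mu): sigma2 = mu(1-mu)/(nbar + 1),
#     a binomial-scale variance at the mean beads library size nbar.
new_beads_prior <- function(peptide_ids, mu, sigma2, nbar, method) {
  mu <- unname(mu)
  sigma2 <- unname(sigma2)
  zero_mu <- !is.finite(mu) | mu <= 0
  mu[zero_mu] <- 1 / (2 * nbar)
  mu <- pmin(mu, 1 - 1e-12)
  bad_var <- !is.finite(sigma2) | sigma2 <= 0 | sigma2 >= mu * (1 - mu)
  sigma2[bad_var] <- mu[bad_var] * (1 - mu[bad_var]) / (nbar + 1)
  sh <- beta_shapes_from_moments(mu, sigma2)
  g <- apply_guard(sh$a, sh$b)
  structure(list(peptide_id = peptide_ids, mu0 = mu, sigma2_0 = sigma2,
                 a0 = g$a, b0 = g$b, method = method,
                 fallback = zero_mu | bad_var),
            class = "BeadsPrior")
}

#' @export
print.BeadsPrior <- function(x, ...) {
  cat(sprintf("BeadsPrior (%s): %d peptides, a0 in [%.3g, %.3g], %d fallback peptide(s)\n",
              x$method, length(x$peptide_id), min(x$a0), max(x$a0),
              sum(x$fallback)))
  invisible(x)
}

#' @export
as.data.frame.BeadsPrior <- function(x, ...) {
  data.frame(peptide_id = x$peptide_id, mu0 = x$mu0, sigma2_0 = x$sigma2_0,
             a0 = x$a0, b0 = x$b0, stringsAsFactors = FALSE)
}

beads_proportions <- function(m) {
  jb <- beads_ids(m)
  if (length(jb) < 2)
    data_error("at least 2 beads-only samples are required")
  sweep(m$counts[, jb, drop = FALSE], 2, m$samples[jb, "lib_size"], "/")
}

#' Method-of-moments beads-only prior
#'
#' For each peptide, the observed beads-only read proportions
#' \eqn{\hat\theta_{ij} = Y_{ij}/n_j} are summarized by their sample mean
#' and (denominator \eqn{N-1}) variance, and Beta shapes are obtained by
#' moment matching (\code{\link{beta_shapes_from_moments}}) followed by the
#' \code{a >= 1} guard. Peptides with zero or infeasible sample variance, or
#' with no beads reads at all, receive documented fallbacks: the variance is
#' replaced by a binomial-scale variance at the mean beads library size, and
#' an all-zero peptide's mean by half a pseudo-read.
#'
#' @param m A \code{\link{phip_counts}} object with at least 2 beads-only
#'   samples.
#' @return A \code{BeadsPrior}: per-peptide \code{mu0}, \code{sigma2_0},
#'   guarded shapes \code{a0 >= 1}, \code{b0 > 0}.
#' @export
estimate_mom <- function(m) {
  th <- beads_proportions(m)
  nbar <- mean(m$samples[beads_ids(m), "lib_size"])
  mu <- rowMeans(th)
  s2 <- apply(th, 1, stats::var)
  new_beads_prior(rownames(th), mu, s2, nbar, "mom")
}

#' Maximum-likelihood beads-only prior
#'
#' Per peptide, the Beta shapes maximizing the log-likelihood of the
#' observed beads-only proportions, fit with \code{optim(method =
#' "L-BFGS-B")} under box constraints keeping both shapes in
#' \code{[1e-6, 1e6]}. Proportions are clipped to \code{[1e-10, 1 - 1e-10]}
#' since the Beta likelihood is undefined at the boundary. Optimization
#' starts from the method-of-moments estimate; peptides where the optimizer
#' fails (or whose proportions are degenerate) fall back to that start and
#' are flagged in the \code{fallback} field.
#'
#' @inheritParams estimate_mom
#' @return A \code{BeadsPrior} with \code{method = "mle"}.
#' @export
estimate_mle <- function(m) {
  th <- beads_proportions(m)
  start <- estimate_mom(m)
  eps <- 1e-10
  x <- clip(th, eps, 1 - eps)
  P <- nrow(x)
  a <- start$a0
  b <- start$b0
  fell_back <- logical(P)
  nll <- function(par, xi) -sum(stats::dbeta(xi, par[1], par[2], log = TRUE))
  for (i in seq_len(P)) {
    xi <- x[i, ]
    if (stats::var(xi) <= 0) { fell_back[i] <- TRUE; next }
    fit <- tryCatch(
      stats::optim(c(a[i], b[i]), nll, xi = xi, method = "L-BFGS-B",
                   lower = 1e-6, upper = 1e6),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0 || !all(is.finite(fit$par))) {
      fell_back[i] <- TRUE
    } else {
      a[i] <- fit$par[1]; b[i] <- fit$par[2]
    }
  }
  g <- apply_guard(unname(a), unname(b))
  mom <- beta_moments(g$a, g$b)
  structure(list(peptide_id = rownames(x), mu0 = mom$mu, sigma2_0 = mom$sigma2,
                 a0 = g$a, b0 = g$b, method = "mle",
                 fallback = fell_back | start$fallback),
            class = "BeadsPrior")
}

#' Dispersion-derived (empirical-Bayes) beads-only prior
#'
#' The recommended default route. The per-peptide variance of the beads
#' proportions is derived from the empirical-Bayes tagwise dispersion
#' \eqn{\tau_i} (the squared coefficient of variation of
#' \eqn{\hat\theta_{ij}}, shrunk toward a plate-wide common value; see
#' \code{\link{estimate_dispersions}}): \eqn{\sigma^2_{i0} = \tau_i
#' \hat\theta_{i0}^2}. Borrowing strength across peptides in this way
#' stabilizes the variance estimates that method-of-moments and maximum
#' likelihood compute from only a handful of mock IP wells. Shapes follow by
#' moment matching plus the \code{a >= 1} guard.
#'
#' @inheritParams estimate_mom
#' @param disp A \code{DispersionEstimate} from
#'   \code{\link{estimate_dispersions}} run on the beads-only samples,
#'   covering every peptide of \code{m}.
#' @return A \code{BeadsPrior} with \code{method = "edger"}.
#' @export
estimate_dispersion_derived <- function(m, disp) {
  th <- beads_proportions(m)
  nbar <- mean(m$samples[beads_ids(m), "lib_size"])
  tau <- disp$tagwise
  if (is.null(names(tau))) {
    if (length(tau) != nrow(th))
      consistency_error("dispersion estimate does not cover all peptides")
    names(tau) <- rownames(th)
  }
  if (!all(rownames(th) %in% names(tau)))
    consistency_error("dispersion estimate does not cover all peptides")
  tau <- tau[rownames(th)]
  mu <- rowMeans(th)
  s2 <- tau * mu^2
  new_beads_prior(rownames(th), mu, s2, nbar, "edger")
}

#' Estimate a beads-only prior by the chosen route
#'
#' Convenience dispatcher over \code{\link{estimate_mom}},
#' \code{\link{estimate_mle}}, and
#' \code{\link{estimate_dispersion_derived}} (the default, which estimates
#' tagwise dispersions from the beads-only columns internally).
#'
#' @inheritParams estimate_mom
#' @param method One of \code{"edger"} (default), \code{"mom"},
#'   \code{"mle"}.
#' @param prior_df Shrinkage weight (prior degrees of freedom) for the
#'   tagwise dispersion moderation; only used for \code{method = "edger"}.
#' @return A \code{BeadsPrior}.
#' @export
estimate_beads_prior <- function(m, method = c("edger", "mom", "mle"),
                                 prior_df = 10) {
  method <- match.arg(method)
  switch(method,
    mom = estimate_mom(m),
    mle = estimate_mle(m),
    edger = {
      jb <- beads_ids(m)
      mb <- phip_counts(m$counts[, jb, drop = FALSE],
                        roles = rep("beads", length(jb)))
      disp <- estimate_dispersions(mb, groups = rep("beads", length(jb)),
                                   prior_df = prior_df)
      estimate_dispersion_derived(m, disp)
    })
}
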