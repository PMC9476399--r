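# Chain initialization and the super-enriched pre-filter.

# Align a BeadsPrior to the peptides of a count matrix (by peptide id).
align_prior <- function(prior, m) {
  stopifnot(inherits(prior, "BeadsPrior"))
  idx <- match(rownames(m$counts), prior$peptide_id)
  if (anyNA(idx))
    consistency_error("prior does not cover all peptides in the count matrix")
  structure(list(peptide_id = prior$peptide_id[idx], mu0 = prior$mu0[idx],
                 sigma2_0 = prior$sigma2_0[idx], a0 = prior$a0[idx],
                 b0 = prior$b0[idx], method = prior$method,
                 fallback = prior$fallback[idx]),
            class = "BeadsPrior")
}

#' Starting values for the Markov chain
#'
#' Maximum-likelihood-style starting values for one serum sample:
#' \itemize{
#'   \item \code{theta}: the observed proportions \code{Y/n};
#'   \item \code{Z}: 1 when the observed count is at least twice the count
#'     expected from the beads-only background
#'     (\code{Y >= 2 * n * mu0});
#'   \item \code{c}: the slope of the through-origin regression of observed
#'     on expected counts over the non-enriched peptides;
#'   \item \code{pi}: the mean of the initial indicators;
#'   \item \code{phi}: 1 for non-enriched peptides, else
#'     \code{Y / (n * c * mu0)}.
#' }
#' Because \code{c} and \code{pi} live in the open unit interval, a small
#' offset (\code{1e-4} for \code{c}, \code{1/P} for \code{pi}) is applied
#' when the plug-in value falls on the boundary.
#'
#' @param m A \code{\link{phip_counts}} object.
#' @param prior A \code{BeadsPrior} covering all peptides of \code{m}.
#' @param serum Sample id to analyse. A beads-only id is accepted with a
#'   warning (round-robin analyses legitimately run mock IPs as samples).
#' @return A \code{ChainState} list with elements \code{theta}, \code{Z},
#'   \code{phi}, \code{c}, \code{pi}.
#' @export
initialize_chain <- function(m, prior, serum) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  if (!serum %in% m$samples$sample_id)
    argument_error(paste0("unknown sample id: ", serum))
  if (m$samples[serum, "role"] == "beads")
    warning(serum, " is a beads-only sample; analysing it as a serum sample")
  prior <- align_prior(prior, m)
  Y <- unname(m$counts[, serum])
  n <- m$samples[serum, "lib_size"]
  P <- length(Y)
  mu0 <- prior$mu0

  theta <- if (n > 0) Y / n else rep(0.5, P)
  # n = 0 (no reads at all) carries no evidence of enrichment
  Z <- if (n > 0) as.integer(Y >= 2 * n * mu0) else integer(P)

  expct <- n * mu0
  w <- Z == 0
  denom <- sum(expct[w]^2)
  c_init <- if (denom > 0) sum(Y[w] * expct[w]) / denom else 1
  if (!is.finite(c_init) || c_init <= 0) c_init <- 1
  c_init <- min(c_init, 1)
  if (c_init == 1) c_init <- 1 - 1e-4

  pi_init <- mean(Z)
  pi_init <- clip(pi_init, 1 / P, 1 - 1 / P)

  phi <- rep(1, P)
  phi[Z == 1] <- Y[Z == 1] / (n * c_init * mu0[Z == 1])

  structure(list(theta = clip(theta, 1e-12, 1 - 1e-12), Z = Z, phi = phi,
                 c = c_init, pi = pi_init),
            class = "ChainState")
}

#' Remove super-enriched peptides before sampling
#'
#' Highly reactive peptides (initial fold-change estimate above
#' \code{threshold}, default 15) are unambiguously enriched, and letting the
#' model accommodate their extreme fold changes destabilizes inference for
#' the remaining peptides. Their reads are removed from the mock IP and
#' serum columns alike, library sizes are recomputed, and the excluded
#' peptides are recorded so they can be reported with posterior probability
#' 1.
#'
#' @inheritParams initialize_chain
#' @param threshold Fold-change cutoff (see
#'   \code{\link{beer_config}$prefilter_threshold}).
#' @return List with \code{matrix} (the filtered
#'   \code{PeptideCountMatrix}) and \code{excluded} (data frame
#'   \code{peptide_id}, \code{phi_init}; zero rows when nothing is
#'   filtered).
#' @export
prefilter_super_enriched <- function(m, prior, serum, threshold = 15) {
  init <- withCallingHandlers(
    initialize_chain(m, prior, serum),
    warning = function(w) invokeRestart("muffleWarning"))
  out <- init$phi > threshold
  excluded <- data.frame(peptide_id = rownames(m$counts)[out],
                         phi_init = init$phi[out],
                         stringsAsFactors = FALSE)
  mat <- if (any(out)) drop_peptides(m, excluded$peptide_id) else m
  list(matrix = mat, excluded = excluded)
}
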