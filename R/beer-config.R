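#' Configuration for the Bayesian enrichment model
#'
#' Collects all model hyperparameters and chain settings. Defaults reflect
#' typical PhIP-Seq plates:
#' \itemize{
#'   \item \code{a_pi = 2}, \code{b_pi = 300}: Beta prior on the proportion
#'     of enriched peptides per sample — most peptides are not reactive, but
#'     the prior stays diffuse enough to support a range of proportions.
#'   \item \code{a_phi = 1.25}, \code{b_phi = 0.1}: Gamma slab for the fold
#'     change of enriched peptides, shifted by \code{phi_min = 1} since only
#'     fold changes above 1 denote enrichment.
#'   \item \code{a_c = 80}, \code{b_c = 20}: Beta prior on the per-sample
#'     attenuation constant \code{c}; reactive peptides consume reads, so
#'     non-reactive peptides in a serum sample pull slightly fewer reads
#'     than in mock IPs (c usually between 0.5 and 1; c = 1 in mock IPs).
#'   \item \code{prefilter_threshold = 15}: peptides whose initial
#'     fold-change estimate exceeds this are removed before sampling (they
#'     are unambiguously enriched and destabilize the chain) and reported
#'     with posterior probability 1.
#'   \item \code{n_burn = 1000}, \code{n_iter = 10000}: burn-in and
#'     retained Gibbs iterations.
#' }
#'
#' @param a_pi,b_pi Beta shapes for the enrichment-proportion prior.
#' @param a_phi,b_phi Gamma shape and rate for the fold-change slab.
#' @param phi_min Minimum fold change of an enriched peptide (>= 1).
#' @param a_c,b_c Beta shapes for the attenuation-constant prior.
#' @param prefilter_threshold Initial fold-change cutoff for removing
#'   super-enriched peptides; must exceed \code{phi_min}.
#' @param n_iter,n_burn Retained and burn-in iteration counts.
#' @param seed Optional RNG seed recorded with the config.
#' @return A \code{BeerConfig} list.
#' @export
beer_config <- function(a_pi = 2, b_pi = 300, a_phi = 1.25, b_phi = 0.1,
                        phi_min = 1, a_c = 80, b_c = 20,
                        prefilter_threshold = 15,
                        n_iter = 10000, n_burn = 1000, seed = NULL) {
  cfg <- list(a_pi = a_pi, b_pi = b_pi, a_phi = a_phi, b_phi = b_phi,
              phi_min = phi_min, a_c = a_c, b_c = b_c,
              prefilter_threshold = prefilter_threshold,
              n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
              seed = seed)
  shapes <- c(cfg$a_pi, cfg$b_pi, cfg$a_phi, cfg$b_phi, cfg$a_c, cfg$b_c)
  if (any(!is.finite(shapes)) || any(shapes <= 0))
    argument_error("all shape/rate hyperparameters must be strictly positive")
  if (cfg$phi_min < 1) argument_error("phi_min must be >= 1")
  if (cfg$prefilter_threshold <= cfg$phi_min)
    argument_error("prefilter_threshold must exceed phi_min")
  if (cfg$n_iter < 1 || cfg$n_burn < 0)
    argument_error("n_iter must be >= 1 and n_burn >= 0")
  structure(cfg, class = "BeerConfig")
}

#' @export
print.BeerConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "BeerConfig: pi ~ Beta(%g, %g); phi | enriched ~ %g + Gamma(%g, %g); ",
    "c ~ Beta(%g, %g)\n  prefilter > %g; %d burn-in + %d retained iterations\n"),
    x$a_pi, x$b_pi, x$phi_min, x$a_phi, x$b_phi, x$a_c, x$b_c,
    x$prefilter_threshold, x$n_burn, x$n_iter))
  invisible(x)
}
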