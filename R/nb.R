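#' Empirical-Bayes negative-binomial dispersion estimation
#'
#' Estimates a plate-wide common dispersion (the squared coefficient of
#' variation of the read-pull proportions) by maximizing the pooled NB
#' conditional likelihood, then per-peptide tagwise dispersions by weighted
#' likelihood shrinkage toward the common value. This is the standard
#' RNA-Seq-style moderation, computed with \pkg{edgeR}
#' (\code{estimateCommonDisp}/\code{estimateTagwiseDisp}).
#'
#' @param m A \code{\link{phip_counts}} object.
#' @param groups Per-sample group labels (e.g. the sample roles). Every
#'   group must contain at least 2 samples, otherwise no within-group
#'   variability is observable.
#' @param prior_df Shrinkage weight: prior degrees of freedom pulling each
#'   peptide's dispersion toward the common value. As \code{prior_df} grows,
#'   tagwise values collapse onto the common dispersion.
#' @return A \code{DispersionEstimate}: list with \code{common} (scalar),
#'   \code{tagwise} (named per-peptide vector), and \code{shrinkage_weight}.
#' @export
estimate_dispersions <- function(m, groups = m$samples$role, prior_df = 10) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  groups <- as.factor(groups)
  if (length(groups) != ncol(m$counts))
    argument_error("one group label per sample is required")
  if (any(table(groups) < 2))
    data_error("each group needs at least 2 samples to estimate dispersion")
  d <- edgeR::DGEList(counts = m$counts, group = groups)
  d <- edgeR::estimateCommonDisp(d)
  d <- edgeR::estimateTagwiseDisp(d, prior.df = prior_df)
  structure(list(common = d$common.dispersion,
                 tagwise = stats::setNames(d$tagwise.dispersion,
                                           rownames(m$counts)),
                 shrinkage_weight = prior_df),
            class = "DispersionEstimate")
}

#' @export
print.DispersionEstimate <- function(x, ...) {
  cat(sprintf("DispersionEstimate: common %.4g, tagwise range [%.4g, %.4g], prior df %g\n",
              x$common, min(x$tagwise), max(x$tagwise), x$shrinkage_weight))
  invisible(x)
}

#' Negative-binomial exact test of one serum sample against the beads
#'
#' The comparator method: each peptide's serum count is tested against the
#' beads-only group with the overdispersion-adapted analogue of Fisher's
#' exact test (conditioning on the quantile-adjusted pseudo-total count,
#' \code{edgeR::exactTest}), after TMM library-size normalization. The "n
#' mock IPs versus 1 serum sample" design is valid here under the equal
#' group-variance assumption. At dispersion zero the test reduces to the
#' conditional binomial (doubletail) exact test.
#'
#' Two-sided p-values are converted to one-sided with
#' \code{\link{to_one_sided}} since the alternative to no reactivity (fold
#' change 1) is enrichment only, and Benjamini-Hochberg adjusted q-values
#' and calls at \code{alpha} are attached.
#'
#' @param m A \code{\link{phip_counts}} object containing the beads-only
#'   samples and \code{serum}.
#' @param disp A \code{DispersionEstimate} covering the peptides of
#'   \code{m}, or a single numeric dispersion recycled over peptides.
#' @param serum Sample id to test.
#' @param alpha FDR level for the \code{called} column (default 0.05).
#' @param normalize Apply TMM normalization factors (default \code{TRUE};
#'   trim fractions 0.3 on M-values and 0.05 on A-values, reference the
#'   beads sample with the median library size).
#' @return A \code{TestResult} data frame with one row per peptide:
#'   \code{peptide_id}, \code{sample_id}, \code{log_fc} (log2 serum vs
#'   beads), \code{p_two}, \code{p_one}, \code{q}, \code{called}. Rows are
#'   ordered as the input peptides.
#' @export
nb_exact_test <- function(m, disp, serum, alpha = 0.05, normalize = TRUE) {
  stopifnot(inherits(m, "PeptideCountMatrix"))
  if (!serum %in% m$samples$sample_id)
    argument_error(paste0("unknown sample id: ", serum))
  if (m$samples[serum, "role"] != "serum")
    argument_error(paste0(serum, " is not a serum sample"))
  jb <- beads_ids(m)
  if (length(jb) < 2) data_error("at least 2 beads-only samples are required")

  if (inherits(disp, "DispersionEstimate")) {
    tau <- disp$tagwise
    if (!is.null(names(tau))) tau <- tau[rownames(m$counts)]
    if (length(tau) != nrow(m$counts) || anyNA(tau))
      consistency_error("dispersion estimate does not cover all peptides")
  } else {
    tau <- rep_len(as.numeric(disp), nrow(m$counts))
  }

  cols <- c(jb, serum)
  grp <- factor(c(rep("beads", length(jb)), "serum"),
                levels = c("beads", "serum"))
  d <- edgeR::DGEList(counts = m$counts[, cols, drop = FALSE], group = grp)
  if (normalize) {
    ref <- which.min(abs(m$samples[jb, "lib_size"] -
                           stats::median(m$samples[jb, "lib_size"])))
    d <- edgeR::calcNormFactors(d, method = "TMM", refColumn = ref,
                                logratioTrim = 0.3, sumTrim = 0.05)
  }
  et <- edgeR::exactTest(d, pair = c("beads", "serum"), dispersion = tau)
  res <- data.frame(peptide_id = rownames(m$counts),
                    sample_id = serum,
                    log_fc = et$table$logFC,
                    p_two = pmin(et$table$PValue, 1),
                    stringsAsFactors = FALSE)
  res <- to_one_sided(res)
  adj <- bh_adjust(res$p_one, alpha = alpha,
                   tie_break = res$peptide_id)
  res$q <- adj$q
  res$called <- adj$called
  class(res) <- c("TestResult", class(res))
  res
}

#' Convert two-sided to one-sided p-values
#'
#' Reactivity can only inflate a peptide's read pull, so the one-sided
#' p-value is \code{p_two/2} when the observed fold change is in the
#' enriched direction (\code{log_fc > 0}) and \code{1 - p_two/2} otherwise.
#'
#' @param r A data frame with columns \code{p_two} and \code{log_fc}.
#' @return The input with a \code{p_one} column added/replaced.
#' @export
to_one_sided <- function(r) {
  stopifnot(all(c("p_two", "log_fc") %in% names(r)))
  r$p_one <- ifelse(r$log_fc > 0, r$p_two / 2, 1 - r$p_two / 2)
  r
}

#' Benjamini-Hochberg adjustment with calls at a target FDR
#'
#' Standard step-up procedure (\code{p.adjust(method = "BH")}); peptides
#' with \code{q <= alpha} are called. Ties in the p-value ranking do not
#' affect q-values; the optional \code{tie_break} vector only fixes the
#' ordering of returned values for deterministic downstream ranking.
#'
#' @param p Vector of p-values in [0, 1].
#' @param alpha FDR level.
#' @param tie_break Optional id vector used for deterministic ordering when
#'   ranking by p elsewhere; ignored by the adjustment itself.
#' @return List with \code{q} (adjusted values, same order as \code{p}) and
#'   \code{called} (logical).
#' @export
bh_adjust <- function(p, alpha = 0.05, tie_break = NULL) {
  if (length(p) == 0) return(list(q = numeric(0), called = logical(0)))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    argument_error("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, called = q <= alpha)
}
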