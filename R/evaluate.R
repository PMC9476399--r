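# Evaluation machinery: interpolated/averaged ROC and PR curves with
# trapezoidal AUC, FDR-matched posterior cutoffs, logistic power curves,
# and ranked-list concordance.

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# ROC points for one dataset: (FPR, TPR) per distinct score threshold,
# anchored at (0,0) and (1,1). Larger scores mean "more enriched".
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # collapse tied scores
  data.frame(fpr = c(0, fp[last] / max(sum(!labels), 1)),
             tpr = c(0, tp[last] / max(sum(labels), 1)))
}

pr_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  k <- seq_along(lab)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  data.frame(recall = c(0, tp[last] / max(sum(labels), 1)),
             ppv = c(1, tp[last] / k[last]))  # curves start at perfect PPV
}

interp_curve <- function(x, y, support) {
  # keep the best y at tied x, then linear interpolation on the support
  agg <- tapply(y, x, max)
  xs <- as.numeric(names(agg))
  stats::approx(xs, as.numeric(agg), xout = support, rule = 2,
                ties = "ordered")$y
}

#' Interpolated and averaged ROC / precision-recall curves
#'
#' For each dataset, standard ROC and PR points are computed from a score
#' vector (larger = more enriched; use the posterior probability for the
#' Bayesian model and \code{1 - p} for the exact test) and linearly
#' interpolated onto a shared support grid so curves from different
#' datasets can be averaged point-wise. ROC curves are anchored at (0, 0)
#' and PR curves start at recall 0 with perfect positive predictive value.
#' Areas under the curves are computed by trapezoidal approximation from
#' the interpolated points.
#'
#' @param scores List of numeric score vectors, one per dataset (a single
#'   vector is treated as one dataset).
#' @param labels List of logical vectors of the same lengths: \code{TRUE}
#'   for truly enriched peptides. When restricting to a fold-change bin,
#'   supply only the non-enriched peptides and the enriched peptides of
#'   that bin (see \code{\link{bin_curve_input}}).
#' @param n_support Number of evenly spaced support points on [0, 1]
#'   (default 501).
#' @return A list of two \code{CurveSet}s (\code{roc}, \code{pr}), each
#'   with \code{support}, per-dataset interpolated \code{curves} (matrix,
#'   one row per dataset), \code{mean_curve}, per-dataset \code{auc}, and
#'   \code{mean_auc} (the AUC of the mean curve).
#' @export
roc_pr_curves <- function(scores, labels, n_support = 501) {
  if (!is.list(scores)) scores <- list(scores)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(length(scores) == length(labels))
  keep <- vapply(labels, function(l) any(l) && any(!l), logical(1))
  if (!any(keep)) argument_error("no dataset has both enriched and non-enriched peptides")
  if (!all(keep))
    warning(sum(!keep), " dataset(s) without both classes skipped")
  scores <- scores[keep]
  labels <- labels[keep]
  support <- seq(0, 1, length.out = n_support)

  one_set <- function(points_fn, xcol, ycol) {
    curves <- t(vapply(seq_along(scores), function(d) {
      pts <- points_fn(scores[[d]], labels[[d]])
      interp_curve(pts[[xcol]], pts[[ycol]], support)
    }, numeric(n_support)))
    auc <- apply(curves, 1, function(yy) trapezoid(support, yy))
    mean_curve <- colMeans(curves)
    structure(list(support = support, curves = curves,
                   mean_curve = mean_curve, auc = auc,
                   mean_auc = trapezoid(support, mean_curve)),
              class = "CurveSet")
  }
  list(roc = one_set(roc_points, "fpr", "tpr"),
       pr = one_set(pr_points, "recall", "ppv"))
}

#' @export
print.CurveSet <- function(x, ...) {
  cat(sprintf("CurveSet: %d dataset(s) on %d support points; AUC %s (mean-curve AUC %.4f)\n",
              nrow(x$curves), length(x$support),
              paste(sprintf("%.4f", x$auc), collapse = ", "), x$mean_auc))
  invisible(x)
}

#' Scores and labels for one fold-change bin
#'
#' Builds the score/label input for \code{\link{roc_pr_curves}} from method
#' results and simulation truth: all non-enriched peptides from the serum
#' columns plus the enriched peptides whose true fold change falls in
#' \code{fc_range} (other enriched peptides are dropped; beads-only columns
#' are never included).
#'
#' @param results Data frame with columns \code{peptide_id},
#'   \code{sample_id}, and \code{score_col} (e.g. the output of
#'   \code{\link{run_beer}}, or an exact-test result with a
#'   \code{1 - p_one} column added).
#' @param truth A \code{SimTruth}.
#' @param score_col Name of the score column (larger = more enriched).
#' @param fc_range Numeric length-2 open-closed interval \code{(lo, hi]};
#'   \code{NULL} keeps all enriched peptides.
#' @param sample_ids Serum columns to pool (default: all non-null truth
#'   columns).
#' @return List with \code{scores} and \code{labels} vectors.
#' @export
bin_curve_input <- function(results, truth, score_col = "post_prob",
                            fc_range = NULL, sample_ids = NULL) {
  stopifnot(inherits(truth, "SimTruth"))
  if (is.null(sample_ids)) sample_ids <- truth$serum_ids[!truth$is_null]
  res <- results[results$sample_id %in% sample_ids, , drop = FALSE]
  idx <- match(res$peptide_id, rownames(truth$Z))
  if (anyNA(idx)) consistency_error("results contain peptides absent from truth")
  jcol <- match(res$sample_id, colnames(truth$Z))
  z <- truth$Z[cbind(idx, jcol)] == 1L
  fc <- truth$phi[cbind(idx, jcol)]
  keep <- !z | if (is.null(fc_range)) TRUE else (fc > fc_range[1] & fc <= fc_range[2])
  list(scores = res[[score_col]][keep], labels = z[keep])
}

#' Posterior-probability cutoff matched to a target false-discovery rate
#'
#' Scans all achievable thresholds and returns the smallest cutoff
#' \code{t} such that among peptides with \code{post_prob > t} the
#' false-discovery proportion is at most \code{target} (an empty call set
#' counts as proportion 0). Used to put the posterior-probability scale on
#' the same footing as p-value-based FDR control when comparing power.
#'
#' @param post_prob Numeric scores in [0, 1].
#' @param truth Logical vector of true enrichment.
#' @param target Target false-discovery proportion in (0, 1).
#' @return The cutoff; 1 (with a warning) when there are no true positives
#'   or no attainable threshold below 1.
#' @export
fdr_matched_cutoff <- function(post_prob, truth, target = 0.05) {
  stopifnot(length(post_prob) == length(truth))
  if (!is_scalar_number(target) || target <= 0 || target >= 1)
    argument_error("target must lie in (0, 1)")
  if (!any(truth)) {
    warning("no true positives; returning cutoff 1")
    return(1)
  }
  cand <- sort(unique(c(0, post_prob)))
  for (t in cand) {
    called <- post_prob > t
    fdp <- if (any(called)) mean(!truth[called]) else 0
    if (fdp <= target) return(t)
  }
  1
}

#' Logistic power curve: detection probability versus fold change
#'
#' Fits a logistic regression of the detection indicator on the log2 true
#' fold change of enriched peptides, and reports \code{fc50}, the fold
#' change at which the fitted detection probability crosses 50%. Under
#' complete separation the boundary between detected and undetected fold
#' changes is reported instead, with \code{separated = TRUE}; a flat
#' (non-positive or vanishing) slope yields \code{fc50 = NA} with
#' \code{degenerate = TRUE}.
#'
#' @param detected Logical vector over enriched peptides.
#' @param fc Their true fold changes (> 1).
#' @return List with the fitted \code{model}, \code{intercept},
#'   \code{slope} (per log2 fold change), \code{fc50}, and flags
#'   \code{separated}, \code{degenerate}.
#' @export
power_curve <- function(detected, fc) {
  stopifnot(length(detected) == length(fc))
  if (sum(detected) < 2 || sum(!detected) < 2)
    data_error("need at least 2 detected and 2 undetected peptides")
  x <- log2(fc)
  sep <- max(x[!detected]) < min(x[detected])
  fit <- suppressWarnings(stats::glm(detected ~ x, family = stats::binomial()))
  b <- stats::coef(fit)
  degenerate <- !is.finite(b[2]) || abs(b[2]) < 1e-8 || b[2] < 0
  fc50 <- if (sep) {
    2^((max(x[!detected]) + min(x[detected])) / 2)
  } else if (degenerate) NA_real_ else 2^(-b[1] / b[2])
  list(model = fit, intercept = unname(b[1]), slope = unname(b[2]),
       fc50 = unname(fc50), separated = sep, degenerate = degenerate && !sep)
}

#' Top-k concordance of two peptide rankings
#'
#' The fraction of peptides shared by the top \code{k} entries of two
#' ranked lists (e.g. technical replicates ranked by posterior probability
#' or by p-value): \code{|top_k(a) intersect top_k(b)| / k}.
#'
#' @param rank_a,rank_b Character vectors of peptide ids in rank order
#'   (best first).
#' @param k Depth of the comparison, \code{1 <= k <= length of both lists}.
#' @return Concordance in [0, 1].
#' @export
topk_concordance <- function(rank_a, rank_b, k) {
  if (!is_scalar_number(k) || k < 1 || k != round(k))
    argument_error("k must be a positive integer")
  if (k > length(rank_a) || k > length(rank_b))
    argument_error("k exceeds the length of a ranking")
  length(intersect(rank_a[seq_len(k)], rank_b[seq_len(k)])) / k
}

#' Rank peptides by a score, deterministically
#'
#' Stable ordering by decreasing score with ties broken by peptide id.
#'
#' @param peptide_id Character vector.
#' @param score Numeric vector (larger = more enriched).
#' @return Peptide ids in rank order.
#' @export
rank_peptides <- function(peptide_id, score) {
  stopifnot(length(peptide_id) == length(score))
  peptide_id[order(-score, peptide_id)]
}
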