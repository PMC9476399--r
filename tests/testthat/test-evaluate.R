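test_that("ROC/PR curves handle the textbook geometries", {
  # perfect separation
  cs <- roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cs$roc$auc, 1)
  expect_equal(cs$pr$auc, 1)
  # uninformative constant score: the diagonal
  cs2 <- roc_pr_curves(rep(0.5, 100), rep(c(TRUE, FALSE), 50))
  expect_equal(cs2$roc$auc, 0.5, tolerance = 1e-9)
  # anchors: ROC starts at (0,0); PR starts at recall 0, PPV 1
  expect_equal(cs$roc$curves[1, 1], 1)  # after the (0,0)->(0,1) jump, max at 0
  expect_equal(cs$pr$curves[1, 1], 1)
})

test_that("scores independent of truth give chance-level AUC", {
  set.seed(50)
  aucs <- replicate(5, {
    sc <- runif(2000)
    lab <- runif(2000) < 0.05
    roc_pr_curves(sc, lab)$roc$auc
  })
  expect_lt(max(abs(aucs - 0.5)), 0.08)
})

test_that("mean-curve AUC lies within the per-dataset AUC range", {
  set.seed(51)
  scores <- lapply(1:4, function(i) c(runif(50, 0.3, 1), runif(450)))
  labels <- lapply(1:4, function(i) c(rep(TRUE, 50), rep(FALSE, 450)))
  cs <- roc_pr_curves(scores, labels)
  expect_gte(cs$roc$mean_auc, min(cs$roc$auc) - 1e-9)
  expect_lte(cs$roc$mean_auc, max(cs$roc$auc) + 1e-9)
})

test_that("FDR-matched cutoffs admit only the affordable false discoveries", {
  expect_equal(fdr_matched_cutoff(c(0.9, 0.8, 0.3), c(TRUE, TRUE, FALSE), 0.05),
               0.3)
  expect_warning(ct <- fdr_matched_cutoff(c(0.9, 0.2), c(FALSE, FALSE), 0.05),
                 "no true positives")
  expect_equal(ct, 1)

  set.seed(52)
  for (rep in 1:20) {
    pp <- runif(40)
    truth <- runif(40) < 0.3
    if (!any(truth)) next
    t <- fdr_matched_cutoff(pp, truth, 0.1)
    called <- pp > t
    fdp <- if (any(called)) mean(!truth[called]) else 0
    expect_lte(fdp, 0.1)
    # brute force: no smaller achievable cutoff satisfies the target
    cand <- sort(unique(c(0, pp)))
    smaller <- cand[cand < t]
    for (s in smaller) {
      cs <- pp > s
      expect_gt(if (any(cs)) mean(!truth[cs]) else 0, 0.1)
    }
  }
})

test_that("logistic power curves recover the 50%-power fold change", {
  set.seed(53)
  n <- 500
  fc <- 2^runif(n, 0, 5)
  eta <- -4 + 2 * log2(fc)       # true fc50 = 2^2 = 4
  det <- runif(n) < plogis(eta)
  pc <- power_curve(det, fc)
  expect_false(pc$separated || pc$degenerate)
  expect_lt(abs(pc$fc50 - 4) / 4, 0.1)

  # hard threshold: complete separation, boundary reported with a flag
  det2 <- fc > 4
  pc2 <- power_curve(det2, fc)
  expect_true(pc2$separated)
  expect_lt(abs(pc2$fc50 - 4) / 4, 0.1)

  # detection unrelated to fold change: flagged, no fc50
  fc3 <- rep(c(2, 4, 8), each = 20)
  det3 <- rep(rep(c(TRUE, FALSE), 10), 3)
  pc3 <- power_curve(det3, fc3)
  expect_true(pc3$degenerate)
  expect_true(is.na(pc3$fc50))

  expect_error(power_curve(c(TRUE, FALSE), c(2, 3)),
               class = "phip_insufficient_data_error")
})

test_that("top-k concordance counts the shared top-ranked peptides", {
  ids <- sprintf("p%03d", 1:100)
  expect_equal(topk_concordance(ids, ids, 10), 1)
  expect_equal(topk_concordance(ids[1:50], ids[51:100], 25), 0)
  expect_error(topk_concordance(ids, ids, 0), class = "phip_argument_error")
  expect_error(topk_concordance(ids, ids, 200), class = "phip_argument_error")

  set.seed(54)
  conc <- replicate(200, topk_concordance(sample(ids), sample(ids), 20))
  expect_lt(abs(mean(conc) - 20 / 100), 0.03)  # hypergeometric expectation k/P

  # deterministic tie-break in ranking
  r <- rank_peptides(c("b", "a", "c"), c(0.5, 0.5, 0.9))
  expect_equal(r, c("c", "a", "b"))
})

test_that("bin filtering keeps nulls plus in-bin enriched peptides only", {
  Z <- matrix(c(1L, 1L, 0L, 0L), 4, 1,
              dimnames = list(paste0("p", 1:4), "serum_1"))
  phi <- matrix(c(3, 10, 1, 1), 4, 1, dimnames = dimnames(Z))
  truth <- structure(list(Z = Z, phi = phi,
                          bin = matrix(NA_character_, 4, 1),
                          c_true = 0.9, is_null = FALSE,
                          replicate_of = NA, serum_ids = "serum_1"),
                     class = "SimTruth")
  res <- data.frame(peptide_id = paste0("p", 1:4), sample_id = "serum_1",
                    post_prob = c(0.9, 1, 0.1, 0.2))
  inp <- bin_curve_input(res, truth, fc_range = c(2, 4))
  expect_equal(length(inp$scores), 3)        # p2 (fc 10) dropped
  expect_equal(sum(inp$labels), 1)
})
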