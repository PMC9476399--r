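test_that("chain initialization follows the twice-expected-count rule", {
  # peptide a: expected 100 reads (n = 1e6, mu0 = 1e-4); 200 observed is on
  # the Z = 1 boundary, 199 is below it
  counts <- rbind(a = 200, b = 400)
  m <- matrix_with_lib_sizes(counts, "serum", 1e6)
  pr <- manual_prior(c("a", "b", "zzz_filler"),
                     mu0 = c(1e-4, 1e-4, 1 - 2e-4),
                     sigma2_0 = c(4e-9, 4e-9, 1e-9))
  st <- initialize_chain(m, pr, "sample_1")
  expect_equal(st$Z[1:2], c(1L, 1L))
  expect_equal(st$theta[1:2], c(2e-4, 4e-4))

  counts2 <- rbind(a = 199, b = 400)
  m2 <- matrix_with_lib_sizes(counts2, "serum", 1e6)
  st2 <- initialize_chain(m2, pr, "sample_1")
  expect_equal(st2$Z[1:2], c(0L, 1L))

  # phi_init = Y / (n * c * mu0); filler keeps c_init essentially 1
  expect_equal(st$phi[2], 400 / (1e6 * st$c * 1e-4), tolerance = 1e-12)
  expect_equal(st$phi[2], 4, tolerance = 1e-3)
})

test_that("boundary initial values are offset into the open support", {
  # every count exactly at its beads expectation: slope 1, no enrichment
  counts <- rbind(a = 100, b = 300)
  m <- matrix_with_lib_sizes(counts, "serum", 1e6)
  pr <- manual_prior(c("a", "b", "zzz_filler"),
                     mu0 = c(1e-4, 3e-4, 1 - 4e-4),
                     sigma2_0 = c(4e-9, 4e-9, 1e-9))
  st <- initialize_chain(m, pr, "sample_1")
  expect_equal(st$Z, c(0L, 0L, 0L))
  expect_equal(st$c, 1 - 1e-4)           # c_init = 1 gets the small offset
  expect_equal(st$pi, 1 / 3)             # pi_init = 0 clamped to 1/P
  expect_true(st$c < 1 && st$pi > 0)

  mm <- toy_plate()
  expect_error(initialize_chain(mm, estimate_mom(mm), "nope"),
               class = "phip_argument_error")
  expect_warning(initialize_chain(mm, estimate_mom(mm), "beads_1"),
                 "beads-only")
})

test_that("super-enriched peptides are pre-filtered with conserved reads", {
  counts <- rbind(hot = c(10, 12, 11, 2000), a = c(100, 110, 90, 105))
  m <- matrix_with_lib_sizes(counts, c(rep("beads", 3), "serum"), rep(1e5, 4))
  pr <- estimate_mom(m)
  pf <- prefilter_super_enriched(m, pr, "sample_4", threshold = 15)
  expect_equal(pf$excluded$peptide_id, "hot")
  expect_gt(pf$excluded$phi_init, 15)
  expect_equal(unname(library_sizes(pf$matrix) + counts["hot", ]),
               unname(library_sizes(m)))

  pf2 <- prefilter_super_enriched(m, pr, "sample_4", threshold = 1e6)
  expect_equal(nrow(pf2$excluded), 0)
  expect_identical(pf2$matrix$counts, m$counts)
})

test_that("theta update has the conjugate Beta-Binomial stationary law", {
  Y <- 120; n <- 1e6
  counts <- rbind(a = Y)
  m <- matrix_with_lib_sizes(counts, "serum", n)
  pr <- manual_prior(c("a", "zzz_filler"), mu0 = c(1e-4, 1 - 1e-4),
                     sigma2_0 = c(4e-9, 1e-9))
  cc <- 0.95
  set.seed(30)
  fit <- run_mcmc(m, pr, beer_config(n_iter = 6000, n_burn = 200), "sample_1",
                  fix = list(Z = 0L, phi = 1, c = cc))
  mom0 <- beta_moments(pr$a0[1], pr$b0[1])
  sh <- beta_shapes_from_moments(cc * mom0$mu, mom0$sigma2)
  post <- beta_moments(sh$a + Y, sh$b + n - Y)
  mc_se <- sqrt(post$sigma2 / 6000)
  expect_lt(abs(fit$theta_mean[1] - post$mu), 5 * mc_se)
  expect_lt(abs(fit$theta_var[1] - post$sigma2) / post$sigma2, 0.15)
})

test_that("with no data the chain samples the priors", {
  P <- 200
  m0 <- phip_counts(matrix(0L, P, 1,
                           dimnames = list(sprintf("p%03d", 1:P), "s1")),
                    roles = "serum")
  pr <- manual_prior(rownames(m0$counts), mu0 = rep(1e-4, P),
                     sigma2_0 = rep(1e-9, P))
  set.seed(5)
  fit <- run_mcmc(m0, pr, beer_config(n_iter = 8000, n_burn = 500), "s1")
  expect_lt(abs(fit$c_hat - 80 / 100), 0.02)
  expect_lt(abs(fit$pi_hat - 2 / 302), 0.003)
  enriched_phi <- fit$summary$phi_hat[fit$summary$phi_hat > 1]
  expect_gt(length(enriched_phi), 20)
  expect_lt(abs(mean(enriched_phi) - (1 + 1.25 / 0.1)), 1.5)
})

test_that("identical seeds give identical posterior summaries", {
  prior <- generate_beads_prior(120, seed = 31)
  sim <- simulate_dataset(prior,
    design = sim_design(n_beads = 4, n_serum = 1, n_null = 0,
                        n_replicate_pairs = 0, n_enriched = 10),
    seed = 32)
  cfg <- beer_config(n_iter = 400, n_burn = 100)
  r1 <- run_beer(sim$matrix, config = cfg, seed = 33)
  r2 <- run_beer(sim$matrix, config = cfg, seed = 33)
  expect_identical(r1, r2)
})

test_that("strong spikes are either pre-filtered at probability 1 or detected", {
  prior <- generate_beads_prior(300, seed = 34)
  spike_bin <- cbind(lower = 30, upper = 34)  # true phi ~ 32
  sim <- simulate_dataset(prior,
    design = sim_design(n_beads = 6, n_serum = 1, n_null = 0,
                        n_replicate_pairs = 0, n_enriched = 8,
                        fc_bins = spike_bin),
    seed = 35)
  spiked <- rownames(sim$truth$Z)[sim$truth$Z[, 1] == 1]

  res <- run_beer(sim$matrix, config = beer_config(n_iter = 2000, n_burn = 500),
                  seed = 36)
  pp <- res$post_prob[match(spiked, res$peptide_id)]
  exc <- res$excluded_flag[match(spiked, res$peptide_id)]
  expect_true(all(pp[exc] == 1))
  expect_true(all(pp >= 0.999))

  # without the pre-filter the sampler still assigns probability ~1
  res2 <- run_beer(sim$matrix,
                   config = beer_config(n_iter = 2000, n_burn = 500,
                                        prefilter_threshold = 1e6),
                   seed = 37)
  pp2 <- res2$post_prob[match(spiked, res2$peptide_id)]
  expect_true(all(pp2 >= 0.999))
})

test_that("enrichment calls respond to the cutoff monotonically", {
  s <- data.frame(post_prob = c(0.2, 0.6, 1), excluded_flag = c(FALSE, FALSE, TRUE))
  expect_equal(call_enriched(s, 0.5), c(FALSE, TRUE, TRUE))
  expect_equal(call_enriched(s, 0.999999), c(FALSE, FALSE, TRUE))
  calls <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(ct) sum(call_enriched(s, ct)), numeric(1))
  expect_true(all(diff(calls) <= 0))
  expect_error(call_enriched(s, 1.5), class = "phip_argument_error")
})
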