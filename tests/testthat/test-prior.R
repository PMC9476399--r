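test_that("moment matching maps means and variances to Beta shapes", {
  sh <- beta_shapes_from_moments(0.5, 0.05)
  expect_equal(sh$a, 2)
  expect_equal(sh$b, 2)
  sh <- beta_shapes_from_moments(0.2, 0.01)
  expect_equal(sh$a, 3)
  expect_equal(sh$b, 12)
  expect_error(beta_shapes_from_moments(0.5, 0.25),
               class = "phip_infeasible_moments_error")

  mom <- beta_moments(2, 2)
  expect_equal(mom$mu, 0.5)
  expect_equal(mom$sigma2, 0.05)
  mom <- beta_moments(1, 1)
  expect_equal(mom$mu, 0.5)
  expect_equal(mom$sigma2, 1 / 12)
  expect_error(beta_moments(-1, 2), class = "phip_argument_error")
})

test_that("shapes -> moments -> shapes is the identity on feasible pairs", {
  set.seed(1)
  a <- exp(runif(50, log(0.2), log(500)))
  b <- exp(runif(50, log(0.2), log(5e5)))
  mom <- beta_moments(a, b)
  sh <- beta_shapes_from_moments(mom$mu, mom$sigma2)
  expect_equal(sh$a, a, tolerance = 1e-10)
  expect_equal(sh$b, b, tolerance = 1e-10)
})

test_that("the a >= 1 guard preserves the mean", {
  g <- apply_guard(0.4, 399.6)
  expect_equal(g$a, 1)
  expect_equal(g$b, 999)
  expect_equal(apply_guard(2, 5), list(a = 2, b = 5))

  set.seed(2)
  a <- exp(runif(100, log(0.01), log(10)))
  b <- exp(runif(100, log(0.01), log(1e4)))
  g <- apply_guard(a, b)
  expect_true(all(g$a >= 1))
  expect_equal(g$a / (g$a + g$b), a / (a + b), tolerance = 1e-12)
})

test_that("method of moments matches the hand-worked beads example", {
  pr <- estimate_mom(toy_beads_matrix())
  i <- match("a", pr$peptide_id)
  expect_equal(pr$mu0[i], 0.2)
  expect_equal(pr$sigma2_0[i], 0.01)
  expect_equal(pr$a0[i], 3)
  expect_equal(pr$b0[i], 12)
  expect_error(estimate_mom(phip_counts(rbind(a = 5), roles = "beads")),
               class = "phip_insufficient_data_error")
})

test_that("degenerate beads data fall back to proper Beta priors", {
  counts <- rbind(const = c(100, 100, 100), zero = c(0, 0, 0),
                  filler = c(900, 900, 900))
  colnames(counts) <- paste0("b", 1:3)
  m <- phip_counts(counts, roles = rep("beads", 3))
  pr <- estimate_mom(m)
  expect_true(all(pr$a0 >= 1) && all(pr$b0 > 0))
  i <- match("const", pr$peptide_id)
  # binomial-scale variance at the mean library size nbar = 1000
  expect_equal(pr$sigma2_0[i], 0.1 * 0.9 / 1001)
  j <- match("zero", pr$peptide_id)
  expect_equal(pr$mu0[j], 1 / 2000)  # half a pseudo-read
  expect_true(pr$fallback[i] && pr$fallback[j])
})

test_that("maximum likelihood recovers known shapes and beats MOM likelihood", {
  set.seed(3)
  N <- 1000
  n <- 1e5
  theta <- rbeta(N, 3, 12)
  ya <- rbinom(N, n, theta)
  counts <- rbind(a = ya, filler = n - ya)
  m <- phip_counts(counts, roles = rep("beads", N))
  mle <- estimate_mle(m)
  i <- match("a", mle$peptide_id)
  expect_lt(abs(mle$a0[i] - 3) / 3, 0.1)
  expect_lt(abs(mle$b0[i] - 12) / 12, 0.1)

  mom <- estimate_mom(m)
  th <- pmin(pmax(counts["a", ] / n, 1e-10), 1 - 1e-10)
  ll <- function(a, b) sum(dbeta(th, a, b, log = TRUE))
  expect_gte(ll(mle$a0[i], mle$b0[i]) + 1e-6, ll(mom$a0[i], mom$b0[i]))
})

test_that("single repeated proportion makes the MLE fall back", {
  counts <- rbind(const = c(50, 50, 50), filler = c(950, 950, 950))
  m <- phip_counts(counts, roles = rep("beads", 3))
  mle <- estimate_mle(m)
  expect_true(mle$fallback[match("const", mle$peptide_id)])
  expect_true(all(mle$a0 >= 1))
})

test_that("dispersion-derived shapes follow sigma2 = tau * mu^2", {
  counts <- rbind(a = c(1000, 1000), b = c(2000, 2000))
  m <- matrix_with_lib_sizes(counts, rep("beads", 2), c(1e6, 1e6))
  disp <- structure(list(common = 0.04,
                         tagwise = c(a = 0.04, b = 0.04, zzz_filler = 0.04),
                         shrinkage_weight = 10),
                    class = "DispersionEstimate")
  pr <- estimate_dispersion_derived(m, disp)
  i <- match("a", pr$peptide_id)
  expect_equal(pr$sigma2_0[i], 0.04 * 0.001^2)
  expect_equal(pr$a0[i], 24.974, tolerance = 1e-4)
  expect_equal(pr$b0[i] / pr$a0[i], 999)

  # tau = 0 is infeasible and triggers the degenerate-variance fallback
  disp0 <- structure(list(common = 0, tagwise = c(a = 0, b = 0, zzz_filler = 0),
                          shrinkage_weight = 10), class = "DispersionEstimate")
  pr0 <- estimate_dispersion_derived(m, disp0)
  expect_true(all(pr0$fallback))
  expect_true(all(pr0$a0 >= 1))

  # a is strictly decreasing in tau at fixed mean
  taus <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  a_of_tau <- vapply(taus, function(tv) {
    d <- structure(list(common = tv,
                        tagwise = setNames(rep(tv, 3), c("a", "b", "zzz_filler")),
                        shrinkage_weight = 10), class = "DispersionEstimate")
    estimate_dispersion_derived(m, d)$a0[i]
  }, numeric(1))
  expect_true(all(diff(a_of_tau) < 0))

  dbad <- structure(list(common = 0.04, tagwise = c(a = 0.04),
                         shrinkage_weight = 10), class = "DispersionEstimate")
  expect_error(estimate_dispersion_derived(m, dbad),
               class = "phip_consistency_error")
})

test_that("all three estimators recover the background mean on simulated beads", {
  set.seed(4)
  prior <- generate_beads_prior(100, seed = 4)
  sim <- simulate_dataset(prior,
    design = sim_design(n_beads = 30, n_serum = 0, n_null = 0,
                        n_replicate_pairs = 0),
    seed = 5)
  for (method in c("mom", "mle", "edger")) {
    est <- estimate_beads_prior(sim$matrix, method)
    relerr <- abs(est$mu0 - prior$mu0) / prior$mu0
    expect_lt(median(relerr), 0.1)
    expect_true(all(est$a0 >= 1) && all(est$b0 > 0))
  }
})
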