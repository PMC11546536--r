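# Estimator formulas against independent brute-force oracles, EIC
# identities, TMLE behavior, and confidence-interval arithmetic.

test_that("mu1_hat is the treated-arm mean", {
  base <- list(d = c(1, 1, 1), x = cbind(x1 = c(0, 0, 0)), pi_a = 0.5)
  dat <- hybrid_data(y = c(2, 4, 9), a = c(1, 1, 0), d = base$d,
                     x = base$x, pi_a = base$pi_a)
  expect_equal(mu1_hat(dat), 3)
  dat2 <- hybrid_data(y = c(1, 2, 6, 0), a = c(1, 1, 1, 0),
                      d = c(1, 1, 1, 1), x = cbind(x1 = rep(0, 4)),
                      pi_a = 0.5)
  expect_equal(mu1_hat(dat2), 3)
  dat3 <- hybrid_data(y = c(7, 7, 1), a = c(1, 1, 0), d = c(1, 1, 1),
                      x = base$x, pi_a = 0.5)
  expect_equal(mu1_hat(dat3), 7)
})

test_that("g-computation averages m0 over trial subjects only", {
  dat <- hybrid_data(y = rep(0, 5), a = c(1, 0, 0, 0, 0),
                     d = c(1, 1, 1, 0, 0),
                     x = cbind(x1 = c(0, 1, 2, 9, -9)), pi_a = 0.5)
  # constant model
  fits_c <- fake_fits(m1 = rep(0, 5), m0 = rep(4.5, 5),
                      pi_d = rep(0.5, 5), pi_a = 0.5)
  expect_equal(estimate_mu0_om(dat, fits_c), 4.5)
  # m0(x) = x1 over study covariates {0, 1, 2} -> 1
  fits_x <- fake_fits(m1 = rep(0, 5), m0 = dat$x[, 1],
                      pi_d = rep(0.5, 5), pi_a = 0.5)
  expect_equal(estimate_mu0_om(dat, fits_x), 1)
  # perturbing external-control rows of m0 leaves the average unchanged
  m0_pert <- dat$x[, 1]; m0_pert[4:5] <- m0_pert[4:5] + 100
  expect_equal(estimate_mu0_om(dat, fake_fits(rep(0, 5), m0_pert,
                                              rep(0.5, 5), 0.5)), 1)
})

test_that("IPDW weights match the closed form and its limits", {
  dat <- hybrid_data(y = rnorm(3), a = c(1, 0, 0), d = c(1, 1, 0),
                     x = cbind(x1 = 1:3), pi_a = 2 / 3)
  fits <- fake_fits(m1 = rep(0, 3), m0 = rep(0, 3),
                    pi_d = c(0.5, 0.5, 0.5), pi_a = 2 / 3)
  w <- ipdw_weights(dat, fits)
  expect_equal(w[1], 0)                # treated
  expect_equal(w[2], 0.75)             # 0.5 / ((1/3)(0.5) + 0.5)
  expect_equal(w[3], 0.75)
  expect_equal(w, oracle_ipdw_weights(dat$a, fits$pred$pi_d,
                                      fits$pred$pi_a))
  # pi_d -> 1 recovers the within-trial inverse-probability weight
  fits1 <- fake_fits(rep(0, 3), rep(0, 3), pi_d = rep(1 - 1e-12, 3),
                     pi_a = 2 / 3)
  expect_equal(ipdw_weights(dat, fits1)[2], 1 / (1 - 2 / 3),
               tolerance = 1e-9)
})

test_that("IPDW mean: hand arithmetic and Hajek normalization", {
  # two controls with weights {0.75, 0.25}, outcomes {4, 8}
  dat <- hybrid_data(y = c(4, 8, 1), a = c(0, 0, 1), d = c(1, 0, 1),
                     x = cbind(x1 = 1:3), pi_a = 2 / 3)
  # choose pi_d values producing those weights: solve w = (1-a) pd /
  # ((1-pa) pd + 1 - pd); for pa = 2/3: w = pd/(1 - (2/3) pd)
  pd_for <- function(w) w / (1 + (2 / 3) * w)
  fits <- fake_fits(rep(0, 3), rep(0, 3),
                    pi_d = c(pd_for(0.75), pd_for(0.25), 0.5),
                    pi_a = 2 / 3)
  w <- ipdw_weights(dat, fits)
  expect_equal(w[1:2], c(0.75, 0.25), tolerance = 1e-12)
  # n_rct = 2 here; the printed estimator divides by n_rct
  expect_equal(estimate_mu0_ipdw(dat, fits),
               (0.75 * 4 + 0.25 * 8) / 2)
  expect_equal(estimate_mu0_ipdw(dat, fits, normalize = TRUE), 5)
  # weighted mean of a constant outcome is that constant
  datc <- hybrid_data(y = c(3, 3, 1), a = c(0, 0, 1), d = c(1, 0, 1),
                      x = cbind(x1 = 1:3), pi_a = 2 / 3)
  expect_equal(estimate_mu0_ipdw(datc, fits, normalize = TRUE), 3)
})

test_that("EIC values match hand evaluation", {
  # treated trial subject with vanishing residuals
  expect_equal(eic_value(y = 2, a = 1, d = 1, m1 = 2, m0 = 1,
                         pi_a = 2 / 3, pi_d = 0.5, r = 1, tau = 1,
                         q = 0.75), 0)
  # internal control: W^dr = 0.5 / ((0.5)(1/3) + 0.5) = 0.75
  expect_equal(eic_value(y = 1, a = 0, d = 1, m1 = 0, m0 = 0,
                         pi_a = 2 / 3, pi_d = 0.5, r = 1, tau = 0,
                         q = 0.75), -1)
  # external control with r = 1 gets the same weight (source-symmetric)
  phi_int <- eic_value(1, 0, 1, m1 = 0.5, m0 = 0, pi_a = 2 / 3,
                       pi_d = 0.5, r = 1, tau = 0.5, q = 0.75)
  phi_ext <- eic_value(1, 0, 0, m1 = 0.5, m0 = 0, pi_a = 2 / 3,
                       pi_d = 0.5, r = 1, tau = 0.5, q = 0.75)
  # the D-only leading term differs; the weighted residual is identical
  w_int <- 0.75
  expect_equal(phi_int, (1 / 0.75) * ((0.5 - 0 - 0.5) - w_int * 1))
  expect_equal(phi_ext, (1 / 0.75) * (-w_int * 1))
  # vectorized agreement with the scalar oracle
  f <- micro_fixture()
  p <- f$fits$pred
  expect_equal(
    eic_value(f$data$y, f$data$a, f$data$d, p$m1, p$m0, p$pi_a, p$pi_d,
              p$r, tau = 0.4, q = 4 / 6),
    oracle_eic(f$data$y, f$data$a, f$data$d, p$m1, p$m0, p$pi_a, p$pi_d,
               p$r, tau = 0.4, q = 4 / 6),
    tolerance = 1e-14)
})

test_that("AIPW equals the brute-force evaluation on micro fixtures", {
  f <- micro_fixture()
  est <- estimate_tau_aipw(f$data, f$fits)
  p <- f$fits$pred
  expected <- oracle_aipw(f$data$y, f$data$a, f$data$d, p$m1, p$m0,
                          p$pi_a, p$pi_d, p$r)
  expect_equal(est$tau_hat, expected, tolerance = 1e-12)
  # influence values average to zero by construction
  expect_lt(abs(mean(est$influence_values)), 1e-12)
  # and equal the oracle EIC at tau_hat
  expect_equal(est$influence_values,
               oracle_eic(f$data$y, f$data$a, f$data$d, p$m1, p$m0,
                          p$pi_a, p$pi_d, p$r, tau = est$tau_hat,
                          q = 4 / 6),
               tolerance = 1e-12)
})

test_that("AIPW with exact nuisances on noiseless data is the plug-in", {
  set.seed(12)
  n <- 40
  d <- c(rep(1L, 30), rep(0L, 10))
  a <- ifelse(d == 1L, rbinom(n, 1, 2 / 3), 0L)
  a[1:2] <- c(1L, 0L)
  x <- cbind(x1 = rnorm(n))
  m0 <- 1 + x[, 1]; m1 <- m0 + 2
  y <- ifelse(a == 1L, m1, m0)  # noiseless
  dat <- hybrid_data(y, a, d, x, pi_a = 2 / 3)
  fits <- fake_fits(m1, m0, pi_d = rep(0.75, n), pi_a = 2 / 3)
  est <- estimate_tau_aipw(dat, fits)
  expect_equal(est$tau_hat, sum(d * (m1 - m0)) / sum(d))
  expect_equal(est$tau_hat, 2)
})

test_that("with no external controls AIPW reduces to the trial AIPW", {
  set.seed(13)
  n <- 50
  a <- rbinom(n, 1, 0.5); a[1:2] <- c(0L, 1L)
  x <- cbind(x1 = rnorm(n))
  y <- x[, 1] + a + rnorm(n)
  dat <- hybrid_data(y, a, d = rep(1L, n), x = x, pi_a = 0.5)
  m1 <- x[, 1] + 1; m0 <- x[, 1]
  fits <- fake_fits(m1, m0, pi_d = rep(1, n), pi_a = 0.5)
  est <- estimate_tau_aipw(dat, fits)
  manual <- mean(m1 - m0 + a / 0.5 * (y - m1) -
                   (1 - a) / 0.5 * (y - m0))
  expect_equal(est$tau_hat, manual, tolerance = 1e-12)
})

test_that("TMLE: zero fluctuation is the identity and bounds hold", {
  dat <- simulate_trial(sim_config(setting = 1), seed = 41)
  fits <- fit_nuisances(dat, learner_spec(), k_folds = 1L, seed = 2)
  fl <- tmle_fluctuate(dat, fits)
  # bounded predictions
  expect_true(all(fl$m1_star >= fl$L & fl$m1_star <= fl$U))
  expect_true(all(fl$m0_star >= fl$L & fl$m0_star <= fl$U))
  # a hand-built zero-epsilon case: residuals orthogonal to h by
  # construction (y identical to the fitted regressions)
  n <- dat$n
  p <- fits$pred
  dat0 <- hybrid_data(y = ifelse(dat$a == 1L, p$m1, p$m0), a = dat$a,
                      d = dat$d, x = dat$x, pi_a = dat$pi_a_design)
  fits0 <- fake_fits(p$m1, p$m0, p$pi_d, p$pi_a, p$r)
  fl0 <- tmle_fluctuate(dat0, fits0)
  expect_lt(abs(fl0$epsilon), 1e-6)
  sc <- function(v) pmin(pmax(v, fl0$L), fl0$U)
  expect_equal(fl0$m1_star, sc(p$m1), tolerance = 1e-4)
  expect_equal(fl0$m0_star, sc(p$m0), tolerance = 1e-4)
})

test_that("TMLE solves the EIC equation after one fluctuation", {
  for (seed in c(42, 43)) {
    dat <- simulate_trial(sim_config(setting = 1), seed = seed)
    fits <- fit_nuisances(dat, learner_spec(), k_folds = 1L, seed = 2)
    est <- estimate_tau_tmle(dat, fits)
    expect_lt(abs(est$metadata$eic_mean), 1e-6)
    # plug-in stays inside the scaled outcome range
    rng <- diff(range(dat$y))
    expect_lt(abs(est$tau_hat), rng)
  }
})

test_that("TMLE and AIPW agree asymptotically under correct models", {
  gaps <- sapply(c(200, 2000, 20000), function(n) {
    cfg <- sim_config(setting = 1, n_rct = round(0.75 * n),
                      n_ec = round(0.25 * n))
    dat <- simulate_trial(cfg, seed = 50 + n)
    fits <- fit_nuisances(dat, learner_spec(), k_folds = 1L, seed = 3)
    abs(estimate_tau_tmle(dat, fits)$tau_hat -
          estimate_tau_aipw(dat, fits)$tau_hat)
  })
  expect_lt(gaps[3], gaps[1] + 1e-3)
  expect_lt(gaps[3], 1e-3)
})

test_that("closed-form CI arithmetic and degenerate cases", {
  # all-zero influence values
  ci0 <- closed_form_ci(rep(0, 10), tau_hat = 1.5)
  expect_true(ci0$degenerate)
  expect_equal(c(ci0$lo, ci0$hi), c(1.5, 1.5))
  # var 4, n 400, tau 1 -> 1 +/- z * 0.1
  set.seed(8)
  v <- rnorm(400)
  v <- (v - mean(v)) / sd(v) * 2  # exact sd 2
  ci <- closed_form_ci(v, tau_hat = 1, alpha = 0.05)
  z <- qnorm(0.975)
  expect_equal(ci$se, 0.1, tolerance = 1e-12)
  expect_equal(ci$lo, 1 - z * 0.1, tolerance = 1e-12)
  expect_equal(ci$hi, 1 + z * 0.1, tolerance = 1e-12)
  expect_equal(ci$p, 2 * pnorm(-10), tolerance = 1e-12)
  # level change scales the width by the quantile ratio
  ci32 <- closed_form_ci(v, tau_hat = 1, alpha = 0.32)
  expect_equal((ci32$hi - ci32$lo) / (ci$hi - ci$lo),
               qnorm(1 - 0.16) / z, tolerance = 1e-12)
})

test_that("estimates are location-equivariant in the outcome", {
  dat <- simulate_trial(sim_config(setting = 1), seed = 61)
  shift <- 7.5
  dat2 <- hybrid_data(dat$y + shift, dat$a, dat$d, dat$x,
                      pi_a = dat$pi_a_design)
  f1 <- fit_nuisances(dat, learner_spec(), k_folds = 1L, seed = 4)
  f2 <- fit_nuisances(dat2, learner_spec(), k_folds = 1L, seed = 4)
  expect_equal(estimate_mu0_om(dat2, f2),
               estimate_mu0_om(dat, f1) + shift, tolerance = 1e-8)
  expect_equal(estimate_tau_aipw(dat2, f2)$tau_hat,
               estimate_tau_aipw(dat, f1)$tau_hat, tolerance = 1e-8)
  expect_equal(estimate_tau_tmle(dat2, f2)$tau_hat,
               estimate_tau_tmle(dat, f1)$tau_hat, tolerance = 1e-6)
  expect_equal(estimate_tau_rct(dat2, f2)$tau_hat,
               estimate_tau_rct(dat, f1)$tau_hat, tolerance = 1e-8)
})

test_that("RCT-only estimator equals hybrid AIPW at pi_d = 1 on the
           trial subset and is exact in the noiseless case", {
  set.seed(14)
  n <- 60
  a <- rbinom(n, 1, 2 / 3); a[1:2] <- c(0L, 1L)
  x <- cbind(x1 = rnorm(n))
  m0 <- 2 - x[, 1]; m1 <- m0 + 3
  y <- ifelse(a == 1, m1, m0)
  dat <- hybrid_data(y, a, d = rep(1L, n), x = x, pi_a = 2 / 3)
  fits <- fit_nuisances(dat, learner_spec(), k_folds = 1L, seed = 5)
  est <- estimate_tau_rct(dat, fits)
  expect_equal(est$tau_hat, 3, tolerance = 1e-9)
  # identity with the hybrid EIC at pi_d = 1, r = 1 on the subset
  fits1 <- fake_fits(fits$pred$m1, fits$pred$m0, pi_d = rep(1, n),
                     pi_a = 2 / 3)
  expect_equal(est$tau_hat, estimate_tau_aipw(dat, fits1)$tau_hat,
               tolerance = 1e-9)
})

test_that("bootstrap is seed-reproducible and degenerates correctly", {
  dat <- random_hybrid(n = 40, seed = 15)
  b1 <- bootstrap_ci(dat, "om", B = 25, seed = 99)
  b2 <- bootstrap_ci(dat, "om", B = 25, seed = 99)
  expect_identical(b1$boot, b2$boot)
  expect_identical(c(b1$lo, b1$hi, b1$p), c(b2$lo, b2$hi, b2$p))
  # constant outcome: every resample estimate equals the constant 0
  datc <- hybrid_data(y = rep(3, 12),
                      a = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
                      d = c(rep(1L, 9), rep(0L, 3)),
                      x = cbind(x1 = rnorm(12)), pi_a = 2 / 3)
  bc <- bootstrap_ci(datc, "om", B = 10, seed = 1)
  expect_equal(unname(bc$lo), unname(bc$hi))
  expect_equal(unname(bc$lo), bc$tau_hat, tolerance = 1e-9)
})
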