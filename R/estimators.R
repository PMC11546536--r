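# Estimators of the average treatment effect in the study population for
# hybrid trials: outcome model (g-computation), inverse probability of
# data-source weighting (IPDW), AIPW and TMLE based on the efficient
# influence curve, plus an RCT-only AIPW comparator.

new_effect_estimate <- function(method, tau_hat, se, ci_low, ci_high, alpha,
                                p_value, n_rct, n_ec,
                                influence_values = NULL, metadata = list()) {
  structure(list(method = method, tau_hat = tau_hat, se = se,
                 ci_low = ci_low, ci_high = ci_high, alpha = alpha,
                 p_value = p_value, n_rct = n_rct, n_ec = n_ec,
                 influence_values = influence_values, metadata = metadata),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of the average treatment effect\n",
              toupper(x$method)))
  cat(sprintf("  tau = %.4g", x$tau_hat))
  if (is.finite(x$se)) cat(sprintf("  (se %.4g)", x$se))
  cat("\n")
  if (is.finite(x$ci_low))
    cat(sprintf("  %d%% CI (%.4g, %.4g)   p = %.3g\n",
                round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  n_rct = %d, n_ec = %d\n", x$n_rct, x$n_ec))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(method = x$method, tau_hat = x$tau_hat, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, alpha = x$alpha,
             p_value = x$p_value, n_rct = x$n_rct, n_ec = x$n_ec,
             stringsAsFactors = FALSE)
}

#' Treated-arm mean outcome
#'
#' Estimates mu1 = E[Y | A = 1], which identifies the mean counterfactual
#' outcome under treatment in the study population because all treated
#' subjects are randomized trial participants.
#'
#' @param data A [hybrid_data()] object with at least one treated subject.
#' @return The sample mean of the outcome among treated subjects.
#' @export
mu1_hat <- function(data) {
  stopifnot(inherits(data, "hybrid_data"))
  tr <- data$a == 1L
  if (!any(tr)) stop("no treated subjects")
  mean(data$y[tr])
}

#' Outcome-model (g-computation) estimate of the control mean
#'
#' Averages the pooled-control outcome regression m0 over the empirical
#' covariate distribution of the trial: mu0_om = n_rct^{-1} sum_i D_i
#' m0(X_i). External controls contribute to fitting m0 but are excluded
#' from the averaging set.
#'
#' @param data A [hybrid_data()] object.
#' @param fits A [fit_nuisances()] object.
#' @return The standardization estimate of E[Y^0 | D = 1].
#' @export
estimate_mu0_om <- function(data, fits) {
  stopifnot(inherits(fits, "nuisance_fits"))
  if (data$n_rct == 0L) stop("no trial subjects to average over")
  sum(data$d * fits$pred$m0) / data$n_rct
}

#' Inverse probability of data-source weights
#'
#' Computes the IPDW weight for each subject,
#' W = (1 - A) pi_d(X) / ( [1 - pi_a(X)] pi_d(X) + [1 - pi_d(X)] ),
#' which re-weights all controls (internal and external) to the trial
#' covariate distribution. Treated subjects receive weight 0; when
#' pi_d = 1 the weight reduces to the classical within-trial
#' inverse-probability weight 1 / (1 - pi_a).
#'
#' @param data A [hybrid_data()] object.
#' @param fits A [fit_nuisances()] object.
#' @return Numeric weight vector of length n.
#' @export
ipdw_weights <- function(data, fits) {
  stopifnot(inherits(fits, "nuisance_fits"))
  pd <- fits$pred$pi_d
  pa <- fits$pred$pi_a
  (1 - data$a) * pd / ((1 - pa) * pd + (1 - pd))
}

#' IPDW estimate of the control mean
#'
#' @param data A [hybrid_data()] object.
#' @param fits A [fit_nuisances()] object.
#' @param normalize If `FALSE` (default) returns the Horvitz-Thompson form
#'   n_rct^{-1} sum_i W_i Y_i; if `TRUE` returns the Hajek form
#'   sum_i W_i Y_i / sum_i W_i.
#' @return The weighting estimate of E[Y^0 | D = 1].
#' @export
estimate_mu0_ipdw <- function(data, fits, normalize = FALSE) {
  w <- ipdw_weights(data, fits)
  if (all(w == 0)) stop("all IPDW weights are zero")
  if (normalize) sum(w * data$y) / sum(w)
  else sum(w * data$y) / data$n_rct
}

# Doubly robust control-side weight W^dr. The (1 - a) factor is applied to
# both numerator summands so treated subjects receive zero weight; for
# external controls a = 0 always, so this only affects counterfactual
# evaluations.
w_dr <- function(a, d, pi_d, pi_a, r) {
  (d * (1 - a) * pi_d + (1 - d) * (1 - a) * pi_d * r) /
    (pi_d * (1 - pi_a) + (1 - pi_d) * r)
}

#' Efficient influence curve value
#'
#' Evaluates the efficient influence curve for the average treatment
#' effect in the study population at one observation (vectorized over
#' observations):
#' phi = (1/q) \{ D [m1 - m0 - tau] + (D A / pi_a) [y - m1]
#'                - W^dr [y - m0] \},
#' where W^dr = [D (1-A) pi_d + (1-D)(1-A) pi_d r] /
#' (pi_d (1 - pi_a) + (1 - pi_d) r) and q = Pr(D = 1).
#'
#' @param y Outcome value(s).
#' @param a Treatment indicator(s), 0/1.
#' @param d Source indicator(s), 0/1.
#' @param m1,m0 Outcome-regression values at the observation's covariates.
#' @param pi_a Treatment propensity in (0, 1).
#' @param pi_d Study propensity in (0, 1).
#' @param r Control-outcome variance ratio, positive.
#' @param tau Value of the target parameter at which to evaluate.
#' @param q Trial sampling fraction Pr(D = 1) in (0, 1].
#' @return Numeric influence value(s).
#' @export
eic_value <- function(y, a, d, m1, m0, pi_a, pi_d, r, tau, q) {
  stopifnot(all(q > 0 & q <= 1), all(pi_a > 0 & pi_a < 1),
            all(pi_d > 0 & pi_d <= 1), all(r > 0))
  w <- w_dr(a, d, pi_d, pi_a, r)
  (1 / q) * (d * (m1 - m0 - tau) + (d * a / pi_a) * (y - m1) -
               w * (y - m0))
}

#' Closed-form influence-curve confidence interval
#'
#' Normal-approximation interval tau_hat +/- z_{1 - alpha/2} * sd(phi) /
#' sqrt(n) with a two-sided p-value for H0: tau = 0 from the same
#' approximation.
#'
#' @param influence_values Numeric vector of estimated influence values
#'   (length >= 2).
#' @param tau_hat Point estimate.
#' @param alpha Two-sided level (default 0.05).
#' @return List with `lo`, `hi`, `se`, `p`, and logical `degenerate`
#'   (`TRUE` when the influence values have zero variance, in which case
#'   the interval collapses to the point estimate).
#' @export
closed_form_ci <- function(influence_values, tau_hat, alpha = 0.05) {
  n <- length(influence_values)
  if (n < 2L) stop("need at least two influence values")
  se <- stats::sd(influence_values) / sqrt(n)
  z <- stats::qnorm(1 - alpha / 2)
  if (se == 0) {
    p <- if (tau_hat == 0) 1 else 0
    return(list(lo = tau_hat, hi = tau_hat, se = 0, p = p,
                degenerate = TRUE))
  }
  list(lo = tau_hat - z * se, hi = tau_hat + z * se, se = se,
       p = 2 * stats::pnorm(-abs(tau_hat) / se), degenerate = FALSE)
}

#' AIPW estimate of the average treatment effect
#'
#' Solves the efficient-influence-curve estimating equation in closed
#' form: tau_aipw = n^{-1} sum_i (1/q_hat) \{ D_i [m1 - m0] +
#' (D_i A_i / pi_a) [Y_i - m1] - W^dr_i [Y_i - m0] \} with
#' q_hat = n_rct / n. The estimator is doubly robust (consistent if either
#' the outcome regressions or the study propensity score is consistently
#' estimated) and, with cross-fitted nuisances, semiparametric efficient
#' with the closed-form interval of [closed_form_ci()].
#'
#' @param data A [hybrid_data()] object.
#' @param fits A [fit_nuisances()] object.
#' @param alpha Two-sided CI level (default 0.05).
#' @return An `"effect_estimate"` with influence values stored; their
#'   empirical mean is zero by construction.
#' @export
estimate_tau_aipw <- function(data, fits, alpha = 0.05) {
  stopifnot(inherits(data, "hybrid_data"), inherits(fits, "nuisance_fits"))
  n <- data$n
  q <- data$n_rct / n
  p <- fits$pred
  phi_unc <- eic_value(data$y, data$a, data$d, p$m1, p$m0,
                       p$pi_a, p$pi_d, p$r, tau = 0, q = q)
  tau <- mean(phi_unc)
  phi <- phi_unc - (data$d / q) * tau
  ci <- closed_form_ci(phi, tau, alpha)
  new_effect_estimate("aipw", tau, ci$se, ci$lo, ci$hi, alpha, ci$p,
                      data$n_rct, data$n_ec, influence_values = phi,
                      metadata = list(q_hat = q, k_folds = fits$k_folds,
                                      trunc_eps = fits$trunc_eps,
                                      seed = fits$seed,
                                      degenerate_ci = ci$degenerate))
}

#' One-step TMLE fluctuation of the outcome regressions
#'
#' Maps the outcome and fitted regressions to [0, 1] using bounds
#' L = min(Y) - delta, U = max(Y) + delta, then fits a one-parameter
#' logistic fluctuation of the scaled outcome on the clever covariate
#' h(D, A, X) = (1/q_hat) \{ D A / pi_a - [D (1-A) pi_d +
#' (1-D)(1-A) pi_d r] / (pi_d (1 - pi_a) + (1 - pi_d) r) \}
#' with offset logit of the scaled fitted regression. Predictions under
#' A = 1 and A = 0 are back-transformed to the outcome scale, giving
#' updated regressions whose plug-in solves the efficient-influence-curve
#' equation after this single update.
#'
#' @param data A [hybrid_data()] object with a continuous outcome.
#' @param fits A [fit_nuisances()] object.
#' @param delta Widening of the scaling bounds (default 0: the sample
#'   range).
#' @return List with per-subject updated predictions `m1_star`, `m0_star`
#'   (outcome scale), the fluctuation coefficient `epsilon`, bounds `L`,
#'   `U`, and the clever covariate values `h1`, `h0` under A = 1 / A = 0.
#' @export
tmle_fluctuate <- function(data, fits, delta = 0) {
  stopifnot(inherits(data, "hybrid_data"), inherits(fits, "nuisance_fits"))
  n <- data$n
  q <- data$n_rct / n
  p <- fits$pred
  L <- min(data$y) - delta
  U <- max(data$y) + delta
  if (U <= L) stop("degenerate outcome: cannot scale to [0, 1]")
  sc <- function(v) (v - L) / (U - L)
  eps_b <- 1e-6  # keep scaled regressions inside (0, 1) for the logit
  h1 <- (1 / q) * (data$d / p$pi_a)
  h0 <- -(1 / q) * (p$pi_d * (data$d + (1 - data$d) * p$r)) /
    (p$pi_d * (1 - p$pi_a) + (1 - p$pi_d) * p$r)
  h_obs <- ifelse(data$a == 1L, h1, h0)
  ys <- clamp(sc(data$y), 0, 1)
  m_obs_s <- clamp(sc(ifelse(data$a == 1L, p$m1, p$m0)), eps_b, 1 - eps_b)
  off <- stats::qlogis(m_obs_s)
  fit <- tryCatch(
    suppressWarnings(stats::glm(
      ys ~ 0 + h_obs, offset = off, family = stats::quasibinomial(),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100))),
    error = function(e) stop("TMLE fluctuation fit failed: ",
                             conditionMessage(e)))
  if (!fit$converged) stop("TMLE fluctuation did not converge (epsilon = ",
                           format(stats::coef(fit)), ")")
  epsilon <- unname(stats::coef(fit))
  m1s <- clamp(sc(p$m1), eps_b, 1 - eps_b)
  m0s <- clamp(sc(p$m0), eps_b, 1 - eps_b)
  m1_star <- L + (U - L) * stats::plogis(stats::qlogis(m1s) + epsilon * h1)
  m0_star <- L + (U - L) * stats::plogis(stats::qlogis(m0s) + epsilon * h0)
  list(m1_star = m1_star, m0_star = m0_star, epsilon = epsilon,
       L = L, U = U, h1 = h1, h0 = h0)
}

#' TMLE estimate of the average treatment effect
#'
#' Plug-in estimator using the fluctuated regressions of
#' [tmle_fluctuate()]: tau_tmle = n_rct^{-1} sum_i D_i [m1*(X_i) -
#' m0*(X_i)]. As a plug-in it respects the bounds of the outcome scale in
#' every sample size; asymptotically it is equivalent to
#' [estimate_tau_aipw()] and shares its influence-curve interval.
#'
#' @inheritParams estimate_tau_aipw
#' @param delta Passed to [tmle_fluctuate()].
#' @return An `"effect_estimate"`; metadata records the fluctuation
#'   coefficient and the post-update mean of the estimated influence
#'   curve.
#' @export
estimate_tau_tmle <- function(data, fits, alpha = 0.05, delta = 0) {
  n <- data$n
  q <- data$n_rct / n
  fl <- tmle_fluctuate(data, fits, delta)
  tau <- sum(data$d * (fl$m1_star - fl$m0_star)) / data$n_rct
  p <- fits$pred
  phi <- eic_value(data$y, data$a, data$d, fl$m1_star, fl$m0_star,
                   p$pi_a, p$pi_d, p$r, tau = tau, q = q)
  ci <- closed_form_ci(phi, tau, alpha)
  new_effect_estimate("tmle", tau, ci$se, ci$lo, ci$hi, alpha, ci$p,
                      data$n_rct, data$n_ec, influence_values = phi,
                      metadata = list(q_hat = q, epsilon = fl$epsilon,
                                      eic_mean = mean(phi),
                                      bounds = c(fl$L, fl$U),
                                      k_folds = fits$k_folds,
                                      trunc_eps = fits$trunc_eps,
                                      seed = fits$seed,
                                      degenerate_ci = ci$degenerate))
}

#' Outcome-model (g-computation) estimate of the treatment effect
#'
#' tau_om = mean(Y | A = 1) - mu0_om. A singly robust estimator:
#' consistent when the pooled-control outcome regression is. Confidence
#' intervals are obtained by the nonparametric bootstrap
#' ([bootstrap_ci()]).
#'
#' @inheritParams estimate_tau_aipw
#' @return An `"effect_estimate"` (no closed-form interval; `se`, CI and
#'   p-value are `NA` unless filled in by [bootstrap_ci()]).
#' @export
estimate_tau_om <- function(data, fits, alpha = 0.05) {
  tau <- mu1_hat(data) - estimate_mu0_om(data, fits)
  new_effect_estimate("om", tau, NA_real_, NA_real_, NA_real_, alpha,
                      NA_real_, data$n_rct, data$n_ec,
                      metadata = list(k_folds = fits$k_folds))
}

#' IPDW estimate of the treatment effect
#'
#' tau_ipdw = mean(Y | A = 1) - mu0_ipdw. A singly robust estimator:
#' consistent when the study propensity score is. Confidence intervals are
#' obtained by the nonparametric bootstrap ([bootstrap_ci()]).
#'
#' @inheritParams estimate_mu0_ipdw
#' @param alpha Two-sided level recorded in the estimate.
#' @return An `"effect_estimate"` (no closed-form interval).
#' @export
estimate_tau_ipdw <- function(data, fits, alpha = 0.05, normalize = FALSE) {
  tau <- mu1_hat(data) - estimate_mu0_ipdw(data, fits, normalize)
  new_effect_estimate("ipdw", tau, NA_real_, NA_real_, NA_real_, alpha,
                      NA_real_, data$n_rct, data$n_ec,
                      metadata = list(normalize = normalize,
                                      k_folds = fits$k_folds))
}

#' RCT-only covariate-adjusted AIPW estimate
#'
#' Discards the external controls and computes the standard within-trial
#' AIPW estimator of the average treatment effect, with outcome
#' regressions refit on trial data only and the known design randomization
#' probability. Serves as the no-borrowing comparator.
#'
#' @param data A [hybrid_data()] object whose trial part contains both
#'   arms.
#' @param fits A [fit_nuisances()] object; its learner specification,
#'   fold count and seed are reused for the refit.
#' @param alpha Two-sided CI level.
#' @return An `"effect_estimate"` with influence-curve interval.
#' @export
estimate_tau_rct <- function(data, fits, alpha = 0.05) {
  stopifnot(inherits(data, "hybrid_data"), inherits(fits, "nuisance_fits"))
  idx <- which(data$d == 1L)
  if (length(idx) < 2L) stop("need at least two trial subjects")
  sub <- subset_hybrid(data, idx)
  if (sum(sub$a == 1L) < 1L || sum(sub$a == 0L) < 1L)
    stop("RCT-only estimator requires both arms within the trial")
  spec <- fits$spec
  k <- min(fits$k_folds, sub$n)
  n <- sub$n
  eps <- spec$trunc_eps
  fold_id <- stratified_folds(paste(sub$a), k, fits$seed)
  pa <- clamp(pi_a_vector(sub), eps, 1 - eps)
  m1v <- numeric(n); m0v <- numeric(n)
  fit_two <- function(train_idx, s) {
    tr1 <- train_idx[sub$a[train_idx] == 1L]
    tr0 <- train_idx[sub$a[train_idx] == 0L]
    if (!length(tr1) || !length(tr0))
      stop("cross-fitting split lost a trial arm")
    list(m1 = fit_learner(spec$m1, sub$x[tr1, , drop = FALSE], sub$y[tr1],
                          args = spec$m1_args, seed = s),
         m0 = fit_learner(spec$m0, sub$x[tr0, , drop = FALSE], sub$y[tr0],
                          args = spec$m0_args, seed = s + 1L))
  }
  if (k == 1L) {
    f <- fit_two(seq_len(n), fits$seed)
    m1v <- f$m1$predict(sub$x); m0v <- f$m0$predict(sub$x)
  } else {
    for (kk in seq_len(k)) {
      test <- which(fold_id == kk); train <- which(fold_id != kk)
      f <- fit_two(train, fits$seed + 13L * kk)
      xk <- sub$x[test, , drop = FALSE]
      m1v[test] <- f$m1$predict(xk); m0v[test] <- f$m0$predict(xk)
    }
  }
  # Standard trial AIPW: the hybrid EIC with pi_d = 1, r = 1, q = 1.
  phi_unc <- eic_value(sub$y, sub$a, sub$d, m1v, m0v, pa,
                       pi_d = rep(1, n), r = rep(1, n),
                       tau = 0, q = 1)
  tau <- mean(phi_unc)
  phi <- phi_unc - tau
  ci <- closed_form_ci(phi, tau, alpha)
  new_effect_estimate("rct_aipw", tau, ci$se, ci$lo, ci$hi, alpha, ci$p,
                      sub$n, 0L, influence_values = phi,
                      metadata = list(k_folds = k, seed = fits$seed,
                                      degenerate_ci = ci$degenerate))
}

#' Nonparametric bootstrap interval for the singly robust estimators
#'
#' Resamples subjects with replacement independently within the trial and
#' within the external source (preserving n_rct and n_ec), refits the
#' nuisance models on each resample, and recomputes the estimator. Returns
#' the percentile interval and a p-value obtained by interval inversion.
#'
#' @param data A [hybrid_data()] object.
#' @param estimator `"om"` or `"ipdw"`.
#' @param spec A [learner_spec()] used to refit nuisances per resample
#'   (no cross-fitting within resamples).
#' @param B Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Integer seed.
#' @param normalize Passed to [estimate_mu0_ipdw()] when
#'   `estimator = "ipdw"`.
#' @return List with `lo`, `hi`, `p`, the point estimate `tau_hat`, the
#'   bootstrap replicates `boot`, and the redraw count `n_redraw`
#'   (resamples that lost a required stratum are redrawn; a warning is
#'   issued when more than 10 percent required redraws).
#' @export
bootstrap_ci <- function(data, estimator = c("om", "ipdw"),
                         spec = learner_spec(), B = 1000L, alpha = 0.05,
                         seed = 1L, normalize = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(data, "hybrid_data"))
  point_fun <- function(dat, s) {
    fits <- fit_nuisances(dat, spec, k_folds = 1L, seed = s)
    if (estimator == "om") mu1_hat(dat) - estimate_mu0_om(dat, fits)
    else mu1_hat(dat) - estimate_mu0_ipdw(dat, fits, normalize)
  }
  tau_hat <- point_fun(data, seed)
  i1 <- which(data$d == 1L)
  i0 <- which(data$d == 0L)
  boot <- numeric(B)
  n_redraw <- 0L
  with_local_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- c(sample(i1, replace = TRUE),
                 if (length(i0)) sample(i0, replace = TRUE))
        ok <- any(data$a[idx] == 1L) && any(data$a[idx] == 0L)
        if (ok) break
        n_redraw <- n_redraw + 1L
      }
      boot[b] <- point_fun(subset_hybrid(data, idx), seed + b)
    }
  })
  if (n_redraw > 0.1 * B)
    warning("bootstrap: ", n_redraw, " resamples redrawn (> 10% of B)")
  lo <- unname(stats::quantile(boot, alpha / 2))
  hi <- unname(stats::quantile(boot, 1 - alpha / 2))
  # interval inversion: smallest level at which the percentile interval
  # excludes zero
  F0 <- mean(boot <= 0)
  p <- min(1, 2 * min(F0, 1 - F0))
  list(lo = lo, hi = hi, p = p, tau_hat = tau_hat, boot = boot,
       n_redraw = n_redraw)
}

#' Estimate the treatment effect by all methods
#'
#' Convenience wrapper running the RCT-only comparator and the four
#' hybrid estimators on one dataset, with bootstrap intervals for the
#' singly robust methods and influence-curve intervals for AIPW/TMLE.
#'
#' @param data A [hybrid_data()] object.
#' @param spec A [learner_spec()].
#' @param k_folds Cross-fitting folds for the doubly robust methods.
#' @param alpha Two-sided level.
#' @param boot_B Bootstrap resamples for om/ipdw intervals; `0` skips
#'   bootstrap intervals.
#' @param seed Integer seed.
#' @param methods Subset of `c("rct", "om", "ipdw", "aipw", "tmle")`.
#' @return A list of `"effect_estimate"` objects (invisibly also a
#'   combined data frame via `as.data.frame`).
#' @export
estimate_all <- function(data, spec = learner_spec(), k_folds = 10L,
                         alpha = 0.05, boot_B = 1000L, seed = 1L,
                         methods = c("rct", "om", "ipdw", "aipw", "tmle")) {
  methods <- match.arg(methods, several.ok = TRUE)
  fits <- fit_nuisances(data, spec, k_folds = k_folds, seed = seed)
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(
      m,
      rct = estimate_tau_rct(data, fits, alpha),
      aipw = estimate_tau_aipw(data, fits, alpha),
      tmle = estimate_tau_tmle(data, fits, alpha),
      om = {
        est <- estimate_tau_om(data, fits, alpha)
        if (boot_B > 0L) {
          bc <- bootstrap_ci(data, "om", spec, B = boot_B, alpha = alpha,
                             seed = seed)
          est$ci_low <- bc$lo; est$ci_high <- bc$hi; est$p_value <- bc$p
          est$metadata$boot_B <- boot_B
        }
        est
      },
      ipdw = {
        est <- estimate_tau_ipdw(data, fits, alpha)
        if (boot_B > 0L) {
          bc <- bootstrap_ci(data, "ipdw", spec, B = boot_B, alpha = alpha,
                             seed = seed)
          est$ci_low <- bc$lo; est$ci_high <- bc$hi; est$p_value <- bc$p
          est$metadata$boot_B <- boot_B
        }
        est
      })
  }
  attr(out, "fits") <- fits
  class(out) <- "effect_estimate_list"
  out
}

#' @export
print.effect_estimate_list <- function(x, ...) {
  df <- do.call(rbind, lapply(x, as.data.frame))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.effect_estimate_list <- function(x, ...) {
  do.call(rbind, lapply(x, as.data.frame))
}
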