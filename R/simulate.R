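# Synthetic hybrid-trial generator and simulation engine. The generator
# emulates the motivating design: a trial of 150 patients randomized 2:1
# to treatment plus 50 external controls, a continuous endpoint, a
# non-constant study propensity (so treatment and source are dependent),
# and configurable nonlinearity so that linear analyst models can be made
# genuinely misspecified.

#' Configure the hybrid-trial simulation
#'
#' Defines the data-generating process and the analyst's learner choices.
#' Covariates are two standard normal and two Bernoulli(0.5) variables.
#' The study propensity is logistic,
#' pi_d(x) = expit(alpha0 + alpha1 x1 + alpha2 x2 + alpha_quad x1^2),
#' and the control outcome surface is
#' m0(x) = beta0 + beta' x + gamma1 x1^2 + gamma2 x1 x2, with
#' Y = m0(X) + tau A + Normal(0, noise_sd) errors. Under the linear truth
#' (settings 1) `alpha_quad` and `gamma` are zero so that linear/logistic
#' analyst models are correctly specified; under the nonlinear truth
#' (settings 2-5) they are nonzero, making those models genuinely
#' misspecified.
#'
#' @param n_rct Trial sample size (default 150).
#' @param n_ec External-control sample size (default 50).
#' @param rand_ratio Treated:control randomization ratio within the trial
#'   (default 2, i.e. 2:1, so pi_a = 2/3).
#' @param tau Constant treatment effect (default 1).
#' @param tau_slope Optional heterogeneity: the unit-level effect is
#'   `tau + tau_slope * x1` (default 0, homogeneous).
#' @param alpha0,alpha_linear,alpha_quad Study-propensity coefficients
#'   (intercept, the two slopes on x1/x2, and the x1^2 coefficient).
#' @param beta0,beta Outcome intercept and linear coefficients (length 4).
#' @param gamma Nonlinear outcome coefficients `c(gamma1, gamma2)` for
#'   x1^2 and x1*x2.
#' @param noise_sd Outcome noise standard deviation (default 1).
#' @param u_shift Injected violation of mean exchangeability: external
#'   controls' mean outcome is lowered by `u_shift` at every covariate
#'   value, so the source difference u(X) equals `u_shift` (default 0:
#'   the assumption holds by construction).
#' @param setting Optional analysis setting 1-5 binding the truth and the
#'   analyst learners (see [setting_spec()]); `NULL` leaves the truth as
#'   given.
#' @param nonlinear Force the nonlinear truth regardless of `setting`.
#' @param k_folds Cross-fitting folds used by the study driver
#'   (default 10).
#' @param rf_args Hyperparameters for the random-forest learners used in
#'   the machine-learning settings.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_rct = 150L, n_ec = 50L, rand_ratio = 2,
                       tau = 1, tau_slope = 0,
                       alpha0 = 1.3, alpha_linear = c(0.7, 0.4),
                       alpha_quad = NULL,
                       beta0 = 0, beta = c(1, 0.8, 0.5, 0.5),
                       gamma = NULL, noise_sd = 1, u_shift = 0,
                       setting = NULL, nonlinear = NULL, k_folds = 10L,
                       rf_args = list(num.trees = 200L)) {
  if (!is.null(setting)) {
    stopifnot(setting %in% 1:5)
    if (is.null(nonlinear)) nonlinear <- setting != 1L
  }
  if (is.null(nonlinear)) nonlinear <- !is.null(gamma) || !is.null(alpha_quad)
  if (is.null(alpha_quad)) alpha_quad <- if (nonlinear) -0.8 else 0
  if (is.null(gamma)) gamma <- if (nonlinear) c(0.8, 0.6) else c(0, 0)
  stopifnot(n_rct >= 2L, n_ec >= 0L, rand_ratio > 0, noise_sd > 0,
            length(alpha_linear) == 2L, length(beta) == 4L,
            length(gamma) == 2L)
  structure(list(n_rct = as.integer(n_rct), n_ec = as.integer(n_ec),
                 rand_ratio = rand_ratio,
                 pi_a = rand_ratio / (rand_ratio + 1),
                 tau = tau, tau_slope = tau_slope,
                 alpha0 = alpha0, alpha_linear = alpha_linear,
                 alpha_quad = alpha_quad,
                 beta0 = beta0, beta = beta, gamma = gamma,
                 noise_sd = noise_sd, u_shift = u_shift,
                 setting = setting, nonlinear = nonlinear,
                 k_folds = as.integer(k_folds), rf_args = rf_args),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Hybrid-trial simulation configuration\n")
  cat(sprintf("  n_rct = %d (pi_a = %.3f), n_ec = %d, tau = %g\n",
              x$n_rct, x$pi_a, x$n_ec, x$tau))
  cat(sprintf("  truth: %s (alpha_quad = %g, gamma = %g, %g)\n",
              if (x$nonlinear) "nonlinear" else "linear",
              x$alpha_quad, x$gamma[1], x$gamma[2]))
  if (!is.null(x$setting)) cat("  analysis setting:", x$setting, "\n")
  invisible(x)
}

# True study propensity and control-outcome surface of the generator.
sim_pi_d <- function(config, x) {
  stats::plogis(config$alpha0 + config$alpha_linear[1] * x[, 1] +
                  config$alpha_linear[2] * x[, 2] +
                  config$alpha_quad * x[, 1]^2)
}

sim_m0 <- function(config, x) {
  config$beta0 + as.numeric(x %*% config$beta) +
    config$gamma[1] * x[, 1]^2 + config$gamma[2] * x[, 1] * x[, 2]
}

#' Learner specification for a simulation setting
#'
#' Maps the analysis settings to analyst learner choices:
#' \describe{
#'   \item{1}{linear outcome models and logistic study propensity
#'     (correctly specified under the linear truth);}
#'   \item{2}{random-forest outcome models, logistic-linear study
#'     propensity (misspecified under the nonlinear truth);}
#'   \item{3}{linear outcome models (misspecified), random-forest study
#'     propensity;}
#'   \item{4}{linear/logistic for both (both misspecified);}
#'   \item{5}{random forests for both.}
#' }
#'
#' @param setting Integer 1-5.
#' @param rf_args Random-forest hyperparameters.
#' @return A [learner_spec()].
#' @export
setting_spec <- function(setting, rf_args = list(num.trees = 200L)) {
  stopifnot(setting %in% 1:5)
  rf <- "random_forest"
  switch(as.character(setting),
         "1" = learner_spec(),
         "2" = learner_spec(m1 = rf, m0 = rf, pi_d = "logistic",
                            m1_args = rf_args, m0_args = rf_args),
         "3" = learner_spec(m1 = "linear", m0 = "linear", pi_d = rf,
                            pi_d_args = rf_args),
         "4" = learner_spec(),
         "5" = learner_spec(m1 = rf, m0 = rf, pi_d = rf,
                            m1_args = rf_args, m0_args = rf_args,
                            pi_d_args = rf_args))
}

#' Simulate one hybrid trial
#'
#' Draws covariates from the base population, assigns the source by the
#' study propensity (rejection sampling until exactly `n_rct` trial and
#' `n_ec` external subjects are collected), randomizes treatment within
#' the trial, and generates outcomes. Mean exchangeability holds by
#' construction unless `u_shift` is nonzero.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (config, seed) pairs give
#'   identical datasets.
#' @return A [hybrid_data()] object.
#' @export
simulate_trial <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  need_rct <- config$n_rct
  need_ec <- config$n_ec
  cap <- 400L * (need_rct + need_ec)
  with_local_seed(seed, {
    rows <- list(); drawn <- 0L
    got_rct <- 0L; got_ec <- 0L
    while ((got_rct < need_rct || got_ec < need_ec) && drawn < cap) {
      m <- max(2L * (need_rct + need_ec), 64L)
      x <- cbind(x1 = stats::rnorm(m), x2 = stats::rnorm(m),
                 x3 = stats::rbinom(m, 1L, 0.5),
                 x4 = stats::rbinom(m, 1L, 0.5))
      dvec <- stats::rbinom(m, 1L, sim_pi_d(config, x))
      drawn <- drawn + m
      for (i in seq_len(m)) {
        if (dvec[i] == 1L && got_rct < need_rct) {
          got_rct <- got_rct + 1L
          rows[[length(rows) + 1L]] <- c(x[i, ], d = 1)
        } else if (dvec[i] == 0L && got_ec < need_ec) {
          got_ec <- got_ec + 1L
          rows[[length(rows) + 1L]] <- c(x[i, ], d = 0)
        }
        if (got_rct >= need_rct && got_ec >= need_ec) break
      }
    }
    if (got_rct < need_rct || got_ec < need_ec)
      stop("could not attain the requested source counts after ", cap,
           " draws; adjust alpha0 toward the desired trial fraction")
    mat <- do.call(rbind, rows)
    x <- mat[, 1:4, drop = FALSE]
    d <- as.integer(mat[, "d"])
    n <- nrow(x)
    a <- integer(n)
    a[d == 1L] <- stats::rbinom(sum(d == 1L), 1L, config$pi_a)
    tau_i <- config$tau + config$tau_slope * x[, 1]
    y <- sim_m0(config, x) + tau_i * a +
      stats::rnorm(n, 0, config$noise_sd)
    y[d == 0L] <- y[d == 0L] - config$u_shift
    hybrid_data(y = y, a = a, d = d, x = x, pi_a = config$pi_a)
  })
}

#' Run a replicated simulation study
#'
#' Per replicate: simulate a trial, fit (cross-fitted) nuisances with the
#' setting's learners, estimate the treatment effect by the requested
#' methods, and record point estimates and confidence intervals.
#' Aggregates bias, mean squared error, 95% CI coverage of the true
#' effect, and the rejection rate of the zero-effect null.
#'
#' @param config A [sim_config()] (its `setting` picks the learners;
#'   default setting 1).
#' @param methods Subset of `c("rct", "om", "ipdw", "aipw", "tmle")`. In
#'   setting 2 the outcome-model estimator is skipped and in setting 3
#'   the weighting estimator is skipped (their defining nuisance is the
#'   flexible one there, so the singly robust contrast is not
#'   meaningful).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param alpha CI level (default 0.05).
#' @param boot_B Bootstrap resamples for om/ipdw intervals; `0` (default)
#'   records only their point estimates (coverage/rejection are `NA`).
#' @return An object of class `"sim_result"`: a data frame with one row
#'   per method (bias, mse, coverage, rejection, n_reps, n_fail).
#' @export
run_study <- function(config = sim_config(setting = 1L),
                      methods = c("rct", "aipw", "tmle"),
                      n_reps = 1000L, seed = 1L, alpha = 0.05,
                      boot_B = 0L) {
  stopifnot(inherits(config, "sim_config"))
  methods <- match.arg(methods,
                       c("rct", "om", "ipdw", "aipw", "tmle"),
                       several.ok = TRUE)
  setting <- config$setting %||% 1L
  if (setting == 2L && "om" %in% methods) {
    message("setting 2: skipping the outcome-model estimator")
    methods <- setdiff(methods, "om")
  }
  if (setting == 3L && "ipdw" %in% methods) {
    message("setting 3: skipping the weighting estimator")
    methods <- setdiff(methods, "ipdw")
  }
  spec <- setting_spec(setting, config$rf_args)
  tau_true <- config$tau
  rec <- list()
  n_fail <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    dat <- simulate_trial(config, rep_seed)
    fits <- tryCatch(
      fit_nuisances(dat, spec, k_folds = config$k_folds, seed = rep_seed),
      error = function(e) NULL)
    if (is.null(fits)) { n_fail[] <- n_fail + 1L; next }
    for (m in methods) {
      est <- tryCatch(switch(
        m,
        rct = estimate_tau_rct(dat, fits, alpha),
        aipw = estimate_tau_aipw(dat, fits, alpha),
        tmle = estimate_tau_tmle(dat, fits, alpha),
        om = {
          e <- estimate_tau_om(dat, fits, alpha)
          if (boot_B > 0L) {
            bc <- bootstrap_ci(dat, "om", spec, B = boot_B,
                               alpha = alpha, seed = rep_seed)
            e$ci_low <- bc$lo; e$ci_high <- bc$hi; e$p_value <- bc$p
          }
          e
        },
        ipdw = {
          e <- estimate_tau_ipdw(dat, fits, alpha)
          if (boot_B > 0L) {
            bc <- bootstrap_ci(dat, "ipdw", spec, B = boot_B,
                               alpha = alpha, seed = rep_seed)
            e$ci_low <- bc$lo; e$ci_high <- bc$hi; e$p_value <- bc$p
          }
          e
        }), error = function(e) NULL)
      if (is.null(est)) { n_fail[m] <- n_fail[m] + 1L; next }
      rec[[length(rec) + 1L]] <- data.frame(
        rep = r, method = m, tau_hat = est$tau_hat, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  if (any(n_fail > 0.01 * n_reps))
    warning("more than 1% of replicates failed for: ",
            paste(names(n_fail)[n_fail > 0.01 * n_reps], collapse = ", "))
  long <- do.call(rbind, rec)
  agg <- do.call(rbind, lapply(methods, function(m) {
    sub <- long[long$method == m, , drop = FALSE]
    has_ci <- is.finite(sub$ci_low) & is.finite(sub$ci_high)
    data.frame(
      setting = setting, method = m, n_reps = nrow(sub),
      n_fail = n_fail[[m]],
      bias = mean(sub$tau_hat) - tau_true,
      mse = mean((sub$tau_hat - tau_true)^2),
      coverage = if (any(has_ci))
        mean(sub$ci_low[has_ci] <= tau_true &
               sub$ci_high[has_ci] >= tau_true) else NA_real_,
      rejection = if (any(has_ci))
        mean(sub$ci_low[has_ci] > 0 | sub$ci_high[has_ci] < 0)
      else NA_real_,
      mean_se = mean(sub$se[is.finite(sub$se)]),
      emp_se = stats::sd(sub$tau_hat),
      stringsAsFactors = FALSE)
  }))
  structure(list(summary = agg, replicates = long, config = config,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation study (setting", x$summary$setting[1], "):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Power and type-I error over effect-size and sample-size grids
#'
#' Replicates the study over a grid of treatment effects and/or
#' external-control sample sizes, reporting the rejection rate of the
#' zero-effect null for the doubly robust estimators and the RCT-only
#' comparator. At `tau = 0` the rejection rate is the type-I error.
#'
#' @param config Base [sim_config()].
#' @param tau_grid Numeric vector of treatment effects (default the
#'   config's `tau`).
#' @param n_ec_grid Integer vector of external-control sample sizes
#'   (default the config's `n_ec`).
#' @param methods Methods to evaluate (default aipw, tmle, rct).
#' @param n_reps Replicates per grid point.
#' @param seed Integer seed.
#' @param alpha Test level (default 0.05).
#' @return Data frame with columns `tau`, `n_ec`, `method`, `rejection`,
#'   `n_reps`, plus class `"power_result"`.
#' @export
power_analysis <- function(config = sim_config(setting = 5L),
                           tau_grid = NULL, n_ec_grid = NULL,
                           methods = c("aipw", "tmle", "rct"),
                           n_reps = 500L, seed = 1L, alpha = 0.05) {
  tau_grid <- tau_grid %||% config$tau
  n_ec_grid <- n_ec_grid %||% config$n_ec
  stopifnot(length(tau_grid) >= 1L, length(n_ec_grid) >= 1L)
  out <- list()
  cell <- 0L
  for (ne in n_ec_grid) for (tv in tau_grid) {
    cell <- cell + 1L
    cfg <- config
    cfg$tau <- tv
    cfg$n_ec <- as.integer(ne)
    res <- run_study(cfg, methods = methods, n_reps = n_reps,
                     seed = seed + 100000L * cell, alpha = alpha)
    s <- res$summary
    out[[cell]] <- data.frame(tau = tv, n_ec = ne, method = s$method,
                              rejection = s$rejection, n_reps = s$n_reps,
                              stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("power_result", "data.frame"))
}
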