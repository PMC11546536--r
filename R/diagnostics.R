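# Diagnostics for hybrid trials: covariate balance between control arms,
# a binned visual check of mean exchangeability across sources, and a
# sensitivity analysis propagating violations of that assumption into the
# treatment-effect interval.

#' Normalized difference between two covariate samples
#'
#' Multivariate balance statistic
#' Delta_x = sqrt( 2 (xbar_1 - xbar_0)' (Sigma_1 + Sigma_0)^{-1}
#'                 (xbar_1 - xbar_0) ),
#' where the means and covariance matrices are computed within each
#' sample. By convention here sample 1 is the internal controls and
#' sample 0 the external controls.
#'
#' @param x1,x0 Numeric matrices with the same number of columns and at
#'   least two rows each.
#' @return A nonnegative scalar; 0 under identical sample moments. If the
#'   summed covariance matrix is singular the Moore-Penrose pseudo-inverse
#'   is used with a warning.
#' @export
normalized_difference <- function(x1, x0) {
  if (is.null(dim(x1))) x1 <- matrix(x1, ncol = 1L)
  if (is.null(dim(x0))) x0 <- matrix(x0, ncol = 1L)
  if (ncol(x1) != ncol(x0))
    stop("x1 and x0 must have the same number of covariates")
  if (nrow(x1) < 2L || nrow(x0) < 2L)
    stop("need at least two rows per sample")
  dbar <- colMeans(x1) - colMeans(x0)
  S <- stats::cov(x1) + stats::cov(x0)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("covariance sum is singular; using pseudo-inverse")
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  val <- 2 * as.numeric(t(dbar) %*% Sinv %*% dbar)
  sqrt(max(val, 0))
}

#' Study-propensity imbalance between sources
#'
#' Difference of the average estimated study propensity score between
#' trial subjects and external controls:
#' Delta_pi_d = n_rct^{-1} sum_i D_i pi_d(X_i) -
#'              n_ec^{-1} sum_i (1 - D_i) pi_d(X_i).
#' Values above 0.25 are flagged as notable imbalance (a reporting
#' reference only, never a gate: hypothesis tests on balance statistics
#' are not a basis for inclusion decisions).
#'
#' @param data A [hybrid_data()] object with at least one external
#'   control.
#' @param fits A [fit_nuisances()] object.
#' @return Numeric scalar with attribute `"flagged"` (`TRUE` when the
#'   absolute value exceeds 0.25).
#' @export
propensity_imbalance <- function(data, fits) {
  stopifnot(inherits(data, "hybrid_data"), inherits(fits, "nuisance_fits"))
  if (data$n_ec == 0L)
    stop("propensity imbalance requires external controls")
  pd <- fits$pred$pi_d
  val <- sum(data$d * pd) / data$n_rct -
    sum((1 - data$d) * pd) / data$n_ec
  attr(val, "flagged") <- abs(val) > 0.25
  val
}

#' Binned diagnostic of mean exchangeability across sources
#'
#' Under the borrowing assumption, control outcomes have the same
#' conditional mean in both sources given the study propensity score.
#' This diagnostic buckets all controls by their estimated propensity
#' score in fixed-width bins and reports, per bin and source, the count,
#' mean outcome, and a normal 95% confidence interval — systematic
#' between-source gaps within bins indicate a violation.
#'
#' @param data A [hybrid_data()] object with controls in both sources.
#' @param fits A [fit_nuisances()] object.
#' @param bin_width Width of the propensity bins (default 0.05).
#' @return Data frame with columns `bin` (interval label), `bin_mid`,
#'   `group` (`"internal"`/`"external"`), `n`, `mean_y`, `ci_lo`, `ci_hi`
#'   (the interval fields are `NA` for bins with fewer than two controls
#'   in a source).
#' @export
a4_bin_diagnostic <- function(data, fits, bin_width = 0.05) {
  stopifnot(inherits(data, "hybrid_data"), inherits(fits, "nuisance_fits"))
  ctl <- which(data$a == 0L)
  if (!length(ctl)) {
    warning("no controls; empty diagnostic")
    return(data.frame(bin = character(), bin_mid = numeric(),
                      group = character(), n = integer(),
                      mean_y = numeric(), ci_lo = numeric(),
                      ci_hi = numeric()))
  }
  pd <- fits$pred$pi_d[ctl]
  y <- data$y[ctl]
  src <- ifelse(data$d[ctl] == 1L, "internal", "external")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- cut(pd, breaks = breaks, include.lowest = TRUE)
  out <- list()
  z <- stats::qnorm(0.975)
  for (b in levels(bin)) {
    for (g in c("internal", "external")) {
      sel <- which(bin == b & src == g)
      if (!length(sel)) next
      m <- mean(y[sel])
      if (length(sel) >= 2L) {
        half <- z * stats::sd(y[sel]) / sqrt(length(sel))
        ci <- c(m - half, m + half)
      } else ci <- c(NA_real_, NA_real_)
      lo_edge <- breaks[match(b, levels(bin))]
      out[[length(out) + 1L]] <- data.frame(
        bin = b, bin_mid = lo_edge + bin_width / 2, group = g,
        n = length(sel), mean_y = m, ci_lo = ci[1], ci_hi = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no populated propensity bins")
    return(data.frame(bin = character(), bin_mid = numeric(),
                      group = character(), n = integer(),
                      mean_y = numeric(), ci_lo = numeric(),
                      ci_hi = numeric()))
  }
  do.call(rbind, out)
}

#' Plug-in estimate of the asymptotic bias from a borrowing violation
#'
#' When mean exchangeability fails by u(X) = E[Y | A=0, D=1, X] -
#' E[Y | A=0, D=0, X], the asymptotic bias of the external-control
#' estimators is E[ Pr(D=0 | A=0, X) u(X) | D=1 ]. This function fits the
#' two control-outcome regressions separately by source, takes their
#' difference as u-hat, fits Pr(D=0 | A=0, X) among controls, and returns
#' the plug-in average of the product over trial subjects. The factored
#' upper-bound form Pr(D=0 | A=0) * E[u(X) | D=1] is also reported.
#'
#' @param data A [hybrid_data()] object with controls in both sources.
#' @param spec A [learner_spec()]; the `m0` learner is used for the
#'   source-specific control regressions and the `pi_d` learner for
#'   Pr(D=0 | A=0, X).
#' @param min_per_source Minimum controls required per source to fit the
#'   regressions (default 10); below it an error suggests the constant-B
#'   sensitivity mode of [tipping_point()].
#' @param seed Integer seed for stochastic learners.
#' @return An object of class `"sensitivity_result"`: a list with
#'   `bias_hat`, `u_hat` (prediction function of a covariate matrix),
#'   `pr_d0_given_a0` (marginal), `mean_u_rct` (E-hat[u(X) | D=1]), and
#'   `bound_factored` = `pr_d0_given_a0 * mean_u_rct`.
#' @export
estimate_bias_bound <- function(data, spec = learner_spec(),
                                min_per_source = 10L, seed = 1L) {
  stopifnot(inherits(data, "hybrid_data"))
  ic <- which(data$d == 1L & data$a == 0L)
  ec <- which(data$d == 0L)
  if (length(ic) < min_per_source || length(ec) < min_per_source)
    stop("too few controls in a source (< ", min_per_source,
         ") to fit source-specific regressions; consider a constant-B ",
         "sensitivity analysis via tipping_point()")
  f_ic <- fit_learner(spec$m0, data$x[ic, , drop = FALSE], data$y[ic],
                      args = spec$m0_args, seed = seed)
  f_ec <- fit_learner(spec$m0, data$x[ec, , drop = FALSE], data$y[ec],
                      args = spec$m0_args, seed = seed + 1L)
  u_hat <- function(x) f_ic$predict(x) - f_ec$predict(x)
  ctl <- c(ic, ec)
  lbl <- as.integer(data$d[ctl] == 0L)  # 1 = external among controls
  f_pd0 <- fit_learner(spec$pi_d, data$x[ctl, , drop = FALSE], lbl,
                       binary = TRUE, args = spec$pi_d_args,
                       seed = seed + 2L)
  rct <- which(data$d == 1L)
  xr <- data$x[rct, , drop = FALSE]
  uv <- u_hat(xr)
  pv <- f_pd0$predict(xr)
  pr_marg <- length(ec) / length(ctl)
  structure(list(bias_hat = mean(pv * uv),
                 u_hat = u_hat,
                 pr_d0_given_a0 = pr_marg,
                 mean_u_rct = mean(uv),
                 bound_factored = pr_marg * mean(uv)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sensitivity analysis for the borrowing assumption\n")
  cat(sprintf("  plug-in bias estimate: %.4g\n", x$bias_hat))
  cat(sprintf("  Pr(D=0 | A=0) = %.3f,  E[u(X) | D=1] = %.4g\n",
              x$pr_d0_given_a0, x$mean_u_rct))
  cat(sprintf("  factored bound: %.4g\n", x$bound_factored))
  invisible(x)
}

#' Tipping-point magnitude of a borrowing violation
#'
#' For a constant violation of magnitude B, the treatment-effect estimate
#' shifts by Pr(D=0 | A=0) * B. This returns the smallest nonnegative B
#' such that shifting the confidence interval toward zero by
#' Pr(D=0 | A=0) * B makes it include zero; 0 when the interval already
#' includes zero. Closed form: the CI bound nearer zero divided by
#' Pr(D=0 | A=0).
#'
#' @param estimate An `"effect_estimate"` with a confidence interval.
#' @param pr_d0_given_a0 Marginal probability that a control subject is
#'   external, in (0, 1).
#' @return Nonnegative scalar B.
#' @export
tipping_point <- function(estimate, pr_d0_given_a0) {
  stopifnot(inherits(estimate, "effect_estimate"),
            pr_d0_given_a0 > 0, pr_d0_given_a0 < 1)
  lo <- estimate$ci_low
  hi <- estimate$ci_high
  if (!is.finite(lo) || !is.finite(hi))
    stop("estimate carries no confidence interval")
  if (lo <= 0 && hi >= 0) return(0)
  if (lo > 0) lo / pr_d0_given_a0 else -hi / pr_d0_given_a0
}

#' Shift a confidence interval under an assumed violation magnitude
#'
#' @param estimate An `"effect_estimate"` with a confidence interval.
#' @param B Assumed constant violation magnitude (may be negative).
#' @param pr_d0_given_a0 Marginal probability that a control is external.
#' @return Numeric `c(lo, hi)`: the interval shifted by
#'   `-sign(tau) * pr_d0_given_a0 * B`; its width equals the original
#'   width.
#' @export
shifted_ci <- function(estimate, B, pr_d0_given_a0) {
  stopifnot(inherits(estimate, "effect_estimate"))
  shift <- -sign(estimate$tau_hat) * pr_d0_given_a0 * B
  c(lo = estimate$ci_low + shift, hi = estimate$ci_high + shift)
}
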