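#' Fit (cross-fitted) nuisance functions for hybrid-trial estimation
#'
#' Fits the outcome regressions m1 and m0, the study propensity score
#' pi_d, the treatment propensity pi_a, and the control-outcome variance
#' ratio r, optionally with K-fold cross-fitting so that each subject's
#' stored prediction comes from models trained on the other folds. Cross
#' fitting permits flexible machine-learning learners while retaining
#' root-n inference for the doubly robust estimators.
#'
#' @param data A [hybrid_data()] object.
#' @param spec A [learner_spec()]; default all-parametric (linear outcome
#'   models, logistic study propensity).
#' @param k_folds Number of cross-fitting folds; `1` disables cross-fitting
#'   (every stored prediction comes from models fit on all subjects).
#'   Default 10.
#' @param seed Integer seed controlling the fold partition and any
#'   stochastic learner.
#'
#' @return An object of class `"nuisance_fits"` with elements:
#'   \describe{
#'     \item{pred}{data frame of per-subject predictions `m1`, `m0`,
#'       `pi_d`, `pi_a`, `r` (out-of-fold when `k_folds > 1`; propensities
#'       already truncated to `[trunc_eps, 1 - trunc_eps]`).}
#'     \item{m1_hat, m0_hat, pi_d_hat, pi_a_hat, r_hat}{prediction
#'       functions (fit on all subjects) mapping a covariate matrix to
#'       predictions, for use on new data.}
#'     \item{fold_id}{integer fold label per subject (all 0 when
#'       `k_folds = 1`).}
#'   }
#'
#' @details m1 is fit among treated subjects (all of whom are in the
#'   trial); m0 is fit on the pooled internal and external controls; pi_d
#'   is fit on all subjects with label D. Folds are assigned by a seeded
#'   random partition stratified by (A, D) so each training split contains
#'   treated, internal-control, and external-control units.
#'
#' @seealso [estimate_tau_aipw()], [estimate_tau_tmle()]
#' @export
fit_nuisances <- function(data, spec = learner_spec(), k_folds = 10L,
                          seed = 1L) {
  stopifnot(inherits(data, "hybrid_data"), inherits(spec, "learner_spec"))
  n <- data$n
  if (k_folds < 1L || k_folds > n) stop("k_folds must lie in 1..n")
  k_folds <- as.integer(k_folds)
  if (sum(data$a == 1L) < 1L)
    stop("no treated subjects: cannot fit m1")
  if (sum(data$a == 0L) < 1L)
    stop("no control subjects: cannot fit m0")
  eps <- spec$trunc_eps
  strata <- paste(data$a, data$d)
  fold_id <- stratified_folds(strata, k_folds, seed)

  pa_design <- pi_a_vector(data)
  pred <- data.frame(m1 = numeric(n), m0 = numeric(n),
                     pi_d = numeric(n), pi_a = pa_design, r = 1)

  fit_three <- function(train_idx, fold_seed) {
    tr1 <- train_idx[data$a[train_idx] == 1L]
    tr0 <- train_idx[data$a[train_idx] == 0L]
    if (length(tr1) == 0L) stop("cross-fitting split has no treated units")
    if (length(tr0) == 0L) stop("cross-fitting split has no control units")
    list(
      m1 = fit_learner(spec$m1, data$x[tr1, , drop = FALSE], data$y[tr1],
                       binary = FALSE, args = spec$m1_args,
                       seed = fold_seed),
      m0 = fit_learner(spec$m0, data$x[tr0, , drop = FALSE], data$y[tr0],
                       binary = FALSE, args = spec$m0_args,
                       seed = fold_seed + 1L),
      pi_d = fit_learner(spec$pi_d, data$x[train_idx, , drop = FALSE],
                         data$d[train_idx], binary = TRUE,
                         args = spec$pi_d_args, seed = fold_seed + 2L))
  }

  if (k_folds == 1L) {
    full <- fit_three(seq_len(n), seed)
    pred$m1 <- full$m1$predict(data$x)
    pred$m0 <- full$m0$predict(data$x)
    pred$pi_d <- clamp(full$pi_d$predict(data$x), eps, 1 - eps)
  } else {
    for (k in seq_len(k_folds)) {
      test <- which(fold_id == k)
      train <- which(fold_id != k)
      fits_k <- fit_three(train, seed + 13L * k)
      xk <- data$x[test, , drop = FALSE]
      pred$m1[test] <- fits_k$m1$predict(xk)
      pred$m0[test] <- fits_k$m0$predict(xk)
      pred$pi_d[test] <- clamp(fits_k$pi_d$predict(xk), eps, 1 - eps)
    }
    full <- fit_three(seq_len(n), seed)
  }

  if (identical(spec$pi_a, "logistic") || is.list(spec$pi_a)) {
    kind <- if (is.list(spec$pi_a)) spec$pi_a else "logistic"
    rct <- which(data$d == 1L)
    pa_fit <- fit_learner(kind, data$x[rct, , drop = FALSE], data$a[rct],
                          binary = TRUE, seed = seed + 7L)
    pred$pi_a <- clamp(pa_fit$predict(data$x), eps, 1 - eps)
    pi_a_hat <- function(x) clamp(pa_fit$predict(x), eps, 1 - eps)
  } else {
    pred$pi_a <- clamp(pa_design, eps, 1 - eps)
    pi_a_hat <- local({
      des <- data$pi_a_design
      function(x) {
        p <- if (is.function(des)) apply(x, 1L, des) else rep(des, nrow(x))
        clamp(p, eps, 1 - eps)
      }
    })
  }

  r_hat <- estimate_variance_ratio(data, pred$m0, mode = spec$r_mode)
  pred$r <- r_hat(data$x)

  structure(
    list(pred = pred,
         m1_hat = function(x) full$m1$predict(x),
         m0_hat = function(x) full$m0$predict(x),
         pi_d_hat = function(x) clamp(full$pi_d$predict(x), eps, 1 - eps),
         pi_a_hat = pi_a_hat,
         r_hat = r_hat,
         fold_id = fold_id, k_folds = k_folds,
         spec = spec, trunc_eps = eps, seed = seed),
    class = "nuisance_fits")
}

#' @export
print.nuisance_fits <- function(x, ...) {
  lab <- function(l) if (is.list(l)) "user-supplied" else l
  cat("Nuisance fits (", if (x$k_folds > 1L)
    paste0(x$k_folds, "-fold cross-fit") else "no cross-fitting", ")\n",
    sep = "")
  cat("  m1:", lab(x$spec$m1), " m0:", lab(x$spec$m0),
      " pi_d:", lab(x$spec$pi_d), " pi_a:", lab(x$spec$pi_a), "\n")
  cat("  r mode:", x$spec$r_mode,
      " truncation:", x$trunc_eps, "\n")
  invisible(x)
}

#' Estimate the control-outcome variance ratio between sources
#'
#' The efficient influence curve involves the ratio r of conditional
#' control-outcome variances between the trial and the external source.
#' It is modelled here as a constant: either fixed at 1 (homoscedastic
#' across sources, the default) or estimated as the ratio of mean squared
#' residuals of internal versus external controls about the pooled control
#' regression m0.
#'
#' @param data A [hybrid_data()] object.
#' @param m0_hat Either a numeric vector of per-subject m0 predictions
#'   aligned with `data`, or a prediction function of the covariate matrix.
#' @param mode `"constant_one"` or `"pooled_ratio"`.
#' @param floor Lower bound for the estimated ratio (default 1e-3).
#'
#' @return A function mapping a covariate matrix to the (constant) ratio,
#'   with attribute `"value"` holding the constant and `"mode"` the mode.
#' @export
estimate_variance_ratio <- function(data, m0_hat,
                                    mode = c("constant_one", "pooled_ratio"),
                                    floor = 1e-3) {
  mode <- match.arg(mode)
  if (mode == "constant_one") {
    f <- function(x) rep(1, nrow(x))
    attr(f, "value") <- 1
    attr(f, "mode") <- mode
    return(f)
  }
  if (data$n_ec == 0L)
    stop("pooled_ratio requires external controls (n_ec >= 1)")
  m0v <- if (is.function(m0_hat)) m0_hat(data$x) else as.numeric(m0_hat)
  ic <- which(data$d == 1L & data$a == 0L)
  ec <- which(data$d == 0L)
  if (length(ic) == 0L)
    stop("pooled_ratio requires internal controls")
  res_ic <- data$y[ic] - m0v[ic]
  res_ec <- data$y[ec] - m0v[ec]
  val <- max(mean(res_ic^2) / mean(res_ec^2), floor)
  f <- function(x) rep(val, nrow(x))
  attr(f, "value") <- val
  attr(f, "mode") <- mode
  f
}
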