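# Interchangeable nuisance learners. Each learner is fit on a covariate
# matrix and response and returns an object whose $predict gives predictions
# (conditional means, or probabilities for binary labels) on new rows.

#' Specify nuisance learners
#'
#' Names a learner for each nuisance function: the arm-specific outcome
#' regressions m1(x) = E[Y | A = 1, X = x] and m0(x) = E[Y | A = 0, X = x],
#' and the study propensity score pi_d(x) = Pr(D = 1 | X = x). The
#' treatment propensity pi_a is the design randomization probability unless
#' a learner is named for it.
#'
#' @param m1,m0 Learner for the outcome regressions: `"linear"`,
#'   `"random_forest"`, or a user-supplied list with elements `fit(x, y)`
#'   and `predict(object, x)`.
#' @param pi_d Learner for the study propensity score: `"logistic"`,
#'   `"random_forest"`, or a user-supplied list as above (returning
#'   probabilities).
#' @param pi_a `"design"` (use the known randomization probability) or
#'   `"logistic"` to re-estimate it within the trial.
#' @param r_mode Estimator for the control-outcome variance ratio r between
#'   sources: `"constant_one"` (default, r = 1) or `"pooled_ratio"` (ratio
#'   of mean squared control residuals, internal / external; see
#'   [estimate_variance_ratio()]).
#' @param trunc_eps Propensity truncation bound: estimated probabilities are
#'   clipped to `[trunc_eps, 1 - trunc_eps]` to stabilize weights.
#'   Default 0.01.
#' @param m1_args,m0_args,pi_d_args Lists of hyperparameters passed to the
#'   learner (for `"random_forest"`: `num.trees`, `min.node.size`, `mtry`).
#'
#' @return An object of class `"learner_spec"`.
#' @export
learner_spec <- function(m1 = "linear", m0 = "linear", pi_d = "logistic",
                         pi_a = "design",
                         r_mode = c("constant_one", "pooled_ratio"),
                         trunc_eps = 0.01,
                         m1_args = list(), m0_args = list(),
                         pi_d_args = list()) {
  r_mode <- match.arg(r_mode)
  if (!is.numeric(trunc_eps) || trunc_eps <= 0 || trunc_eps >= 0.5)
    stop("trunc_eps must lie in (0, 0.5)")
  chk <- function(l, allowed, what) {
    if (is.list(l)) {
      if (!all(c("fit", "predict") %in% names(l)))
        stop("user-supplied ", what,
             " learner must be a list with fit() and predict()")
    } else if (!l %in% allowed)
      stop("unknown ", what, " learner: ", l)
  }
  chk(m1, c("linear", "random_forest"), "m1")
  chk(m0, c("linear", "random_forest"), "m0")
  chk(pi_d, c("logistic", "random_forest"), "pi_d")
  if (!is.list(pi_a) && !pi_a %in% c("design", "logistic"))
    stop("pi_a learner must be 'design', 'logistic', or user-supplied")
  structure(list(m1 = m1, m0 = m0, pi_d = pi_d, pi_a = pi_a,
                 r_mode = r_mode, trunc_eps = trunc_eps,
                 m1_args = m1_args, m0_args = m0_args,
                 pi_d_args = pi_d_args),
            class = "learner_spec")
}

# Fit one learner. `binary = TRUE` means the response is a 0/1 label and
# predictions are probabilities.
fit_learner <- function(kind, x, y, binary = FALSE, args = list(),
                        seed = 1L) {
  if (nrow(x) == 0L) stop("cannot fit a learner on an empty stratum")
  if (is.list(kind)) {
    obj <- kind$fit(x, y)
    return(list(predict = function(newx) as.numeric(kind$predict(obj, newx))))
  }
  if (kind == "linear") {
    X <- cbind(1, x)
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    return(list(predict = function(newx)
      as.numeric(cbind(1, newx) %*% beta)))
  }
  if (kind == "logistic") {
    if (length(unique(y)) < 2L) {
      p <- mean(y)  # degenerate label: constant probability
      return(list(predict = function(newx) rep(p, nrow(newx))))
    }
    X <- cbind(1, x)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    return(list(predict = function(newx)
      stats::plogis(as.numeric(cbind(1, newx) %*% beta))))
  }
  if (kind == "random_forest") {
    df <- data.frame(.y = y, x, check.names = TRUE)
    nt <- args$num.trees %||% 200L
    mns <- args$min.node.size %||% NULL  # ranger's own default by type
    mtry <- args$mtry %||% NULL
    if (binary) {
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = transform(df, .y = factor(.y, levels = c(0, 1))),
        num.trees = nt, min.node.size = mns, mtry = mtry,
        probability = TRUE, seed = seed, num.threads = 1L,
        respect.unordered.factors = "order", verbose = FALSE)
      return(list(predict = function(newx) {
        nd <- data.frame(newx, check.names = TRUE)
        as.numeric(stats::predict(fit, data = nd,
                                  num.threads = 1L)$predictions[, "1"])
      }))
    }
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = nt, min.node.size = mns, mtry = mtry,
      seed = seed, num.threads = 1L, verbose = FALSE)
    return(list(predict = function(newx) {
      nd <- data.frame(newx, check.names = TRUE)
      as.numeric(stats::predict(fit, data = nd, num.threads = 1L)$predictions)
    }))
  }
  stop("unknown learner kind: ", kind)
}
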