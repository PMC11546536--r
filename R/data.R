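#' Construct a hybrid-trial dataset
#'
#' Bundles the observed-data vector O = (Y, X, A, D) for a hybrid trial,
#' i.e. a randomized trial (D = 1) augmented with an external control arm
#' (D = 0), together with the design randomization probability
#' Pr(A = 1 | X, D = 1), which is known by design within the trial.
#'
#' @param y Numeric outcome vector.
#' @param a Integer 0/1 treatment vector (1 = experimental treatment).
#' @param d Integer 0/1 source vector (1 = randomized trial, 0 = external
#'   control).
#' @param x Numeric matrix (or data frame of numeric columns) of baseline
#'   covariates, one row per subject.
#' @param pi_a Known randomization probability within the trial: either a
#'   single probability in (0, 1) (e.g. 2/3 for 2:1 randomization) or a
#'   function of a covariate row returning such a probability.
#' @param covariate_names Optional character vector of covariate names;
#'   defaults to the column names of `x`.
#' @param outcome_scale `"continuous"` or `"binary"`.
#'
#' @return An object of class `"hybrid_data"`: a list with elements
#'   `y`, `a`, `d`, `x`, `covariate_names`, `pi_a_design`, `outcome_scale`,
#'   and counts `n`, `n_rct`, `n_ec`.
#'
#' @details External controls are assumed to have received the control
#'   treatment, so every record with `d == 0` must have `a == 0`; a
#'   violation is an error naming the offending rows. Missing values are
#'   not allowed (complete-case analysis; see [load_hybrid_csv()]).
#'
#' @examples
#' x <- cbind(x1 = rnorm(8))
#' dat <- hybrid_data(y = rnorm(8), a = c(1, 1, 1, 1, 0, 0, 0, 0),
#'                    d = c(1, 1, 1, 1, 1, 1, 0, 0), x = x, pi_a = 2/3)
#' dat$n_rct
#' @export
hybrid_data <- function(y, a, d, x, pi_a,
                        covariate_names = NULL,
                        outcome_scale = c("continuous", "binary")) {
  outcome_scale <- match.arg(outcome_scale)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  rownames(x) <- NULL
  n <- length(y)
  if (length(a) != n || length(d) != n || nrow(x) != n)
    stop("y, a, d, and x must describe the same subjects (lengths differ)")
  if (!all(a %in% c(0, 1))) stop("treatment indicator a must be coded 0/1")
  if (!all(d %in% c(0, 1))) stop("source indicator d must be coded 0/1")
  a <- as.integer(a)
  d <- as.integer(d)
  bad <- which(d == 0L & a == 1L)
  if (length(bad))
    stop("external controls must be untreated; rows with d = 0, a = 1: ",
         paste(bad, collapse = ", "))
  if (anyNA(y) || anyNA(a) || anyNA(d) || anyNA(x))
    stop("missing values are not allowed in a hybrid_data object")
  if (sum(d) < 1L) stop("at least one trial (d = 1) subject is required")
  if (is.null(covariate_names)) {
    covariate_names <- colnames(x)
    if (is.null(covariate_names))
      covariate_names <- paste0("x", seq_len(ncol(x)))
  }
  if (length(covariate_names) != ncol(x))
    stop("covariate_names must have one entry per column of x")
  colnames(x) <- covariate_names
  if (is.function(pi_a)) {
    pa <- apply(x, 1L, pi_a)
    if (any(pa <= 0 | pa >= 1))
      stop("pi_a(x) must lie strictly inside (0, 1) for every subject")
  } else {
    if (!is.numeric(pi_a) || length(pi_a) != 1L || pi_a <= 0 || pi_a >= 1)
      stop("pi_a must be a single probability strictly inside (0, 1)")
  }
  structure(
    list(y = as.numeric(y), a = a, d = d, x = x,
         covariate_names = covariate_names,
         pi_a_design = pi_a, outcome_scale = outcome_scale,
         n = n, n_rct = sum(d == 1L), n_ec = sum(d == 0L)),
    class = "hybrid_data")
}

#' @export
print.hybrid_data <- function(x, ...) {
  cat("Hybrid-trial data: n =", x$n,
      sprintf("(%d trial, %d external controls)\n", x$n_rct, x$n_ec))
  cat("  treated:", sum(x$a == 1L),
      " internal controls:", sum(x$d == 1L & x$a == 0L), "\n")
  cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  if (!is.function(x$pi_a_design))
    cat("  design Pr(A=1|D=1) =", format(x$pi_a_design, digits = 4), "\n")
  invisible(x)
}

#' Evaluate the design randomization probability per subject
#' @param data A `hybrid_data` object.
#' @return Numeric vector of Pr(A = 1 | X, D = 1) per subject.
#' @keywords internal
pi_a_vector <- function(data) {
  if (is.function(data$pi_a_design)) apply(data$x, 1L, data$pi_a_design)
  else rep(data$pi_a_design, data$n)
}

#' Load hybrid-trial data from a delimited text file
#'
#' Reads a CSV (or other delimited file) with a header, maps columns onto
#' the outcome/treatment/source/covariate roles, drops incomplete rows
#' (complete-case analysis), and validates the result.
#'
#' @param path Path to a delimited text file with a header row.
#' @param pi_a Known randomization probability (see [hybrid_data()]).
#' @param outcome Column name holding the outcome; default `"y"`.
#' @param treatment Column name holding the 0/1 treatment; default `"a"`.
#' @param source Column name holding the 0/1 source indicator; default `"d"`.
#' @param covariates Character vector of covariate column names; default:
#'   every remaining column.
#' @param sep Field separator, default comma.
#' @param outcome_scale Passed to [hybrid_data()].
#' @param quiet Suppress the dropped-row message.
#'
#' @return A validated `hybrid_data` object with attribute `"n_dropped"`
#'   recording how many incomplete rows were removed.
#' @export
load_hybrid_csv <- function(path, pi_a, outcome = "y", treatment = "a",
                            source = "d", covariates = NULL, sep = ",",
                            outcome_scale = "continuous", quiet = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c(outcome, treatment, source)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("mapped column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (is.null(covariates)) covariates <- setdiff(names(tab), need)
  missing_cov <- setdiff(covariates, names(tab))
  if (length(missing_cov))
    stop("covariate column(s) not present: ",
         paste(missing_cov, collapse = ", "))
  if (length(covariates) == 0L) stop("no covariate columns found")
  used <- tab[, c(need, covariates), drop = FALSE]
  keep <- stats::complete.cases(used)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L && !quiet)
    message("load_hybrid_csv: dropped ", n_dropped,
            " incomplete row(s); ", sum(keep), " rows retained")
  used <- used[keep, , drop = FALSE]
  av <- used[[treatment]]
  dv <- used[[source]]
  if (!all(av %in% c(0, 1))) stop("treatment column must be coded 0/1")
  if (!all(dv %in% c(0, 1))) stop("source column must be coded 0/1")
  bad <- which(dv == 0 & av == 1)
  if (length(bad))
    stop("external controls must be untreated; offending row(s) ",
         "(after dropping incomplete rows): ", paste(bad, collapse = ", "))
  dat <- hybrid_data(y = used[[outcome]], a = av, d = dv,
                     x = as.matrix(used[, covariates, drop = FALSE]),
                     pi_a = pi_a, covariate_names = covariates,
                     outcome_scale = outcome_scale)
  attr(dat, "n_dropped") <- n_dropped
  dat
}

#' Write hybrid-trial data to CSV
#'
#' Inverse of [load_hybrid_csv()]: writes columns y, a, d and the
#' covariates so that reloading reproduces the dataset.
#'
#' @param data A `hybrid_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hybrid_csv <- function(data, path) {
  stopifnot(inherits(data, "hybrid_data"))
  tab <- data.frame(y = data$y, a = data$a, d = data$d,
                    data$x, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Subset a hybrid_data object by row index
#' @keywords internal
subset_hybrid <- function(data, idx) {
  hybrid_data(y = data$y[idx], a = data$a[idx], d = data$d[idx],
              x = data$x[idx, , drop = FALSE], pi_a = data$pi_a_design,
              covariate_names = data$covariate_names,
              outcome_scale = data$outcome_scale)
}
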