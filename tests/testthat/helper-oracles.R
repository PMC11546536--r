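# Independent brute-force oracles and fixture builders. These re-derive
# every formula from scratch (scalar loops, path enumeration) and must not
# call the implementation paths they check.

# -- estimator oracles -------------------------------------------------

# Doubly robust control weight, written out longhand per subject.
oracle_w_dr <- function(a, d, pi_d, pi_a, r) {
  num <- d * (1 - a) * pi_d + (1 - d) * (1 - a) * pi_d * r
  den <- pi_d * (1 - pi_a) + (1 - pi_d) * r
  num / den
}

oracle_eic <- function(y, a, d, m1, m0, pi_a, pi_d, r, tau, q) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    w <- oracle_w_dr(a[i], d[i], pi_d[i], pi_a[i], r[i])
    out[i] <- (1 / q) * (d[i] * (m1[i] - m0[i] - tau) +
                           (d[i] * a[i] / pi_a[i]) * (y[i] - m1[i]) -
                           w * (y[i] - m0[i]))
  }
  out
}

oracle_aipw <- function(y, a, d, m1, m0, pi_a, pi_d, r) {
  n <- length(y)
  q <- sum(d) / n
  total <- 0
  for (i in seq_len(n)) {
    w <- oracle_w_dr(a[i], d[i], pi_d[i], pi_a[i], r[i])
    total <- total + (1 / q) * (d[i] * (m1[i] - m0[i]) +
                                  (d[i] * a[i] / pi_a[i]) * (y[i] - m1[i]) -
                                  w * (y[i] - m0[i]))
  }
  total / n
}

oracle_mu0_om <- function(y, d, m0) sum(m0[d == 1]) / sum(d == 1)

oracle_ipdw_weights <- function(a, pi_d, pi_a) {
  (1 - a) * pi_d / ((1 - pi_a) * pi_d + (1 - pi_d))
}

# -- fixtures ----------------------------------------------------------

# A 6-subject micro dataset with hand-set nuisance values, used for
# spreadsheet-style equivalence checks.
micro_fixture <- function() {
  dat <- hybrid_data(
    y = c(2.0, 4.0, 1.5, 0.5, 1.0, 2.5),
    a = c(1, 1, 0, 0, 0, 0),
    d = c(1, 1, 1, 1, 0, 0),
    x = cbind(x1 = c(0.5, -1.0, 0.2, 1.5, -0.3, 0.8)),
    pi_a = 2 / 3)
  pred <- data.frame(
    m1 = c(2.2, 3.5, 1.8, 2.6, 1.4, 2.9),
    m0 = c(1.1, 0.7, 1.6, 0.9, 1.2, 2.1),
    pi_d = c(0.8, 0.6, 0.7, 0.5, 0.4, 0.55),
    pi_a = rep(2 / 3, 6),
    r = c(1, 1, 1, 1, 1.3, 1.3))
  fits <- structure(
    list(pred = pred, fold_id = rep(0L, 6), k_folds = 1L,
         spec = learner_spec(), trunc_eps = 0.01, seed = 1L),
    class = "nuisance_fits")
  list(data = dat, fits = fits)
}

# Fake nuisance fits from explicit prediction columns.
fake_fits <- function(m1, m0, pi_d, pi_a, r = 1) {
  n <- length(m1)
  structure(
    list(pred = data.frame(m1 = m1, m0 = m0, pi_d = pi_d,
                           pi_a = rep_len(pi_a, n), r = rep_len(r, n)),
         fold_id = rep(0L, n), k_folds = 1L, spec = learner_spec(),
         trunc_eps = 0.01, seed = 1L),
    class = "nuisance_fits")
}

# Random small hybrid dataset for property tests.
random_hybrid <- function(n = 40, seed = 1) {
  set.seed(seed)
  d <- c(rep(1L, ceiling(0.7 * n)), rep(0L, n - ceiling(0.7 * n)))
  a <- ifelse(d == 1L, rbinom(n, 1, 2 / 3), 0L)
  while (sum(a[d == 1L]) == 0 || sum(d == 1L & a == 0L) == 0) {
    a <- ifelse(d == 1L, rbinom(n, 1, 2 / 3), 0L)
  }
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  hybrid_data(y = rnorm(n, x[, 1]), a = a, d = d, x = x, pi_a = 2 / 3)
}

# -- d-separation oracle: exhaustive path enumeration ------------------

# All simple undirected paths between two nodes.
oracle_all_paths <- function(g, from, to) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    nbrs <- union(g$parents[[v]], g$children[[v]])
    for (w in setdiff(nbrs, path)) walk(c(path, w))
  }
  walk(from)
  paths
}

oracle_descendants <- function(g, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    ch <- unique(unlist(g$children[frontier], use.names = FALSE))
    frontier <- setdiff(ch, out)
    out <- union(out, frontier)
  }
  out
}

# Path blocked given cond? Classic rule applied edge pair by edge pair.
oracle_path_blocked <- function(g, path, cond) {
  if (length(path) <= 2L) return(FALSE)
  for (i in seq(2L, length(path) - 1L)) {
    v <- path[i]
    collider <- (path[i - 1L] %in% g$parents[[v]]) &&
      (path[i + 1L] %in% g$parents[[v]])
    if (collider) {
      desc <- oracle_descendants(g, v)
      if (!any(desc %in% cond)) return(TRUE)
    } else {
      if (v %in% cond) return(TRUE)
    }
  }
  FALSE
}

oracle_d_separated <- function(g, src, dst, cond = character()) {
  for (s in src) for (t in dst) {
    for (p in oracle_all_paths(g, s, t)) {
      if (!oracle_path_blocked(g, p, cond)) return(FALSE)
    }
  }
  TRUE
}

# Random DAG over nodes n1..k using an upper-triangular edge scheme.
random_dag <- function(k, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(k))
  from <- character(); to <- character()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (runif(1) < p_edge) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
    }
  }
  causal_graph(if (length(from)) data.frame(from = from, to = to)
               else NULL, nodes = nodes)
}

# SMA-style example graph with a conservative selection model.
sma_swig <- function() {
  g <- load_graph(system.file("extdata", "sma_graph.txt",
                              package = "hybridec"))
  build_selection_swig(
    g, differing_covariates = c("Age", "Type", "Scoliosis", "MFM0"))
}
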