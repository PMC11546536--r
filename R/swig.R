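# Causal graphs, selection single-world intervention graphs (SWIGs), and
# d-separation checks of the borrowing (mean-exchangeability) assumption.
#
# A selection SWIG augments the investigator's causal DAG with selection
# (S) nodes marking conditionals that may differ between the study and
# external-control populations, and splits the treatment node into a
# random half (inheriting incoming edges) and a fixed half set to the
# control value (inheriting outgoing edges). The borrowing assumption
# holds for an adjustment set X when the counterfactual control outcome
# is d-separated from every S node given X on this graph.

#' Construct a causal DAG
#'
#' @param edges Two-column matrix or data frame of directed edges
#'   (from, to), or `NULL` for an edgeless graph.
#' @param roles Named character vector mapping node names to roles among
#'   `"covariate"`, `"treatment"`, `"outcome"`, `"unmeasured"`. Nodes
#'   appearing in `edges` but not in `roles` default to `"covariate"`.
#' @param nodes Optional character vector of additional (isolated) nodes.
#' @return An object of class `"causal_graph"` with elements `nodes`,
#'   `edges` (data frame `from`, `to`), `roles`, and adjacency lists
#'   `parents`, `children`.
#' @details The graph must be acyclic (an error lists a cycle otherwise),
#'   contain at most one outcome node, and nodes with role
#'   `"unmeasured"` are latent: they participate in paths but may not be
#'   conditioned on.
#' @export
causal_graph <- function(edges = NULL, roles = character(),
                         nodes = character()) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  nodes <- unique(c(nodes, edges$from, edges$to, names(roles)))
  if (!length(nodes)) stop("graph has no nodes")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  ok_roles <- c("covariate", "treatment", "outcome", "unmeasured")
  bad <- setdiff(roles, ok_roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  full_roles <- stats::setNames(rep("covariate", length(nodes)), nodes)
  full_roles[names(roles)] <- roles
  if (sum(full_roles == "outcome") > 1L)
    stop("at most one outcome node is allowed")
  parents <- children <- stats::setNames(
    rep(list(character()), length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    parents[[edges$to[i]]] <- c(parents[[edges$to[i]]], edges$from[i])
    children[[edges$from[i]]] <- c(children[[edges$from[i]]], edges$to[i])
  }
  g <- structure(list(nodes = nodes, edges = edges, roles = full_roles,
                      parents = parents, children = children),
                 class = "causal_graph")
  cyc <- find_cycle(g)
  if (!is.null(cyc))
    stop("graph contains a cycle: ", paste(cyc, collapse = " -> "))
  g
}

# Returns a cycle as a node vector, or NULL if the graph is acyclic.
find_cycle <- function(g) {
  color <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  stack <- character()
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    color[[v]] <<- 1L
    stack <<- c(stack, v)
    for (w in g$children[[v]]) {
      if (color[[w]] == 1L) {
        i <- match(w, stack)
        cyc <<- c(stack[i:length(stack)], w)
        return()
      }
      if (color[[w]] == 0L) visit(w)
      if (!is.null(cyc)) return()
    }
    color[[v]] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in g$nodes) if (color[[v]] == 0L) visit(v)
  cyc
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("Causal DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  special <- x$roles[x$roles != "covariate"]
  if (length(special))
    cat(paste0("  ", names(special), ": ", special, collapse = "\n"), "\n")
  invisible(x)
}

#' Load a causal DAG from an edge-list text file
#'
#' The file contains one directive per line: directed edges written
#' `parent -> child`, role annotations written `node: role` with role in
#' covariate / treatment / outcome / unmeasured, blank lines, and `#`
#' comments.
#'
#' @param path Path to the edge-list file.
#' @return A validated [causal_graph()].
#' @export
load_graph <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  from <- to <- character()
  roles <- character()
  extra <- character()
  for (ln in lines) {
    if (grepl("->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1]])
      if (length(parts) != 2L || !all(nzchar(parts)))
        stop("cannot parse edge line: ", ln)
      from <- c(from, parts[1]); to <- c(to, parts[2])
    } else if (grepl(":", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, ":", fixed = TRUE)[[1]])
      if (length(parts) != 2L ||
          !parts[2] %in% c("covariate", "treatment", "outcome",
                           "unmeasured"))
        stop("cannot parse role line: ", ln)
      roles[parts[1]] <- parts[2]
    } else if (grepl("^[A-Za-z0-9_.]+$", ln)) {
      extra <- c(extra, ln)
    } else stop("cannot parse line: ", ln)
  }
  causal_graph(if (length(from)) data.frame(from = from, to = to) else NULL,
               roles = roles, nodes = extra)
}

#' Export a graph to Graphviz DOT format
#' @param g A `causal_graph` or `selection_swig`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path) {
  if (inherits(g, "selection_swig")) g <- g$graph
  stopifnot(inherits(g, "causal_graph"))
  shape <- ifelse(g$roles[g$nodes] == "unmeasured", "dashed", "solid")
  lines <- c("digraph G {",
             sprintf("  \"%s\" [style=%s];", g$nodes, shape),
             sprintf("  \"%s\" -> \"%s\";", g$edges$from, g$edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Build a selection SWIG
#'
#' Augments a causal DAG with selection nodes for the conditionals the
#' investigator declares as (possibly) differing between the study and
#' external-control populations, and splits the treatment node under the
#' control intervention. Declarations are user assertions about the two
#' populations, not quantities computable from data; declaring a
#' selection node on every covariate is the conservative model.
#'
#' @param g A [causal_graph()] with a treatment and an outcome node.
#' @param differing_covariates Character vector of covariate (or
#'   unmeasured) nodes whose conditional distribution may differ between
#'   populations; each receives a selection node `S_<name>` with a single
#'   edge into it.
#' @param outcome_mechanism_differs If `TRUE`, adds `S_<outcome>` into
#'   the outcome (the outcome mechanism itself differs; the borrowing
#'   assumption is then unverifiable by adjustment for covariates).
#' @param treatment Name of the treatment node; defaults to the node with
#'   role `"treatment"`.
#' @param a Fixed intervention value for the split (only the control
#'   value 0 is meaningful here).
#'
#' @return An object of class `"selection_swig"`: a list with the split
#'   graph (`graph`), `s_nodes`, `treatment_random`, `treatment_fixed`,
#'   `outcome` (the counterfactual control outcome node), and the role
#'   bookkeeping of the base graph.
#' @details In the split graph the random half of the treatment keeps its
#'   incoming edges and the fixed half (a constant, written `<A>=0`)
#'   keeps the outgoing edges; the outcome node then represents the
#'   counterfactual outcome under control. Being constant, the fixed half
#'   blocks any path through it.
#' @export
build_selection_swig <- function(g, differing_covariates = character(),
                                 outcome_mechanism_differs = FALSE,
                                 treatment = NULL, a = 0) {
  stopifnot(inherits(g, "causal_graph"))
  if (!identical(a, 0) && !identical(a, 0L))
    stop("only the control intervention a = 0 is supported")
  if (is.null(treatment)) {
    treatment <- names(g$roles)[g$roles == "treatment"]
    if (length(treatment) != 1L)
      stop("graph must have exactly one treatment node (or name one)")
  }
  if (!treatment %in% g$nodes) stop("unknown treatment node: ", treatment)
  outcome <- names(g$roles)[g$roles == "outcome"]
  if (length(outcome) != 1L) stop("graph must have one outcome node")
  bad <- setdiff(differing_covariates,
                 g$nodes[g$roles[g$nodes] %in% c("covariate", "unmeasured")])
  if (treatment %in% differing_covariates)
    stop("cannot declare a selection edge into the treatment's fixed half")
  if (length(bad))
    stop("differing_covariates must be covariate nodes; offending: ",
         paste(bad, collapse = ", "))
  fixed <- paste0(treatment, "=0")
  e <- g$edges
  # fixed half inherits the outgoing edges of the treatment
  e$from[e$from == treatment] <- fixed
  roles <- g$roles
  roles[fixed] <- "covariate"  # placeholder; fixed node handled specially
  s_nodes <- character()
  for (z in differing_covariates) {
    s <- paste0("S_", z)
    e <- rbind(e, data.frame(from = s, to = z, stringsAsFactors = FALSE))
    roles[s] <- "covariate"
    s_nodes <- c(s_nodes, s)
  }
  if (outcome_mechanism_differs) {
    s <- paste0("S_", outcome)
    e <- rbind(e, data.frame(from = s, to = outcome,
                             stringsAsFactors = FALSE))
    roles[s] <- "covariate"
    s_nodes <- c(s_nodes, s)
  }
  split <- causal_graph(e, roles = roles,
                        nodes = unique(c(g$nodes, fixed, s_nodes)))
  structure(list(graph = split, s_nodes = s_nodes,
                 treatment_random = treatment, treatment_fixed = fixed,
                 outcome = outcome,
                 latent = g$nodes[g$roles[g$nodes] == "unmeasured"]),
            class = "selection_swig")
}

#' @export
print.selection_swig <- function(x, ...) {
  cat("Selection SWIG: treatment", x$treatment_random, "split (fixed half",
      paste0(x$treatment_fixed, ")"), "\n")
  cat("  counterfactual outcome:", x$outcome, "\n")
  cat("  selection nodes:",
      if (length(x$s_nodes)) paste(x$s_nodes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Test d-separation on a DAG
#'
#' Determines whether every path between `src` and `dst` is blocked given
#' `cond` under the standard d-separation rules (chains and forks are
#' blocked by conditioning; a collider is open only if it or one of its
#' descendants is conditioned on). Implemented by the reachability
#' (Bayes-ball) algorithm.
#'
#' @param g A [causal_graph()] (or the graph inside a selection SWIG).
#' @param src,dst,cond Character vectors of node names; `src` and `dst`
#'   must be disjoint from each other and from `cond`.
#' @param fixed Character vector of constant (intervention) nodes, which
#'   block any path through them.
#' @return `TRUE` if `src` and `dst` are d-separated given `cond`.
#' @export
d_separated <- function(g, src, dst, cond = character(),
                        fixed = character()) {
  stopifnot(inherits(g, "causal_graph"))
  unknown <- setdiff(c(src, dst, cond, fixed), g$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(src, dst)) || length(intersect(src, cond)) ||
      length(intersect(dst, cond)))
    stop("src, dst, and cond must be disjoint")
  blocked <- union(cond, fixed)  # nodes that block chains and forks
  # ancestors of the conditioning set (colliders open iff in this set);
  # fixed nodes are constants, not conditioned variables
  anc <- cond
  frontier <- cond
  while (length(frontier)) {
    pa <- unique(unlist(g$parents[frontier], use.names = FALSE))
    frontier <- setdiff(pa, anc)
    anc <- union(anc, frontier)
  }
  # reachability over (node, direction): "up" = arrived from a child,
  # "down" = arrived from a parent
  seen <- character()
  queue <- c(paste0(src, "|up"))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    parts <- strsplit(cur, "|", fixed = TRUE)[[1]]
    v <- parts[1]; dir <- parts[2]
    if (!(v %in% blocked) && v %in% dst) return(FALSE)
    if (dir == "up") {
      if (!(v %in% blocked)) {
        queue <- c(queue, paste0(g$parents[[v]], "|up"),
                   paste0(g$children[[v]], "|down"))
      }
    } else {
      if (!(v %in% blocked))
        queue <- c(queue, paste0(g$children[[v]], "|down"))
      if (v %in% anc)  # collider (or conditioned descendant path): go up
        queue <- c(queue, paste0(g$parents[[v]], "|up"))
    }
  }
  TRUE
}

# Enumerate simple undirected paths between two nodes and return the
# first one active given cond (used for witness reporting).
find_open_path <- function(g, from, to, cond, fixed = character()) {
  blocked <- union(cond, fixed)
  anc_cond <- cond
  frontier <- cond
  while (length(frontier)) {
    pa <- unique(unlist(g$parents[frontier], use.names = FALSE))
    frontier <- setdiff(pa, anc_cond)
    anc_cond <- union(anc_cond, frontier)
  }
  path_active <- function(path) {
    if (length(path) < 3L)
      return(!(length(path) == 2L) ||
               !(path[1] %in% blocked || path[2] %in% blocked))
    for (i in seq(2L, length(path) - 1L)) {
      v <- path[i]
      into_prev <- path[i - 1L] %in% g$parents[[v]]
      into_next <- path[i + 1L] %in% g$parents[[v]]
      if (into_prev && into_next) {
        if (!(v %in% anc_cond)) return(FALSE)  # closed collider
      } else {
        if (v %in% blocked) return(FALSE)      # blocked chain/fork
      }
    }
    TRUE
  }
  res <- NULL
  dfs <- function(path) {
    if (!is.null(res)) return()
    v <- path[length(path)]
    if (v == to) {
      if (path_active(path)) res <<- path
      return()
    }
    for (w in setdiff(union(g$parents[[v]], g$children[[v]]), path))
      dfs(c(path, w))
  }
  dfs(from)
  res
}

#' Graphical check of the borrowing assumption
#'
#' The borrowing (mean-exchangeability) assumption holds for an
#' adjustment set X when the counterfactual control outcome is
#' d-separated from every selection node given X on the selection SWIG.
#'
#' @param swig A [build_selection_swig()] object.
#' @param adjustment_set Character vector of measured covariate nodes.
#' @return A list with `holds` (logical) and, on failure, `witnesses`: a
#'   named list giving one open path per offending selection node.
#' @export
check_a4 <- function(swig, adjustment_set = character()) {
  stopifnot(inherits(swig, "selection_swig"))
  g <- swig$graph
  latent_in <- intersect(adjustment_set, swig$latent)
  if (length(latent_in))
    stop("adjustment set may only contain measured nodes; latent: ",
         paste(latent_in, collapse = ", "))
  if (swig$outcome %in% adjustment_set)
    stop("the outcome cannot be part of the adjustment set")
  if (swig$treatment_fixed %in% adjustment_set ||
      swig$treatment_random %in% adjustment_set)
    stop("the treatment node cannot be part of the adjustment set")
  unknown <- setdiff(adjustment_set, g$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (!length(swig$s_nodes))
    return(list(holds = TRUE, witnesses = list()))
  witnesses <- list()
  for (s in swig$s_nodes) {
    sep <- d_separated(g, src = s, dst = swig$outcome,
                       cond = adjustment_set,
                       fixed = swig$treatment_fixed)
    if (!sep)
      witnesses[[s]] <- find_open_path(g, s, swig$outcome, adjustment_set,
                                       fixed = swig$treatment_fixed)
  }
  list(holds = length(witnesses) == 0L, witnesses = witnesses)
}

#' Enumerate inclusion-minimal valid adjustment sets
#'
#' Exhaustively searches subsets of the candidate covariates for sets
#' under which the borrowing assumption holds ([check_a4()]), returning
#' the inclusion-minimal ones ordered by size.
#'
#' @param swig A [build_selection_swig()] object.
#' @param candidates Character vector of measured covariate nodes;
#'   defaults to all measured covariates of the base graph. At most 20.
#' @param max_size Largest subset size to consider (default
#'   `length(candidates)`).
#' @return List of character vectors (possibly empty; `list(character(0))`
#'   when the empty set suffices).
#' @export
minimal_adjustment_sets <- function(swig, candidates = NULL,
                                    max_size = NULL) {
  stopifnot(inherits(swig, "selection_swig"))
  g <- swig$graph
  if (is.null(candidates)) {
    base_nodes <- setdiff(g$nodes, c(swig$s_nodes, swig$treatment_fixed,
                                     swig$treatment_random, swig$outcome))
    candidates <- base_nodes[g$roles[base_nodes] == "covariate"]
    candidates <- setdiff(candidates, swig$latent)
  }
  if (length(candidates) > 20L)
    stop("more than 20 candidates: exhaustive enumeration refused; ",
         "supply manual adjustment sets")
  if (is.null(max_size)) max_size <- length(candidates)
  found <- list()
  for (size in 0:max_size) {
    combs <- if (size == 0L) list(character()) else
      utils::combn(candidates, size, simplify = FALSE)
    for (s in combs) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1))))
        next  # superset of a known minimal set
      if (check_a4(swig, s)$holds) found[[length(found) + 1L]] <- s
    }
  }
  found
}
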