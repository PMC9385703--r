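## Node-level and global topological indices. Node indices are reported
## raw and min-max normalized to [0,1] so they can be overlaid across webs
## of different size in parallel-coordinates comparisons.

#' Min-max normalization to [0, 1]
#'
#' x' = (x - min x) / (max x - min x). Order-preserving and invariant to
#' positive affine transforms of the input. When all values are equal the
#' ratio is undefined; the whole vector maps to 0 so outputs stay in [0,1]
#' and remain plottable.
#'
#' @param values numeric vector (optionally named by node).
#' @return numeric vector of the same length and names, in [0, 1].
#' @export
minmax_normalize <- function(values) {
  stopifnot(length(values) > 0)
  rng <- range(values)
  if (rng[1] == rng[2]) return(stats::setNames(rep(0, length(values)),
                                               names(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

node_index_table <- function(nodes, raw, index_name) {
  df <- data.frame(node = nodes, index = index_name, raw = unname(raw),
                   normalized = unname(minmax_normalize(raw)),
                   stringsAsFactors = FALSE)
  class(df) <- c("node_index_table", "data.frame")
  df
}

#' Network summary row
#'
#' Number of nodes and edges, average degree and directed density. The
#' average degree here is E/n — the mean number of edges per node, the
#' convention under which the printed summary of a 71-node, 148-edge web
#' reads 2.08 — not the textbook mean total degree 2E/n. Density is
#' E/(n(n-1)), the fraction of possible directed links realized; it is
#' undefined (NA) below two nodes rather than reported as 0.
#'
#' @param web a [food_web].
#' @return one-row data frame: `name`, `n_nodes`, `n_edges`,
#'   `average_degree`, `density`.
#' @export
web_summary <- function(web) {
  stopifnot(inherits(web, "food_web"))
  n <- length(web$nodes)
  e <- nrow(web$edges)
  data.frame(name = web$name, n_nodes = n, n_edges = e,
             average_degree = if (n >= 1) e / n else NA_real_,
             density = if (n >= 2) e / (n * (n - 1)) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Total node degrees (in + out)
#'
#' @param web a [food_web].
#' @return named integer vector; a self-loop contributes 2.
#' @export
node_degrees <- function(web) {
  g <- as_igraph(web)
  deg <- igraph::degree(g, mode = "all", loops = TRUE)
  deg[web$nodes]
}

#' Degree centrality
#'
#' DC(v) = (in-degree + out-degree) / (n - 1).
#'
#' @param web a [food_web].
#' @return a `node_index_table` (`node`, `index`, `raw`, `normalized`).
#' @export
degree_centrality <- function(web) {
  n <- length(web$nodes)
  deg <- node_degrees(web)
  raw <- if (n > 1) deg / (n - 1) else rep(0, n)
  node_index_table(web$nodes, raw, "degree_centrality")
}

path_weights <- function(web, weights_as_distance) {
  ## interaction weights are flows, not costs: shortest paths are
  ## unweighted unless 1/w costs are explicitly requested
  if (weights_as_distance == "inverse") 1 / web$edges$weight else NA
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest directed paths passing through a node,
#' normalized by (n-1)(n-2). Paths are unweighted by default;
#' `weights_as_distance = "inverse"` uses 1/weight as the traversal cost.
#'
#' @param web a [food_web].
#' @param weights_as_distance `"none"` (default) or `"inverse"`.
#' @return a `node_index_table`; all zero below 3 nodes by convention.
#' @export
betweenness_centrality <- function(web,
                                   weights_as_distance = c("none",
                                                           "inverse")) {
  weights_as_distance <- match.arg(weights_as_distance)
  n <- length(web$nodes)
  if (n < 3) return(node_index_table(web$nodes, rep(0, n), "betweenness"))
  g <- as_igraph(web)
  bc <- igraph::betweenness(g, directed = TRUE,
                            weights = path_weights(web, weights_as_distance))
  raw <- bc[web$nodes] / ((n - 1) * (n - 2))
  node_index_table(web$nodes, raw, "betweenness")
}

#' Closeness centrality
#'
#' Incoming-distance closeness with per-component scaling for disconnected
#' graphs: with r nodes able to reach v at total distance d,
#' CC(v) = (r / d) * (r / (n - 1)); nodes nothing can reach score 0.
#'
#' @inheritParams betweenness_centrality
#' @return a `node_index_table`.
#' @export
closeness_centrality <- function(web,
                                 weights_as_distance = c("none",
                                                         "inverse")) {
  weights_as_distance <- match.arg(weights_as_distance)
  n <- length(web$nodes)
  if (n < 2) return(node_index_table(web$nodes, rep(0, n), "closeness"))
  g <- as_igraph(web)
  D <- igraph::distances(g, mode = "out",
                         weights = path_weights(web, weights_as_distance))
  D <- D[web$nodes, web$nodes, drop = FALSE]
  raw <- vapply(seq_len(n), function(i) {
    d <- D[-i, i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0 || sum(d) == 0) return(0)
    (r / sum(d)) * (r / (n - 1))
  }, 0)
  node_index_table(web$nodes, raw, "closeness")
}

#' Trophic levels from the energy-flow linear system
#'
#' Basal nodes (no incoming prey edge) sit at level 1; every consumer sits
#' one level above the diet-weighted mean of its prey:
#' s_i = 1 + sum_j (w_ji s_j) / sum_j w_ji over incoming edges j -> i.
#' The solution exists and is unique when every consumer is reachable from
#' at least one basal node; otherwise a structured error names the
#' offending nodes and points at the regularized fallback, which is never
#' switched on silently.
#'
#' The fallback solves the regularized level problem
#' (diag(u) - A - A^t) h = in - out (u = total incident weight) per weakly
#' connected component, shifted so the minimum level is 1; it is defined on
#' webs with no basal species (e.g. dominated by loops).
#'
#' @param web a [food_web].
#' @param fallback logical; use the regularized levels instead of erroring
#'   when the basal-anchored system has no solution.
#' @return object of class `trophic_levels`: list with `levels` (named
#'   numeric, >= 1) and `basal` (named logical).
#' @export
trophic_levels <- function(web, fallback = FALSE) {
  stopifnot(inherits(web, "food_web"))
  n <- length(web$nodes)
  if (n == 0) {
    return(structure(list(levels = stats::setNames(numeric(0), character(0)),
                          basal = logical(0)), class = "trophic_levels"))
  }
  A <- web_adjacency(web)              # A[prey, predator] = weight
  in_w <- colSums(A)
  basal <- in_w == 0
  if (!fallback) {
    if (!any(basal)) {
      stop("trophic levels undefined: no basal node (every node has prey); ",
           "consider trophic_levels(web, fallback = TRUE)", call. = FALSE)
    }
    ## reachability from the basal set along prey -> predator edges
    g <- as_igraph(web)
    reach <- unique(unlist(lapply(web$nodes[basal], function(v)
      names(igraph::subcomponent(g, v, mode = "out")))))
    missing <- setdiff(web$nodes[!basal], reach)
    if (length(missing) > 0) {
      stop("trophic levels undefined: node(s) not reachable from any basal ",
           "node: ", paste(missing, collapse = ", "),
           "; consider trophic_levels(web, fallback = TRUE)", call. = FALSE)
    }
    s <- stats::setNames(rep(1, n), web$nodes)
    cons <- which(!basal)
    if (length(cons) > 0) {
      P <- sweep(t(A[, cons, drop = FALSE]), 1, in_w[cons], "/")
      ## P[i, j]: diet fraction of consumer i on prey j
      M <- diag(length(cons)) - P[, cons, drop = FALSE]
      rhs <- 1 + if (any(basal)) {
        rowSums(P[, basal, drop = FALSE])
      } else 0
      s[cons] <- solve(M, rhs)
    }
    return(structure(list(levels = s, basal = stats::setNames(basal,
                                                              web$nodes)),
                     class = "trophic_levels"))
  }
  ## regularized levels, component by component
  s <- stats::setNames(rep(1, n), web$nodes)
  g <- as_igraph(web)
  comp <- igraph::components(g, mode = "weak")$membership[web$nodes]
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) == 1) { s[idx] <- 1; next }
    Ak <- A[idx, idx, drop = FALSE]
    u <- rowSums(Ak) + colSums(Ak)
    v <- colSums(Ak) - rowSums(Ak)
    L <- diag(u) - Ak - t(Ak)
    h <- qr.solve(rbind(L, rep(1, length(idx))), c(v, 0))
    s[idx] <- h - min(h) + 1
  }
  structure(list(levels = s, basal = stats::setNames(basal, web$nodes)),
            class = "trophic_levels")
}

#' @export
print.trophic_levels <- function(x, ...) {
  cat("<trophic_levels>", length(x$levels), "nodes,",
      sum(x$basal), "basal; range",
      paste(round(range(x$levels), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Katz centrality
#'
#' x_i = alpha * sum over incoming edges j->i of A_ji x_j + beta, solved
#' directly as (I - alpha A^t) x = beta. Convergence requires alpha below
#' the reciprocal spectral radius of the adjacency matrix; alpha at or
#' above 0.9 of that bound is shrunk to it with a warning (or, with
#' `auto_shrink = FALSE`, raises an error reporting the computed bound).
#' The raw vector is scaled to unit Euclidean norm before min-max
#' normalization.
#'
#' @param web a [food_web].
#' @param alpha attenuation factor (default 0.1).
#' @param beta baseline centrality given to every node for free (default 1).
#' @param use_weights logical; attenuate over weighted adjacency instead of
#'   binary (default binary, the common toolkit behaviour).
#' @param auto_shrink logical, see above.
#' @return a `node_index_table`.
#' @export
katz_centrality <- function(web, alpha = 0.1, beta = 1,
                            use_weights = FALSE, auto_shrink = TRUE) {
  n <- length(web$nodes)
  stopifnot(n > 0, beta > 0, alpha > 0)
  A <- web_adjacency(web, binary = !use_weights)
  lmax <- if (n > 0 && any(A > 0)) {
    max(Mod(eigen(A, only.values = TRUE)$values))
  } else 0
  if (lmax > 0) {
    bound <- 1 / lmax
    if (alpha >= 0.9 * bound) {
      if (auto_shrink) {
        warning(sprintf(
          "alpha = %g at or above 0.9/spectral radius (bound %g); shrunk to %g",
          alpha, bound, 0.9 * bound))
        alpha <- 0.9 * bound
      } else if (alpha >= bound) {
        stop(sprintf(
          "katz does not converge: alpha = %g >= 1/spectral radius = %g",
          alpha, bound), call. = FALSE)
      }
    }
  }
  x <- solve(diag(n) - alpha * t(A), rep(beta, n))
  raw <- stats::setNames(x / sqrt(sum(x^2)), web$nodes)
  node_index_table(web$nodes, raw, "katz")
}

#' Average directed clustering coefficient
#'
#' Mean over nodes of the all-motif directed clustering coefficient
#' (directed triangles of every orientation): with S = A + A^t,
#' C_i = (S^3)_ii / (2 * (d_i (d_i - 1) - 2 d_i^bidir)), d_i the total
#' (in+out) degree and d_i^bidir the number of reciprocated neighbours;
#' nodes with an undefined denominator score 0. Self-loops are excluded.
#'
#' @param web a [food_web].
#' @return numeric scalar in [0, 1]; 0 for an edgeless web.
#' @export
average_clustering <- function(web) {
  n <- length(web$nodes)
  if (n == 0) return(0)
  A <- web_adjacency(web, binary = TRUE)
  diag(A) <- 0
  if (sum(A) == 0) return(0)
  S <- A + t(A)
  Tri <- diag(S %*% S %*% S) / 2
  dtot <- rowSums(A) + colSums(A)
  dbi <- rowSums(A * t(A))
  denom <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  ci <- ifelse(denom > 0, Tri / denom, 0)
  mean(ci)
}

#' Flow hierarchy
#'
#' Fraction of edges that do not lie on any cycle, i.e. edges whose
#' endpoints are not in the same nontrivial strongly connected component
#' (self-loops count as cyclic). 1 on any DAG, 0 when every edge sits in a
#' cycle; an edgeless web is vacuously acyclic (1).
#'
#' An alternative hierarchy reading based on trophic coherence is available
#' as `method = "coherence"`: 1/(1 + q) with q the standard deviation of
#' the trophic-level jump over edges (regularized levels, so it is defined
#' on loop-dominated webs too).
#'
#' @param web a [food_web].
#' @param method `"flow"` (default) or `"coherence"`.
#' @return numeric scalar in [0, 1].
#' @export
flow_hierarchy <- function(web, method = c("flow", "coherence")) {
  method <- match.arg(method)
  e <- nrow(web$edges)
  if (method == "coherence") {
    if (e == 0) return(1)
    s <- trophic_levels(web, fallback = TRUE)$levels
    jump <- s[web$edges$predator] - s[web$edges$prey]
    q <- sqrt(max(0, mean(jump^2) - 1))  # coherent webs have jumps ~ 1
    return(1 / (1 + q))
  }
  if (e == 0) return(1)
  g <- as_igraph(web)
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership[web$nodes]
  sizes <- comp$csize
  cyc <- (member[web$edges$prey] == member[web$edges$predator]) &
    (sizes[member[web$edges$prey]] > 1 |
       web$edges$prey == web$edges$predator)
  1 - sum(cyc) / e
}

#' Compute one or more node indices on a web
#'
#' Convenience wrapper producing a long table over the requested indices.
#' Index keys: `dc` (degree centrality), `bc` (betweenness), `cc`
#' (closeness), `tl` (trophic level), `katz`.
#'
#' @param web a [food_web].
#' @param indices character vector of index keys.
#' @param ... passed to the individual index functions.
#' @return data frame `node`, `index`, `raw`, `normalized` stacked over
#'   indices.
#' @export
compute_indices <- function(web, indices = c("dc", "bc", "cc", "tl",
                                             "katz"), ...) {
  out <- lapply(indices, function(key) compute_one_index(web, key, ...))
  do.call(rbind, out)
}

compute_one_index <- function(web, key, alpha = 0.1, beta = 1,
                              weights_as_distance = "none",
                              tl_fallback = FALSE) {
  switch(key,
    dc = , degree_centrality = degree_centrality(web),
    bc = , betweenness = betweenness_centrality(web, weights_as_distance),
    cc = , closeness = closeness_centrality(web, weights_as_distance),
    tl = , trophic_level = {
      s <- trophic_levels(web, fallback = tl_fallback)$levels
      node_index_table(web$nodes, s[web$nodes], "trophic_level")
    },
    katz = katz_centrality(web, alpha = alpha, beta = beta),
    stop("unknown index `", key, "`; use dc, bc, cc, tl or katz",
         call. = FALSE))
}
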