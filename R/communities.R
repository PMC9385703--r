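## Partitions of a web's nodes (value-based, divisive, adapter-backed) and
## the five agreement scores used to compare a clustering against another
## clustering or against an expected grouping.

#' Construct a partition
#'
#' Cluster ids are relabeled to contiguous integers from 0 in order of
#' first appearance, so partitions compare deterministically; all agreement
#' scores are invariant to relabeling anyway.
#'
#' @param assignment named vector (node -> cluster id).
#' @param method provenance tag (e.g. `by_trophic_value`, `girvan_newman`,
#'   `expected`).
#' @param parameters list of the parameters that produced it.
#' @return named integer vector of class `fw_partition`.
#' @export
partition <- function(assignment, method = "manual", parameters = list()) {
  stopifnot(!is.null(names(assignment)), all(nzchar(names(assignment))))
  ids <- match(as.vector(assignment), unique(as.vector(assignment))) - 1L
  structure(stats::setNames(ids, names(assignment)),
            class = "fw_partition", method = method,
            parameters = parameters)
}

#' @export
print.fw_partition <- function(x, ...) {
  cat(sprintf("<fw_partition> %d nodes in %d clusters (method: %s)\n",
              length(x), length(unique(as.vector(x))), attr(x, "method")))
  invisible(x)
}

#' Cluster nodes by (near-)equality of a scalar value
#'
#' Nodes are sorted by value and chained into one cluster while successive
#' gaps are at most `tol` (transitive closure: a chain of small gaps can
#' span more than `tol` end to end). `tol = 0` groups exact equals. Typical
#' use: clustering by trophic level or Katz value.
#'
#' @param values named numeric vector (node -> value).
#' @param tol non-negative gap tolerance.
#' @param method provenance tag for the resulting partition.
#' @return an `fw_partition`; cluster ids increase with the value.
#' @export
cluster_by_value <- function(values, tol = 0, method = "by_value") {
  stopifnot(tol >= 0, !is.null(names(values)))
  if (length(values) == 0) {
    return(partition(stats::setNames(integer(0), character(0)), method))
  }
  ord <- order(values, names(values))
  v <- values[ord]
  breaks <- c(0, cumsum(diff(v) > tol))
  partition(stats::setNames(breaks, names(v))[names(values)],
            method = method, parameters = list(tol = tol))
}

#' Girvan-Newman divisive clustering
#'
#' Repeatedly removes the edge of maximal edge betweenness (directed,
#' unweighted shortest paths) until the number of weakly connected
#' components first reaches `target_k`. Ties are broken by removing the
#' lexicographically smallest (prey, predator) pair, making the dendrogram
#' fully deterministic. Self-loops never separate components and are never
#' removed.
#'
#' @param web a [food_web].
#' @param target_k requested number of (weakly connected) communities,
#'   between 1 and the number of nodes. `target_k = 1` returns the trivial
#'   single cluster without removals.
#' @return list with `partition` (an `fw_partition`), `removals` (data
#'   frame `step`, `prey`, `predator`, `betweenness`) and `dendrogram`
#'   (list of membership snapshots, one per component-count increase).
#' @export
girvan_newman <- function(web, target_k) {
  stopifnot(inherits(web, "food_web"))
  n <- length(web$nodes)
  if (target_k < 1 || target_k > n) {
    stop("target_k must be between 1 and the number of nodes (", n, ")",
         call. = FALSE)
  }
  members <- function(g) {
    igraph::components(g, mode = "weak")$membership[web$nodes]
  }
  if (target_k == 1) {
    part <- partition(stats::setNames(rep(0L, n), web$nodes),
                      method = "girvan_newman",
                      parameters = list(target_k = 1))
    return(list(partition = part,
                removals = data.frame(step = integer(), prey = character(),
                                      predator = character(),
                                      betweenness = numeric()),
                dendrogram = list()))
  }
  g <- as_igraph(web)
  removals <- list()
  dendro <- list()
  k_now <- igraph::components(g, mode = "weak")$no
  step <- 0L
  while (k_now < target_k) {
    el <- igraph::as_edgelist(g)
    keep <- el[, 1] != el[, 2]
    if (!any(keep)) break   # only self-loops left; components cannot grow
    eb <- igraph::edge_betweenness(g, directed = TRUE, weights = NA)
    cand <- which(keep)
    best <- cand[eb[cand] == max(eb[cand])]
    if (length(best) > 1) {
      best <- best[order(el[best, 1], el[best, 2])][1]
    }
    step <- step + 1L
    removals[[step]] <- data.frame(step = step, prey = el[best, 1],
                                   predator = el[best, 2],
                                   betweenness = eb[best],
                                   stringsAsFactors = FALSE)
    g <- igraph::delete_edges(g, best)
    k_new <- igraph::components(g, mode = "weak")$no
    if (k_new > k_now) {
      k_now <- k_new
      dendro[[length(dendro) + 1]] <- list(k = k_now, membership = members(g))
    }
  }
  part <- partition(members(g), method = "girvan_newman",
                    parameters = list(target_k = target_k))
  list(partition = part,
       removals = if (step > 0) do.call(rbind, removals) else
         data.frame(step = integer(), prey = character(),
                    predator = character(), betweenness = numeric()),
       dendrogram = dendro)
}

#' Community detection through a uniform adapter
#'
#' Dispatches to a registered backend and always returns an
#' `fw_partition`. Built-in methods: `girvan_newman` (needs `k`),
#' `by_trophic_value` and `by_katz_value` (optional `tol`), and the
#' map-equation adapter `infomap` (delegated to igraph's Infomap binding;
#' if the backend fails, a structured "unavailable" error is raised rather
#' than a crash).
#'
#' @param web a [food_web].
#' @param method method name.
#' @param k target community count for `girvan_newman`.
#' @param tol value tolerance for the value-based methods.
#' @param ... passed to the underlying index computation (e.g. `alpha`,
#'   `beta` for Katz; `fallback` for trophic levels).
#' @return an `fw_partition`.
#' @export
detect_communities <- function(web, method, k = NULL, tol = 0, ...) {
  stopifnot(inherits(web, "food_web"))
  switch(method,
    girvan_newman = {
      if (is.null(k)) stop("girvan_newman needs `k`", call. = FALSE)
      girvan_newman(web, k)$partition
    },
    by_trophic_value = {
      s <- trophic_levels(web, ...)$levels
      cluster_by_value(s, tol = tol, method = "by_trophic_value")
    },
    by_katz_value = {
      kt <- katz_centrality(web, ...)
      cluster_by_value(stats::setNames(kt$raw, kt$node), tol = tol,
                       method = "by_katz_value")
    },
    infomap = {
      res <- tryCatch(
        igraph::cluster_infomap(as_igraph(web)),
        error = function(e) {
          stop("map-equation backend unavailable: ", conditionMessage(e),
               call. = FALSE)
        })
      partition(igraph::membership(res)[web$nodes], method = "infomap")
    },
    stop("unknown method `", method, "`; available: girvan_newman, ",
         "by_trophic_value, by_katz_value, infomap", call. = FALSE))
}

#' Agreement between two partitions
#'
#' All five scores are computed from the contingency table of the two
#' labelings over the same node set and are invariant to relabeling.
#' Rand index: fraction of concordant node pairs. Homogeneity:
#' 1 - H(ref|pred)/H(ref), 1 when H(ref) = 0; completeness is the same with
#' the roles swapped; entropies are natural-log with 0 log 0 = 0.
#' V-measure: harmonic mean of homogeneity and completeness (0 when both
#' are 0). Fowlkes-Mallows: TP / sqrt((TP+FP)(TP+FN)) over co-membership
#' pairs; when both partitions have no co-membership pairs at all (all
#' singletons) they agree perfectly and the score is 1.
#'
#' @param predicted,reference `fw_partition`s (or named vectors) over the
#'   same node set; a mismatch is an error listing the differing nodes.
#' @return list of class `agreement_scores`: `rand`, `homogeneity`,
#'   `completeness`, `v_measure`, `fowlkes_mallows`, all in [0, 1].
#' @export
agreement_scores <- function(predicted, reference) {
  pn <- names(predicted); rn <- names(reference)
  if (!setequal(pn, rn) || length(pn) != length(rn)) {
    diffs <- c(setdiff(pn, rn), setdiff(rn, pn))
    stop("partitions cover different node sets; differing nodes: ",
         paste(unique(diffs), collapse = ", "), call. = FALSE)
  }
  pred <- as.vector(predicted[rn])
  ref <- as.vector(reference)
  n <- length(ref)
  ct <- table(ref, pred)
  choose2 <- function(x) x * (x - 1) / 2
  tp <- sum(choose2(ct))
  pairs_ref <- sum(choose2(rowSums(ct)))
  pairs_pred <- sum(choose2(colSums(ct)))
  total <- choose2(n)
  fp <- pairs_pred - tp
  fn <- pairs_ref - tp
  tn <- total - tp - fp - fn
  rand <- if (total > 0) (tp + tn) / total else 1
  fm <- if (pairs_pred == 0 && pairs_ref == 0) 1 else
    if (pairs_pred == 0 || pairs_ref == 0) 0 else
      tp / sqrt(pairs_pred * pairs_ref)
  ent <- function(sizes) {
    p <- sizes[sizes > 0] / n
    -sum(p * log(p))
  }
  h_ref <- ent(rowSums(ct))
  h_pred <- ent(colSums(ct))
  cond_ent <- function(tab) {
    ## H(rows | cols)
    tot <- colSums(tab)
    s <- 0
    for (j in seq_len(ncol(tab))) {
      nz <- tab[, j][tab[, j] > 0]
      s <- s - sum(nz / n * log(nz / tot[j]))
    }
    s
  }
  homogeneity <- if (h_ref == 0) 1 else 1 - cond_ent(ct) / h_ref
  completeness <- if (h_pred == 0) 1 else 1 - cond_ent(t(ct)) / h_pred
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  structure(list(rand = rand, homogeneity = homogeneity,
                 completeness = completeness, v_measure = v,
                 fowlkes_mallows = fm),
            class = "agreement_scores")
}

#' @export
print.agreement_scores <- function(x, ...) {
  cat(sprintf(paste0("<agreement_scores> rand %.3f | homogeneity %.3f | ",
                     "completeness %.3f | v %.3f | fowlkes-mallows %.3f\n"),
              x$rand, x$homogeneity, x$completeness, x$v_measure,
              x$fowlkes_mallows))
  invisible(x)
}
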