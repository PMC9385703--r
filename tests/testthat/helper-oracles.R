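# Brute-force oracles, deliberately independent of the package internals
# (explicit path enumeration, fixed-point iteration, pairwise counting).
# Only usable at toy sizes; that is the point.

oracle_adj <- function(web) {
  n <- length(web$nodes)
  A <- matrix(0, n, n, dimnames = list(web$nodes, web$nodes))
  for (k in seq_len(nrow(web$edges))) {
    A[web$edges$prey[k], web$edges$predator[k]] <- web$edges$weight[k]
  }
  A
}

# all simple directed paths s -> t as vectors of node indices
oracle_paths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (w in seq_len(n)) {
      if (A[v, w] > 0 && !(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

oracle_betweenness <- function(web) {
  A <- oracle_adj(web); n <- nrow(A)
  bc <- setNames(rep(0, n), web$nodes)
  if (n < 3) return(bc)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- oracle_paths(A, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, 0L)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  bc / ((n - 1) * (n - 2))
}

oracle_closeness <- function(web) {
  A <- oracle_adj(web); n <- nrow(A)
  cc <- setNames(rep(0, n), web$nodes)
  if (n < 2) return(cc)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) { dist[s, t] <- 0; next }
    paths <- oracle_paths(A, s, t)
    if (length(paths) > 0) {
      dist[s, t] <- min(vapply(paths, length, 0L)) - 1
    }
  }
  for (u in seq_len(n)) {
    d <- dist[-u, u]
    d <- d[is.finite(d)]
    if (length(d) > 0 && sum(d) > 0) {
      cc[u] <- (length(d) / sum(d)) * (length(d) / (n - 1))
    }
  }
  cc
}

oracle_degree_centrality <- function(web) {
  n <- length(web$nodes)
  deg <- setNames(rep(0, n), web$nodes)
  for (k in seq_len(nrow(web$edges))) {
    deg[web$edges$prey[k]] <- deg[web$edges$prey[k]] + 1
    deg[web$edges$predator[k]] <- deg[web$edges$predator[k]] + 1
  }
  if (n > 1) deg / (n - 1) else deg * 0
}

oracle_katz <- function(web, alpha = 0.1, beta = 1, iters = 500) {
  A <- oracle_adj(web)
  A[A > 0] <- 1
  x <- rep(0, nrow(A))
  for (i in seq_len(iters)) x <- alpha * t(A) %*% x + beta
  x <- as.vector(x)
  setNames(x / sqrt(sum(x^2)), web$nodes)
}

oracle_trophic <- function(web, iters = 400) {
  A <- oracle_adj(web)
  inw <- colSums(A)
  s <- setNames(rep(1, length(web$nodes)), web$nodes)
  for (i in seq_len(iters)) {
    s_new <- s
    for (v in which(inw > 0)) {
      s_new[v] <- 1 + sum(A[, v] * s) / inw[v]
    }
    s <- s_new
  }
  s
}

oracle_simplify <- function(web, mapping) {
  m <- setNames(mapping$group, mapping$original)
  acc <- list()
  for (k in seq_len(nrow(web$edges))) {
    key <- paste(m[web$edges$prey[k]], m[web$edges$predator[k]],
                 sep = " -> ")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
      web$edges$weight[k]
  }
  acc
}

oracle_triangles <- function(web) {
  # cyclic + all-motif directed triangles per node, counted by triple loops
  A <- oracle_adj(web); A[A > 0] <- 1; diag(A) <- 0
  n <- nrow(A)
  S <- A + t(A)
  tri <- setNames(rep(0, n), web$nodes)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k) {
      tri[i] <- tri[i] + S[i, j] * S[j, k] * S[k, i]
    }
  }
  tri / 2
}

oracle_clustering <- function(web) {
  A <- oracle_adj(web); A[A > 0] <- 1; diag(A) <- 0
  n <- nrow(A)
  if (n == 0) return(0)
  tri <- oracle_triangles(web)
  ci <- rep(0, n)
  for (i in seq_len(n)) {
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    denom <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    if (denom > 0) ci[i] <- tri[i] / denom
  }
  mean(ci)
}

oracle_agreement <- function(pred, ref) {
  nodes <- names(ref)
  p <- as.vector(pred[nodes]); r <- as.vector(ref)
  n <- length(nodes)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- p[i] == p[j]; sr <- r[i] == r[j]
    if (sp && sr) tp <- tp + 1
    else if (sp && !sr) fp <- fp + 1
    else if (!sp && sr) fn <- fn + 1
    else tn <- tn + 1
  }
  total <- tp + fp + fn + tn
  rand <- if (total > 0) (tp + tn) / total else 1
  fm <- if (tp + fp == 0 && tp + fn == 0) 1 else
    if (tp + fp == 0 || tp + fn == 0) 0 else
      tp / sqrt((tp + fp) * (tp + fn))
  h_of <- function(x) {
    s <- 0
    for (lv in unique(x)) {
      q <- mean(x == lv)
      s <- s - q * log(q)
    }
    s
  }
  cond <- function(a, b) { # H(a | b)
    s <- 0
    for (lb in unique(b)) {
      idx <- b == lb
      for (la in unique(a[idx])) {
        pj <- sum(a == la & b == lb) / n
        s <- s - pj * log(sum(a == la & idx) / sum(idx))
      }
    }
    s
  }
  hom <- if (h_of(r) == 0) 1 else 1 - cond(r, p) / h_of(r)
  com <- if (h_of(p) == 0) 1 else 1 - cond(p, r) / h_of(p)
  v <- if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
  list(rand = rand, homogeneity = hom, completeness = com, v_measure = v,
       fowlkes_mallows = fm)
}

random_partition <- function(nodes, k) {
  partition(setNames(sample.int(k, length(nodes), replace = TRUE), nodes))
}

# lift a nested synthetic taxonomy onto the group labels of a simplified
# web, so a simplified web can itself be simplified one level further
lift_taxonomy <- function(taxonomy, mapping) {
  rows <- lapply(unique(mapping$group), function(g) {
    member <- mapping$original[mapping$group == g][1]
    row <- taxonomy[member, , drop = FALSE]
    row$taxon <- g
    used <- match(TRUE, unlist(row[accepted_ranks()]) == g)
    if (!is.na(used)) {
      finer <- accepted_ranks()[seq_len(used - 1)]
      row[, finer] <- NA_character_
    }
    row
  })
  taxonomy_table(do.call(rbind, rows))
}
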