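#' Construct a food web
#'
#' A food web is a directed graph whose edges run from prey to predator,
#' following the direction of energy flow. Each ordered (prey, predator)
#' pair carries a single positive weight; duplicate pairs passed to the
#' constructor are merged by summing their weights, mirroring how repeated
#' interaction records are treated when taxa are lumped.
#'
#' @param edges data frame with character columns `prey` and `predator` and
#'   an optional numeric `weight` column (defaults to 1 per row).
#' @param nodes character vector of node labels; defaults to the labels seen
#'   in `edges`. Extra labels become isolated nodes, which are permitted
#'   (e.g. producers with no recorded consumer).
#' @param name network name, carried through for reporting.
#' @param weighted logical: did the source data carry weights? Unweighted
#'   sources still materialise weight 1 per interaction record.
#' @return An object of class `food_web`: a list with elements `name`,
#'   `nodes` (character), `edges` (data frame `prey`, `predator`, `weight`,
#'   sorted canonically) and `weighted`.
#' @examples
#' web <- food_web(data.frame(prey = c("alga", "midge"),
#'                            predator = c("midge", "trout")))
#' web_summary(web)
#' @export
food_web <- function(edges = NULL, nodes = NULL, name = "web",
                     weighted = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(prey = character(), predator = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("prey", "predator") %in% names(edges))) {
    stop("`edges` must have columns `prey` and `predator`", call. = FALSE)
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$prey <- normalize_label(as.character(edges$prey))
  edges$predator <- normalize_label(as.character(edges$predator))
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) {
    stop("non-numeric edge weight at row ",
         paste(which(is.na(edges$weight)), collapse = ", "), call. = FALSE)
  }
  if (any(edges$weight <= 0)) {
    stop("non-positive edge weight at row ",
         paste(which(edges$weight <= 0), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(edges$prey)) || any(!nzchar(edges$predator))) {
    stop("empty node label in edge list", call. = FALSE)
  }
  ## merge parallel records for the same ordered pair by weight summation
  if (nrow(edges) > 0) {
    key <- paste(edges$prey, edges$predator, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(edges$weight, key, sum)
      parts <- strsplit(names(w), "\r", fixed = TRUE)
      edges <- data.frame(prey = vapply(parts, `[`, "", 1),
                          predator = vapply(parts, `[`, "", 2),
                          weight = as.numeric(w),
                          stringsAsFactors = FALSE)
    }
    edges <- edges[order(edges$prey, edges$predator), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) {
    nodes <- character()
  } else {
    nodes <- normalize_label(as.character(nodes))
  }
  nodes <- sort(unique(c(nodes, edges$prey, edges$predator)))
  if (any(!nzchar(nodes))) stop("empty node label", call. = FALSE)
  structure(list(name = as.character(name)[1], nodes = nodes, edges = edges,
                 weighted = isTRUE(weighted)),
            class = "food_web")
}

#' Normalize a taxon label
#'
#' Trims leading/trailing whitespace and collapses internal runs to a single
#' space; case is preserved. Databases frequently carry inconsistent spacing
#' in taxonomy strings, and label-keyed graphs must not split one taxon into
#' two over a stray blank.
#'
#' @param x character vector of labels.
#' @return character vector of cleaned labels.
#' @export
normalize_label <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("<food_web> %s: %d nodes, %d edges (%s), total weight %g\n",
              x$name, length(x$nodes), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted",
              total_weight(x)))
  invisible(x)
}

#' Total interaction weight of a web
#'
#' For an unweighted source this equals the number of interaction records
#' that went into the web; it is conserved by taxonomic simplification.
#'
#' @param web a `food_web`.
#' @return numeric scalar.
#' @export
total_weight <- function(web) {
  stopifnot(inherits(web, "food_web"))
  sum(web$edges$weight)
}

#' Number of self-loops in a web
#'
#' Self-loops appear when a predator and its prey are lumped into the same
#' group; they are retained by simplification so the pathology stays visible.
#'
#' @param web a `food_web`.
#' @return integer count.
#' @export
count_self_loops <- function(web) {
  stopifnot(inherits(web, "food_web"))
  sum(web$edges$prey == web$edges$predator)
}

#' Convert a food web to an igraph graph
#'
#' Edges keep the prey-to-predator direction; edge weights are carried in
#' the `weight` attribute.
#'
#' @param web a `food_web`.
#' @return a directed `igraph` graph.
#' @export
as_igraph <- function(web) {
  stopifnot(inherits(web, "food_web"))
  igraph::graph_from_data_frame(
    web$edges[, c("prey", "predator", "weight")],
    directed = TRUE, vertices = web$nodes)
}

## adjacency matrix A with A[prey, predator] = weight (or 1 if binary)
web_adjacency <- function(web, binary = FALSE) {
  n <- length(web$nodes)
  A <- matrix(0, n, n, dimnames = list(web$nodes, web$nodes))
  if (nrow(web$edges) > 0) {
    idx <- cbind(match(web$edges$prey, web$nodes),
                 match(web$edges$predator, web$nodes))
    A[idx] <- if (binary) 1 else web$edges$weight
  }
  A
}

#' Test two food webs for equality
#'
#' Compares node sets, edge sets and weights exactly (labels as strings,
#' weights with a tolerance for floating point).
#'
#' @param a,b `food_web` objects.
#' @param tol numeric tolerance on weights.
#' @return logical scalar.
#' @export
webs_identical <- function(a, b, tol = 1e-12) {
  stopifnot(inherits(a, "food_web"), inherits(b, "food_web"))
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  if (nrow(a$edges) != nrow(b$edges)) return(FALSE)
  if (nrow(a$edges) == 0) return(TRUE)
  identical(a$edges$prey, b$edges$prey) &&
    identical(a$edges$predator, b$edges$predator) &&
    all(abs(a$edges$weight - b$edges$weight) <= tol)
}
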