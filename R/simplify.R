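## The core operator: collapse food-web nodes by taxonomy to a scheme level
## and merge edges by weight summation, so the output has exactly one
## predator-prey interaction per ordered group pair.

## Resolve one taxon to (label, rank_used). rank_used is NA for raw,
## literal and passthrough labels.
map_node_full <- function(taxon, taxonomy, scheme, level,
                          unknown = c("passthrough", "strict",
                                      "group-label")) {
  unknown <- match.arg(unknown)
  if (!level %in% scheme$levels) {
    stop("unknown level `", level, "`; scheme levels: ",
         paste(scheme$levels, collapse = ", "), call. = FALSE)
  }
  if (level == "raw") return(list(label = taxon, rank = NA_character_))
  row <- if (taxon %in% rownames(taxonomy)) {
    taxonomy[taxon, , drop = FALSE]
  } else NULL
  if (is.null(row)) {
    if (unknown == "strict") {
      stop("unknown taxon `", taxon, "` not in taxonomy (strict mode)",
           call. = FALSE)
    }
    return(list(label = taxon, rank = NA_character_))
  }
  if (unknown == "group-label" && !is.na(row$group)) {
    return(list(label = row$group, rank = NA_character_))
  }
  target <- scheme_target(scheme, taxon, row, level)
  if (is.null(target)) {
    stop("no scheme rule matches taxon `", taxon, "` at level `", level,
         "` (tried exact label, phylum, default)", call. = FALSE)
  }
  ci <- rank_coarseness(target)
  if (is.na(ci)) return(list(label = target, rank = NA_character_)) # literal
  ## ragged-lineage fallback: nearest PRESENT rank at-or-coarser than target
  for (r in accepted_ranks()[ci:length(accepted_ranks())]) {
    v <- row[[r]]
    if (!is.na(v)) return(list(label = v, rank = r))
  }
  list(label = taxon, rank = NA_character_)
}

#' Map one taxon to its group label at a simplification level
#'
#' Applies the scheme rule matched for the taxon (exact label, then phylum,
#' then default) and returns the lineage value at the target rank. When the
#' target rank is absent from a ragged lineage, the nearest present coarser
#' rank is used; with nothing present the taxon keeps its own label. Level
#' `raw` is the identity.
#'
#' @param taxon node label.
#' @param taxonomy a [taxonomy_table].
#' @param scheme a [simplification_scheme].
#' @param level level name.
#' @param unknown policy for taxa absent from the taxonomy: `passthrough`
#'   keeps the original label (undetermined entities stay visible under
#'   their own name), `strict` raises an error, `group-label` uses the
#'   taxonomy's vernacular group column when present.
#' @return group label (character scalar).
#' @export
map_node <- function(taxon, taxonomy, scheme, level,
                     unknown = c("passthrough", "strict", "group-label")) {
  map_node_full(normalize_label(taxon), taxonomy, scheme, level,
                unknown)$label
}

#' Simplify a food web to a scheme level
#'
#' Every node is mapped to its group label; an output edge (G1, G2) exists
#' iff at least one original edge maps onto it, and its weight is the sum
#' of the constituent original weights (weight 1 per record for unweighted
#' sources). The result therefore has exactly one predator-prey interaction
#' per ordered group pair and conserves total weight. Self-loops — a
#' predator lumped together with its own prey — are retained by default and
#' counted, so the over-simplification pathology is surfaced rather than
#' hidden; dropping them (opt-in) breaks weight conservation.
#'
#' Homonym guard: a rank-derived group label shared by lineages from
#' different phyla (e.g. the same genus name in two phyla) is disambiguated
#' by suffixing the phylum, so unrelated taxa are never silently merged.
#'
#' @inheritParams map_node
#' @param web a [food_web].
#' @param drop_self_loops logical, default `FALSE`.
#' @return list with elements `web` (the simplified [food_web]), `mapping`
#'   (data frame `original`, `group`, with attribute `level`) and
#'   `n_self_loops` (count before any dropping).
#' @examples
#' fx <- make_fixture("table4")
#' simplify_web(fx$web, fx$taxonomy, fx$scheme, "low")$web
#' @export
simplify_web <- function(web, taxonomy, scheme, level,
                         unknown = c("passthrough", "strict", "group-label"),
                         drop_self_loops = FALSE) {
  stopifnot(inherits(web, "food_web"))
  unknown <- match.arg(unknown)
  res <- lapply(web$nodes, map_node_full, taxonomy = taxonomy,
                scheme = scheme, level = level, unknown = unknown)
  labels <- vapply(res, `[[`, "", "label")
  ranks <- vapply(res, function(x) as.character(x$rank), "")
  labels <- disambiguate_homonyms(web$nodes, labels, ranks, taxonomy)
  assignment <- stats::setNames(labels, web$nodes)
  ed <- web$edges
  new_edges <- data.frame(prey = unname(assignment[ed$prey]),
                          predator = unname(assignment[ed$predator]),
                          weight = ed$weight, stringsAsFactors = FALSE)
  n_self <- if (nrow(new_edges) > 0) {
    sum(new_edges$prey == new_edges$predator)
  } else 0L
  if (drop_self_loops && n_self > 0) {
    new_edges <- new_edges[new_edges$prey != new_edges$predator, ,
                           drop = FALSE]
  }
  out <- food_web(new_edges, nodes = unique(unname(assignment)),
                  name = paste0(web$name, "_", level),
                  weighted = if (level == "raw") web$weighted else TRUE)
  mapping <- data.frame(original = web$nodes, group = unname(assignment),
                        stringsAsFactors = FALSE)
  attr(mapping, "level") <- level
  list(web = out, mapping = mapping, n_self_loops = as.integer(n_self))
}

## suffix the phylum when one rank-derived label spans several phyla
disambiguate_homonyms <- function(nodes, labels, ranks, taxonomy) {
  fine <- !is.na(ranks) & ranks %in% accepted_ranks()[1:5] # finer than phylum
  if (!any(fine)) return(labels)
  phyla <- rep(NA_character_, length(nodes))
  known <- nodes %in% rownames(taxonomy)
  phyla[known] <- taxonomy[nodes[known], "phylum"]
  for (lab in unique(labels[fine])) {
    idx <- which(labels == lab & fine)
    ph <- unique(phyla[idx][!is.na(phyla[idx])])
    if (length(ph) > 1) {
      fix <- idx[!is.na(phyla[idx])]
      labels[fix] <- paste(lab, phyla[fix], sep = "_")
    }
  }
  labels
}

#' Simplify a web across all scheme levels
#'
#' Returns the web at every level in scheme order (starting with `raw`).
#' Under a rank-monotone (nested) scheme, simplifying the raw web directly
#' to a level equals cascading through the intermediate levels, and node
#' and edge counts are non-increasing along the list.
#'
#' @inheritParams simplify_web
#' @param levels subset of scheme levels to produce (default: all).
#' @return named list (one element per level) of [simplify_web()] results.
#' @export
simplify_cascade <- function(web, taxonomy, scheme,
                             levels = scheme$levels,
                             unknown = c("passthrough", "strict",
                                         "group-label"),
                             drop_self_loops = FALSE) {
  unknown <- match.arg(unknown)
  validate_monotonicity(scheme)
  stopifnot(all(levels %in% scheme$levels))
  out <- lapply(levels, function(lv) {
    simplify_web(web, taxonomy, scheme, lv, unknown = unknown,
                 drop_self_loops = drop_self_loops)
  })
  names(out) <- levels
  out
}
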