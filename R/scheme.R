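## Simplification schemes: the ordered resolution levels and the per-group
## target ranks that drive taxonomic lumping. A scheme is the shareable
## meta-file documenting exactly how much resolution a web retains.

#' Taxonomic ranks, finest to coarsest
#' @return character vector of the accepted rank names.
#' @export
accepted_ranks <- function() {
  c("species", "genus", "family", "order", "class", "phylum", "kingdom")
}

rank_coarseness <- function(rank) {
  match(tolower(rank), accepted_ranks())
}

#' Construct a simplification scheme
#'
#' A scheme holds an ordered list of level names and, for each
#' (group key, level), a target: either a taxonomic rank (nodes are lumped
#' to their lineage value at that rank) or a literal label (mixed-mode
#' "common word" grouping, e.g. `Beetles_water`). Group keys are resolved
#' per taxon in the order: exact taxon label, then the taxon's phylum, then
#' the key `default`.
#'
#' The level `raw` always maps every taxon to itself and is prepended if
#' absent. Within each group key the target rank must be equal or coarser
#' at every successive level (rank monotonicity); this guarantees that each
#' level is a simplified version of its predecessor, and violations are a
#' validation error.
#'
#' @param rules data frame with columns `group_key`, `level`, `target`.
#' @param levels character vector of level names in simplification order.
#' @param strict_ranks logical; when `TRUE`, a target that is not a rank
#'   name is a validation error (listing the accepted ranks) instead of
#'   being treated as a literal label.
#' @return a `simplification_scheme` (list with `levels` and `rules`).
#' @export
simplification_scheme <- function(rules,
                                  levels = c("raw", "low", "med",
                                             "med-high", "high", "top"),
                                  strict_ranks = FALSE) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  stopifnot(all(c("group_key", "level", "target") %in% names(rules)))
  levels <- as.character(levels)
  if (!"raw" %in% levels) levels <- c("raw", levels)
  if (anyDuplicated(levels)) stop("duplicate level names", call. = FALSE)
  rules <- rules[rules$level != "raw", , drop = FALSE]
  bad <- setdiff(rules$level, levels)
  if (length(bad) > 0) {
    stop("validation error: rule for unknown level ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  is_rank <- !is.na(rank_coarseness(rules$target))
  if (strict_ranks && any(!is_rank)) {
    stop("validation error: unknown rank `",
         paste(unique(rules$target[!is_rank]), collapse = "`, `"),
         "`; accepted ranks: ", paste(accepted_ranks(), collapse = ", "),
         call. = FALSE)
  }
  ## canonical lowercase for rank targets, literals kept verbatim
  rules$target[is_rank] <- tolower(rules$target[is_rank])
  scheme <- structure(list(levels = levels, rules = rules),
                      class = "simplification_scheme")
  validate_monotonicity(scheme)
  scheme
}

validate_monotonicity <- function(scheme) {
  ord <- scheme$levels
  for (key in unique(scheme$rules$group_key)) {
    sub <- scheme$rules[scheme$rules$group_key == key, , drop = FALSE]
    sub <- sub[order(match(sub$level, ord)), , drop = FALSE]
    coarse <- rank_coarseness(sub$target)
    ranked <- which(!is.na(coarse))
    if (length(ranked) > 1) {
      cr <- coarse[ranked]
      drop_at <- which(diff(cr) < 0)
      if (length(drop_at) > 0) {
        i <- ranked[drop_at[1]]
        stop("validation error: rank monotonicity violated for group `",
             key, "`: level `", sub$level[ranked[drop_at[1] + 1]],
             "` (", sub$target[ranked[drop_at[1] + 1]],
             ") is finer than level `", sub$level[i], "` (", sub$target[i],
             ")", call. = FALSE)
      }
    }
  }
  invisible(scheme)
}

#' Default 6-level scheme
#'
#' Levels raw, low, med, med-high, high, top with a single `default` rule
#' lumping at genus, family, order, class and phylum respectively — the
#' generic progression used when no per-group scheme is supplied.
#'
#' @return a [simplification_scheme].
#' @export
default_scheme <- function() {
  simplification_scheme(data.frame(
    group_key = "default",
    level = c("low", "med", "med-high", "high", "top"),
    target = c("genus", "family", "order", "class", "phylum"),
    stringsAsFactors = FALSE))
}

#' Read a scheme meta-file
#'
#' One row per group key, one column per level naming a rank or a literal
#' label; the first column (named `group` or simply first) holds the group
#' key. Empty cells mean "no rule at this level for this group" (the
#' default rule, if present, applies). Rank monotonicity is enforced.
#'
#' @inheritParams read_edgelist
#' @param strict_ranks see [simplification_scheme()].
#' @return a [simplification_scheme].
#' @export
read_scheme <- function(source, delim = NULL, strict_ranks = FALSE) {
  df <- read_delim_table(source, delim = delim)
  key_col <- if ("group" %in% tolower(names(df))) {
    which(tolower(names(df)) == "group")[1]
  } else 1L
  level_cols <- setdiff(seq_along(df), key_col)
  levels <- names(df)[level_cols]
  rows <- lapply(level_cols, function(j) {
    tgt <- normalize_label(as.character(df[[j]]))
    keep <- nzchar(tgt) & !is.na(tgt) & tgt != "NA"
    data.frame(group_key = normalize_label(df[[key_col]])[keep],
               level = names(df)[j], target = tgt[keep],
               stringsAsFactors = FALSE)
  })
  simplification_scheme(do.call(rbind, rows),
                        levels = c("raw", setdiff(levels, "raw")),
                        strict_ranks = strict_ranks)
}

#' @export
print.simplification_scheme <- function(x, ...) {
  cat("<simplification_scheme> levels:", paste(x$levels, collapse = " > "),
      "\n", nrow(x$rules), "rules over",
      length(unique(x$rules$group_key)), "group keys\n")
  invisible(x)
}

## look up the target for a taxon at a level; `row` is the taxonomy row
## (or NULL when the taxon is absent from the taxonomy)
scheme_target <- function(scheme, taxon, row, level) {
  rules <- scheme$rules[scheme$rules$level == level, , drop = FALSE]
  keys <- rules$group_key
  hit <- which(keys == taxon)
  if (length(hit) == 0 && !is.null(row) && !is.na(row$phylum)) {
    hit <- which(keys == row$phylum)
  }
  if (length(hit) == 0) hit <- which(keys == "default")
  if (length(hit) == 0) return(NULL)
  rules$target[hit[1]]
}
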