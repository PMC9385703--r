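## Readers and writers for the delimited formats the package exchanges:
## edge lists, interaction matrices, taxonomy tables, scheme meta-files,
## group mappings and partitions. All are plain text with a header; lines
## starting with `#` are treated as comments (the CLI writes provenance
## comments there).

read_text_lines <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
}

## isolated nodes recorded by write_edgelist in a structured comment
read_isolated_comment <- function(source) {
  lines <- readLines(source, warn = FALSE)
  hit <- grep("^#[[:space:]]*%% isolated-nodes:", lines, value = TRUE)
  if (length(hit) == 0) return(character())
  strsplit(sub("^#[[:space:]]*%% isolated-nodes:[[:space:]]*", "",
               hit[1]), "|", fixed = TRUE)[[1]]
}

sniff_delim <- function(line) {
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

read_delim_table <- function(source, delim = NULL, dec = ".",
                             row_names = FALSE) {
  lines <- read_text_lines(source)
  if (length(lines) == 0) stop("format error: empty input", call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(lines[1])
  utils::read.table(text = lines, sep = delim, dec = dec, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = if (row_names) 1 else NULL,
                    quote = "\"", comment.char = "")
}

match_column <- function(df, column, what) {
  if (is.numeric(column)) {
    if (column < 1 || column > ncol(df)) {
      stop("format error: no column ", column, " for ", what, call. = FALSE)
    }
    return(as.integer(column))
  }
  hit <- which(tolower(names(df)) == tolower(column))
  if (length(hit) == 0) {
    stop("format error: missing column `", column, "` (", what, ")",
         call. = FALSE)
  }
  hit[1]
}

#' Read a food web from a delimited edge list
#'
#' The file must have a header; predator and prey columns are located by
#' name (case-insensitive) or by position. Edges are stored prey-to-predator
#' regardless of the column order in the file. Rows repeating the same
#' ordered (prey, predator) pair are summed into a single weighted edge, so
#' raw interaction-record files need no pre-aggregation.
#'
#' @param source file path or connection.
#' @param predator_col,prey_col,weight_col column name or 1-based position.
#' @param has_weights logical; `NULL` (default) auto-detects from the
#'   presence of the weight column. When `FALSE`, every record counts 1.
#' @param delim field delimiter; `NULL` auto-detects among comma, tab and
#'   semicolon.
#' @param dec decimal mark; set `","` for locales that print decimal commas.
#' @param name network name.
#' @return a [food_web].
#' @export
read_edgelist <- function(source, predator_col = "predator",
                          prey_col = "prey", weight_col = "weight",
                          has_weights = NULL, delim = NULL, dec = ".",
                          name = "web") {
  isolated <- if (is.character(source)) read_isolated_comment(source) else
    character()
  df <- read_delim_table(source, delim = delim, dec = dec)
  ip <- match_column(df, predator_col, "predator")
  iq <- match_column(df, prey_col, "prey")
  iw <- tryCatch(match_column(df, weight_col, "weight"), error = function(e) NA)
  if (is.null(has_weights)) has_weights <- !is.na(iw)
  if (has_weights && is.na(iw)) {
    stop("format error: has_weights = TRUE but no weight column", call. = FALSE)
  }
  w <- if (has_weights) {
    wv <- df[[iw]]
    if (is.character(wv)) {
      wv <- suppressWarnings(as.numeric(sub(",", ".", wv, fixed = TRUE)))
    }
    if (anyNA(wv)) {
      stop("value error: non-numeric weight at row ",
           paste(which(is.na(wv)), collapse = ", "), call. = FALSE)
    }
    if (any(wv <= 0)) {
      stop("value error: non-positive weight at row ",
           paste(which(wv <= 0), collapse = ", "), call. = FALSE)
    }
    wv
  } else rep(1, nrow(df))
  food_web(data.frame(prey = df[[iq]], predator = df[[ip]], weight = w,
                      stringsAsFactors = FALSE),
           nodes = isolated, name = name, weighted = has_weights)
}

#' Read a food web from a labelled interaction matrix
#'
#' Web of Life style export: first column holds row labels, remaining
#' columns are labelled numeric cells; a cell greater than zero is an
#' interaction with that value as weight. By default rows are resources
#' (prey) and columns consumers (predators); `rows_are_prey = FALSE` flips
#' the interpretation explicitly — orientation is never guessed.
#'
#' @inheritParams read_edgelist
#' @param rows_are_prey logical orientation flag.
#' @param weighted logical: carry cell values as weights (default) or mark
#'   the web unweighted (cells are still used as weights, which are all 1
#'   in a binary matrix).
#' @return a [food_web]; row and column label sets are unioned into the
#'   node set, so all-zero rows/columns become isolated nodes.
#' @export
read_interaction_matrix <- function(source, rows_are_prey = TRUE,
                                    delim = NULL, dec = ".", name = "web",
                                    weighted = TRUE) {
  m <- tryCatch(read_delim_table(source, delim = delim, dec = dec,
                                 row_names = TRUE),
                error = function(e) {
                  stop("format error: ", conditionMessage(e), call. = FALSE)
                })
  mat <- as.matrix(m)
  if (!is.numeric(mat)) {
    mat2 <- suppressWarnings(apply(mat, 2, function(col)
      as.numeric(sub(",", ".", col, fixed = TRUE))))
    if (anyNA(mat2)) stop("value error: non-numeric cell", call. = FALSE)
    mat <- matrix(mat2, nrow = nrow(m), dimnames = dimnames(m))
  }
  if (anyNA(mat)) stop("format error: ragged or missing cells", call. = FALSE)
  if (any(mat < 0)) stop("value error: negative cell", call. = FALSE)
  nz <- which(mat > 0, arr.ind = TRUE)
  rlab <- normalize_label(rownames(m))
  clab <- normalize_label(colnames(m))
  edges <- data.frame(
    prey = if (rows_are_prey) rlab[nz[, 1]] else clab[nz[, 2]],
    predator = if (rows_are_prey) clab[nz[, 2]] else rlab[nz[, 1]],
    weight = mat[nz], stringsAsFactors = FALSE)
  food_web(edges, nodes = c(rlab, clab), name = name, weighted = weighted)
}

#' Write a food web as a CSV edge list
#'
#' Columns `predator,prey,weight`; reading the result back with
#' [read_edgelist()] reproduces an identical web (round-trip identity).
#' Isolated nodes, which an edge list cannot carry as rows, are recorded in
#' a structured `#%% isolated-nodes:` comment that [read_edgelist()]
#' understands.
#'
#' @param web a [food_web].
#' @param sink file path or connection.
#' @param header_comment optional character vector written as `#` comment
#'   lines before the header (used by the CLI for provenance).
#' @export
write_edgelist <- function(web, sink, header_comment = NULL) {
  stopifnot(inherits(web, "food_web"))
  isolated <- setdiff(web$nodes, c(web$edges$prey, web$edges$predator))
  if (length(isolated) > 0) {
    header_comment <- c(header_comment,
                        paste0("%% isolated-nodes: ",
                               paste(isolated, collapse = "|")))
  }
  df <- data.frame(predator = web$edges$predator, prey = web$edges$prey,
                   weight = web$edges$weight, stringsAsFactors = FALSE)
  write_with_comments(df, sink, header_comment)
  invisible(sink)
}

write_with_comments <- function(df, sink, header_comment = NULL) {
  con <- if (is.character(sink)) file(sink, "w") else sink
  if (is.character(sink)) on.exit(close(con))
  for (line in header_comment) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

rank_names <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Read a taxonomy table
#'
#' Expected header: `taxon,kingdom,phylum,class,order,family,genus,species`
#' plus an optional `group` column carrying a vernacular group label
#' (e.g. `Beetles_water`). Any rank slot may be empty — real taxonomies are
#' ragged, and missing ranks are handled downstream by falling back to the
#' nearest present coarser rank.
#'
#' @inheritParams read_edgelist
#' @return a `taxonomy_table`: a data frame keyed by unique `taxon`.
#' @export
read_taxonomy <- function(source, delim = NULL) {
  df <- read_delim_table(source, delim = delim)
  names(df) <- tolower(names(df))
  if (!"taxon" %in% names(df)) {
    stop("format error: missing column `taxon`", call. = FALSE)
  }
  taxonomy_table(df)
}

#' Construct a taxonomy table
#'
#' @param df data frame with column `taxon`, any of the rank columns
#'   kingdom..species, and optionally `group`.
#' @return a `taxonomy_table` (data frame subclass).
#' @export
taxonomy_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  keep <- c("taxon", rank_names(), "group")
  for (col in keep) if (is.null(df[[col]])) df[[col]] <- NA_character_
  df <- df[, keep]
  for (col in keep) {
    v <- normalize_label(as.character(df[[col]]))
    v[!nzchar(v) | is.na(v) | v == "NA"] <- NA_character_
    df[[col]] <- v
  }
  if (anyNA(df$taxon)) stop("taxonomy row with empty taxon label", call. = FALSE)
  if (anyDuplicated(df$taxon)) {
    stop("duplicate taxon labels: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- df$taxon
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Write / read a group mapping (original node to group label)
#'
#' The two-column CSV `original,group` is the shareable meta-file that
#' documents how a simplified web was derived from the original one.
#'
#' @param mapping data frame with columns `original` and `group` (as
#'   returned in the `mapping` element of [simplify_web()]).
#' @param sink,source file path or connection.
#' @param header_comment optional `#` comment lines.
#' @export
write_group_mapping <- function(mapping, sink, header_comment = NULL) {
  stopifnot(all(c("original", "group") %in% names(mapping)))
  write_with_comments(mapping[, c("original", "group")], sink, header_comment)
  invisible(sink)
}

#' @rdname write_group_mapping
#' @export
read_group_mapping <- function(source) {
  df <- read_delim_table(source)
  names(df) <- tolower(names(df))
  if (!all(c("original", "group") %in% names(df))) {
    stop("format error: mapping needs columns original,group", call. = FALSE)
  }
  data.frame(original = normalize_label(df$original),
             group = normalize_label(df$group), stringsAsFactors = FALSE)
}

#' Write / read a partition (`node,cluster` CSV)
#'
#' @param partition an `fw_partition` (see [partition()]).
#' @param sink,source file path or connection.
#' @param header_comment optional `#` comment lines.
#' @export
write_partition <- function(partition, sink, header_comment = NULL) {
  df <- data.frame(node = names(partition), cluster = as.integer(partition),
                   stringsAsFactors = FALSE)
  write_with_comments(df, sink, header_comment)
  invisible(sink)
}

#' @rdname write_partition
#' @export
read_partition <- function(source) {
  df <- read_delim_table(source)
  names(df) <- tolower(names(df))
  if (!all(c("node", "cluster") %in% names(df))) {
    stop("format error: partition needs columns node,cluster", call. = FALSE)
  }
  partition(stats::setNames(as.integer(df$cluster),
                            normalize_label(df$node)),
            method = "file")
}
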