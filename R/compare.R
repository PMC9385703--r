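## Original-vs-simplified comparison tables: paired normalized indices
## (parallel-coordinates data), degree flow (node -> group -> group mean)
## and cluster flux (entity -> cluster -> entity -> cluster), plus
## data-first exporters. Every figure has a CSV twin so nothing is ever
## asserted on pixels.

#' Paired normalized indices for original vs simplified webs
#'
#' Each index is computed and min-max normalized independently on each web,
#' then paired through the group mapping: one row per original node, the
#' simplified column repeating its group's value — the overlay structure of
#' a categorical parallel-coordinates comparison. An index that fails on
#' either web (e.g. the trophic precondition) is skipped with a warning and
#' the others proceed.
#'
#' @param original,simplified [food_web]s.
#' @param mapping group mapping data frame (`original`, `group`) consistent
#'   with both webs.
#' @param indices index keys as in [compute_indices()].
#' @param ... passed through to the index functions.
#' @return data frame `group`, `index`, `node`, `original`, `simplified`
#'   (both value columns in [0, 1]).
#' @export
paired_metrics <- function(original, simplified, mapping,
                           indices = c("dc", "bc", "cc", "tl", "katz"),
                           ...) {
  check_mapping(original, simplified, mapping)
  out <- list()
  for (key in indices) {
    oi <- tryCatch(compute_one_index(original, key, ...),
                   error = function(e) e)
    si <- tryCatch(compute_one_index(simplified, key, ...),
                   error = function(e) e)
    if (inherits(oi, "error") || inherits(si, "error")) {
      bad <- if (inherits(oi, "error")) oi else si
      warning("index `", key, "` skipped: ", conditionMessage(bad),
              call. = FALSE)
      next
    }
    ov <- stats::setNames(oi$normalized, oi$node)
    sv <- stats::setNames(si$normalized, si$node)
    out[[key]] <- data.frame(
      group = mapping$group, index = oi$index[1], node = mapping$original,
      original = unname(ov[mapping$original]),
      simplified = unname(sv[mapping$group]),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(group = character(), index = character(), node = character(),
               original = numeric(), simplified = numeric())
  rownames(res) <- NULL
  res
}

check_mapping <- function(original, simplified, mapping) {
  stopifnot(all(c("original", "group") %in% names(mapping)))
  miss <- setdiff(original$nodes, mapping$original)
  if (length(miss) > 0) {
    stop("mapping does not cover original node(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stray <- setdiff(mapping$group, simplified$nodes)
  if (length(stray) > 0) {
    stop("mapping targets absent from simplified web: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Degree flow from original nodes to their groups
#'
#' One row per original node: its total degree (in + out), its group, the
#' group's degree sum and mean over the original web, and the group node's
#' degree in the simplified web. The degree sums over all rows equal twice
#' the original edge count, and that total is conserved into the group
#' column.
#'
#' @inheritParams paired_metrics
#' @return data frame of class `degree_flow`: `node`, `degree`, `group`,
#'   `group_sum`, `group_size`, `group_mean`, `grouped_degree`.
#' @export
degree_flow <- function(original, simplified, mapping) {
  check_mapping(original, simplified, mapping)
  od <- node_degrees(original)
  sd_ <- node_degrees(simplified)
  deg <- od[mapping$original]
  gsum <- tapply(deg, mapping$group, sum)
  gsize <- tapply(deg, mapping$group, length)
  out <- data.frame(
    node = mapping$original, degree = as.integer(unname(deg)),
    group = mapping$group,
    group_sum = as.integer(unname(gsum[mapping$group])),
    group_size = as.integer(unname(gsize[mapping$group])),
    group_mean = unname(gsum[mapping$group] / gsize[mapping$group]),
    grouped_degree = as.integer(unname(sd_[mapping$group])),
    stringsAsFactors = FALSE)
  class(out) <- c("degree_flow", "data.frame")
  out
}

#' Cluster flux table for Sankey visualisation
#'
#' For each side (original, simplified) one row per entity: its value
#' (e.g. trophic level), its cluster, and the split value obtained by
#' dividing the entity value by the cluster size — so five entities at
#' trophic level 2.5 each carry a split of 0.5 into their shared cluster.
#' Middle fluxes out of a cluster all carry the standard value 1, so a
#' cluster block displays max(cluster size, 1): the five-entity cluster
#' shows a block of 5 feeding five outbound unit links.
#'
#' @param original_values,simplified_values named numeric vectors
#'   (entity -> value) on the respective webs.
#' @param original_partition,simplified_partition `fw_partition`s over the
#'   same entities as the value vectors.
#' @param mapping optional group mapping (`original`, `group`); when
#'   supplied, the returned object also carries a `links` attribute with
#'   the entity -> cluster -> entity -> cluster unit links.
#' @return data frame of class `cluster_flux`: `side`, `entity`, `value`,
#'   `cluster`, `cluster_size`, `split_value`, `block_value`,
#'   `middle_flux`.
#' @export
cluster_flux <- function(original_values, original_partition,
                         simplified_values, simplified_partition,
                         mapping = NULL) {
  one_side <- function(values, part, side) {
    if (length(values) == 0) {
      return(data.frame(side = character(), entity = character(),
                        value = numeric(), cluster = integer(),
                        cluster_size = integer(), split_value = numeric(),
                        block_value = numeric(), middle_flux = numeric()))
    }
    stopifnot(setequal(names(values), names(part)))
    cl <- as.vector(part[names(values)])
    size <- table(cl)
    csize <- as.integer(size[as.character(cl)])
    data.frame(side = side, entity = names(values), value = unname(values),
               cluster = cl, cluster_size = csize,
               split_value = unname(values) / csize,
               block_value = pmax(csize, 1) * 1,  # one unit flux per member
               middle_flux = 1, stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(original_values, original_partition, "original"),
               one_side(simplified_values, simplified_partition,
                        "simplified"))
  rownames(out) <- NULL
  if (!is.null(mapping) && nrow(out) > 0) {
    m <- stats::setNames(mapping$group, mapping$original)
    op <- original_partition; sp <- simplified_partition
    ents <- names(original_values)
    attr(out, "links") <- data.frame(
      entity = ents,
      original_cluster = as.vector(op[ents]),
      simplified_entity = unname(m[ents]),
      simplified_cluster = as.vector(sp[unname(m[ents])]),
      stringsAsFactors = FALSE)
  }
  class(out) <- c("cluster_flux", "data.frame")
  out
}

#' Sankey links from a degree-flow table
#'
#' Three-column layout: original node -> group weighted by the node's
#' degree, then group -> a mean-degree block labelled with the group mean
#' printed to one decimal (full precision stays in the CSV twin).
#'
#' @param flow a `degree_flow` data frame.
#' @return data frame `source`, `target`, `value`.
#' @export
degree_flow_links <- function(flow) {
  stopifnot(inherits(flow, "degree_flow"))
  groups <- !duplicated(flow$group)
  rbind(
    data.frame(source = flow$node, target = flow$group, value = flow$degree,
               stringsAsFactors = FALSE),
    data.frame(source = flow$group[groups],
               target = sprintf("%s [m.d. %.1f]", flow$group[groups],
                                flow$group_mean[groups]),
               value = flow$group_mean[groups], stringsAsFactors = FALSE))
}

#' Export a self-contained Sankey HTML document
#'
#' Writes a single-file HTML page embedding the link table as JSON (the
#' machine-readable twin, recoverable by parsing the page) plus a simple
#' SVG rendering and a fallback table. No external assets are referenced.
#'
#' @param links data frame with columns `source`, `target`, `value` (e.g.
#'   from [degree_flow_links()]).
#' @param sink output file path.
#' @param title document title.
#' @return the path, invisibly.
#' @export
export_sankey_html <- function(links, sink, title = "Sankey flow") {
  stopifnot(all(c("source", "target", "value") %in% names(links)),
            nrow(links) > 0)
  payload <- jsonlite::toJSON(links, dataframe = "rows", digits = NA,
                              auto_unbox = FALSE)
  labels <- unique(c(links$source, links$target))
  rows_html <- paste(sprintf(
    "<tr><td>%s</td><td>%s</td><td>%g</td></tr>",
    escape_html(links$source), escape_html(links$target), links$value),
    collapse = "\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">\n<title>",
    escape_html(title), "</title>\n<style>body{font-family:sans-serif}",
    "rect{fill:#b22}text{font-size:11px}</style></head>\n<body>\n<h1>",
    escape_html(title), "</h1>\n",
    "<script type=\"application/json\" id=\"sankey-data\">\n",
    payload, "\n</script>\n",
    "<svg id=\"sankey\" width=\"960\" height=\"", 40 + 22 * nrow(links),
    "\"></svg>\n<script>\n",
    "var data=JSON.parse(document.getElementById('sankey-data').textContent);\n",
    "var svg=document.getElementById('sankey');\n",
    "var max=Math.max.apply(null,data.map(function(d){return d.value;}));\n",
    "data.forEach(function(d,i){\n",
    " var y=30+22*i,w=10+600*d.value/max;\n",
    " svg.innerHTML+='<rect x=\"180\" y=\"'+(y-10)+'\" width=\"'+w+",
    "'\" height=\"14\"></rect>'+\n",
    "  '<text x=\"175\" y=\"'+y+'\" text-anchor=\"end\">'+d.source+'</text>'+\n",
    "  '<text x=\"'+(190+w)+'\" y=\"'+y+'\">'+d.target+' ('+d.value+')</text>';\n",
    "});\n</script>\n",
    "<table border=\"1\"><tr><th>source</th><th>target</th><th>value</th>",
    "</tr>\n", rows_html, "\n</table>\n",
    "<!-- labels: ", paste(escape_html(labels), collapse = " | "),
    " -->\n</body></html>\n")
  writeLines(html, sink)
  invisible(sink)
}

escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Read back the link table embedded in an exported Sankey HTML file
#'
#' @param source path to a file written by [export_sankey_html()].
#' @return data frame `source`, `target`, `value`.
#' @export
read_sankey_html <- function(source) {
  lines <- readLines(source, warn = FALSE)
  from <- grep("id=\"sankey-data\"", lines) + 1
  to <- grep("^</script>$", lines)
  to <- to[to > from][1]
  jsonlite::fromJSON(paste(lines[from:(to - 1)], collapse = "\n"))
}

#' Export a parallel-coordinates comparison plot
#'
#' One panel per index: every original node's normalized value on the left
#' axis joined to its group's value in the simplified web on the right
#' axis. Vector output (SVG where cairo is available, otherwise PDF); the
#' data twin is the [paired_metrics()] table itself.
#'
#' @param rows a [paired_metrics()] data frame.
#' @param sink output path; extension `.svg` or `.pdf`.
#' @return the path, invisibly.
#' @export
export_parallel_plot <- function(rows, sink) {
  stopifnot(nrow(rows) > 0)
  ext <- tolower(tools::file_ext(sink))
  if (ext == "svg" && capabilities("cairo")) {
    grDevices::svg(sink, width = 8, height = 3 * length(unique(rows$index)))
  } else {
    if (ext == "svg") sink <- sub("\\.svg$", ".pdf", sink)
    grDevices::pdf(sink, width = 8, height = 3 * length(unique(rows$index)))
  }
  on.exit(grDevices::dev.off())
  idx <- unique(rows$index)
  graphics::par(mfrow = c(length(idx), 1), mar = c(2, 4, 2, 1))
  for (ix in idx) {
    sub <- rows[rows$index == ix, ]
    graphics::plot(NA, xlim = c(0.8, 2.2), ylim = c(0, 1), xaxt = "n",
                   ylab = "normalized value", main = ix)
    graphics::axis(1, at = c(1, 2), labels = c("original", "simplified"))
    graphics::segments(1, sub$original, 2, sub$simplified,
                       col = "#00000055")
    graphics::points(rep(1, nrow(sub)), sub$original, pch = 16,
                     col = "steelblue")
    graphics::points(rep(2, nrow(sub)), sub$simplified, pch = 16,
                     col = "darkorange")
  }
  invisible(sink)
}
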