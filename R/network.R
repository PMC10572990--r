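#' Build the confidence-thresholded marker interaction graph
#'
#' Induces the subgraph of the interaction edge list on the marker
#' proteins, keeping edges whose confidence is at least
#' `min_confidence` (inclusive, the "medium confidence" convention).
#' Confidence scores on the 0-1000 database scale are auto-detected
#' (any value above 1) and divided by 1000. Markers left without any
#' qualifying edge are excluded from the graph and reported in the
#' `unmapped` field instead of being silently dropped.
#'
#' @param markers an `lfq_marker_set` or character vector of protein
#'   ids.
#' @param edges edge tibble (protein_a, protein_b, confidence), e.g.
#'   from [read_string_edges()] or [generate_interaction_edges()].
#'   Duplicate unordered pairs keep the highest confidence; self-loops
#'   are discarded.
#' @param min_confidence minimum retained confidence (default 0.4).
#' @return An object of class `lfq_interaction_graph`: fields `graph`
#'   (an igraph), `unmapped` (isolated markers), `min_confidence`.
#' @export
build_marker_graph <- function(markers, edges, min_confidence = 0.4) {
  if (inherits(markers, "lfq_marker_set")) markers <- markers$proteins
  markers <- unique(as.character(markers))
  edges <- normalize_edges(edges)
  edges <- edges[edges$confidence >= min_confidence &
                   edges$protein_a %in% markers &
                   edges$protein_b %in% markers, ]
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b", "confidence")],
    directed = FALSE,
    vertices = data.frame(name = sort(markers))
  )
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  structure(
    list(graph = g,
         unmapped = setdiff(markers, igraph::V(g)$name),
         min_confidence = min_confidence),
    class = "lfq_interaction_graph"
  )
}

# Canonical undirected edge table: 0-1 confidences, no self-loops, one
# row per unordered pair (highest confidence wins), endpoints ordered.
normalize_edges <- function(edges) {
  stopifnot(all(c("protein_a", "protein_b", "confidence") %in%
                  names(edges)))
  conf <- as.numeric(edges$confidence)
  if (any(!is.finite(conf)) || any(conf < 0)) {
    abort("edge confidences must be finite and >= 0",
          class = "lfq_validation_error")
  }
  if (any(conf > 1)) {
    if (any(conf > 1000)) {
      abort("edge confidences exceed both the 0-1 and 0-1000 scales",
            class = "lfq_validation_error")
    }
    conf <- conf / 1000
  }
  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- tibble::tibble(protein_a = lo, protein_b = hi,
                        confidence = conf)
  out <- out[order(out$protein_a, out$protein_b, -out$confidence), ]
  out[!duplicated(paste(out$protein_a, out$protein_b)), ]
}

#' @export
print.lfq_interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<lfq_interaction_graph> %d nodes, %d edges (confidence >= %.2f), %d unmapped marker(s)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$min_confidence,
    length(x$unmapped)))
  invisible(x)
}

#' Decompose an interaction graph into functional subnetworks
#'
#' Computes connected components, then splits each component by
#' functional category: every maximal same-label node set within a
#' component is one subnetwork. A subnetwork is `isolated` when its
#' component contains no other label — it is not connected to any other
#' subnetwork.
#'
#' @param graph an `lfq_interaction_graph`.
#' @param category_map named character vector protein id -> functional
#'   label, covering every graph node.
#' @return Tibble (subnetwork, component, size, isolated, members)
#'   sorted by size descending then label.
#' @export
decompose_subnetworks <- function(graph, category_map) {
  stopifnot(inherits(graph, "lfq_interaction_graph"))
  nodes <- igraph::V(graph$graph)$name
  unlabeled <- setdiff(nodes, names(category_map))
  if (length(unlabeled) > 0) {
    abort(sprintf("unlabeled graph node(s): %s",
                  paste(unlabeled, collapse = ", ")),
          class = "lfq_config_error")
  }
  comp <- igraph::components(graph$graph)$membership[nodes]
  label <- unname(category_map[nodes])
  out <- tibble::tibble(protein_id = nodes, component = unname(comp),
                        subnetwork = label) |>
    dplyr::group_by(.data$component, .data$subnetwork) |>
    dplyr::summarise(members = list(sort(.data$protein_id)),
                     size = dplyr::n(), .groups = "drop")
  labels_per_comp <- table(unique(
    out[, c("component", "subnetwork")])$component)
  out$isolated <- as.vector(labels_per_comp[as.character(out$component)]) == 1
  out <- out[order(-out$size, out$subnetwork), ]
  out[, c("subnetwork", "component", "size", "isolated", "members")]
}

#' Rank graph nodes by centrality
#'
#' Unweighted degree and shortest-path betweenness per node, ranked by
#' betweenness descending, ties broken by degree descending then node
#' name — making "centrally located, connected to the other
#' subnetworks" operational.
#'
#' @param graph an `lfq_interaction_graph`.
#' @return Tibble (protein_id, degree, betweenness, rank).
#' @export
rank_centrality <- function(graph) {
  stopifnot(inherits(graph, "lfq_interaction_graph"))
  g <- graph$graph
  if (igraph::vcount(g) == 0) {
    abort("rank_centrality: empty graph", class = "lfq_validation_error")
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  out <- tibble::tibble(
    protein_id = igraph::V(g)$name,
    degree = unname(deg),
    betweenness = unname(btw)
  )
  out <- out[order(-out$betweenness, -out$degree, out$protein_id), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Read a STRING-style interaction edge list
#'
#' Tab- or space-delimited three-column file; both the package's own
#' header (protein_a, protein_b, confidence) and the STRING export
#' dialect (protein1, protein2, combined_score) are accepted.
#'
#' @param path file path.
#' @return Edge tibble (protein_a, protein_b, confidence), confidences
#'   normalized to 0-1.
#' @export
read_string_edges <- function(path) {
  tbl <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(tbl))
  dialects <- list(
    c("protein_a", "protein_b", "confidence"),
    c("protein1", "protein2", "combined_score")
  )
  for (d in dialects) {
    if (all(d %in% nm)) {
      out <- tbl[, match(d, nm)]
      names(out) <- c("protein_a", "protein_b", "confidence")
      return(normalize_edges(out))
    }
  }
  abort(sprintf("unrecognized edge-list columns: %s",
                paste(names(tbl), collapse = ", ")),
        class = "lfq_validation_error")
}

#' Write an edge list as three-column TSV
#' @param edges edge tibble (protein_a, protein_b, confidence).
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(edges[, c("protein_a", "protein_b", "confidence")],
                   path, progress = FALSE)
  invisible(path)
}

#' Export an interaction graph as GraphML
#' @param graph an `lfq_interaction_graph`.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "lfq_interaction_graph"))
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}

#' Node table of an interaction graph
#'
#' One row per graph node with component id, subnetwork label, degree,
#' betweenness and the isolated flag of its subnetwork; unmapped
#' markers are appended with NA graph fields.
#'
#' @param graph an `lfq_interaction_graph`.
#' @param category_map named character vector protein -> label.
#' @return Tibble (protein_id, component, subnetwork, degree,
#'   betweenness, isolated, mapped).
#' @export
node_table <- function(graph, category_map) {
  cent <- rank_centrality(graph)
  subs <- decompose_subnetworks(graph, category_map)
  comp <- igraph::components(graph$graph)$membership
  iso <- setNames(subs$isolated, paste(subs$component, subs$subnetwork))
  out <- tibble::tibble(
    protein_id = cent$protein_id,
    component = unname(comp[cent$protein_id]),
    subnetwork = unname(category_map[cent$protein_id]),
    degree = cent$degree,
    betweenness = cent$betweenness
  )
  out$isolated <- unname(iso[paste(out$component, out$subnetwork)])
  out$mapped <- TRUE
  if (length(graph$unmapped) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      protein_id = sort(graph$unmapped),
      component = NA_integer_,
      subnetwork = unname(category_map[sort(graph$unmapped)]),
      degree = NA_integer_, betweenness = NA_real_,
      isolated = NA, mapped = FALSE
    ))
  }
  out
}
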