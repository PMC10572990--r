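#' Pathway frequency summary of a protein set
#'
#' Counts, for each annotated pathway, how many query proteins it
#' contains, drops zero-count pathways, sorts by count descending with
#' ties broken by pathway id (lexicographic, for determinism), and
#' truncates to the top `k` — the "top pathways" bar-chart summary.
#' Ranking is by raw protein count, not by an overrepresentation
#' statistic.
#'
#' @param query character vector of protein ids (may be an
#'   `lfq_marker_set`, whose proteins are used).
#' @param annotation pathway annotation tibble (pathway_id, description,
#'   proteins list-column), e.g. from [read_gmt()] or
#'   [generate_pathway_annotation()].
#' @param k number of rows to keep (default 6).
#' @return Tibble (pathway_id, description, count, proteins) with at
#'   most `k` rows; empty for an empty query.
#' @export
pathway_frequency <- function(query, annotation, k = 6) {
  if (inherits(query, "lfq_marker_set")) query <- query$proteins
  if (k < 1) abort("k must be >= 1", class = "lfq_validation_error")
  if (is.null(annotation) || nrow(annotation) == 0) {
    abort("pathway annotation is empty", class = "lfq_validation_error")
  }
  stopifnot(all(c("pathway_id", "description", "proteins") %in%
                  names(annotation)))
  hits <- lapply(annotation$proteins, intersect, x = unique(query))
  out <- tibble::tibble(
    pathway_id = annotation$pathway_id,
    description = annotation$description,
    count = lengths(hits),
    proteins = hits
  )
  out <- out[out$count > 0, ]
  out <- out[order(-out$count, out$pathway_id), ]
  head(out, k)
}

#' Read a GMT pathway annotation file
#'
#' Standard tab-delimited gene-set format: set id, description, then one
#' member per remaining field.
#'
#' @param path file path.
#' @return Annotation tibble (pathway_id, description, proteins).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "lfq_validation_error")
  }
  tibble::tibble(
    pathway_id = vapply(fields, `[`, character(1), 1),
    description = vapply(fields, `[`, character(1), 2),
    proteins = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a pathway annotation as GMT
#'
#' @param annotation annotation tibble (pathway_id, description,
#'   proteins).
#' @param path output file path.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(annotation$pathway_id[i], annotation$description[i],
            annotation$proteins[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
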