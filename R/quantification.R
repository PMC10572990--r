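#' Apply the protein identification filter
#'
#' Retains proteins supported by at least `min_peptides` distinct
#' peptides and observed (through any of their peptides) in at least
#' `min_runs` distinct runs; all peptide rows of other proteins are
#' dropped. The output row set is a subset of the input.
#'
#' @param peptides long-format peptide table (peptide_id, protein_id,
#'   sex, group, pool, tech, intensity).
#' @param min_peptides minimum distinct peptides per protein (default 2).
#' @param min_runs minimum distinct runs in which the protein was
#'   observed (default 2).
#' @return The filtered peptide table.
#' @export
filter_identifications <- function(peptides, min_peptides = 2,
                                   min_runs = 2) {
  validate_peptide_table(peptides)
  per_protein <- peptides |>
    dplyr::mutate(run = run_id(.data$sex, .data$group, .data$pool,
                               .data$tech)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$peptide_id),
      n_runs = dplyr::n_distinct(.data$run),
      .groups = "drop"
    )
  keep <- per_protein$protein_id[
    per_protein$n_peptides >= min_peptides & per_protein$n_runs >= min_runs
  ]
  peptides[peptides$protein_id %in% keep, ]
}

validate_peptide_table <- function(peptides) {
  required <- c("peptide_id", "protein_id", "sex", "group", "pool",
                "tech", "intensity")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0) {
    abort(sprintf("peptide table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "lfq_validation_error")
  }
  bad <- which(!is.finite(peptides$intensity) | peptides$intensity < 0)
  if (length(bad) > 0) {
    abort(sprintf("peptide table has non-finite or negative intensity at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "lfq_validation_error")
  }
  # one protein per peptide
  map <- unique(peptides[, c("peptide_id", "protein_id")])
  dup <- map$peptide_id[duplicated(map$peptide_id)]
  if (length(dup) > 0) {
    abort(sprintf("peptide(s) mapped to more than one protein: %s",
                  paste(head(dup, 5), collapse = ", ")),
          class = "lfq_validation_error")
  }
  key <- paste(peptides$peptide_id,
               run_id(peptides$sex, peptides$group, peptides$pool,
                      peptides$tech))
  dup_rows <- which(duplicated(key))
  if (length(dup_rows) > 0) {
    abort(sprintf("duplicate (peptide, run) observation at row(s): %s",
                  paste(head(dup_rows, 5), collapse = ", ")),
          class = "lfq_validation_error")
  }
  invisible(peptides)
}

#' Hi3 (Top3) protein quantification
#'
#' For every (protein, run) cell with at least one observed peptide, the
#' protein's run-level abundance is the arithmetic mean of its
#' `min(3, available)` highest peptide intensities in that run. Cells
#' with no observed peptide are absent from the output (missing), never
#' zero-filled. Apply [filter_identifications()] first.
#'
#' @param peptides filtered peptide table.
#' @return Run-level protein abundance tibble (protein_id, sex, group,
#'   pool, tech, abundance, n_peptides_used, level = "run").
#' @examples
#' tbl <- tibble::tibble(
#'   peptide_id = paste0("p", 1:4), protein_id = "P0001",
#'   sex = "M", group = "CT", pool = 1L, tech = 1L,
#'   intensity = c(10, 8, 6, 4)
#' )
#' hi3_quantify(tbl)$abundance # mean(10, 8, 6) = 8
#' @export
hi3_quantify <- function(peptides) {
  validate_peptide_table(peptides)
  out <- peptides |>
    dplyr::group_by(.data$protein_id, .data$sex, .data$group, .data$pool,
                    .data$tech) |>
    dplyr::summarise(
      abundance = mean(sort(.data$intensity, decreasing = TRUE)[
        seq_len(min(3L, dplyr::n()))
      ]),
      n_peptides_used = min(3L, dplyr::n()),
      .groups = "drop"
    )
  out$level <- "run"
  out
}

#' Aggregate technical replicates to pool-level abundances
#'
#' Pool-level abundance is the mean of a protein's run-level abundances
#' across the technical replicates of the pool. A pool is counted as
#' present only if the protein was observed in at least one of its
#' technical replicates; otherwise no pool row is emitted.
#'
#' @param run_table run-level output of [hi3_quantify()].
#' @return Pool-level tibble (protein_id, sex, group, pool, abundance,
#'   n_tech_used, level = "pool").
#' @export
aggregate_technical <- function(run_table) {
  stopifnot(all(c("protein_id", "sex", "group", "pool", "abundance") %in%
                  names(run_table)))
  out <- run_table |>
    dplyr::group_by(.data$protein_id, .data$sex, .data$group, .data$pool) |>
    dplyr::summarise(
      abundance = mean(.data$abundance),
      n_tech_used = dplyr::n(),
      .groups = "drop"
    )
  out$level <- "pool"
  out
}
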