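#' Read a long-format peptide intensity table
#'
#' Comma- or tab-delimited by extension (`.csv` vs anything else).
#' Required columns: peptide_id, protein_id, sex, group, pool, tech,
#' intensity. Schema violations (missing columns, negative intensities,
#' duplicate (peptide, run) rows, peptides mapped to several proteins)
#' raise validation errors naming the offending column or row.
#'
#' @param path file path.
#' @return A validated peptide tibble.
#' @export
read_peptide_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  tbl$pool <- as.integer(tbl$pool)
  tbl$tech <- as.integer(tbl$tech)
  validate_peptide_table(tbl)
  tbl
}

#' Write a peptide intensity table
#' @param peptides peptide tibble.
#' @param path output path (`.csv` for comma-delimited, else tab).
#' @export
write_peptide_table <- function(peptides, path) {
  validate_peptide_table(peptides)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(peptides, path, progress = FALSE)
  } else {
    readr::write_tsv(peptides, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a pairwise comparison result as CSV
#' @param comparison an `lfq_comparison`.
#' @param path output path.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "lfq_comparison"))
  cols <- c("protein_id", "n_present_focal", "n_present_ref",
            "mean_focal", "mean_ref", "cv_focal", "cv_ref",
            "fold_change", "f_stat", "p_value", "q_value", "direction",
            "filter_failed", "is_de")
  readr::write_csv(comparison$records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write a marker set as a table mirroring the published layout
#'
#' One row per marker with its per-comparison direction columns; a
#' `subnetwork` column is filled from `category_map` when supplied.
#'
#' @param markers an `lfq_marker_set`.
#' @param path output path.
#' @param category_map optional named vector protein -> subnetwork.
#' @export
write_marker_table <- function(markers, path, category_map = NULL) {
  stopifnot(inherits(markers, "lfq_marker_set"))
  out <- markers$directions
  out <- tibble::add_column(
    out,
    subnetwork = if (is.null(category_map)) NA_character_ else
      unname(category_map[out$protein_id]),
    .before = 1
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write Venn regions as JSON
#' @param regions output of [venn_partition()].
#' @param path output path.
#' @export
write_venn_regions <- function(regions, path) {
  jsonlite::write_json(regions, path, pretty = TRUE)
  invisible(path)
}

#' Load a packaged marker-table fixture
#'
#' The package ships the two published marker tables (male and female
#' combined-insult markers with subnetwork assignments and
#' per-comparison directions) plus reconstructed interactome edge
#' lists. The marker rows are packaged verbatim; the edge lists are
#' synthetic reconstructions consistent with the described map
#' connectivity (files named `*_synthetic.tsv`) — fixtures for testing
#' graph operations, not measured interaction data.
#'
#' @param name `"table1"` (male) or `"table2"` (female).
#' @return A list: `markers` (tibble subnetwork, protein_name,
#'   gene_name, vsCT, vsNIC, vsPCP), `edges` (tibble protein_a,
#'   protein_b, confidence), `category_map` (named vector gene ->
#'   subnetwork).
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  files <- list(
    table1 = c("table1_male_markers.tsv", "male_map_edges_synthetic.tsv"),
    table2 = c("table2_female_markers.tsv", "female_map_edges_synthetic.tsv")
  )[[name]]
  marker_path <- system.file("extdata", files[1], package = "lfqmarkers",
                             mustWork = TRUE)
  edge_path <- system.file("extdata", files[2], package = "lfqmarkers",
                           mustWork = TRUE)
  markers <- readr::read_tsv(marker_path, show_col_types = FALSE,
                             progress = FALSE)
  list(
    markers = markers,
    edges = read_string_edges(edge_path),
    category_map = setNames(markers$subnetwork, markers$gene_name)
  )
}

#' Assemble a validated pipeline configuration
#'
#' Accepts either a list of settings or a path to a YAML/JSON file
#' (selected by extension) holding them. Recognized settings: input
#' paths or in-memory objects (`peptides`, `edges`, `annotation`,
#' `category_map`), `out_dir`, `thresholds` (passed to
#' [de_thresholds()]), `marker_mode`, `top_k`, `min_confidence`,
#' `seed`, `verbose`.
#'
#' @param config list or file path.
#' @return Normalized configuration list of class `lfq_pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    peptides = NULL, edges = NULL, annotation = NULL,
    category_map = NULL, out_dir = NULL,
    thresholds = list(), marker_mode = "exclusivity_refined",
    top_k = 6, min_confidence = 0.4, seed = 1L, verbose = FALSE
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown pipeline settings: %s",
                  paste(unknown, collapse = ", ")),
          class = "lfq_config_error")
  }
  config <- utils::modifyList(defaults, config)
  config$thresholds <- do.call(de_thresholds, as.list(config$thresholds))
  structure(config, class = "lfq_pipeline_config")
}

#' Run the full marker-discovery pipeline
#'
#' Orchestrates quantification (identification filter, Hi3, technical
#' aggregation), all pairwise comparisons of the lattice per sex, Venn
#' partition of the vs-control DE sets, marker calls per non-control
#' group, the sex-exclusivity fraction, pathway-frequency summaries of
#' the combined-insult markers (when an annotation is supplied), and
#' the interactome analysis (when an edge list is supplied). When
#' `out_dir` is set, stage CSVs, Venn-region JSON and a JSON run
#' manifest are written there; inputs are never mutated.
#'
#' @param config a [pipeline_config()] list, raw list, or config file
#'   path.
#' @return A report bundle (list): `pools`, `comparisons` (per sex),
#'   `venn_vs_control` (per sex), `markers` (per sex per group),
#'   `sex_exclusivity`, `enrichment`, `network`, `summary` (per-arrow DE
#'   counts with up/down splits, exclusive counts and marker counts —
#'   the lattice-style overview), and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- if (inherits(config, "lfq_pipeline_config")) config else
    pipeline_config(config)
  say <- function(fmt, ...) {
    if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "lfq_pipeline_error", parent = e)
    })
  }

  peptides <- stage("read", {
    if (is.character(config$peptides)) read_peptide_table(config$peptides)
    else if (is.data.frame(config$peptides)) {
      validate_peptide_table(config$peptides)
      config$peptides
    } else abort("config$peptides must be a path or a data frame",
                 class = "lfq_config_error")
  })
  edges <- stage("read", {
    if (is.character(config$edges)) read_string_edges(config$edges)
    else config$edges
  })
  annotation <- stage("read", {
    if (is.character(config$annotation)) read_gmt(config$annotation)
    else config$annotation
  })

  say("quantify: %d peptide observations", nrow(peptides))
  filtered <- stage("quantify", filter_identifications(peptides))
  pools <- stage("quantify",
                 aggregate_technical(hi3_quantify(filtered)))

  sexes <- sort(unique(pools$sex))
  groups <- unique(peptides$group)
  canon <- intersect(DEFAULT_GROUPS, toupper(groups))
  groups <- if (length(canon) == length(groups)) canon else groups
  lattice <- comparison_lattice(groups)
  control <- lattice$reference[1]
  thresholds <- config$thresholds

  comparisons <- list()
  for (sex in sexes) {
    comparisons[[sex]] <- stage("compare", {
      res <- lapply(seq_len(nrow(lattice)), function(i) {
        pairwise_compare(pools, sex, lattice$focal[i],
                         lattice$reference[i], thresholds)
      })
      setNames(res, lattice$name)
    })
    say("compare (%s): %s", sex, paste(
      vapply(comparisons[[sex]],
             function(r) sprintf("%s=%d", comparison_name(r$focal,
                                                          r$reference),
                                 sum(r$records$is_de)), character(1)),
      collapse = ", "))
  }

  venn_vs_control <- lapply(comparisons, function(res) {
    vs_ct <- lattice$name[lattice$reference == control]
    venn_partition(lapply(setNames(vs_ct, vs_ct),
                          function(nm) de_proteins(res[[nm]])))
  })

  marker_groups <- setdiff(groups, control)
  markers <- list()
  for (sex in sexes) {
    markers[[sex]] <- stage("markers", {
      res <- lapply(marker_groups, function(g) {
        mode <- if (g == utils::tail(groups, 1)) config$marker_mode else
          "plain_intersection"
        group_markers(comparisons[[sex]], g, mode = mode)
      })
      setNames(res, marker_groups)
    })
  }

  sex_excl <- if (length(sexes) == 2) {
    suppressWarnings(
      sex_exclusivity_fraction(comparisons[[sexes[1]]],
                               comparisons[[sexes[2]]])
    )
  } else NA_real_

  focal_group <- utils::tail(groups, 1)
  enrichment <- if (!is.null(annotation)) {
    stage("enrich", lapply(markers, function(m) {
      pathway_frequency(m[[focal_group]], annotation, k = config$top_k)
    }))
  } else NULL

  network <- if (!is.null(edges)) {
    stage("network", lapply(markers, function(m) {
      graph <- build_marker_graph(m[[focal_group]], edges,
                                  min_confidence = config$min_confidence)
      out <- list(graph = graph)
      if (!is.null(config$category_map) &&
          igraph::vcount(graph$graph) > 0) {
        cmap <- unlist(config$category_map)
        out$subnetworks <- decompose_subnetworks(graph, cmap)
        out$nodes <- node_table(graph, cmap)
      } else if (igraph::vcount(graph$graph) > 0) {
        out$centrality <- rank_centrality(graph)
      }
      out
    }))
  } else NULL

  summary <- dplyr::bind_rows(lapply(sexes, function(sex) {
    res <- comparisons[[sex]]
    excl_family <- lapply(res, de_proteins)
    tibble::tibble(
      sex = sex,
      comparison = names(res),
      n_de = vapply(res, function(r) sum(r$records$is_de), integer(1)),
      n_up = vapply(res, function(r)
        sum(r$records$is_de & r$records$direction == "up"), integer(1)),
      n_down = vapply(res, function(r)
        sum(r$records$is_de & r$records$direction == "down"), integer(1)),
      n_exclusive = vapply(names(res), function(nm)
        length(exclusive_proteins(excl_family, nm)), integer(1))
    )
  }))

  manifest <- list(
    package = "lfqmarkers",
    seed = config$seed,
    thresholds = unclass(thresholds),
    marker_mode = config$marker_mode,
    top_k = config$top_k,
    min_confidence = config$min_confidence,
    groups = groups,
    control = control,
    sexes = sexes,
    n_peptide_rows = nrow(peptides),
    n_proteins_quantified = length(unique(pools$protein_id)),
    de_counts = setNames(as.list(summary$n_de),
                         paste(summary$sex, summary$comparison)),
    marker_counts = lapply(markers, function(m)
      lapply(m, function(x) length(x$proteins))),
    sex_exclusivity = sex_excl
  )

  bundle <- list(pools = pools, comparisons = comparisons,
                 venn_vs_control = venn_vs_control, markers = markers,
                 sex_exclusivity = sex_excl, enrichment = enrichment,
                 network = network, summary = summary,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    stage("write", write_bundle(bundle, config))
    say("wrote outputs to %s", config$out_dir)
  }
  bundle
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  readr::write_csv(bundle$summary, p("summary.csv"), progress = FALSE)
  for (sex in names(bundle$comparisons)) {
    for (nm in names(bundle$comparisons[[sex]])) {
      write_comparison(bundle$comparisons[[sex]][[nm]],
                       p(sprintf("comparison_%s_%s.csv", sex,
                                 gsub(" ", "_", nm))))
    }
    write_venn_regions(bundle$venn_vs_control[[sex]],
                       p(sprintf("venn_vs_control_%s.json", sex)))
    for (g in names(bundle$markers[[sex]])) {
      write_marker_table(
        bundle$markers[[sex]][[g]],
        p(sprintf("markers_%s_%s.csv", sex, g)),
        category_map = if (!is.null(config$category_map))
          unlist(config$category_map) else NULL
      )
    }
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
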