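#' The pairwise comparison lattice of a group design
#'
#' Every unordered pair of groups is compared once. Orientation follows
#' the study's convention: the reference role goes to whichever group
#' comes first in `reference_order` (control first, then the single
#' insults, so the combined-insult group is always focal). For the
#' default four-arm design this yields the six arrows
#' PCP/NIC/PCPNIC vs CT, PCP/PCPNIC vs NIC, and PCPNIC vs PCP.
#'
#' @param groups character vector of group labels.
#' @param reference_order priority order for the reference role; groups
#'   absent from it fall back to their position in `groups`.
#' @return A tibble (focal, reference, name).
#' @export
comparison_lattice <- function(groups,
                               reference_order = c("CT", "NIC", "PCP",
                                                   "PCPNIC")) {
  rank <- match(groups, reference_order)
  rank[is.na(rank)] <- length(reference_order) + seq_len(sum(is.na(rank)))
  pairs <- utils::combn(groups, 2)
  focal <- character(ncol(pairs))
  reference <- character(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (rank[match(a, groups)] <= rank[match(b, groups)]) {
      reference[i] <- a; focal[i] <- b
    } else {
      reference[i] <- b; focal[i] <- a
    }
  }
  out <- tibble::tibble(focal = focal, reference = reference,
                        name = comparison_name(focal, reference))
  dplyr::arrange(out, match(.data$reference, groups),
                 match(.data$focal, groups))
}

comparison_name <- function(focal, reference) {
  paste(focal, "vs", reference)
}

#' Partition a family of named sets into disjoint Venn regions
#'
#' For every non-empty signature S (a subset of the family's names),
#' region(S) holds the elements belonging to every set in S and to no
#' set outside S. Regions are pairwise disjoint and their union equals
#' the union of the input sets; the empty-signature region is excluded.
#'
#' @param family named list of character vectors (sets may overlap).
#' @return Named list of character vectors; each name is the signature's
#'   member set names joined by `"&"` in family order. Signatures with
#'   empty regions are omitted.
#' @examples
#' venn_partition(list(A = c("p1", "p2"), B = "p2"))
#' @export
venn_partition <- function(family) {
  if (length(family) == 0 || is.null(names(family)) ||
      any(names(family) == "")) {
    abort("venn_partition: family must be a non-empty named list",
          class = "lfq_validation_error")
  }
  if (anyDuplicated(names(family))) {
    abort("venn_partition: family names must be unique",
          class = "lfq_validation_error")
  }
  universe <- unique(unlist(family, use.names = FALSE))
  if (length(universe) == 0) return(list())
  membership <- vapply(family, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(family)))
  signature <- apply(membership, 1, function(row) {
    paste(names(family)[row], collapse = "&")
  })
  split(universe, signature)[unique(signature)] |>
    (\(x) x[order(match(names(x), venn_signature_order(names(family))))])()
}

# All non-empty signatures in deterministic order: by size, then by
# position of member names in the family.
venn_signature_order <- function(set_names) {
  n <- length(set_names)
  sigs <- character(0)
  for (size in seq_len(n)) {
    combos <- utils::combn(set_names, size)
    sigs <- c(sigs, apply(combos, 2, paste, collapse = "&"))
  }
  sigs
}

#' Elements exclusive to one set of a family
#'
#' Returns the proteins present in the named set and in no other set of
#' the family — the "exclusively deregulated" region of the Venn
#' partition.
#'
#' @param family named list of character vectors.
#' @param name the set whose exclusive region to extract.
#' @return Character vector (possibly empty).
#' @export
exclusive_proteins <- function(family, name) {
  if (!name %in% names(family)) {
    abort(sprintf("exclusive_proteins: no set named '%s'", name),
          class = "lfq_key_error")
  }
  others <- unlist(family[setdiff(names(family), name)], use.names = FALSE)
  setdiff(family[[name]], others)
}

# Core marker set algebra on plain named DE sets, shared by the pipeline
# and by the ground-truth oracle.
#
# plain_intersection: proteins DE in every comparison involving the
#   group.
# exclusivity_refined: for each comparison involving the group, take the
#   group's exclusive region within the family of comparisons sharing
#   the same reference, then intersect across the group's comparisons.
marker_set_algebra <- function(de_sets, lattice, group,
                               mode = c("exclusivity_refined",
                                        "plain_intersection")) {
  mode <- match.arg(mode)
  involving <- lattice[lattice$focal == group | lattice$reference == group, ]
  if (nrow(involving) == 0) {
    abort(sprintf("group %s has no comparisons in the lattice", group),
          class = "lfq_config_error")
  }
  missing_cmp <- setdiff(involving$name, names(de_sets))
  if (length(missing_cmp) > 0) {
    abort(sprintf("missing comparison result(s): %s",
                  paste(missing_cmp, collapse = ", ")),
          class = "lfq_config_error")
  }
  pieces <- lapply(seq_len(nrow(involving)), function(i) {
    cmp <- involving[i, ]
    if (mode == "plain_intersection" || cmp$reference == group) {
      # When the group itself is the reference of the stored arrow, the
      # only same-reference family member involving it is that arrow:
      # exclusivity degenerates to plain DE membership.
      de_sets[[cmp$name]]
    } else {
      fam_rows <- lattice[lattice$reference == cmp$reference, ]
      fam <- lapply(setNames(fam_rows$name, fam_rows$name),
                    function(nm) de_sets[[nm]] %||% character(0))
      exclusive_proteins(fam, cmp$name)
    }
  })
  Reduce(intersect, pieces)
}

comparison_lookup <- function(results) {
  if (inherits(results, "lfq_comparison")) results <- list(results)
  nm <- vapply(results, function(r) comparison_name(r$focal, r$reference),
               character(1))
  setNames(results, nm)
}

#' Marker set of one experimental group
#'
#' Combines the group's three (or more) pairwise comparisons into a
#' single marker call. In `plain_intersection` mode a marker is a
#' protein DE in every comparison involving the group. In
#' `exclusivity_refined` mode (the default for the combined-insult
#' group, see [pcpnic_markers()]) each comparison contributes only the
#' group's exclusive Venn region among comparisons sharing the same
#' reference, and the regions are intersected.
#'
#' Per-marker directions are reported from the group's own perspective
#' for each contributing comparison ("Up" when the group's mean is
#' higher), with a `consistent` flag when all directions agree;
#' direction never affects membership.
#'
#' @param results list of `lfq_comparison` objects covering every arrow
#'   of the lattice that involves `group` (for exclusivity refinement,
#'   also the parallel arrows sharing each reference).
#' @param group the group whose markers to call.
#' @param mode `"plain_intersection"` or `"exclusivity_refined"`.
#' @return An object of class `lfq_marker_set`: fields `sex`, `group`,
#'   `mode`, `proteins`, and `directions` (tibble with one `vs<REF>`
#'   column per contributing comparison plus `consistent`).
#' @export
group_markers <- function(results, group,
                          mode = c("plain_intersection",
                                   "exclusivity_refined")) {
  mode <- match.arg(mode)
  results <- comparison_lookup(results)
  sexes <- unique(vapply(results, function(r) r$sex, character(1)))
  if (length(sexes) != 1) {
    abort("group_markers: all comparisons must come from one sex",
          class = "lfq_config_error")
  }
  groups <- unique(unlist(lapply(results,
                                 function(r) c(r$focal, r$reference))))
  lattice <- comparison_lattice(groups)
  involving <- lattice[lattice$focal == group | lattice$reference == group, ]
  if (nrow(involving) == 0) {
    abort(sprintf("no comparisons involve group %s", group),
          class = "lfq_config_error")
  }
  required <- if (mode == "exclusivity_refined") {
    # exclusivity needs the parallel arrows sharing each reference too
    lattice$name[lattice$reference %in% involving$reference |
                   lattice$name %in% involving$name]
  } else {
    involving$name
  }
  missing_cmp <- setdiff(required, names(results))
  if (length(missing_cmp) > 0) {
    abort(sprintf("missing comparison(s) in the lattice: %s",
                  paste(missing_cmp, collapse = ", ")),
          class = "lfq_config_error")
  }
  lattice <- lattice[lattice$name %in% names(results), ]
  de_sets <- lapply(results, de_proteins)
  markers <- marker_set_algebra(de_sets, lattice, group, mode)
  markers <- sort(markers)

  directions <- tibble::tibble(protein_id = markers)
  for (i in seq_len(nrow(involving))) {
    cmp <- results[[involving$name[i]]]
    other <- if (cmp$focal == group) cmp$reference else cmp$focal
    dir <- de_directions(cmp, from = group)
    directions[[paste0("vs", other)]] <- unname(dir[markers])
  }
  dir_cols <- directions[, -1, drop = FALSE]
  directions$consistent <- if (ncol(dir_cols) == 0) logical(0) else
    apply(dir_cols, 1, function(r) length(unique(r)) == 1)

  structure(list(sex = sexes, group = group, mode = mode,
                 proteins = markers, directions = directions),
            class = "lfq_marker_set")
}

#' @export
print.lfq_marker_set <- function(x, ...) {
  cat(sprintf("<lfq_marker_set> %s (sex %s, %s): %d marker(s)\n",
              x$group, x$sex, x$mode, length(x$proteins)))
  invisible(x)
}

#' Markers of the combined-insult (PCPNIC) group
#'
#' Convenience wrapper around [group_markers()] with the
#' exclusivity-refined mode as default: markers are the proteins
#' exclusively deregulated versus control (among all groups' vs-control
#' comparisons), exclusively deregulated versus the nicotine group
#' (among the phencyclidine-exposed groups' vs-nicotine comparisons),
#' and deregulated versus the phencyclidine group.
#'
#' @inheritParams group_markers
#' @export
pcpnic_markers <- function(results, group = "PCPNIC",
                           mode = c("exclusivity_refined",
                                    "plain_intersection")) {
  mode <- match.arg(mode)
  group_markers(results, group = group, mode = mode)
}

#' Fraction of DE proteins deregulated in exactly one sex
#'
#' Over the union U of proteins DE in at least one comparison of at
#' least one sex, the fraction whose DE evidence is confined to a
#' single sex.
#'
#' @param male_results,female_results lists of `lfq_comparison` objects
#'   over the same comparison lattice.
#' @return A fraction in \[0, 1\]; `NA` (with a warning) when no protein
#'   is DE anywhere.
#' @export
sex_exclusivity_fraction <- function(male_results, female_results) {
  de_union <- function(results) {
    unique(unlist(lapply(comparison_lookup(results), de_proteins)))
  }
  male <- de_union(male_results)
  female <- de_union(female_results)
  u <- union(male, female)
  if (length(u) == 0) {
    warn("sex_exclusivity_fraction: no DE proteins in either sex")
    return(NA_real_)
  }
  length(setdiff(male, female) %union% setdiff(female, male)) / length(u)
}

`%union%` <- function(a, b) union(a, b)
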