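#' Configuration for the synthetic peptide-intensity generator
#'
#' Describes a label-free LC-MS study design: a set of proteins digested
#' into peptides, measured across experimental groups and sexes, with
#' biological replicate pools and technical replicate injections per pool.
#' Defaults emulate a four-arm exposure design (control, phencyclidine,
#' nicotine, combined) with both sexes, four pools per condition and
#' technical triplicates, sized to yield roughly 3594 peptides over 337
#' proteins.
#'
#' Intensities follow a multiplicative model: protein pool abundance =
#' base abundance x biological noise x planted fold change; peptide
#' intensity = pool abundance x peptide ionization factor x technical
#' noise. Noise at both levels is log-normal with unit mean, parameterized
#' by coefficient of variation so `tech_cv`/`bio_cv` are directly
#' interpretable. Missingness is intensity-dependent: the probability that
#' an observation drops out is logistic in log intensity, decreasing as
#' intensity grows.
#'
#' @param n_proteins number of proteins (default 337).
#' @param mean_peptides_per_protein expected peptides per protein (default
#'   3594/337). Counts are drawn as `min_peptides_per_protein + Poisson`,
#'   so the identification filter (2 peptides) is satisfiable by design.
#' @param min_peptides_per_protein floor on peptides per protein (default
#'   2; set to 1 to generate sub-threshold proteins for filter tests).
#' @param groups ordered group labels; the first is the control/reference.
#' @param sexes sex labels.
#' @param n_pools biological replicate pools per group/sex (default 4).
#' @param n_tech technical replicates (injections) per pool (default 3).
#' @param base_abundance_log_mean,base_abundance_log_sd natural-log
#'   location and spread of protein base abundance.
#' @param ionization_log_sd log-scale SD of per-peptide ionization
#'   efficiency factors (peptides of one protein ionize very differently).
#' @param tech_cv technical (injection-to-injection) coefficient of
#'   variation; 0 disables technical noise.
#' @param bio_cv biological (pool-to-pool) coefficient of variation; 0
#'   disables biological noise.
#' @param dropout_midpoint natural-log intensity at which the dropout
#'   probability is 0.5; `-Inf` disables dropout entirely.
#' @param dropout_slope steepness of the logistic dropout curve (per
#'   natural-log-intensity unit, >= 0).
#' @param seed default RNG seed used by [generate_dataset()] when none is
#'   given explicitly.
#' @return A list of class `lfq_synth_config`.
#' @seealso [generate_dataset()], [planted_effects()]
#' @export
synthetic_config <- function(n_proteins = 337,
                             mean_peptides_per_protein = 3594 / 337,
                             min_peptides_per_protein = 2,
                             groups = DEFAULT_GROUPS,
                             sexes = DEFAULT_SEXES,
                             n_pools = 4,
                             n_tech = 3,
                             base_abundance_log_mean = log(1e6),
                             base_abundance_log_sd = 1.2,
                             ionization_log_sd = 0.8,
                             tech_cv = 0.10,
                             bio_cv = 0.15,
                             dropout_midpoint = -Inf,
                             dropout_slope = 1,
                             seed = 1L) {
  config <- list(
    n_proteins = as.integer(n_proteins),
    mean_peptides_per_protein = mean_peptides_per_protein,
    min_peptides_per_protein = as.integer(min_peptides_per_protein),
    groups = as.character(groups),
    sexes = as.character(sexes),
    n_pools = as.integer(n_pools),
    n_tech = as.integer(n_tech),
    base_abundance_log_mean = base_abundance_log_mean,
    base_abundance_log_sd = base_abundance_log_sd,
    ionization_log_sd = ionization_log_sd,
    tech_cv = tech_cv,
    bio_cv = bio_cv,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    seed = as.integer(seed)
  )
  class(config) <- "lfq_synth_config"
  validate_synth_config(config)
  config
}

validate_synth_config <- function(config) {
  counts <- c(
    n_proteins = config$n_proteins, n_pools = config$n_pools,
    n_tech = config$n_tech,
    min_peptides_per_protein = config$min_peptides_per_protein
  )
  bad <- counts < 1L
  if (any(bad)) {
    abort(sprintf(
      "synthetic_config: counts must be >= 1 (offending: %s)",
      paste(names(counts)[bad], collapse = ", ")
    ), class = "lfq_validation_error")
  }
  if (config$mean_peptides_per_protein < config$min_peptides_per_protein) {
    abort("synthetic_config: mean_peptides_per_protein below the minimum",
          class = "lfq_validation_error")
  }
  cvs <- c(tech_cv = config$tech_cv, bio_cv = config$bio_cv,
           ionization_log_sd = config$ionization_log_sd,
           base_abundance_log_sd = config$base_abundance_log_sd,
           dropout_slope = config$dropout_slope)
  if (any(cvs < 0)) {
    abort("synthetic_config: CVs, log-SDs and dropout_slope must be >= 0",
          class = "lfq_validation_error")
  }
  if (anyDuplicated(config$groups) || anyDuplicated(config$sexes)) {
    abort("synthetic_config: group and sex labels must be unique",
          class = "lfq_validation_error")
  }
  if (length(config$groups) < 2) {
    abort("synthetic_config: need at least two groups",
          class = "lfq_validation_error")
  }
  invisible(config)
}

#' Planted differential-expression effects
#'
#' Builds a validated table of multiplicative effects applied to specific
#' (protein, sex, group) cells relative to the control group. A
#' `fold_change` above 1 plants upregulation, below 1 downregulation.
#'
#' @param protein_id character protein ids (as produced by
#'   [generate_dataset()]: `"P0001"`, `"P0002"`, ...).
#' @param sex,group labels, recycled to the length of `protein_id`.
#' @param fold_change multiplicative factors, all > 0.
#' @return A tibble of class `lfq_planted_effects` with one row per
#'   (protein, sex, group).
#' @export
planted_effects <- function(protein_id, sex, group, fold_change) {
  effects <- tibble::tibble(
    protein_id = as.character(protein_id),
    sex = as.character(sex),
    group = as.character(group),
    fold_change = as.numeric(fold_change)
  )
  if (any(!is.finite(effects$fold_change)) || any(effects$fold_change <= 0)) {
    abort("planted_effects: fold_change must be finite and > 0",
          class = "lfq_validation_error")
  }
  key <- paste(effects$protein_id, effects$sex, effects$group)
  if (anyDuplicated(key)) {
    abort("planted_effects: (protein, sex, group) must be unique",
          class = "lfq_validation_error")
  }
  class(effects) <- c("lfq_planted_effects", class(effects))
  effects
}

empty_effects <- function() {
  planted_effects(character(), character(), character(), numeric())
}

check_effects_against_config <- function(effects, config) {
  reference <- config$groups[1]
  if (nrow(effects) == 0) return(invisible(effects))
  bad_group <- setdiff(effects$group, setdiff(config$groups, reference))
  bad_sex <- setdiff(effects$sex, config$sexes)
  if (length(bad_group) > 0 || length(bad_sex) > 0) {
    abort(sprintf(
      "planted effects reference labels outside the design: %s",
      paste(c(bad_group, bad_sex), collapse = ", ")
    ), class = "lfq_config_error")
  }
  ids <- protein_ids(config$n_proteins)
  bad_id <- setdiff(effects$protein_id, ids)
  if (length(bad_id) > 0) {
    abort(sprintf("planted effects reference unknown proteins: %s",
                  paste(bad_id, collapse = ", ")),
          class = "lfq_config_error")
  }
  invisible(effects)
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

# Log-normal multiplier with unit mean and the requested CV.
# cv = 0 degenerates to the constant 1.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic peptide-intensity dataset with known ground truth
#'
#' Simulates the full design described by `config`: per-protein base
#' abundances, per-peptide ionization factors, biological pool noise,
#' planted group effects, technical noise, and logistic
#' intensity-dependent dropout. Identical `(config, effects, seed)` give
#' identical output.
#'
#' @param config an [synthetic_config()] object.
#' @param effects a [planted_effects()] table (possibly empty).
#' @param seed integer RNG seed; defaults to `config$seed`.
#' @return A list with elements `peptides` (a long-format tibble with
#'   columns peptide_id, protein_id, sex, group, pool, tech, intensity;
#'   dropped observations are absent rows, never zeros) and `truth` (an
#'   `lfq_ground_truth` list: effects, peptide map with ionization
#'   factors, base abundances, expected DE sets and expected marker sets
#'   per sex, and dropout accounting).
#' @examples
#' config <- synthetic_config(n_proteins = 20, seed = 7)
#' sim <- generate_dataset(config)
#' dplyr::count(sim$peptides, sex, group)
#' @export
generate_dataset <- function(config, effects = empty_effects(),
                             seed = config$seed) {
  stopifnot(inherits(config, "lfq_synth_config"))
  if (!inherits(effects, "lfq_planted_effects")) {
    abort("effects must be built with planted_effects()",
          class = "lfq_validation_error")
  }
  validate_synth_config(config)
  check_effects_against_config(effects, config)

  set.seed(as.integer(seed))
  n <- config$n_proteins
  prot <- protein_ids(n)

  n_pep <- config$min_peptides_per_protein +
    rpois(n, config$mean_peptides_per_protein - config$min_peptides_per_protein)
  base <- rlnorm(n, config$base_abundance_log_mean,
                 config$base_abundance_log_sd)

  peptide_map <- tibble::tibble(
    protein_id = rep(prot, n_pep),
    peptide_id = sprintf("%s.pep%02d", rep(prot, n_pep),
                         unlist(lapply(n_pep, seq_len))),
    ion_factor = rlnorm(sum(n_pep), 0, config$ionization_log_sd)
  )

  # Biological pool abundances: base x bio-noise x planted fold change.
  pools <- tidyr::expand_grid(
    protein_id = prot,
    sex = config$sexes,
    group = config$groups,
    pool = seq_len(config$n_pools)
  )
  pools$bio <- rlnorm_cv(nrow(pools), config$bio_cv)
  pools$base <- base[match(pools$protein_id, prot)]
  fold <- rep(1, nrow(pools))
  if (nrow(effects) > 0) {
    idx <- match(paste(pools$protein_id, pools$sex, pools$group),
                 paste(effects$protein_id, effects$sex, effects$group))
    fold[!is.na(idx)] <- effects$fold_change[idx[!is.na(idx)]]
  }
  pools$abundance <- pools$base * pools$bio * fold

  # One candidate row per (peptide, sex, group, pool, tech).
  rows <- dplyr::inner_join(peptide_map, pools,
                            by = "protein_id", relationship = "many-to-many")
  rows <- tidyr::expand_grid(
    dplyr::select(rows, "peptide_id", "protein_id", "sex", "group", "pool",
                  "abundance", "ion_factor"),
    tech = seq_len(config$n_tech)
  )
  n_cells_total <- nrow(rows)
  rows$intensity <- rows$abundance * rows$ion_factor *
    rlnorm_cv(n_cells_total, config$tech_cv)

  p_drop <- stats::plogis(
    config$dropout_slope * (config$dropout_midpoint - log(rows$intensity))
  )
  keep <- runif(n_cells_total) >= p_drop
  n_dropped <- sum(!keep)

  peptides <- tibble::as_tibble(rows[keep, c(
    "peptide_id", "protein_id", "sex", "group", "pool", "tech", "intensity"
  )])
  peptides <- dplyr::arrange(peptides, .data$peptide_id, .data$sex,
                             .data$group, .data$pool, .data$tech)

  truth <- new_ground_truth(config, effects, peptide_map,
                            tibble::tibble(protein_id = prot, base = base),
                            n_cells_total, n_dropped)
  list(peptides = peptides, truth = truth)
}

new_ground_truth <- function(config, effects, peptide_map, base_abundance,
                             n_cells_total, n_dropped) {
  truth <- list(
    config = config,
    effects = effects,
    peptide_map = peptide_map,
    base_abundance = base_abundance,
    n_cells_total = n_cells_total,
    n_dropped = n_dropped
  )
  truth$expected_de <- truth_de_sets(truth)
  truth$expected_markers <- truth_marker_sets(truth)
  class(truth) <- "lfq_ground_truth"
  truth
}

# Fold change planted for each (protein, sex, group); 1 where no effect.
planted_fold <- function(truth, sex, group) {
  fold <- rep(1, truth$config$n_proteins)
  names(fold) <- protein_ids(truth$config$n_proteins)
  eff <- truth$effects
  eff <- eff[eff$sex == sex & eff$group == group, ]
  fold[eff$protein_id] <- eff$fold_change
  fold
}

# Expected DE sets per sex for every arrow of the comparison lattice,
# from the planted truth alone: a protein is expected-DE in (focal vs
# reference) iff its planted fold ratio between the two groups exceeds
# the fold-change threshold in either direction.
truth_de_sets <- function(truth, fc_min = 1.5) {
  lattice <- comparison_lattice(truth$config$groups)
  out <- list()
  for (sex in truth$config$sexes) {
    sets <- list()
    for (i in seq_len(nrow(lattice))) {
      focal <- lattice$focal[i]
      reference <- lattice$reference[i]
      ratio <- planted_fold(truth, sex, focal) /
        planted_fold(truth, sex, reference)
      de <- names(ratio)[pmax(ratio, 1 / ratio) > fc_min]
      sets[[comparison_name(focal, reference)]] <- de
    }
    out[[sex]] <- sets
  }
  out
}

# Expected marker sets per sex per non-reference group, applying the same
# exclusivity/intersection logic used by the pipeline to the expected DE
# sets.
truth_marker_sets <- function(truth) {
  lattice <- comparison_lattice(truth$config$groups)
  groups <- setdiff(truth$config$groups, truth$config$groups[1])
  out <- list()
  for (sex in truth$config$sexes) {
    de_sets <- truth$expected_de[[sex]] %||% NULL
    if (is.null(de_sets)) {
      de_sets <- truth_de_sets(truth)[[sex]]
    }
    out[[sex]] <- lapply(
      setNames(groups, groups),
      function(g) marker_set_algebra(de_sets, lattice, g,
                                     mode = "exclusivity_refined")
    )
  }
  out
}

#' Generate a synthetic protein-protein interaction edge list
#'
#' Stands in for an offline interaction-database export. Proteins are
#' partitioned into communities (by default one community per planted
#' (sex, group) effect block); each within-community pair receives an
#' edge with probability `p_within`, every other pair with probability
#' `p_between`. Confidences are drawn uniformly from `confidence_range`.
#'
#' @param truth an `lfq_ground_truth` object (supplies protein ids and
#'   default communities).
#' @param p_within,p_between edge probabilities, `0 <= p_between <=
#'   p_within <= 1`.
#' @param confidence_range length-2 numeric within \[0, 1\].
#' @param seed integer RNG seed.
#' @param communities optional list of protein-id vectors overriding the
#'   default effect-derived communities.
#' @return A tibble (protein_a, protein_b, confidence): undirected, no
#'   self-loops, no duplicate unordered pairs.
#' @export
generate_interaction_edges <- function(truth, p_within, p_between,
                                       confidence_range = c(0.4, 0.99),
                                       seed = 1L, communities = NULL) {
  if (!(p_between >= 0 && p_within <= 1 && p_between <= p_within)) {
    abort("require 0 <= p_between <= p_within <= 1",
          class = "lfq_validation_error")
  }
  if (length(confidence_range) != 2 || any(confidence_range < 0) ||
      any(confidence_range > 1) ||
      confidence_range[1] > confidence_range[2]) {
    abort("confidence_range must be an interval within [0, 1]",
          class = "lfq_validation_error")
  }
  ids <- truth$base_abundance$protein_id
  if (is.null(communities)) {
    eff <- truth$effects
    communities <- if (nrow(eff) == 0) list() else
      split(eff$protein_id, paste(eff$sex, eff$group))
    communities <- lapply(communities, unique)
  }
  membership <- rep(NA_integer_, length(ids))
  names(membership) <- ids
  for (k in seq_along(communities)) {
    membership[intersect(communities[[k]], ids)] <- k
  }

  set.seed(as.integer(seed))
  pairs <- utils::combn(ids, 2)
  same <- membership[pairs[1, ]] == membership[pairs[2, ]]
  same[is.na(same)] <- FALSE
  prob <- ifelse(same, p_within, p_between)
  keep <- runif(ncol(pairs)) < prob
  conf <- runif(sum(keep), confidence_range[1], confidence_range[2])
  tibble::tibble(
    protein_a = pairs[1, keep],
    protein_b = pairs[2, keep],
    confidence = conf
  )
}

#' Generate a synthetic pathway annotation
#'
#' Stands in for an offline pathway-database export (GMT-style). Each
#' (pathway, protein) membership is drawn independently with probability
#' `density`; proteins may belong to several pathways.
#'
#' @param truth an `lfq_ground_truth` object (supplies protein ids).
#' @param n_pathways number of pathways (>= 1).
#' @param density membership probability in \[0, 1\].
#' @param seed integer RNG seed.
#' @param ensure_nonempty when TRUE (default), a pathway that drew no
#'   members receives one random protein so every pathway is non-empty;
#'   set FALSE to allow (and drop) empty pathways.
#' @return A tibble (pathway_id, description, proteins list-column), the
#'   package's `PathwayAnnotation` representation.
#' @export
generate_pathway_annotation <- function(truth, n_pathways, density,
                                        seed = 1L, ensure_nonempty = TRUE) {
  if (n_pathways < 1) {
    abort("n_pathways must be >= 1", class = "lfq_validation_error")
  }
  if (density < 0 || density > 1) {
    abort("density must be within [0, 1]", class = "lfq_validation_error")
  }
  ids <- truth$base_abundance$protein_id
  set.seed(as.integer(seed))
  sets <- lapply(seq_len(n_pathways), function(k) {
    members <- ids[runif(length(ids)) < density]
    if (length(members) == 0 && ensure_nonempty) {
      members <- sample(ids, 1)
    }
    members
  })
  annotation <- tibble::tibble(
    pathway_id = sprintf("PW%04d", seq_len(n_pathways)),
    description = sprintf("synthetic pathway %d", seq_len(n_pathways)),
    proteins = sets
  )
  annotation[lengths(annotation$proteins) > 0, ]
}
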