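#' Differential-expression filter thresholds
#'
#' The cascade applied to every pairwise comparison: presence (observed
#' in at least `presence_min` of `presence_of` pools in BOTH
#' conditions), condition-wise coefficient of variation at most
#' `cv_max`, fold change strictly above `fc_min`, and one-way ANOVA
#' p-value strictly below `alpha`. Defaults are the conventional LFQ
#' screening values: CV <= 30%, FC > 1.5, p < 0.05, presence 3/4.
#'
#' @param cv_max maximum condition CV (fraction, default 0.30).
#' @param fc_min fold-change threshold (ratio >= 1, strict >, default 1.5).
#' @param alpha ANOVA significance level (strict <, default 0.05).
#' @param presence_min minimum pools with an observation per condition
#'   (default 3).
#' @param presence_of number of pools per condition (default 4).
#' @return A list of class `lfq_de_thresholds`.
#' @export
de_thresholds <- function(cv_max = 0.30, fc_min = 1.5, alpha = 0.05,
                          presence_min = 3L, presence_of = 4L) {
  if (!(alpha > 0 && alpha < 1)) {
    abort("alpha must be in (0, 1)", class = "lfq_validation_error")
  }
  if (fc_min < 1) {
    abort("fc_min must be >= 1", class = "lfq_validation_error")
  }
  if (cv_max <= 0) {
    abort("cv_max must be > 0", class = "lfq_validation_error")
  }
  if (presence_min > presence_of) {
    abort("presence_min must be <= presence_of",
          class = "lfq_validation_error")
  }
  structure(list(cv_max = cv_max, fc_min = fc_min, alpha = alpha,
                 presence_min = as.integer(presence_min),
                 presence_of = as.integer(presence_of)),
            class = "lfq_de_thresholds")
}

#' Per-protein statistics for one pairwise comparison
#'
#' For one sex and two groups, computes per protein (over pool-level
#' abundances): presence counts, condition means and CVs, fold change
#' (larger mean over smaller mean, on raw abundances), the two-level
#' one-way ANOVA F and p, and the direction of the focal group relative
#' to the reference. Proteins observed in at least one pool of either
#' condition get a record; a protein with fewer than two pools bearing
#' values in a condition is flagged (`stats_defined = FALSE`) and its
#' ANOVA is skipped rather than raising an error.
#'
#' Degenerate within-group variance (all pool values identical in both
#' conditions) is resolved as F = 0, p = 1 when the means are equal and
#' p = 0 (infinite F) when they differ, so zero-noise data never
#' divides by zero.
#'
#' @param pools pool-level abundance table from [aggregate_technical()].
#' @param sex sex label to analyze.
#' @param focal,reference the two group labels; direction is "up" when
#'   the focal mean exceeds the reference mean.
#' @param log_transform when TRUE, ANOVA (and the means used for fold
#'   change and direction) run on natural-log abundances; off by
#'   default, matching the raw-intensity screening convention.
#' @return A tibble with one row per protein: presence counts, means,
#'   CVs, fold_change, f_stat, p_value, q_value (Benjamini-Hochberg,
#'   reported for transparency, never used for calls), direction,
#'   stats_defined.
#' @export
protein_stats <- function(pools, sex, focal, reference,
                          log_transform = FALSE) {
  stopifnot(all(c("protein_id", "sex", "group", "pool", "abundance") %in%
                  names(pools)))
  groups_present <- unique(pools$group)
  unknown <- setdiff(c(focal, reference), groups_present)
  if (length(unknown) > 0) {
    abort(sprintf("unknown group label(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "lfq_config_error")
  }
  if (focal == reference) {
    abort("focal and reference groups must differ",
          class = "lfq_config_error")
  }
  sub <- pools[pools$sex == sex & pools$group %in% c(focal, reference), ]
  if (log_transform) sub$abundance <- log(sub$abundance)

  stats_one <- function(d) {
    xf <- d$abundance[d$group == focal]
    xr <- d$abundance[d$group == reference]
    mean_f <- if (length(xf) > 0) mean(xf) else NA_real_
    mean_r <- if (length(xr) > 0) mean(xr) else NA_real_
    defined <- length(xf) >= 2 && length(xr) >= 2
    f_stat <- NA_real_
    p_value <- NA_real_
    if (defined) {
      if (sd(xf) == 0 && sd(xr) == 0) {
        if (isTRUE(all.equal(mean_f, mean_r))) {
          f_stat <- 0; p_value <- 1
        } else {
          f_stat <- Inf; p_value <- 0
        }
      } else {
        fit <- oneway.test(
          abundance ~ group,
          data = data.frame(abundance = c(xf, xr),
                            group = rep(c("f", "r"),
                                        c(length(xf), length(xr)))),
          var.equal = TRUE
        )
        f_stat <- unname(fit$statistic)
        p_value <- unname(fit$p.value)
      }
    }
    fold <- if (!is.na(mean_f) && !is.na(mean_r) &&
                min(mean_f, mean_r) > 0) {
      max(mean_f, mean_r) / min(mean_f, mean_r)
    } else NA_real_
    tibble::tibble(
      n_present_focal = length(xf), n_present_ref = length(xr),
      mean_focal = mean_f, mean_ref = mean_r,
      cv_focal = cv_of(xf), cv_ref = cv_of(xr),
      fold_change = fold, f_stat = f_stat, p_value = p_value,
      direction = if (is.na(mean_f) || is.na(mean_r)) NA_character_
                  else if (mean_f > mean_r) "up" else "down",
      stats_defined = defined
    )
  }

  records <- sub |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(~stats_one(.x)) |>
    dplyr::ungroup()
  records$q_value <- p.adjust(records$p_value, method = "BH")
  records
}

#' Pairwise comparison with the full filter cascade
#'
#' Applies, in order: (1) coexistence/presence — the protein must be
#' present in at least `presence_min` of `presence_of` pools in both
#' conditions; (2) CV at most `cv_max` in both conditions; (3) fold
#' change strictly above `fc_min`; (4) ANOVA p strictly below `alpha`.
#' A protein is differentially expressed (DE) iff it passes all four;
#' `filter_failed` records the first filter that eliminated it.
#'
#' @inheritParams protein_stats
#' @param thresholds a [de_thresholds()] object.
#' @return An object of class `lfq_comparison` with fields `sex`,
#'   `focal`, `reference`, `thresholds`, `records` (the annotated
#'   statistics tibble) and accessors [de_proteins()] /
#'   [de_directions()].
#' @export
pairwise_compare <- function(pools, sex, focal, reference,
                             thresholds = de_thresholds(),
                             log_transform = FALSE) {
  stopifnot(inherits(thresholds, "lfq_de_thresholds"))
  records <- protein_stats(pools, sex, focal, reference,
                           log_transform = log_transform)
  pass_presence <- records$n_present_focal >= thresholds$presence_min &
    records$n_present_ref >= thresholds$presence_min
  pass_cv <- !is.na(records$cv_focal) & !is.na(records$cv_ref) &
    records$cv_focal <= thresholds$cv_max &
    records$cv_ref <= thresholds$cv_max
  pass_fc <- !is.na(records$fold_change) &
    records$fold_change > thresholds$fc_min
  pass_anova <- records$stats_defined & !is.na(records$p_value) &
    records$p_value < thresholds$alpha

  filter_failed <- rep(NA_character_, nrow(records))
  filter_failed[!pass_anova] <- "anova"
  filter_failed[!pass_fc] <- "fold_change"
  filter_failed[!pass_cv] <- "cv"
  filter_failed[!pass_presence] <- "presence"

  records$pass_presence <- pass_presence
  records$pass_cv <- pass_cv
  records$pass_fc <- pass_fc
  records$pass_anova <- pass_anova
  records$filter_failed <- filter_failed
  records$is_de <- pass_presence & pass_cv & pass_fc & pass_anova

  structure(
    list(sex = sex, focal = focal, reference = reference,
         thresholds = thresholds, records = records),
    class = "lfq_comparison"
  )
}

#' @export
print.lfq_comparison <- function(x, ...) {
  cat(sprintf("<lfq_comparison> %s vs %s (sex %s): %d proteins, %d DE\n",
              x$focal, x$reference, x$sex, nrow(x$records),
              sum(x$records$is_de)))
  invisible(x)
}

#' DE protein set of a comparison
#' @param comparison an `lfq_comparison` object.
#' @return Character vector of protein ids flagged DE.
#' @export
de_proteins <- function(comparison) {
  stopifnot(inherits(comparison, "lfq_comparison"))
  comparison$records$protein_id[comparison$records$is_de]
}

#' Direction of DE proteins, from a given group's perspective
#'
#' @param comparison an `lfq_comparison` object.
#' @param from group label whose perspective to take (default the focal
#'   group); asking from the reference's perspective flips every
#'   direction.
#' @return Named character vector protein id -> "Up"/"Down".
#' @export
de_directions <- function(comparison, from = comparison$focal) {
  stopifnot(inherits(comparison, "lfq_comparison"))
  if (!from %in% c(comparison$focal, comparison$reference)) {
    abort(sprintf("group %s is not part of this comparison", from),
          class = "lfq_config_error")
  }
  de <- comparison$records[comparison$records$is_de, ]
  dir <- ifelse(de$direction == "up", "Up", "Down")
  if (from == comparison$reference) {
    dir <- ifelse(dir == "Up", "Down", "Up")
  }
  setNames(dir, de$protein_id)
}
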