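#' Classify a behavioural phenotype and grade anxiety-like behaviour
#'
#' Maps the fitted evidence for one subject or cohort to a phenotype
#' label and an ordinal anxiety-like-behaviour (ALB) grade:
#' \itemize{
#'   \item open-arm NEG never exceeding `open_floor` percent -> avoidant
#'     (no open-arm exploration), graded maximal;
#'   \item dual-phase growth selected for the total maze with open-arm
#'     exploration confined to the later phase -> delayed;
#'   \item open-arm exploration present in the first phase -> exploratory.
#' }
#' Within the exploratory and delayed bands the grade is refined by the
#' end-of-test depth gap (closed minus open NEG): similar deep
#' exploration of both arm types means lower ALB, a much shallower
#' open-arm depth means higher ALB.  Grades are ordered low <
#' moderately-low < moderately-high < high < maximal; exploratory maps
#' into \{low, moderately-low\} and delayed into \{moderately-low,
#' moderately-high\}, matching the phenotype-to-ALB gradient.
#'
#' @param comparison a `neg_model_comparison` for the total-maze series
#'   (from [compare_models()]).
#' @param final_open,final_closed end-of-test NEG (percent) per scope.
#' @param decisions optional `neg_decisions` for the open-vs-closed arm
#'   contrast; when supplied, a dual-phase selection with an arm contrast
#'   that never leaves equivalence is reported as conflicting evidence
#'   (undecided call).
#' @param open_floor percent threshold under which open-arm exploration
#'   counts as absent (default 5).
#' @param gap_cuts depth-gap cutpoints (percentage points) between the
#'   raw grade bands (default 25/50/75).
#' @return a `phenotype_call`: `label`, `alb_grade`, `evidence`.
#' @export
classify_phenotype <- function(comparison, final_open, final_closed,
                               decisions = NULL, open_floor = 5,
                               gap_cuts = c(25, 50, 75)) {
  stopifnot(inherits(comparison, "neg_model_comparison"),
            is.numeric(final_open), is.numeric(final_closed))
  grades <- c("low", "moderately-low", "moderately-high", "high", "maximal")
  dual <- comparison$selected_n_phases >= 2L
  gap <- final_closed - final_open
  raw <- findInterval(gap, gap_cuts) + 1L  # 1..4 by depth gap

  if (final_open <= open_floor) {
    label <- "avoidant"; grade_i <- 5L
  } else if (dual) {
    label <- "delayed"
    if (!is.null(decisions) &&
        !any(decisions$decision == "not-equivalent")) {
      label <- "undecided"  # two phases but the arms never differed
    }
    grade_i <- clamp(raw, 2L, 3L)
  } else {
    label <- "exploratory"
    grade_i <- clamp(raw, 1L, 2L)
  }
  evidence <- list(
    selected_model = comparison$selected,
    n_phases = comparison$selected_n_phases,
    final_open = final_open, final_closed = final_closed,
    depth_gap = gap,
    arm_contrast_states = if (!is.null(decisions)) table(decisions$decision))
  structure(list(label = label,
                 alb_grade = if (label == "undecided") NA_character_
                             else grades[grade_i],
                 evidence = evidence),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("Phenotype call: %s (ALB grade: %s)\n", x$label,
              x$alb_grade %||% "NA"))
  e <- x$evidence
  cat(sprintf("  total-maze model: %s (%d phase%s); end-of-test NEG open %.1f%% / closed %.1f%% (gap %.1f)\n",
              e$selected_model, e$n_phases, if (e$n_phases > 1) "s" else "",
              e$final_open, e$final_closed, e$depth_gap))
  invisible(x)
}
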