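# Screening-plus-intervention arithmetic: performance from published 2x2
# counts, events prevented under treatment, number needed to genotype, and a
# two-stage screening flow.

#' Screening counts from a published risk-model evaluation
#'
#' @param n_total cohort size.
#' @param n_affected individuals who went on to have an event.
#' @param n_flagged individuals above the risk cut-off (offered treatment).
#' @param n_affected_flagged affected individuals above the cut-off.
#' @return An object of class `polyscreen_counts`.
#' @examples
#' screen_counts(100000, 7997, 26722, 4783)
#' @export
screen_counts <- function(n_total, n_affected, n_flagged, n_affected_flagged) {
  check_count(n_total, "n_total", lower = 1)
  check_count(n_affected, "n_affected")
  check_count(n_flagged, "n_flagged")
  check_count(n_affected_flagged, "n_affected_flagged")
  if (n_affected > n_total || n_flagged > n_total) {
    abort_validation("group counts cannot exceed `n_total`")
  }
  if (n_affected_flagged > min(n_affected, n_flagged)) {
    abort_validation(
      "`n_affected_flagged` cannot exceed `n_affected` or `n_flagged`")
  }
  structure(list(n_total = n_total, n_affected = n_affected,
                 n_flagged = n_flagged,
                 n_affected_flagged = n_affected_flagged),
            class = "polyscreen_counts")
}

#' Detection and false positive rates from screening counts
#'
#' `dr` is the fraction of affected individuals above the cut-off;
#' `fpr` is the fraction of unaffected individuals above it.
#'
#' @param counts a [screen_counts()].
#' @return A list with `dr` and `fpr`, both in `[0, 1]`.
#' @examples
#' screening_metrics_from_counts(screen_counts(100000, 7997, 26722, 4783))
#' @export
screening_metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "polyscreen_counts"))
  n_unaffected <- counts$n_total - counts$n_affected
  if (counts$n_affected == 0 || n_unaffected == 0) {
    abort_validation("need at least one affected and one unaffected individual")
  }
  list(
    dr = counts$n_affected_flagged / counts$n_affected,
    fpr = (counts$n_flagged - counts$n_affected_flagged) / n_unaffected
  )
}

#' A preventive intervention
#'
#' @param relative_risk_reduction fraction of events prevented among treated
#'   individuals, in `[0, 1]` (e.g. 0.2 for statins).
#' @param adherence fraction of flagged individuals who take up and adhere to
#'   treatment, in `[0, 1]`.
#' @return An object of class `polyscreen_intervention`.
#' @export
intervention_model <- function(relative_risk_reduction, adherence = 1) {
  check_number(relative_risk_reduction, "relative_risk_reduction",
               lower = 0, upper = 1)
  check_number(adherence, "adherence", lower = 0, upper = 1)
  structure(list(relative_risk_reduction = relative_risk_reduction,
                 adherence = adherence),
            class = "polyscreen_intervention")
}

#' Events prevented by treating individuals above a risk cut-off
#'
#' `round(rrr * adherence * events)`, rounded half away from zero to whole
#' events, matching printed whole-person tables.
#'
#' @param events_above_cutoff events occurring among flagged individuals.
#' @param model a [intervention_model()].
#' @return Integer count of events prevented.
#' @examples
#' events_prevented(4783, intervention_model(0.2)) # 957
#' @export
events_prevented <- function(events_above_cutoff, model) {
  check_count(events_above_cutoff, "events_above_cutoff")
  stopifnot(inherits(model, "polyscreen_intervention"))
  as.integer(round_half_up(
    model$relative_risk_reduction * model$adherence * events_above_cutoff))
}

#' Events prevented if the whole cohort were treated
#'
#' The treat-all comparator: [events_prevented()] applied to every event in
#' the cohort, irrespective of any risk score.
#'
#' @param total_events all events in the cohort.
#' @param model a [intervention_model()].
#' @return Integer count of events prevented.
#' @export
treat_all_events_prevented <- function(total_events, model) {
  events_prevented(total_events, model)
}

#' Number needed to genotype
#'
#' Individuals who must be genotyped (and a polygenic score calculated) to
#' prevent one additional event relative to a non-genetic strategy:
#' `cohort / (prevented_with - prevented_without)`. Passing the per-arm
#' prevented counts already rounded to whole events reproduces printed
#' arithmetic (e.g. 100000 / (974 - 957) = 5882); passing unrounded values
#' gives the continuous alternative.
#'
#' @param cohort cohort size.
#' @param prevented_with events prevented with genotyping.
#' @param prevented_without events prevented without genotyping.
#' @return Positive real; round for display. If `prevented_with` does not
#'   exceed `prevented_without`, a classed error
#'   (`polyscreen_no_incremental_benefit`) is signalled rather than a number
#'   returned.
#' @export
number_needed_to_genotype <- function(cohort, prevented_with,
                                      prevented_without) {
  check_count(cohort, "cohort", lower = 1)
  check_number(prevented_with, "prevented_with", lower = 0)
  check_number(prevented_without, "prevented_without", lower = 0)
  if (prevented_with <= prevented_without) {
    cond <- structure(
      class = c("polyscreen_no_incremental_benefit", "error", "condition"),
      list(message = paste0(
        "no incremental benefit: genotyping prevents ",
        prevented_with, " events versus ", prevented_without, " without"),
        call = NULL)
    )
    stop(cond)
  }
  cohort / (prevented_with - prevented_without)
}

#' Two-stage screening flow
#'
#' Models a polygenic score used as a stage 1 triage for an established stage
#' 2 test: everyone above the unaffected `1 - top_fraction` quantile of the
#' score distribution is referred to stage 2, which detects a fraction
#' `stage2_dr` of the affected referrals at a false positive rate
#' `stage2_fpr`. All counts are whole people; each stage rounds its expected
#' count to the nearest integer (half away from zero) and downstream counts
#' are obtained by differencing so the cohort is conserved exactly.
#'
#' @param n_cohort cohort size.
#' @param background background `polyscreen_odds` (or odds string) of
#'   becoming affected in the screening time frame.
#' @param stage1_model a `polyscreen_risk_model` or numeric delta for the
#'   polygenic score.
#' @param stage1_top_fraction fraction of the unaffected distribution
#'   referred to stage 2 (the cut-off is its `1 - top_fraction` quantile).
#' @param stage2_dr detection rate of the stage 2 test among referrals.
#' @param stage2_fpr false positive rate of the stage 2 test.
#' @return An object of class `polyscreen_flow`: a list of whole-person
#'   counts (`n_cohort`, `n_affected`, `n_unaffected`,
#'   `stage1_affected_positives`, `stage1_unaffected_positives`,
#'   `stage2_detected`, `stage2_missed`, `stage2_false_positives`,
#'   `missed_below_cutoff`) plus `odds_given_stage1_positive`.
#' @examples
#' two_stage_screen(100000, "1:64", 0.486, 0.025, 0.75, 0.08)
#' @export
two_stage_screen <- function(n_cohort, background, stage1_model,
                             stage1_top_fraction, stage2_dr, stage2_fpr) {
  check_count(n_cohort, "n_cohort", lower = 1)
  background <- parse_odds(background)
  delta <- as_delta(stage1_model)
  check_number(stage1_top_fraction, "stage1_top_fraction", lower = 0,
               upper = 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(stage2_dr, "stage2_dr", lower = 0, upper = 1)
  check_number(stage2_fpr, "stage2_fpr", lower = 0, upper = 1)

  n_affected <- round_half_up(n_cohort * risk_from_odds(background))
  n_unaffected <- n_cohort - n_affected
  dr1 <- detection_rate(delta, screening_cut(fpr = stage1_top_fraction))
  aff_pos <- round_half_up(n_affected * dr1)
  unaff_pos <- round_half_up(n_unaffected * stage1_top_fraction)
  detected <- round_half_up(stage2_dr * aff_pos)

  structure(list(
    n_cohort = n_cohort,
    n_affected = n_affected,
    n_unaffected = n_unaffected,
    stage1_affected_positives = aff_pos,
    stage1_unaffected_positives = unaff_pos,
    stage2_detected = detected,
    stage2_missed = aff_pos - detected,
    stage2_false_positives = round_half_up(stage2_fpr * unaff_pos),
    missed_below_cutoff = n_affected - aff_pos,
    odds_given_stage1_positive = odds(aff_pos, unaff_pos)
  ), class = "polyscreen_flow")
}

#' @export
print.polyscreen_flow <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<two-stage screen> cohort %d (%d affected, %d unaffected)\n",
      "  stage 1 positive: %d affected + %d unaffected (odds %s)\n",
      "  stage 2: %d detected, %d missed, %d false positives\n",
      "  below stage 1 cut-off and missed: %d affected\n"),
    x$n_cohort, x$n_affected, x$n_unaffected,
    x$stage1_affected_positives, x$stage1_unaffected_positives,
    format_one_in_n(x$odds_given_stage1_positive),
    x$stage2_detected, x$stage2_missed, x$stage2_false_positives,
    x$missed_below_cutoff))
  invisible(x)
}
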