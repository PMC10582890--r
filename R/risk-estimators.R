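# Likelihood-ratio constructions and the calculators built on them.
#
# Three likelihood ratios arise from the binormal model, one per use case:
#   screening        LR+ = DR / FPR                       (threshold form)
#   individual risk  LR(z) = density ratio at a centile   (point form)
#   stratification   LR(group) = area ratio over a slice  (group form)
# Each multiplies the background odds to give posterior odds of becoming
# affected. Centiles and quantiles always refer to the UNAFFECTED
# distribution.

#' A centile of the unaffected score distribution
#'
#' @param centile position on the unaffected distribution. Interpreted
#'   according to `unit`: `"percent"` (97.5) or `"fraction"` (0.975). No
#'   magnitude guessing is performed.
#' @param unit `"percent"` (default) or `"fraction"`.
#' @return An object of class `polyscreen_centile` carrying the centile (as
#'   percent) and the implied standard-normal quantile `z`.
#' @examples
#' centile_query(97.5)
#' centile_query(0.975, unit = "fraction")
#' @export
centile_query <- function(centile, unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  if (unit == "fraction") {
    check_number(centile, "centile", lower = 0, upper = 1,
                 closed_lower = FALSE, closed_upper = FALSE)
    centile <- 100 * centile
  } else {
    check_number(centile, "centile", lower = 0, upper = 100,
                 closed_lower = FALSE, closed_upper = FALSE)
  }
  structure(list(centile = centile, z = stats::qnorm(centile / 100)),
            class = "polyscreen_centile")
}

#' A quantile group of the unaffected score distribution
#'
#' @param q_lo,q_hi cumulative bounds in `[0, 1]`, `q_lo < q_hi`.
#' @return An object of class `polyscreen_group`.
#' @examples
#' quantile_group(0.8, 1) # the top quintile
#' @export
quantile_group <- function(q_lo, q_hi) {
  check_number(q_lo, "q_lo", lower = 0, upper = 1)
  check_number(q_hi, "q_hi", lower = 0, upper = 1)
  if (q_lo >= q_hi) abort_validation("`q_lo` must be below `q_hi`")
  structure(list(q_lo = q_lo, q_hi = q_hi, width = q_hi - q_lo),
            class = "polyscreen_group")
}

#' Likelihood ratio of a positive screen
#'
#' The ratio of detection rate to false positive rate at the cut-off.
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param cut a `polyscreen_cut`.
#' @return Positive likelihood ratio; 1 when `delta = 0`.
#' @examples
#' lr_positive(risk_model(0.48)) # ~2.4
#' @export
lr_positive <- function(model, cut = screening_cut(fpr = 0.05)) {
  detection_rate(model, cut) / cut$fpr
}

#' Likelihood ratio at a score centile
#'
#' Ratio of the affected to unaffected Gaussian densities at the score value
#' sitting at a given centile of the unaffected distribution. With equal unit
#' variances this has the closed form `exp(delta * z - delta^2 / 2)`, which
#' is log-linear in `z`.
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param q a `polyscreen_centile` (or a percent centile, coerced).
#' @return Positive likelihood ratio.
#' @examples
#' lr_at_centile(risk_model(0.48), centile_query(97.5))
#' @export
lr_at_centile <- function(model, q) {
  delta <- as_delta(model)
  if (!inherits(q, "polyscreen_centile")) q <- centile_query(q)
  exp(delta * q$z - delta^2 / 2)
}

#' Odds of becoming affected for an individual at a centile
#'
#' Background odds updated by the centile density-ratio likelihood ratio.
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param q a `polyscreen_centile` (or a percent centile).
#' @param background background `polyscreen_odds` (or an odds string).
#' @return Posterior `polyscreen_odds`.
#' @examples
#' individual_odds(risk_model(0.48), centile_query(25), parse_odds("1:19"))
#' @export
individual_odds <- function(model, q, background) {
  apply_lr(parse_odds(background), lr_at_centile(model, q))
}

#' Likelihood ratio for a quantile group
#'
#' Ratio of the areas under the affected and unaffected densities over the
#' score interval whose unaffected cumulative probabilities are
#' `[q_lo, q_hi]`. As the group narrows this converges to [lr_at_centile()].
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param g a `polyscreen_group`.
#' @return Positive likelihood ratio; 1 when `delta = 0`.
#' @examples
#' lr_quantile_group(risk_model(0.48), quantile_group(0, 0.2))
#' @export
lr_quantile_group <- function(model, g) {
  delta <- as_delta(model)
  stopifnot(inherits(g, "polyscreen_group"))
  z_lo <- stats::qnorm(g$q_lo)  # -Inf at 0
  z_hi <- stats::qnorm(g$q_hi)  # +Inf at 1
  (stats::pnorm(z_hi - delta) - stats::pnorm(z_lo - delta)) / g$width
}

#' Risk stratification table over quantile groups
#'
#' Partitions the unaffected score distribution into `n_groups` equal-width
#' quantile groups and reports, per group, the area-ratio likelihood ratio,
#' the posterior odds of becoming affected, and whole-person counts of
#' affected and unaffected individuals in a hypothetical cohort.
#'
#' Counts are allocated by rounding the real-valued expectations (affected in
#' proportion to `width * lr`, unaffected in proportion to `width`) and then
#' repairing by largest remainder so every column sums exactly to its total.
#' `share_of_cases` is the continuous (area-based) share; a count-based share
#' is included alongside as `share_of_cases_counts`.
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param n_groups number of equal-width quantile groups (>= 2).
#' @param background background `polyscreen_odds` (or odds string).
#' @param population cohort size (> 0).
#' @return A data.frame with columns `group_lo`, `group_hi`, `lr`,
#'   `odds_1_in_n`, `n_affected`, `n_unaffected`, `share_of_cases`,
#'   `share_of_cases_counts`.
#' @examples
#' stratification_table(risk_model(0.48), 5, parse_odds("1:19"), 100000)
#' @export
stratification_table <- function(model, n_groups, background, population) {
  delta <- as_delta(model)
  check_count(n_groups, "n_groups", lower = 2)
  check_count(population, "population", lower = 1)
  background <- parse_odds(background)

  breaks <- seq(0, 1, length.out = n_groups + 1)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  width <- hi - lo
  lr <- vapply(seq_len(n_groups), function(i) {
    lr_quantile_group(delta, quantile_group(lo[i], hi[i]))
  }, numeric(1))

  n_affected_total <- round_half_up(population * risk_from_odds(background))
  n_unaffected_total <- population - n_affected_total
  share <- width * lr  # affected density mass per group; sums to 1
  n_aff <- allocate_integer_counts(n_affected_total * share, n_affected_total)
  n_unaff <- allocate_integer_counts(n_unaffected_total * width,
                                     n_unaffected_total)
  odds_n <- vapply(lr, function(l) {
    odds_denominator(apply_lr(background, l))
  }, integer(1))

  data.frame(
    group_lo = lo,
    group_hi = hi,
    lr = lr,
    odds_1_in_n = odds_n,
    n_affected = n_aff,
    n_unaffected = n_unaff,
    share_of_cases = share,
    share_of_cases_counts = if (n_affected_total > 0) {
      n_aff / n_affected_total
    } else {
      rep(NA_real_, n_groups)
    }
  )
}

#' Risk in the upper tail of the score distribution
#'
#' Examines the individuals above the unaffected `1 - top_fraction` quantile:
#' their likelihood ratio, their posterior odds of becoming affected, and the
#' share of all cases they contribute (`1 - pnorm(z_cut - delta)`).
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param top_fraction fraction of the unaffected distribution in the tail,
#'   in (0, 0.5].
#' @param background background `polyscreen_odds` (or odds string).
#' @return A list with `lr`, `odds` (a `polyscreen_odds`), and
#'   `share_of_cases`.
#' @examples
#' tail_analysis(risk_model(0.48), 0.025, parse_odds("1:19"))
#' @export
tail_analysis <- function(model, top_fraction, background) {
  delta <- as_delta(model)
  check_number(top_fraction, "top_fraction", lower = 0, upper = 0.5,
               closed_lower = FALSE)
  background <- parse_odds(background)
  share <- stats::pnorm(stats::qnorm(1 - top_fraction) - delta,
                        lower.tail = FALSE)
  lr <- share / top_fraction
  list(lr = lr, odds = apply_lr(background, lr), share_of_cases = share)
}

#' Odds ratio comparing symmetric top and bottom tails
#'
#' The ratio of the tail-area likelihood ratios for the top versus the bottom
#' `fraction` of the unaffected distribution — the "top x% versus bottom x%"
#' odds ratio often quoted in aetiological comparisons. It is invariant to
#' the background odds and is large even when the detection rate is modest,
#' which is why it overstates screening performance.
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param fraction tail size in (0, 0.5).
#' @return Odds ratio (>= 1 for `delta >= 0`), decreasing in `fraction`.
#' @examples
#' top_vs_bottom_odds_ratio(risk_model(0.48), 0.01) # ~13
#' @export
top_vs_bottom_odds_ratio <- function(model, fraction) {
  delta <- as_delta(model)
  check_number(fraction, "fraction", lower = 0, upper = 0.5,
               closed_lower = FALSE, closed_upper = FALSE)
  z <- stats::qnorm(1 - fraction)
  lr_top <- stats::pnorm(z - delta, lower.tail = FALSE) / fraction
  lr_bottom <- stats::pnorm(-z - delta) / fraction
  lr_top / lr_bottom
}

#' Write a stratification table to TSV or JSON
#'
#' @param table a data.frame from [stratification_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_stratification <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
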