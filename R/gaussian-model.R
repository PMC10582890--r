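#' The binormal equal-variance screening model
#'
#' The polygenic risk score is modelled as Gaussian with unit standard
#' deviation in both the affected and unaffected groups, the affected mean
#' shifted by `delta` standard deviation units. Every screening quantity in
#' this package (detection rates, likelihood ratios, odds) is a function of
#' this single parameter.
#'
#' @param delta difference in mean score between affected and unaffected
#'   groups, in unaffected-SD units. Negative values (a protective
#'   orientation) are accepted with a warning so that mis-oriented records
#'   remain analysable.
#' @return An object of class `polyscreen_risk_model`.
#' @examples
#' risk_model(0.48) # coronary artery disease, median catalog performance
#' @export
risk_model <- function(delta) {
  check_number(delta, "delta")
  if (delta < 0) {
    warning("delta < 0: score is oriented protectively; ",
            "results will describe reduced risk at high scores",
            call. = FALSE)
  }
  structure(list(delta = delta), class = "polyscreen_risk_model")
}

#' @export
print.polyscreen_risk_model <- function(x, ...) {
  cat(sprintf("<binormal risk model> delta = %.4g SD; DR_5 = %.1f%%\n",
              x$delta,
              100 * detection_rate(x, screening_cut(fpr = 0.05))))
  invisible(x)
}

metric_kinds <- c("or_per_sd", "hr_per_sd", "auc", "c_index")

#' A reported performance metric
#'
#' One published performance estimate for a polygenic risk score: an odds or
#' hazard ratio per one-SD increment of the score, an area under the ROC
#' curve, or a C-index.
#'
#' @param kind one of `"or_per_sd"`, `"hr_per_sd"`, `"auc"`, `"c_index"`.
#' @param value the reported value; ratios must be positive, AUC and C-index
#'   must lie strictly in (0, 1).
#' @return An object of class `polyscreen_metric`.
#' @export
reported_metric <- function(kind, value) {
  kind <- match.arg(kind, metric_kinds)
  if (kind %in% c("or_per_sd", "hr_per_sd")) {
    check_number(value, kind, lower = 0, closed_lower = FALSE)
  } else {
    check_number(value, kind, lower = 0, upper = 1,
                 closed_lower = FALSE, closed_upper = FALSE)
  }
  structure(list(kind = kind, value = value), class = "polyscreen_metric")
}

#' Convert a reported metric to the model's mean difference
#'
#' Conversions: `delta = log(OR_SD)`; hazard ratios are treated identically
#' (`delta = log(HR_SD)`); `delta = sqrt(2) * qnorm(AUC)`; a C-index is
#' treated as an AUC. The ratio conversions are exact in the rare-disease
#' limit of the binormal model; the AUC conversion is exact under it.
#'
#' @param metric a `polyscreen_metric`, or a kind string (with `value`).
#' @param value metric value when `metric` is given as a kind string.
#' @return A `polyscreen_risk_model`.
#' @examples
#' delta_from_metric("auc", 0.8)        # delta ~ 1.19
#' delta_from_metric("or_per_sd", 1.31) # the catalog's median odds ratio
#' @export
delta_from_metric <- function(metric, value = NULL) {
  if (!inherits(metric, "polyscreen_metric")) {
    metric <- reported_metric(metric, value)
  }
  delta <- switch(metric$kind,
    or_per_sd = log(metric$value),
    hr_per_sd = log(metric$value),
    auc = sqrt(2) * stats::qnorm(metric$value),
    c_index = sqrt(2) * stats::qnorm(metric$value)
  )
  risk_model(delta)
}

#' Convert a mean difference back to a reported metric scale
#'
#' Exact inverse of [delta_from_metric()].
#'
#' @param model a `polyscreen_risk_model` (or a numeric delta).
#' @param kind target metric kind.
#' @return The metric value on the requested scale.
#' @export
metric_from_delta <- function(model, kind) {
  delta <- as_delta(model)
  kind <- match.arg(kind, metric_kinds)
  switch(kind,
    or_per_sd = exp(delta),
    hr_per_sd = exp(delta),
    auc = stats::pnorm(delta / sqrt(2)),
    c_index = stats::pnorm(delta / sqrt(2))
  )
}

as_delta <- function(model) {
  if (inherits(model, "polyscreen_risk_model")) return(model$delta)
  check_number(model, "delta")
  model
}

#' A screening cut-off
#'
#' The score cut-off is parameterised by the false positive rate it induces:
#' a cut-off at the unaffected distribution's upper-tail quantile `z_cut`
#' flags a fraction `fpr` of unaffected individuals. Supply either one.
#'
#' @param fpr false positive rate in (0, 1).
#' @param z_cut cut-off in unaffected-SD units (upper-tail quantile at `fpr`).
#' @return An object of class `polyscreen_cut` with both fields populated.
#' @examples
#' screening_cut(fpr = 0.05) # the conventional DR_5 cut-off, z ~ 1.645
#' @export
screening_cut <- function(fpr = NULL, z_cut = NULL) {
  if (is.null(fpr) && is.null(z_cut)) {
    abort_validation("supply `fpr` or `z_cut`")
  }
  if (is.null(fpr)) {
    check_number(z_cut, "z_cut")
    fpr <- stats::pnorm(z_cut, lower.tail = FALSE)
  } else {
    check_number(fpr, "fpr", lower = 0, upper = 1,
                 closed_lower = FALSE, closed_upper = FALSE)
    z_implied <- stats::qnorm(fpr, lower.tail = FALSE)
    if (!is.null(z_cut) && abs(z_cut - z_implied) > 1e-9) {
      abort_validation("`fpr` and `z_cut` are inconsistent")
    }
    z_cut <- z_implied
  }
  structure(list(fpr = fpr, z_cut = z_cut), class = "polyscreen_cut")
}

#' Detection rate at a screening cut-off
#'
#' The fraction of affected individuals whose score exceeds the cut-off:
#' `DR = 1 - pnorm(z_cut - delta)`. At `delta = 0` the detection rate equals
#' the false positive rate (a null score detects at chance).
#'
#' @param model a `polyscreen_risk_model` or numeric delta.
#' @param cut a `polyscreen_cut`; defaults to the 5% false positive rate
#'   cut-off, giving the conventional DR_5.
#' @return Detection rate in (0, 1).
#' @examples
#' detection_rate(risk_model(0.48))  # ~0.12: DR_5 of 12%
#' @export
detection_rate <- function(model, cut = screening_cut(fpr = 0.05)) {
  delta <- as_delta(model)
  stopifnot(inherits(cut, "polyscreen_cut"))
  stats::pnorm(cut$z_cut - delta, lower.tail = FALSE)
}

#' Metric value required for a target detection rate
#'
#' Solves `detection_rate(delta, cut) = target_dr` for `delta`
#' (`delta = z_cut + qnorm(target_dr)`) and converts to the requested metric
#' scale. A target below the false positive rate implies a below-null metric;
#' this is returned with a warning rather than an error.
#'
#' @param target_dr desired detection rate in (0, 1).
#' @param cut a `polyscreen_cut`.
#' @param kind metric kind for the answer.
#' @return Required metric value.
#' @examples
#' required_metric_for_dr(0.80, kind = "or_per_sd") # ~12
#' required_metric_for_dr(0.80, kind = "auc")       # ~0.96
#' @export
required_metric_for_dr <- function(target_dr, cut = screening_cut(fpr = 0.05),
                                   kind = "or_per_sd") {
  check_number(target_dr, "target_dr", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  stopifnot(inherits(cut, "polyscreen_cut"))
  delta <- cut$z_cut + stats::qnorm(target_dr)
  if (target_dr <= cut$fpr) {
    warning("target detection rate at or below the false positive rate: ",
            "required metric is at or below the null value", call. = FALSE)
  }
  metric_from_delta(suppressWarnings(risk_model(delta)), kind)
}
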