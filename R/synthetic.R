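# Synthetic inputs with known ground truth: individual-level score cohorts
# drawn from the binormal model, and mock catalog tables with planted
# violations for exercising the ingestion pipeline end to end.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Specification of a simulated score cohort
#'
#' @param n cohort size (>= 2).
#' @param delta mean score difference between affected and unaffected groups,
#'   in SD units.
#' @param risk probability of becoming affected, in (0, 1).
#' @param seed integer seed; the same spec always yields the same cohort.
#' @return An object of class `polyscreen_cohort_spec`.
#' @export
cohort_spec <- function(n, delta, risk, seed) {
  check_count(n, "n", lower = 2)
  check_number(delta, "delta")
  check_number(risk, "risk", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_count(seed, "seed")
  structure(list(n = n, delta = delta, risk = risk, seed = seed),
            class = "polyscreen_cohort_spec")
}

#' Simulate an individual-level polygenic score cohort
#'
#' Draws the stated generative model directly: affected status is Bernoulli
#' with probability `risk`; scores are standard normal for the unaffected and
#' normal with mean `delta`, SD 1, for the affected. No genotypes, linkage
#' structure, or effect estimation are simulated — the model is phenotypic.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with columns `score` (numeric) and `affected`
#'   (logical), `spec$n` rows.
#' @examples
#' cohort <- simulate_prs_cohort(cohort_spec(1000, 0.48, 0.05, seed = 1))
#' mean(cohort$affected)
#' @export
simulate_prs_cohort <- function(spec) {
  stopifnot(inherits(spec, "polyscreen_cohort_spec"))
  with_seed(spec$seed, {
    affected <- stats::runif(spec$n) < spec$risk
    score <- stats::rnorm(spec$n, mean = ifelse(affected, spec$delta, 0),
                          sd = 1)
    data.frame(score = score, affected = affected)
  })
}

#' Empirical performance metrics from a simulated cohort
#'
#' Estimates, from individual-level data, the same metrics a publication
#' would report: the AUC by the rank (concordance) statistic, the odds ratio
#' per SD by a logistic regression of affected status on the score, and the
#' detection rate at a 5% false positive rate as the affected fraction above
#' the empirical unaffected 95th centile. Used to validate the closed-form
#' conversions by round-trip.
#'
#' @param cohort a data.frame from [simulate_prs_cohort()].
#' @param fpr false positive rate for the empirical detection rate.
#' @return A list with `auc_hat`, `or_per_sd_hat`, `dr_hat`.
#' @export
estimate_metrics_empirical <- function(cohort, fpr = 0.05) {
  stopifnot(is.data.frame(cohort),
            all(c("score", "affected") %in% names(cohort)))
  n_aff <- sum(cohort$affected)
  n_unaff <- sum(!cohort$affected)
  if (n_aff < 50 || n_unaff < 50) {
    abort_validation("need at least 50 affected and 50 unaffected individuals")
  }
  r <- rank(cohort$score)
  auc_hat <- (sum(r[cohort$affected]) - n_aff * (n_aff + 1) / 2) /
    (n_aff * n_unaff)
  fit <- stats::glm(affected ~ score, family = stats::binomial(),
                    data = cohort)
  or_hat <- exp(stats::coef(fit)[["score"]])
  cut_hat <- stats::quantile(cohort$score[!cohort$affected], 1 - fpr,
                             type = 7, names = FALSE)
  dr_hat <- mean(cohort$score[cohort$affected] > cut_hat)
  list(auc_hat = auc_hat, or_per_sd_hat = or_hat, dr_hat = dr_hat)
}

#' Specification of a mock performance-metrics catalog
#'
#' Describes a synthetic stand-in for a catalog download: a mix of metric
#' kinds whose values derive from a known distribution of true mean
#' differences, plus deliberately planted implausible records and
#' continuous-trait records, in known numbers, so the filtering pipeline can
#' be checked against ground truth.
#'
#' The defaults emulate a realistic catalog slice: metric kinds in roughly
#' the proportions seen in public catalog data (odds ratio 31%, hazard ratio
#' 10%, AUC 53%, C-index 6%) and true `delta` values log-normal with median
#' 0.42 (a DR_5 near 11%) and log-SD 0.5.
#'
#' @param n_records number of plausible binary-trait records.
#' @param kind_mix named probabilities over the four metric kinds.
#' @param delta_meanlog,delta_sdlog log-normal parameters of the true delta
#'   distribution.
#' @param violations named counts of planted implausible records:
#'   `or_hr_lt_1`, `auc_lt_half`, `cindex_gt_1`.
#' @param n_continuous number of planted continuous-trait records.
#' @param seed integer seed.
#' @return An object of class `polyscreen_catalog_spec`.
#' @export
mock_catalog_spec <- function(n_records = 200,
                              kind_mix = c(or_per_sd = 0.31, hr_per_sd = 0.10,
                                           auc = 0.53, c_index = 0.06),
                              delta_meanlog = log(0.42), delta_sdlog = 0.5,
                              violations = c(or_hr_lt_1 = 0, auc_lt_half = 0,
                                             cindex_gt_1 = 0),
                              n_continuous = 0, seed = 1) {
  check_count(n_records, "n_records", lower = 1)
  stopifnot(setequal(names(kind_mix), metric_kinds), all(kind_mix >= 0),
            sum(kind_mix) > 0)
  v <- c(or_hr_lt_1 = 0, auc_lt_half = 0, cindex_gt_1 = 0)
  v[names(violations)] <- violations
  check_count(n_continuous, "n_continuous")
  check_count(seed, "seed")
  structure(list(n_records = n_records, kind_mix = kind_mix[metric_kinds],
                 delta_meanlog = delta_meanlog, delta_sdlog = delta_sdlog,
                 violations = v, n_continuous = n_continuous, seed = seed),
            class = "polyscreen_catalog_spec")
}

#' Generate a mock catalog table and its ground-truth manifest
#'
#' Writes a TSV in the default [catalog_dialect()] (schema-valid input for
#' [parse_performance_table()]) and a JSON manifest recording the planted
#' violation counts and each plausible record's true delta.
#'
#' @param spec a [mock_catalog_spec()].
#' @param dir directory for the output files.
#' @return A list with `table_path`, `manifest_path`, and the `manifest`
#'   itself (fields `n_rows`, `planted`, `records`).
#' @export
make_mock_catalog <- function(spec, dir = tempdir()) {
  stopifnot(inherits(spec, "polyscreen_catalog_spec"))
  with_seed(spec$seed, {
    kinds <- sample(metric_kinds, spec$n_records, replace = TRUE,
                    prob = spec$kind_mix)
    true_delta <- stats::rlnorm(spec$n_records, spec$delta_meanlog,
                                spec$delta_sdlog)
    value <- vapply(seq_len(spec$n_records), function(i) {
      metric_from_delta(suppressWarnings(risk_model(true_delta[i])), kinds[i])
    }, numeric(1))
    good <- data.frame(kind = kinds, value = value, trait_type = "binary",
                       true_delta = true_delta, planted = "none",
                       stringsAsFactors = FALSE)

    v <- spec$violations
    bad <- list()
    if (v[["or_hr_lt_1"]] > 0) {
      bad$ratio <- data.frame(
        kind = sample(c("or_per_sd", "hr_per_sd"), v[["or_hr_lt_1"]],
                      replace = TRUE),
        value = stats::runif(v[["or_hr_lt_1"]], 0.5, 0.99),
        trait_type = "binary", true_delta = NA_real_,
        planted = "or_hr_lt_1", stringsAsFactors = FALSE)
    }
    if (v[["auc_lt_half"]] > 0) {
      bad$auc <- data.frame(
        kind = "auc",
        value = stats::runif(v[["auc_lt_half"]], 0.3, 0.49),
        trait_type = "binary", true_delta = NA_real_,
        planted = "auc_lt_half", stringsAsFactors = FALSE)
    }
    if (v[["cindex_gt_1"]] > 0) {
      bad$cindex <- data.frame(
        kind = "c_index",
        value = stats::runif(v[["cindex_gt_1"]], 1.5, 700),
        trait_type = "binary", true_delta = NA_real_,
        planted = "cindex_gt_1", stringsAsFactors = FALSE)
    }
    if (spec$n_continuous > 0) {
      bad$continuous <- data.frame(
        kind = "auc",
        value = stats::runif(spec$n_continuous, 0.5, 0.9),
        trait_type = "continuous", true_delta = NA_real_,
        planted = "continuous", stringsAsFactors = FALSE)
    }
    all_rows <- do.call(rbind, c(list(good), unname(bad)))
    all_rows <- all_rows[sample(nrow(all_rows)), , drop = FALSE]

    n <- nrow(all_rows)
    table <- data.frame(
      score_id = sprintf("MPS%06d", seq_len(n)),
      trait_id = sprintf("EFO_%07d", sample(1:40, n, replace = TRUE)),
      trait_type = all_rows$trait_type,
      metric_kind = all_rows$kind,
      metric_value = format(all_rows$value, digits = 10),
      publication_id = sprintf("MPP%06d", sample(1:30, n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    table_path <- file.path(dir, "mock_catalog.tsv")
    utils::write.table(table, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    manifest <- list(
      n_rows = n,
      planted = list(
        continuous = spec$n_continuous,
        or_hr_lt_1 = unname(v[["or_hr_lt_1"]]),
        auc_lt_half = unname(v[["auc_lt_half"]]),
        cindex_gt_1 = unname(v[["cindex_gt_1"]])
      ),
      records = data.frame(score_id = table$score_id,
                           kind = all_rows$kind,
                           true_delta = all_rows$true_delta,
                           planted = all_rows$planted,
                           stringsAsFactors = FALSE)
    )
    manifest_path <- file.path(dir, "mock_catalog_manifest.json")
    jsonlite::write_json(manifest, manifest_path, digits = NA,
                         dataframe = "rows", auto_unbox = TRUE)
    list(table_path = table_path, manifest_path = manifest_path,
         manifest = manifest)
  })
}
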