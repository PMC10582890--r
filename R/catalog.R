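# Ingestion and summary of catalog-style performance-metric tables.
#
# The pipeline is parse -> filter -> summarise. Parsing is deliberately
# permissive: implausible metric values (an odds ratio below 1, a C-index of
# 632) must survive parsing so that the filter stage can count them; only
# structurally malformed rows are rejected at parse time, and those are
# collected in a rejects table rather than silently dropped.

#' Column and spelling dialect for performance tables
#'
#' Describes how to read a catalog-style table: which columns hold each
#' field, and how reported metric-name spellings map onto the four canonical
#' kinds. The defaults accept the long-format headers used by this package's
#' writers as well as the common catalog spellings of the metric names.
#'
#' @param columns named character vector mapping the canonical fields
#'   (`score_id`, `trait_id`, `trait_type`, `metric_kind`, `metric_value`,
#'   `publication_id`) to column names in the file.
#' @param metric_spellings named character vector mapping lower-cased metric
#'   spellings found in files to canonical kinds.
#' @param sep field separator, default tab.
#' @return A list of class `polyscreen_dialect`.
#' @export
catalog_dialect <- function(columns = NULL, metric_spellings = NULL,
                            sep = "\t") {
  default_cols <- c(
    score_id = "score_id",
    trait_id = "trait_id",
    trait_type = "trait_type",
    metric_kind = "metric_kind",
    metric_value = "metric_value",
    publication_id = "publication_id"
  )
  default_spellings <- c(
    "or" = "or_per_sd",
    "or_per_sd" = "or_per_sd",
    "odds ratio (or, per sd)" = "or_per_sd",
    "odds ratio" = "or_per_sd",
    "hr" = "hr_per_sd",
    "hr_per_sd" = "hr_per_sd",
    "hazard ratio (hr, per sd)" = "hr_per_sd",
    "hazard ratio" = "hr_per_sd",
    "auc" = "auc",
    "auroc" = "auc",
    "area under the receiver-operating characteristic curve (auroc)" = "auc",
    "c_index" = "c_index",
    "c-index" = "c_index",
    "c index" = "c_index",
    "concordance statistic (c-index)" = "c_index"
  )
  if (!is.null(columns)) default_cols[names(columns)] <- columns
  if (!is.null(metric_spellings)) {
    names(metric_spellings) <- tolower(names(metric_spellings))
    default_spellings[names(metric_spellings)] <- metric_spellings
  }
  structure(list(columns = default_cols,
                 metric_spellings = default_spellings,
                 sep = sep),
            class = "polyscreen_dialect")
}

#' Parse a catalog-style performance-metrics table
#'
#' Reads a delimited file of published performance estimates, one row per
#' estimate, and validates each row structurally. Rows with a missing score
#' identifier, an unrecognised metric spelling, a non-numeric or empty metric
#' value, or an unknown trait type are returned in a rejects table with a
#' reason; they are never silently dropped. Plausibility of metric values is
#' *not* checked here — that is [filter_records()]'s job.
#'
#' @param path path to a TSV/CSV file.
#' @param dialect a [catalog_dialect()].
#' @return A list with `records` (data.frame: `score_id`, `trait_id`,
#'   `trait_type`, `kind`, `value`, `publication_id`) and `rejects`
#'   (data.frame with a `reason` column).
#' @export
parse_performance_table <- function(path, dialect = catalog_dialect()) {
  stopifnot(inherits(dialect, "polyscreen_dialect"))
  if (!file.exists(path)) {
    stop("cannot read performance table: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, sep = dialect$sep, header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    abort_validation(paste0("performance table is missing mandatory columns: ",
                            paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(raw)
  empty <- data.frame(
    score_id = character(), trait_id = character(), trait_type = character(),
    kind = character(), value = numeric(), publication_id = character(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(list(records = empty,
                rejects = cbind(empty, reason = character())))
  }

  score_id <- trimws(raw[[cols[["score_id"]]]])
  trait_id <- trimws(raw[[cols[["trait_id"]]]])
  trait_type <- tolower(trimws(raw[[cols[["trait_type"]]]]))
  kind_raw <- trimws(raw[[cols[["metric_kind"]]]])
  kind <- unname(dialect$metric_spellings[tolower(kind_raw)])
  value <- suppressWarnings(as.numeric(raw[[cols[["metric_value"]]]]))
  publication_id <- trimws(raw[[cols[["publication_id"]]]])

  reason <- rep(NA_character_, n)
  reason[is.na(kind)] <- sprintf("unknown metric kind '%s'",
                                 kind_raw[is.na(kind)])
  reason[is.na(reason) & (is.na(value))] <- "missing or non-numeric value"
  reason[is.na(reason) & score_id == ""] <- "empty score_id"
  reason[is.na(reason) & !trait_type %in% c("binary", "continuous")] <-
    "trait_type must be 'binary' or 'continuous'"

  out <- data.frame(score_id = score_id, trait_id = trait_id,
                    trait_type = trait_type, kind = kind, value = value,
                    publication_id = publication_id,
                    stringsAsFactors = FALSE)
  ok <- is.na(reason)
  rejects <- out[!ok, , drop = FALSE]
  rejects$reason <- reason[!ok]
  rownames(rejects) <- NULL
  records <- out[ok, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, rejects = rejects)
}

#' Apply plausibility filters to parsed records
#'
#' Reproduces the exclusion rules used when screening a catalog download:
#' records for continuous traits are removed, as are implausible values —
#' odds or hazard ratios per SD below 1 (a protective orientation or
#' reporting error), AUC below 0.5, and a C-index outside (0.5, 1]. The
#' counts removed under each rule are reconciled in a filter report.
#'
#' @param records a records data.frame from [parse_performance_table()].
#' @return A list with `retained` (records data.frame) and `report`, a list
#'   with fields `n_input`, `n_removed_continuous`, `n_removed_or_hr_lt_1`,
#'   `n_removed_auc_lt_half`, `n_removed_cindex_implausible`, `n_retained`.
#' @export
filter_records <- function(records) {
  stopifnot(is.data.frame(records))
  n_input <- nrow(records)
  continuous <- records$trait_type == "continuous"
  rest <- records[!continuous, , drop = FALSE]

  bad_ratio <- rest$kind %in% c("or_per_sd", "hr_per_sd") & rest$value < 1
  bad_auc <- rest$kind == "auc" & rest$value < 0.5
  bad_cindex <- rest$kind == "c_index" & (rest$value <= 0.5 | rest$value > 1)

  retained <- rest[!(bad_ratio | bad_auc | bad_cindex), , drop = FALSE]
  rownames(retained) <- NULL
  report <- list(
    n_input = n_input,
    n_removed_continuous = sum(continuous),
    n_removed_or_hr_lt_1 = sum(bad_ratio),
    n_removed_auc_lt_half = sum(bad_auc),
    n_removed_cindex_implausible = sum(bad_cindex),
    n_retained = nrow(retained)
  )
  stopifnot(report$n_input == report$n_retained +
              report$n_removed_continuous + report$n_removed_or_hr_lt_1 +
              report$n_removed_auc_lt_half +
              report$n_removed_cindex_implausible)
  list(retained = retained, report = report)
}

record_dr5 <- function(records, fpr = 0.05) {
  cut <- screening_cut(fpr = fpr)
  vapply(seq_len(nrow(records)), function(i) {
    m <- suppressWarnings(
      delta_from_metric(records$kind[i], records$value[i])
    )
    detection_rate(m, cut)
  }, numeric(1))
}

#' Summarise detection rates across a filtered catalog
#'
#' Attaches a DR_5 (detection rate at a 5% false positive rate) to every
#' retained record via the binormal model, then reports the median and
#' interquartile range of record-level DR_5 values — overall, per trait, or
#' per metric kind. Quantiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7) so summaries are stable and
#' reproducible. The aggregation unit is the record (one published estimate);
#' set `collapse_scores = TRUE` to first collapse each score to the median of
#' its estimates.
#'
#' @param retained a retained records data.frame from [filter_records()].
#' @param group_by `"overall"`, `"trait_id"`, or `"kind"`.
#' @param fpr false positive rate defining the detection rate, default 0.05.
#' @param collapse_scores collapse multiple estimates per score first.
#' @return A data.frame with columns `group`, `n_records`, `n_scores`,
#'   `median_dr5`, `iqr_lo`, `iqr_hi` (DR values as fractions).
#' @export
summarize_dr5 <- function(retained, group_by = c("overall", "trait_id", "kind"),
                          fpr = 0.05, collapse_scores = FALSE) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(retained))
  if (nrow(retained) == 0L) {
    warning("no retained records to summarise", call. = FALSE)
    return(data.frame(group = character(), n_records = integer(),
                      n_scores = integer(), median_dr5 = numeric(),
                      iqr_lo = numeric(), iqr_hi = numeric()))
  }
  retained$dr5 <- record_dr5(retained, fpr = fpr)
  key <- switch(group_by,
    overall = rep("overall", nrow(retained)),
    trait_id = retained$trait_id,
    kind = retained$kind
  )
  groups <- split(retained, key)
  out <- lapply(names(groups), function(g) {
    grp <- groups[[g]]
    vals <- if (collapse_scores) {
      as.numeric(tapply(grp$dr5, grp$score_id, stats::median))
    } else {
      grp$dr5
    }
    qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n_records = nrow(grp),
               n_scores = length(unique(grp$score_id)),
               median_dr5 = qs[2], iqr_lo = qs[1], iqr_hi = qs[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
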