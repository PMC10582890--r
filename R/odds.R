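#' Odds of becoming affected
#'
#' An odds `a:b` of being affected versus unaffected. Odds are the natural
#' currency of Bayesian updating in screening: multiplying the background odds
#' of disease by the likelihood ratio of a test result gives the posterior
#' odds of becoming affected. An odds object keeps its numerator and
#' denominator separately so that updating scales the affected side only and
#' display rounding happens at the last possible moment.
#'
#' @param numerator affected side of the odds (>= 0).
#' @param denominator unaffected side of the odds (> 0).
#' @return An object of class `polyscreen_odds`.
#' @examples
#' odds(1, 19)                 # 10-year background odds, 5% risk
#' apply_lr(odds(1, 19), 2.44) # odds given a positive screen
#' @export
odds <- function(numerator, denominator) {
  check_number(numerator, "numerator", lower = 0)
  check_number(denominator, "denominator", lower = 0, closed_lower = FALSE)
  structure(list(numerator = numerator, denominator = denominator),
            class = "polyscreen_odds")
}

#' @export
print.polyscreen_odds <- function(x, ...) {
  cat(sprintf("<odds> %g:%g (risk %.4g, %s)\n",
              x$numerator, x$denominator, risk_from_odds(x),
              format_one_in_n(x)))
  invisible(x)
}

#' Convert a probability of becoming affected to odds
#'
#' @param risk probability in `[0, 1)`.
#' @return A `polyscreen_odds` with numerator `risk` and denominator
#'   `1 - risk`.
#' @examples
#' odds_from_risk(0.05) # 1:19
#' @export
odds_from_risk <- function(risk) {
  check_number(risk, "risk", lower = 0, upper = 1, closed_upper = FALSE)
  odds(risk, 1 - risk)
}

#' Convert odds to a probability
#'
#' @param o a `polyscreen_odds`.
#' @return `numerator / (numerator + denominator)`.
#' @export
risk_from_odds <- function(o) {
  stopifnot(inherits(o, "polyscreen_odds"))
  o$numerator / (o$numerator + o$denominator)
}

#' Update odds with a likelihood ratio
#'
#' Posterior odds of becoming affected: the likelihood ratio multiplies the
#' affected side only, `(a:b, lr) -> (lr*a : b)`.
#'
#' @param o background `polyscreen_odds`.
#' @param lr positive likelihood ratio.
#' @return Updated `polyscreen_odds`.
#' @export
apply_lr <- function(o, lr) {
  stopifnot(inherits(o, "polyscreen_odds"))
  check_number(lr, "lr", lower = 0, closed_lower = FALSE)
  odds(o$numerator * lr, o$denominator)
}

#' Format odds as "1:N"
#'
#' Normalises the odds to a numerator of 1 and rounds the denominator to the
#' nearest integer, half away from zero. This is the display convention for
#' odds of becoming affected (an odds of 1:8 is a risk of about 1 in 9).
#'
#' @param o a `polyscreen_odds`.
#' @return Character scalar `"1:N"`.
#' @export
format_one_in_n <- function(o) {
  sprintf("1:%d", odds_denominator(o))
}

#' Rounded "1:N" denominator of an odds
#'
#' @param o a `polyscreen_odds`.
#' @return Integer `N` such that `o` displays as `1:N`.
#' @export
odds_denominator <- function(o) {
  stopifnot(inherits(o, "polyscreen_odds"))
  if (o$numerator <= 0) {
    abort_validation("cannot display zero odds as 1:N")
  }
  as.integer(round_half_up(o$denominator / o$numerator))
}

#' Parse an odds string or probability
#'
#' Accepts `"a:b"` (e.g. `"1:19"`), a decimal probability (`"0.05"`), or a
#' percentage with an explicit `%` suffix (`"5%"`). Magnitude guessing is
#' deliberately not attempted.
#'
#' @param text character scalar (or a number, taken as a probability).
#' @return A `polyscreen_odds`.
#' @examples
#' parse_odds("1:19")
#' parse_odds("5%")
#' @export
parse_odds <- function(text) {
  if (inherits(text, "polyscreen_odds")) return(text)
  if (is.numeric(text)) return(odds_from_risk(text))
  if (!is.character(text) || length(text) != 1L) {
    abort_validation("odds must be a string like \"1:19\", \"0.05\" or \"5%\"")
  }
  txt <- trimws(text)
  if (grepl(":", txt, fixed = TRUE)) {
    parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (length(nums) != 2L || anyNA(nums)) {
      abort_validation(sprintf("malformed odds string: \"%s\"", text))
    }
    return(odds(nums[1], nums[2]))
  }
  pct <- grepl("%$", txt)
  val <- suppressWarnings(as.numeric(sub("%$", "", txt)))
  if (is.na(val)) {
    abort_validation(sprintf("malformed odds string: \"%s\"", text))
  }
  odds_from_risk(if (pct) val / 100 else val)
}
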