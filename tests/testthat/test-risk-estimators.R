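# Likelihood-ratio constructions and the calculators built from them.

cad <- risk_model(0.48)
breast <- risk_model(0.37)

test_that("threshold likelihood ratio is DR/FPR", {
  expect_equal(round(lr_positive(cad), 1), 2.4)
  expect_equal(round(lr_positive(breast), 1), 2.0)
  expect_equal(lr_positive(risk_model(0)), 1, tolerance = 1e-12)
  expect_equal(lr_positive(cad, screening_cut(fpr = 0.01)),
               detection_rate(cad, screening_cut(fpr = 0.01)) / 0.01)
})

test_that("centile likelihood ratio matches the density-ratio closed form", {
  # oracle: ratio of the two normal densities evaluated directly
  for (d in c(0.2, 0.48, 1)) {
    for (cc in c(2.5, 25, 50, 75, 97.5)) {
      z <- qnorm(cc / 100)
      oracle <- dnorm(z, mean = d) / dnorm(z)
      expect_equal(lr_at_centile(risk_model(d), centile_query(cc)), oracle,
                   tolerance = 1e-12)
    }
    expect_equal(lr_at_centile(risk_model(d), centile_query(50)),
                 exp(-d^2 / 2), tolerance = 1e-12)
  }
  expect_equal(lr_at_centile(risk_model(0), centile_query(90)), 1)
  expect_equal(lr_at_centile(cad, centile_query(97.5)), 2.283,
               tolerance = 1e-3)
  # percent and fraction units agree under the explicit flag
  expect_equal(centile_query(97.5)$z, centile_query(0.975, "fraction")$z)
})

test_that("individual odds reproduce the printed centile odds lists", {
  bg_cad <- parse_odds("1:19")
  # 2.5th-centile cell is the known +/-1 display-rounding cell (printed 54)
  n_2_5 <- odds_denominator(individual_odds(cad, centile_query(2.5), bg_cad))
  expect_true(abs(n_2_5 - 54) <= 1)
  expect_odds_n(individual_odds(cad, centile_query(25), bg_cad), 29)
  expect_odds_n(individual_odds(cad, centile_query(75), bg_cad), 15)
  expect_odds_n(individual_odds(cad, centile_query(97.5), bg_cad), 8)

  bg_br <- parse_odds("1:41")
  expect_odds_n(individual_odds(breast, centile_query(2.5), bg_br), 91)
  expect_odds_n(individual_odds(breast, centile_query(25), bg_br), 56)
  expect_odds_n(individual_odds(breast, centile_query(75), bg_br), 34)
  expect_odds_n(individual_odds(breast, centile_query(97.5), bg_br), 21)

  # null score leaves the background odds unchanged
  expect_odds_n(individual_odds(risk_model(0), centile_query(75), bg_cad), 19)
})

test_that("quantile-group likelihood ratio matches the area-ratio oracle", {
  # oracle: numerical integration of the affected density over the slice
  for (d in c(0.48, 1)) {
    for (g in list(c(0, 0.2), c(0.4, 0.6), c(0.8, 1))) {
      oracle <- integrate(dnorm, qnorm(g[1]), qnorm(g[2]), mean = d,
                          rel.tol = 1e-10)$value / (g[2] - g[1])
      expect_equal(lr_quantile_group(risk_model(d),
                                     quantile_group(g[1], g[2])),
                   oracle, tolerance = 1e-8)
    }
  }
  expect_equal(lr_quantile_group(cad, quantile_group(0, 0.2)), 0.466,
               tolerance = 1e-3)
  expect_equal(lr_quantile_group(cad, quantile_group(0.8, 1)), 1.794,
               tolerance = 1e-3)
  expect_equal(lr_quantile_group(risk_model(0), quantile_group(0.3, 0.7)), 1)
})

test_that("group LRs integrate to one over any full partition", {
  partitions <- list(
    seq(0, 1, by = 0.2),
    c(0, 0.01, 0.2, 0.5, 0.77, 1),
    seq(0, 1, length.out = 12)
  )
  for (d in c(0, 0.48, 1.3)) {
    for (breaks in partitions) {
      lo <- breaks[-length(breaks)]
      hi <- breaks[-1]
      total <- sum(vapply(seq_along(lo), function(i) {
        (hi[i] - lo[i]) * lr_quantile_group(risk_model(d),
                                            quantile_group(lo[i], hi[i]))
      }, numeric(1)))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("group LR converges to the centile LR as the group narrows", {
  eps <- 1e-4
  for (d in c(0.2, 0.48, 1.0)) {
    for (q in c(0.1, 0.5, 0.9)) {
      point <- lr_at_centile(risk_model(d), centile_query(q, "fraction"))
      narrow <- lr_quantile_group(risk_model(d),
                                  quantile_group(q - eps, q + eps))
      expect_lt(abs(narrow - point), 1e-3 * point)
    }
  }
})

test_that("stratification table reproduces printed quintile odds", {
  tab <- stratification_table(cad, 5, "1:19", 100000)
  expect_equal(tab$odds_1_in_n[1], 41L)
  expect_equal(tab$odds_1_in_n[5], 11L)

  tab_br <- stratification_table(breast, 5, "1:41", 100000)
  expect_true(abs(tab_br$odds_1_in_n[1] - 72) <= 1) # printed 72, +/-1 cell
  expect_equal(tab_br$odds_1_in_n[5], 26L)
})

test_that("stratification table conserves counts and shares", {
  for (d in c(0, 0.48, 1.1)) {
    for (n_groups in c(2, 5, 10)) {
      pop <- 100000
      bg <- parse_odds("1:19")
      tab <- stratification_table(risk_model(d), n_groups, bg, pop)
      expect_equal(sum(tab$n_affected) + sum(tab$n_unaffected), pop)
      expect_equal(sum(tab$n_affected),
                   round(pop * risk_from_odds(bg)))
      expect_equal(sum(tab$share_of_cases), 1, tolerance = 1e-9)
      width <- tab$group_hi - tab$group_lo
      expect_equal(sum(width), 1)
      expect_equal(sum(width * tab$lr), 1, tolerance = 1e-9)
      expect_equal(sum(tab$share_of_cases_counts), 1, tolerance = 1e-12)
    }
  }
  # null model: every group carries the background odds and equal counts
  tab0 <- stratification_table(risk_model(0), 5, "1:19", 100000)
  expect_true(all(tab0$odds_1_in_n == 19L))
  expect_true(max(tab0$n_affected) - min(tab0$n_affected) <= 1)
})

test_that("tail analysis reproduces the printed upper-tail quantities", {
  res <- tail_analysis(cad, 0.025, "1:19")
  expect_odds_n(res$odds, 7)
  expect_equal(round(100 * res$share_of_cases), 7)

  res_br <- tail_analysis(breast, 0.025, "1:41")
  expect_equal(round(100 * res_br$share_of_cases), 6)

  # null: the tail holds its own share and the background odds
  res0 <- tail_analysis(risk_model(0), 0.1, "1:19")
  expect_equal(res0$share_of_cases, 0.1, tolerance = 1e-12)
  expect_odds_n(res0$odds, 19)
  # share of cases always at least the tail fraction for delta >= 0
  for (d in c(0, 0.3, 1)) {
    expect_gte(tail_analysis(risk_model(d), 0.025, "1:19")$share_of_cases,
               0.025)
  }
})

test_that("top-vs-bottom odds ratios match the printed ladder", {
  printed <- c("0.01" = 13, "0.05" = 7, "0.1" = 5, "0.2" = 4, "0.25" = 3)
  for (f in names(printed)) {
    expect_equal(round(top_vs_bottom_odds_ratio(cad, as.numeric(f))),
                 unname(printed[f]))
  }
  expect_equal(top_vs_bottom_odds_ratio(risk_model(0), 0.1), 1,
               tolerance = 1e-12)
  # decreasing in the tail fraction; equals the ratio of tail LRs;
  # invariant to background odds by construction (no odds argument)
  fr <- c(0.01, 0.05, 0.1, 0.2, 0.25, 0.4)
  vals <- vapply(fr, function(f) top_vs_bottom_odds_ratio(cad, f), numeric(1))
  expect_true(all(diff(vals) < 0))
  f <- 0.05
  lr_top <- tail_analysis(cad, f, "1:19")$lr
  lr_bottom <- lr_quantile_group(cad, quantile_group(0, f)) # bottom tail
  expect_equal(top_vs_bottom_odds_ratio(cad, f), lr_top / lr_bottom,
               tolerance = 1e-12)
})

test_that("stratification tables serialise to TSV and JSON faithfully", {
  tab <- stratification_table(cad, 5, "1:19", 100000)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_stratification(tab, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(back$odds_1_in_n, tab$odds_1_in_n)
  expect_equal(back$lr, tab$lr, tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  write_stratification(tab, js, "json")
  back_js <- jsonlite::fromJSON(js)
  expect_equal(back_js$n_affected, tab$n_affected)
})
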