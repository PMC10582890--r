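# Shared fixture builders. Fixtures are written programmatically at test time
# in the default catalog dialect.

write_fixture_tsv <- function(rows, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_row <- function(kind, value, trait_type = "binary",
                        score_id = "PGS000001", trait_id = "EFO_0000001",
                        publication_id = "PGP000001") {
  list(score_id = score_id, trait_id = trait_id, trait_type = trait_type,
       metric_kind = kind, metric_value = value,
       publication_id = publication_id)
}

expect_odds_n <- function(object, n) {
  expect_s3_class(object, "polyscreen_odds")
  expect_equal(odds_denominator(object), as.integer(n))
}
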