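table1_strings <- function() {
  readLines(system.file("extdata", "table1_nuc_ish.txt", package = "bapfish"),
            encoding = "UTF-8")
}

count_of <- function(ci) c(ci$lo, ci$hi)

test_that("published nomenclature strings parse to the expected structures", {
  # simple counts with a con term
  res <- parse_nuc_ish("nuc ish(5′MYCx2,3′MYCx1)(5′MYC con 3′MYCx1)[100]")
  expect_length(res$clones, 1L)
  cl <- res$clones[[1]]
  expect_equal(count_of(cl$probe_counts[[1]]$count), c(2, 2))
  expect_equal(cl$probe_counts[[1]]$probe, "FIVE_PRIME_MYC")
  expect_equal(count_of(cl$probe_counts[[2]]$count), c(1, 1))
  expect_equal(cl$relations[[1]]$kind, "CON")
  expect_equal(count_of(cl$relations[[1]]$count), c(1, 1))
  expect_equal(cl$cells_observed, 100L)
  expect_equal(cl$cells_total, 100L)

  # normal result, bare MYC token sets both probes
  res2 <- parse_nuc_ish("nuc ish(MYCx2)[100]")
  expect_equal(res2$clones[[1]]$probe_counts[[1]]$probe, "MYC_BOTH")
  expect_length(res2$clones[[1]]$relations, 0L)

  # ranges with mixed tilde/hyphen separators and interior whitespace,
  # plus the stray comma after the prefix as printed
  res3 <- parse_nuc_ish("nuc ish,(5′MYCx2 ~ 3,3′MYCx1-2)(5′MYC con 3′MYCx1-2)[97/100]")
  cl3 <- res3$clones[[1]]
  expect_equal(count_of(cl3$probe_counts[[1]]$count), c(2, 3))
  expect_equal(count_of(cl3$probe_counts[[2]]$count), c(1, 2))
  expect_equal(count_of(cl3$relations[[1]]$count), c(1, 2))
  expect_equal(cl3$cells_observed, 97L)

  # shared multiplier expands to both probes
  res4 <- parse_nuc_ish("nuc ish(5′MYC,3′MYC)x2∼4(5′MYC con 3′MYCx1 ~ 2)[93/100]")
  cl4 <- res4$clones[[1]]
  expect_length(cl4$probe_counts, 2L)
  expect_equal(count_of(cl4$probe_counts[[1]]$count), c(2, 4))
  expect_equal(count_of(cl4$probe_counts[[2]]$count), c(2, 4))

  # multiple clones
  res5 <- parse_nuc_ish("nuc ish(5’MYCx3,3′MYCx2)(5’MYC con 3′MYCx2)[42/100]/(MYCx3)[30/100]")
  expect_length(res5$clones, 2L)
  expect_equal(res5$clones[[2]]$cells_observed, 30L)
})

test_that("malformed nomenclature is rejected with informative errors", {
  err <- tryCatch(parse_nuc_ish("nuc ish(5'MYCx2,3'MYCq1)[100]"),
                  error = function(e) e)
  expect_s3_class(err, "bapfish_parse_error")
  expect_false(is.na(err$offset))
  expect_error(parse_nuc_ish("nuc ish(5'MYCx2)[101/100]"), "exceed")
  expect_error(parse_nuc_ish("karyotype 46,XY"), "nuc ish")
  expect_error(parse_nuc_ish(""), "non-empty")
  expect_error(
    parse_nuc_ish("nuc ish(MYCx2)(5'MYC con 3'MYCx1)(5'MYC sep 3'MYCx1)[100]"),
    "con and sep")
  # clone cell counts may not exceed the cells scored
  expect_error(parse_nuc_ish("nuc ish(MYCx2)[60/100]/(MYCx3)[50/100]"),
               "exceeding")
})

test_that("clone summaries derive fusion and isolated counts", {
  s <- summarize_clone(parse_nuc_ish(
    "nuc ish(5'MYCx2,3'MYCx1)(5'MYC con 3'MYCx1)[100]")$clones[[1]])
  expect_equal(s$fusion, c(1, 1))
  expect_equal(s$r_isolated, c(1, 1))
  expect_equal(s$g_isolated, c(0, 0))

  # sep term: F = min(R, G) - SEP
  s2 <- summarize_clone(parse_nuc_ish(
    "nuc ish(MYCx2)(5'MYC sep 3'MYCx1)[96/100]")$clones[[1]])
  expect_equal(s2$fusion, c(1, 1))
  expect_equal(s2$r_isolated, c(1, 1))
  expect_equal(s2$g_isolated, c(1, 1))

  # no relation term: everything that can fuse does
  s3 <- summarize_clone(parse_nuc_ish("nuc ish(MYCx3)[100]")$clones[[1]])
  expect_equal(s3$fusion, c(3, 3))
  expect_equal(s3$r_isolated, c(0, 0))

  # ranges evaluated at both endpoints
  s4 <- summarize_clone(parse_nuc_ish(
    "nuc ish(5'MYCx2~5,3'MYCx1~2)(5'MYC con 3'MYCx1~2)[100]")$clones[[1]])
  expect_equal(s4$r_isolated, c(1, 3))
  expect_equal(s4$g_isolated, c(0, 0))

  # more separated than present is inconsistent
  expect_error(
    summarize_clone(parse_nuc_ish("nuc ish(MYCx2)(5'MYC sep 3'MYCx3)[100]")$clones[[1]]),
    "inconsistent")
})

test_that("conservation holds for every clone the parser accepts", {
  for (txt in table1_strings()) {
    for (cl in parse_nuc_ish(txt)$clones) {
      s <- summarize_clone(cl)
      expect_equal(s$r_isolated + s$fusion, s$r_total)
      expect_equal(s$g_isolated + s$fusion, s$g_total)
      expect_true(all(s$r_isolated >= 0 & s$g_isolated >= 0 & s$fusion >= 0))
    }
  }
})

test_that("canonical writer round-trips all published strings", {
  for (txt in table1_strings()) {
    parsed <- parse_nuc_ish(txt)
    canon <- format_nuc_ish(parsed)
    reparsed <- parse_nuc_ish(canon)
    expect_true(bapfish:::nuc_ish_equal(parsed, reparsed), info = txt)
    # canonical dialect is pure ASCII; the only interior spaces flank con/sep
    expect_false(grepl("[′’∼]", canon))
    expect_false(grepl(" ", gsub(" (con|sep) ", "", sub("^nuc ish", "", canon))))
    # idempotent
    expect_identical(format_nuc_ish(reparsed), canon)
  }
})

test_that("prime/tilde dialect variants do not change the parse", {
  set.seed(77)
  for (txt in table1_strings()) {
    base <- parse_nuc_ish(txt)
    canon <- format_nuc_ish(base)
    for (k in 1:15) {
      fuzzed <- fuzz_nuc_ish(canon)
      expect_true(bapfish:::nuc_ish_equal(base, parse_nuc_ish(fuzzed)),
                  info = fuzzed)
    }
  }
})
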