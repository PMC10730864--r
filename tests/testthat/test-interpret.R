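test_that("interpretation follows the unbalanced-result decision rules", {
  # unbalanced pattern without further data is 'likely positive'
  rf <- interpret_result("RF")
  expect_equal(rf$category, "LIKELY_POSITIVE_RECOMMEND_TESTING")
  expect_true(all(c("IG/MYC D-FISH", "MYC IHC", "WGS or RNAseq") %in%
                    rf$recommended_tests))

  # normal pattern is negative, with the false-negative caveat in the text
  neg <- interpret_result("NORMAL")
  expect_equal(neg$category, "NEGATIVE_WITH_FN_CAVEAT")
  expect_match(neg$narrative, "4%")

  # confirmed pure copy-number change is not a rearrangement
  gf_cn <- interpret_result("GF", has_confirmed_juxtaposition = FALSE)
  expect_equal(gf_cn$category, "CN_ALTERATION_NOT_CLASSIFIED_AS_R")

  # confirmed juxtaposition upgrades an unbalanced pattern to positive
  expect_equal(interpret_result("RF", has_confirmed_juxtaposition = TRUE)$category,
               "POSITIVE_MYC_REARRANGEMENT")
  # ... including via an IGH/MYC dual-fusion positive ancillary finding
  expect_equal(interpret_result("GF",
                                ancillary_findings(dfish_igh_positive = TRUE))$category,
               "POSITIVE_MYC_REARRANGEMENT")

  expect_equal(interpret_result("RGF")$category, "POSITIVE_MYC_REARRANGEMENT")
  expect_equal(interpret_result("FUSION_CN")$category,
               "CN_ALTERATION_NOT_CLASSIFIED_AS_R")
})

test_that("the decision table is total over pattern x juxtaposition space", {
  patterns <- c("NORMAL", "RGF", "RF", "GF", "FUSION_CN", "AMBIGUOUS")
  juxta_states <- list(TRUE, FALSE, NA)
  ancillaries <- list(
    ancillary_findings(),
    ancillary_findings(dfish_igh_positive = TRUE),
    ancillary_findings(ihc_overexpressed = TRUE),
    ancillary_findings(partner_is_ig = FALSE))
  cats <- c("NEGATIVE_WITH_FN_CAVEAT", "POSITIVE_MYC_REARRANGEMENT",
            "LIKELY_POSITIVE_RECOMMEND_TESTING",
            "CN_ALTERATION_NOT_CLASSIFIED_AS_R", "AMBIGUOUS_RECOMMEND_TESTING")
  for (p in patterns) for (j in juxta_states) for (a in ancillaries) {
    res <- interpret_result(p, a, has_confirmed_juxtaposition = j)
    expect_true(res$category %in% cats,
                info = sprintf("%s / juxta=%s", p, format(j)))
    expect_true(nzchar(res$narrative))
  }
  expect_error(interpret_result("NOT_A_PATTERN"), "unknown pattern")
})

test_that("reconcile compares observed and predicted classes with a CN explanation", {
  probes <- tiny_probes()
  params <- sim_params(d_fuse = 500, min_visible_frac = 0.3)
  diploid <- build_diploid_reference(probes, flank = 500)
  rep <- reconcile("nuc ish(MYCx2)[100]", diploid, probes, params)
  expect_true(rep$concordant)
  expect_equal(rep$observed_class, "NORMAL")
  expect_equal(rep$cn_five_prime, 2)
  expect_match(rep$cn_explanation, "=")

  # RF-style configuration: gain of the 5' side
  hom <- derivative_chromosome(list(segment_ref(genomic_interval("c", 0, 3000))), "hom")
  extra5 <- derivative_chromosome(list(segment_ref(genomic_interval("c", 800, 1500))), "x5")
  cfg <- genome_configuration(list(hom, hom, extra5))
  rep2 <- reconcile("nuc ish(5'MYCx3,3'MYCx2)(5'MYC con 3'MYCx2)[100]",
                    cfg, probes, params)
  expect_true(rep2$concordant)
  expect_equal(rep2$predicted_class, "RF")
  expect_gt(rep2$cn_five_prime, rep2$cn_three_prime)
  expect_match(rep2$cn_explanation, "CN\\(5'\\) > CN\\(3'\\)")

  # discordant pairing is reported, not hidden
  rep3 <- reconcile("nuc ish(MYCx2)(5'MYC sep 3'MYCx1)[100]", diploid, probes, params)
  expect_false(rep3$concordant)
})

test_that("survey percentages use half-up integer rounding", {
  tab <- survey_percentages(data.frame(
    label = c("a", "b", "c", "d", "e"),
    k = c(23, 30, 36, 0, 1),
    n = c(54, 54, 54, 54, 8)))
  expect_equal(tab$percent, c(43L, 56L, 67L, 0L, 13L))  # 12.5 rounds up
  expect_error(survey_percentages(data.frame(label = "x", k = 5, n = 4)),
               "0 <= k <= n")
  expect_error(survey_percentages(data.frame(label = "x", k = 0, n = 0)),
               "positive")
})
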