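# the miniature locus has a 400-base red-green gap, so 500 fuses an intact
# homologue and the footprints are 300 bases wide
tiny_params <- function() sim_params(d_fuse = 500, min_visible_frac = 0.3)

test_that("intact, translocated and gained loci produce the canonical patterns", {
  probes <- tiny_probes()
  diploid <- build_diploid_reference(probes, flank = 500)
  pat <- simulate_signals(diploid, probes, tiny_params())
  expect_equal(c(pat$n_red_isolated, pat$n_green_isolated, pat$n_fusion),
               c(0L, 0L, 2L))
  expect_equal(classify_pattern(pat), "NORMAL")

  # reciprocal translocation between the footprints, other homologue intact
  hom <- derivative_chromosome(list(segment_ref(genomic_interval("c", 0, 3000))), "hom")
  derA <- derivative_chromosome(list(
    segment_ref(genomic_interval("c", 0, 1500)),
    segment_ref(genomic_interval("p", 1000, 2000))), "derA")
  derB <- derivative_chromosome(list(
    segment_ref(genomic_interval("p", 0, 1000)),
    segment_ref(genomic_interval("c", 1500, 3000))), "derB")
  pat2 <- simulate_signals(genome_configuration(list(hom, derA, derB)),
                           probes, tiny_params())
  expect_equal(c(pat2$n_red_isolated, pat2$n_green_isolated, pat2$n_fusion),
               c(1L, 1L, 1L))
  expect_equal(classify_pattern(pat2), "RGF")

  # extra 5' copy far from any green, plus one intact homologue: RF with
  # totals R=2, G=1, F=1
  der_loss <- derivative_chromosome(list(
    segment_ref(genomic_interval("c", 0, 1500)),
    segment_ref(genomic_interval("p", 1000, 2000))), "der_loss")
  pat3 <- simulate_signals(genome_configuration(list(hom, der_loss)),
                           probes, tiny_params())
  expect_equal(c(pat3$n_red_isolated, pat3$n_green_isolated, pat3$n_fusion),
               c(1L, 0L, 1L))
  expect_equal(pat3$n_red_isolated + pat3$n_fusion, 2L)   # red total
  expect_equal(pat3$n_green_isolated + pat3$n_fusion, 1L) # green total
  expect_equal(classify_pattern(pat3), "RF")
})

test_that("partial footprints emit spots only above the visibility threshold", {
  probes <- tiny_probes()
  hom <- derivative_chromosome(list(segment_ref(genomic_interval("c", 0, 3000))), "hom")
  # 20% of the red footprint: invisible at min_visible_frac 0.3
  dim_part <- derivative_chromosome(list(
    segment_ref(genomic_interval("c", 1000, 1060))), "dim")
  pat <- simulate_signals(genome_configuration(list(hom, dim_part)),
                          probes, tiny_params())
  expect_equal(pat$n_red_isolated, 0L)
  # 60% is visible
  bright <- derivative_chromosome(list(
    segment_ref(genomic_interval("c", 1000, 1180))), "bright")
  pat2 <- simulate_signals(genome_configuration(list(hom, bright)),
                           probes, tiny_params())
  expect_equal(pat2$n_red_isolated, 1L)
  expect_equal(pat2$spots$intensity_fraction[pat2$spots$derivative == "bright"], 0.6)
})

test_that("fusion calling respects the colocalisation distance", {
  probes <- tiny_probes()
  # red and green on one derivative with the native 400-base gap
  der <- derivative_chromosome(list(segment_ref(genomic_interval("c", 900, 2100))), "d")
  cfg <- genome_configuration(list(der))
  close_pat <- simulate_signals(cfg, probes, sim_params(d_fuse = 500, min_visible_frac = 0.3))
  expect_equal(close_pat$n_fusion, 1L)
  far_pat <- simulate_signals(cfg, probes, sim_params(d_fuse = 100, min_visible_frac = 0.3))
  expect_equal(far_pat$n_fusion, 0L)
  expect_equal(far_pat$n_red_isolated, 1L)
  expect_equal(far_pat$n_green_isolated, 1L)
})

test_that("pattern classification follows the RGF/RF/GF rules", {
  # GF: isolated green without isolated red (1R2G with one fusion)
  s7 <- summarize_clone(parse_nuc_ish(
    "nuc ish(5'MYCx1,3'MYCx2)(5'MYC con 3'MYCx1)[68/100]")$clones[[1]])
  expect_equal(classify_pattern(s7), "GF")

  # RGF at both endpoints of a range
  s9 <- summarize_clone(parse_nuc_ish(
    "nuc ish(5'MYC,3'MYC)x2~4(5'MYC con 3'MYCx1~2)[93/100]")$clones[[1]])
  expect_equal(classify_pattern(s9), "RGF")

  # no isolated signals: fusion count against ploidy
  expect_equal(classify_pattern(simulated_pattern(0, 0, 2)), "NORMAL")
  expect_equal(classify_pattern(simulated_pattern(0, 0, 3)), "FUSION_CN")
  expect_equal(classify_pattern(simulated_pattern(0, 0, 2), ploidy = 4), "FUSION_CN")

  # endpoints that disagree are ambiguous
  amb <- summarize_clone(parse_nuc_ish(
    "nuc ish(5'MYCx2~3,3'MYCx2)(5'MYC con 3'MYCx2)[100]")$clones[[1]])
  expect_equal(classify_pattern(amb), "AMBIGUOUS")
})

test_that("dominant abnormal clone drives whole-result classification", {
  expect_equal(classify_result("nuc ish(MYCx2)[100]"), "NORMAL")
  # normal clone in the majority, abnormal clone still decides
  expect_equal(classify_result("nuc ish(MYCx2)[70/100]/(5'MYCx2,3'MYCx1)(5'MYC con 3'MYCx1)[30/100]"),
               "RF")
  # largest abnormal clone wins
  expect_equal(classify_result(
    "nuc ish(5'MYCx3,3'MYCx2)(5'MYC con 3'MYCx2)[42/100]/(MYCx3)[30/100]"), "RF")
})

test_that("pattern_to_iscn emits nomenclature that reproduces the pattern", {
  # spot patterns from the published forms
  expect_equal(format_nuc_ish(pattern_to_iscn(simulated_pattern(1, 1, 1))),
               "nuc ish(MYCx2)(5'MYC sep 3'MYCx1)[100]")
  expect_equal(format_nuc_ish(pattern_to_iscn(simulated_pattern(0, 0, 2))),
               "nuc ish(MYCx2)[100]")
  expect_equal(format_nuc_ish(pattern_to_iscn(simulated_pattern(1, 0, 1))),
               "nuc ish(5'MYCx2,3'MYCx1)(5'MYC con 3'MYCx1)[100]")

  # closure: classify(summarize(pattern_to_iscn(p))) == classify(p)
  for (r in 0:3) for (g in 0:3) for (f in 0:3) {
    if (r + g + f == 0) next
    p <- simulated_pattern(r, g, f)
    s <- summarize_clone(pattern_to_iscn(p)$clones[[1]])
    expect_equal(classify_pattern(s), classify_pattern(p),
                 info = sprintf("%dR %dG %dF", r, g, f))
    expect_equal(s$r_isolated, c(r, r))
    expect_equal(s$g_isolated, c(g, g))
    expect_equal(s$fusion, c(f, f))
  }
})

test_that("simulator agrees with the exhaustive per-base oracle", {
  probes <- tiny_probes()
  set.seed(2024)
  for (k in 1:80) {
    cfg <- random_tiny_config(max_der = 6L, max_seg = 3L)
    expect_matches_oracle(cfg, probes, random_tiny_params())
  }
})

test_that("adding a disjoint 5' copy never decreases red signal content", {
  probes <- tiny_probes()
  set.seed(515)
  for (k in 1:40) {
    cfg <- random_tiny_config()
    params <- random_tiny_params()
    base <- simulate_signals(cfg, probes, params)
    extra <- derivative_chromosome(list(
      segment_ref(genomic_interval("c", 1000, 1300))), "extra_red")
    cfg2 <- genome_configuration(c(cfg$derivatives, list(extra)),
                                 clone_fraction = cfg$clone_fraction)
    more <- simulate_signals(cfg2, probes, params)
    expect_gte(more$n_red_isolated + more$n_fusion,
               base$n_red_isolated + base$n_fusion)
  }
})
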