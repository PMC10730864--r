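test_that("diploid reference construction spans both footprints with flanks", {
  probes <- tiny_probes()
  cfg <- build_diploid_reference(probes, flank = 500)
  expect_length(cfg$derivatives, 2L)
  for (der in cfg$derivatives) {
    expect_length(der$segments, 1L)
    iv <- der$segments[[1]]$interval
    expect_equal(iv$start, 500)   # red start 1000 - 500
    expect_equal(iv$end, 2500)    # green end 2000 + 500
  }
  expect_equal(footprint_copy_number(cfg, probes[[1]]), 2)
  expect_equal(footprint_copy_number(cfg, probes[[2]]), 2)
})

test_that("invalid probe pairs and flanks are rejected", {
  overlapping <- list(
    probe_footprint("FIVE_PRIME_MYC", genomic_interval("c", 1000, 1800)),
    probe_footprint("THREE_PRIME_MYC", genomic_interval("c", 1700, 2000)))
  expect_error(build_diploid_reference(overlapping), "overlap")
  swapped <- list(
    probe_footprint("FIVE_PRIME_MYC", genomic_interval("c", 1700, 2000)),
    probe_footprint("THREE_PRIME_MYC", genomic_interval("c", 1000, 1300)))
  expect_error(build_diploid_reference(swapped), "centromeric")
  expect_error(build_diploid_reference(tiny_probes(), flank = 0), "flank")
})

test_that("assemble_derivative joins segments consistently with junctions", {
  # reciprocal-translocation style join: left flank of c to right part of p
  j <- junction("c", 1500, "left", "p", 800, "right", event_id = "t1")
  der <- assemble_derivative(list(j), list(
    segment_ref(genomic_interval("c", 0, 1500)),
    segment_ref(genomic_interval("p", 800, 2000))), "der_t")
  expect_length(der$segments, 2L)

  # identity: no junctions, one segment
  seg <- segment_ref(genomic_interval("c", 0, 3000))
  der1 <- assemble_derivative(list(), list(seg), "hom")
  expect_identical(der1$segments[[1]], seg)

  # inconsistent junction names the offender
  bad <- junction("c", 1501, "left", "p", 800, "right", event_id = "bad_j")
  expect_error(
    assemble_derivative(list(bad), list(
      segment_ref(genomic_interval("c", 0, 1500)),
      segment_ref(genomic_interval("p", 800, 2000)))),
    "bad_j")
})

test_that("a deletion derivative retains exactly the bases outside [p, q)", {
  p <- 900; q <- 1450
  j <- junction("c", p, "left", "c", q, "right", event_id = "del1")
  der <- assemble_derivative(list(j), list(
    segment_ref(genomic_interval("c", 0, p)),
    segment_ref(genomic_interval("c", q, 3000))), "der_del")
  got <- oracle_derivative_bases(der)
  all_bases <- 0:2999
  want <- paste0("c:", all_bases[all_bases < p | all_bases >= q])
  expect_identical(got, want)

  # determinism: identical inputs, identical structure
  der2 <- assemble_derivative(list(j), list(
    segment_ref(genomic_interval("c", 0, p)),
    segment_ref(genomic_interval("c", q, 3000))), "der_del")
  expect_identical(der, der2)
})

test_that("footprint copy number counts fractional and deleted footprints", {
  probes <- tiny_probes()
  # one homologue lost its red footprint entirely
  del_hom <- derivative_chromosome(list(
    segment_ref(genomic_interval("c", 0, 900)),
    segment_ref(genomic_interval("c", 1500, 3000))), "del_hom")
  hom <- derivative_chromosome(list(segment_ref(genomic_interval("c", 0, 3000))), "hom")
  cfg <- genome_configuration(list(hom, del_hom))
  expect_equal(footprint_copy_number(cfg, probes[[1]]), 1)
  expect_equal(footprint_copy_number(cfg, probes[[2]]), 2)

  # a derivative carrying 60% of the red footprint plus an intact homologue
  part <- derivative_chromosome(list(
    segment_ref(genomic_interval("c", 1000, 1180))), "part")  # 180/300 = 0.6
  cfg2 <- genome_configuration(list(hom, part))
  expect_equal(footprint_copy_number(cfg2, probes[[1]]), 1.6)
  expect_equal(oracle_copy_number(cfg2, probes[[1]]), 1.6)
})

test_that("copy number is additive, subdivision-invariant and matches the base oracle", {
  probes <- tiny_probes()
  set.seed(401)
  for (rep in 1:25) {
    cfg <- random_tiny_config()
    for (fp in probes) {
      cn <- footprint_copy_number(cfg, fp)
      expect_equal(cn, oracle_copy_number(cfg, fp), tolerance = 1e-12)
      # additivity over derivatives
      parts <- vapply(cfg$derivatives, function(d)
        footprint_copy_number(genome_configuration(list(d)), fp), 0)
      expect_equal(cn, sum(parts), tolerance = 1e-12)
    }
    # subdivision invariance: split every splittable segment at a random
    # interior point
    split_ders <- lapply(cfg$derivatives, function(d) {
      segs <- list()
      for (s in d$segments) {
        iv <- s$interval
        if (interval_width_(iv) > 2) {
          cut <- iv$start + sample.int(interval_width_(iv) - 1L, 1L)
          halves <- list(
            segment_ref(genomic_interval(iv$chrom, iv$start, cut), s$orientation),
            segment_ref(genomic_interval(iv$chrom, cut, iv$end), s$orientation))
          if (s$orientation == "-") halves <- rev(halves)
          segs <- c(segs, halves)
        } else {
          segs <- c(segs, list(s))
        }
      }
      derivative_chromosome(segs, d$name)
    })
    cfg_split <- genome_configuration(split_ders)
    for (fp in probes)
      expect_equal(footprint_copy_number(cfg_split, fp),
                   footprint_copy_number(cfg, fp), tolerance = 1e-12)
  }
})
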