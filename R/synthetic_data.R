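# Seeded generator of rearrangement scenarios with analytically known
# pattern class. Archetypes mirror the event types seen in unbalanced and
# balanced MYC break-apart cases: balanced reciprocal translocation,
# unbalanced juxtapositions gaining 5' or losing 3' material, whole-locus
# copy gain, focal deletion removing the 5' probe and MYC, templated
# insertion of the 5' region into a partner locus, and genic intron-1
# breakpoints. Partner loci are abstract labelled chromosomes: the pattern
# class depends only on topology, so the generator is reference-free.

ARCHETYPES <- c("NORMAL", "BALANCED_TRANSLOCATION", "UNBALANCED_5P_GAIN",
                "UNBALANCED_3P_LOSS", "WHOLE_LOCUS_GAIN",
                "DELETION_5P_AND_MYC", "TEMPLATED_INSERTION",
                "GENIC_INTRON1_BREAK")

# abstract partner chromosome used by all juxtaposing archetypes
PARTNER_CHROM <- "chrP"
PARTNER_LEN <- 4e6
PARTNER_MID <- 2e6

#' Scenario specification
#'
#' @param archetype One of `NORMAL`, `BALANCED_TRANSLOCATION`,
#'   `UNBALANCED_5P_GAIN`, `UNBALANCED_3P_LOSS`, `WHOLE_LOCUS_GAIN`,
#'   `DELETION_5P_AND_MYC`, `TEMPLATED_INSERTION`, `GENIC_INTRON1_BREAK`.
#' @param seed Integer seed fixing all randomness of the scenario.
#' @param params Archetype-specific overrides: `clone_fraction`;
#'   breakpoint windows (`break_window`, a length-2 vector); for
#'   `GENIC_INTRON1_BREAK`, `retain_reciprocal` (`TRUE` keeps both
#'   derivatives of the reciprocal exchange, giving a balanced RGF truth;
#'   `FALSE` retains only the green-bearing derivative, giving GF).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(archetype, seed = 1L, params = list()) {
  if (!archetype %in% ARCHETYPES)
    stop_validation("unknown archetype '%s'", archetype)
  if (!is_count1(seed)) stop_validation("seed must be a non-negative integer")
  structure(list(archetype = archetype, seed = as.integer(seed),
                 params = params),
            class = "scenario_spec")
}

# archetype-legal breakpoint windows on the modeled locus (0-based);
# margins keep breaks clear of footprint edges
archetype_windows <- function(probes, locus) {
  pr <- validate_probes(probes)
  gap <- c(pr$five$interval$end + 10e3, pr$three$interval$start - 10e3)
  list(
    gap = gap,                                              # between footprints
    intron1 = c(locus$myc$start + 1e3, locus$myc$start + 6e3),
    before_red = c(locus$span$start + 50e3, pr$five$interval$start - 10e3),
    after_myc = c(locus$myc$end + 5e3, pr$three$interval$start - 10e3)
  )
}

draw_pos <- function(window) round(runif(1, window[1], window[2]))

seg <- function(chrom, start, end, orientation = "+")
  segment_ref(genomic_interval(chrom, start, end), orientation)

#' Generate one rearrangement scenario
#'
#' Deterministic for a fixed spec: the seed fixes every breakpoint draw.
#' The truth class is set analytically by the archetype (not by running the
#' simulator): `NORMAL -> NORMAL`, `BALANCED_TRANSLOCATION -> RGF`,
#' `UNBALANCED_5P_GAIN -> RF`, `UNBALANCED_3P_LOSS -> RF`,
#' `WHOLE_LOCUS_GAIN -> FUSION_CN`, `DELETION_5P_AND_MYC -> GF`,
#' `TEMPLATED_INSERTION -> RF`, `GENIC_INTRON1_BREAK -> RGF` or `GF`
#' depending on `retain_reciprocal`.
#'
#' @param spec A [scenario_spec()] (or an archetype name, with `seed`).
#' @param seed Used when `spec` is given as an archetype name.
#' @param probes,locus Locus model (defaults: [default_probes()],
#'   [default_locus()]).
#' @return An object of class `scenario`: fields `spec`, `config`
#'   (a [genome_configuration()]), `truth_class`, `description`,
#'   `junctions`, `cn_segments` (the events realised, for serialisation).
#' @export
generate_scenario <- function(spec, seed = 1L, probes = default_probes(),
                              locus = default_locus()) {
  if (is.character(spec)) spec <- scenario_spec(spec, seed)
  if (!inherits(spec, "scenario_spec")) stop_validation("spec must be a scenario_spec")
  pr <- validate_probes(probes)
  win <- archetype_windows(probes, locus)
  p <- spec$params
  frac <- p$clone_fraction %||% 1
  span <- locus$span
  hom <- function(name) derivative_chromosome(list(seg(span$chrom, span$start, span$end)), name)
  check_window <- function(w) {
    if (w[1] >= w[2] || w[1] < span$start || w[2] > span$end)
      stop_validation("breakpoint window [%.0f, %.0f) lies outside the modeled locus",
                      w[1], w[2])
    w
  }

  with_seed(spec$seed, {
    res <- switch(
      spec$archetype,
      NORMAL = list(
        ders = list(hom("hom1"), hom("hom2")),
        truth = "NORMAL", junctions = list(), cn = list(),
        desc = "intact diploid locus"),
      BALANCED_TRANSLOCATION = {
        bp <- draw_pos(check_window(p$break_window %||% win$gap))
        j1 <- junction(span$chrom, bp, "left", PARTNER_CHROM, PARTNER_MID, "right",
                       "bt_der8", "PARTNER")
        j2 <- junction(PARTNER_CHROM, PARTNER_MID, "left", span$chrom, bp, "right",
                       "bt_derP", "PARTNER")
        derA <- assemble_derivative(list(j1), list(
          seg(span$chrom, span$start, bp),
          seg(PARTNER_CHROM, PARTNER_MID, PARTNER_LEN)), "der8")
        derB <- assemble_derivative(list(j2), list(
          seg(PARTNER_CHROM, 0, PARTNER_MID),
          seg(span$chrom, bp, span$end)), "derP")
        list(ders = list(hom("hom1"), derA, derB), truth = "RGF",
             junctions = list(j1, j2), cn = list(),
             desc = sprintf("balanced reciprocal translocation at %.0f", bp))
      },
      UNBALANCED_5P_GAIN = {
        bp <- draw_pos(check_window(p$break_window %||% win$gap))
        j1 <- junction(span$chrom, bp, "left", PARTNER_CHROM, PARTNER_MID, "right",
                       "gain5_der", "PARTNER")
        der <- assemble_derivative(list(j1), list(
          seg(span$chrom, span$start, bp),
          seg(PARTNER_CHROM, PARTNER_MID, PARTNER_LEN)), "der_gain5")
        list(ders = list(hom("hom1"), hom("hom2"), der), truth = "RF",
             junctions = list(j1), cn = list(),
             desc = sprintf("extra copy of the 5' side juxtaposed to a partner at %.0f", bp))
      },
      UNBALANCED_3P_LOSS = {
        bp <- draw_pos(check_window(p$break_window %||% win$gap))
        j1 <- junction(span$chrom, bp, "left", PARTNER_CHROM, PARTNER_MID, "right",
                       "loss3_der", "PARTNER")
        der <- assemble_derivative(list(j1), list(
          seg(span$chrom, span$start, bp),
          seg(PARTNER_CHROM, PARTNER_MID, PARTNER_LEN)), "der_loss3")
        list(ders = list(hom("hom1"), der), truth = "RF",
             junctions = list(j1), cn = list(),
             desc = sprintf("one homologue loses material 3' of the break at %.0f", bp))
      },
      WHOLE_LOCUS_GAIN = {
        cnseg <- cn_segment(genomic_interval(span$chrom, span$start, span$end), 3L,
                            "whole_locus_gain")
        list(ders = list(hom("hom1"), hom("hom2"), hom("hom3")),
             truth = "FUSION_CN", junctions = list(), cn = list(cnseg),
             desc = "whole-locus copy gain (three intact copies)")
      },
      DELETION_5P_AND_MYC = {
        del_start <- draw_pos(check_window(p$del_start_window %||% win$before_red))
        del_end <- draw_pos(check_window(p$del_end_window %||% win$after_myc))
        j1 <- junction(span$chrom, del_start, "left", span$chrom, del_end, "right",
                       "del5_myc")
        der <- assemble_derivative(list(j1), list(
          seg(span$chrom, span$start, del_start),
          seg(span$chrom, del_end, span$end)), "der_del")
        cnseg <- cn_segment(genomic_interval(span$chrom, del_start, del_end), 1L,
                            "del5_myc")
        list(ders = list(hom("hom1"), der), truth = "GF",
             junctions = list(j1), cn = list(cnseg),
             desc = sprintf("focal deletion [%.0f, %.0f) removing the 5' probe and MYC",
                            del_start, del_end))
      },
      TEMPLATED_INSERTION = {
        ins_start <- draw_pos(check_window(p$ins_start_window %||% win$before_red))
        ins_end <- draw_pos(check_window(p$ins_end_window %||% win$after_myc))
        j1 <- junction(PARTNER_CHROM, PARTNER_MID, "left", span$chrom, ins_start, "right",
                       "tins_a", "PARTNER")
        j2 <- junction(span$chrom, ins_end, "left", PARTNER_CHROM, PARTNER_MID, "right",
                       "tins_b", "PARTNER")
        der <- assemble_derivative(list(j1, j2), list(
          seg(PARTNER_CHROM, 0, PARTNER_MID),
          seg(span$chrom, ins_start, ins_end),
          seg(PARTNER_CHROM, PARTNER_MID, PARTNER_LEN)), "der_tins")
        list(ders = list(hom("hom1"), hom("hom2"), der), truth = "RF",
             junctions = list(j1, j2), cn = list(),
             desc = sprintf("templated insertion of [%.0f, %.0f) into a partner locus",
                            ins_start, ins_end))
      },
      GENIC_INTRON1_BREAK = {
        bp <- draw_pos(check_window(p$break_window %||% win$intron1))
        retain <- p$retain_reciprocal %||% TRUE
        j2 <- junction(PARTNER_CHROM, PARTNER_MID, "left", span$chrom, bp, "right",
                       "intron1_derP", "PARTNER")
        derB <- assemble_derivative(list(j2), list(
          seg(PARTNER_CHROM, 0, PARTNER_MID),
          seg(span$chrom, bp, span$end)), "derP")
        if (isTRUE(retain)) {
          j1 <- junction(span$chrom, bp, "left", PARTNER_CHROM, PARTNER_MID, "right",
                         "intron1_der8", "PARTNER")
          derA <- assemble_derivative(list(j1), list(
            seg(span$chrom, span$start, bp),
            seg(PARTNER_CHROM, PARTNER_MID, PARTNER_LEN)), "der8")
          list(ders = list(hom("hom1"), derA, derB), truth = "RGF",
               junctions = list(j1, j2), cn = list(),
               desc = sprintf("genic intron-1 break at %.0f, reciprocal retained", bp))
        } else {
          list(ders = list(hom("hom1"), derB), truth = "GF",
               junctions = list(j2), cn = list(),
               desc = sprintf("genic intron-1 break at %.0f, only the green-bearing derivative retained", bp))
        }
      }
    )
    structure(list(
      spec = spec,
      config = genome_configuration(res$ders, clone_fraction = frac,
                                    label = spec$archetype),
      truth_class = res$truth,
      description = res$desc,
      junctions = res$junctions,
      cn_segments = res$cn
    ), class = "scenario")
  })
}

#' Serialize a scenario to canonical JSON
#'
#' Byte-identical for identical specs; used by the determinism tests and
#' the `synth` CLI subcommand.
#'
#' @param scenario A `scenario`.
#' @return A JSON string.
#' @export
serialize_scenario <- function(scenario) {
  cfg <- scenario$config
  as.character(jsonlite::toJSON(list(
    archetype = scenario$spec$archetype,
    seed = scenario$spec$seed,
    truth_class = scenario$truth_class,
    description = scenario$description,
    clone_fraction = cfg$clone_fraction,
    derivatives = lapply(cfg$derivatives, function(d) list(
      name = d$name,
      segments = lapply(d$segments, function(s)
        list(chrom = s$interval$chrom, start = s$interval$start,
             end = s$interval$end, orientation = s$orientation))))
  ), auto_unbox = TRUE, digits = NA))
}

#' Generate a reproducible cohort of scenarios
#'
#' When `mix` is a vector of non-negative integers summing to `n`, the
#' cohort contains exactly those archetype counts (deterministically
#' shuffled); when it is a vector of weights summing to 1, archetypes are
#' sampled with those probabilities. Per-scenario seeds are drawn from the
#' cohort seed, so the cohort is fully reproducible.
#'
#' @param n Number of scenarios (> 0).
#' @param mix Named vector over archetypes: integer counts or probability
#'   weights.
#' @param seed Cohort seed.
#' @param probes,locus Passed to [generate_scenario()].
#' @return A list of `scenario` objects.
#' @export
generate_cohort <- function(n, mix, seed = 1L, probes = default_probes(),
                            locus = default_locus()) {
  if (!is_count1(n) || n < 1) stop_validation("n must be a positive integer")
  if (is.null(names(mix)) || !all(names(mix) %in% ARCHETYPES))
    stop_validation("mix must be named by archetype")
  if (any(mix < 0)) stop_validation("mix entries must be non-negative")
  with_seed(seed, {
    if (all(mix == floor(mix)) && sum(mix) == n) {
      archetypes <- sample(rep(names(mix), times = mix))
    } else {
      if (abs(sum(mix) - 1) > 1e-8)
        stop_validation("mix must be integer counts summing to n or weights summing to 1")
      archetypes <- sample(names(mix), n, replace = TRUE, prob = mix)
    }
    seeds <- sample.int(2^31 - 2, n)
    lapply(seq_len(n), function(i)
      generate_scenario(scenario_spec(archetypes[i], seeds[i]),
                        probes = probes, locus = locus))
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s seed=%d> truth %s: %s\n", x$spec$archetype,
              x$spec$seed, x$truth_class, x$description))
  invisible(x)
}
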