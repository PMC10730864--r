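# Locus model: genomic intervals, probe footprints, breakpoint junctions,
# copy-number segments, and derivative chromosomes assembled from oriented
# reference segments. Coordinates are 0-based, half-open throughout; the VCF
# reader converts at the boundary.

#' Genomic interval (0-based, half-open)
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start,end Base offsets, `start < end`, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop_validation("interval chrom must be a non-empty string")
  if (!is_count1(start) || !is_count1(end))
    stop_validation("interval start/end must be non-negative integers")
  if (start >= end)
    stop_validation("interval start (%.0f) must be < end (%.0f)", start, end)
  if (!strand %in% c("+", "-"))
    stop_validation("strand must be '+' or '-'")
  structure(
    list(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         strand = strand),
    class = "genomic_interval"
  )
}

interval_width <- function(x) x$end - x$start

# overlap width of two intervals; 0 if on different chromosomes
interval_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Probe footprint of the break-apart assay
#'
#' The BAP design hybridises a red probe 5' (centromeric) and a green probe
#' 3' (telomeric) of *MYC*; an intact locus therefore yields a fused signal.
#'
#' @param label `"FIVE_PRIME_MYC"` or `"THREE_PRIME_MYC"`.
#' @param color `"RED"` or `"GREEN"`. Defaults to the conventional colour for
#'   the label (5' = red, 3' = green).
#' @param interval A [genomic_interval()].
#' @return An object of class `probe_footprint`.
#' @export
probe_footprint <- function(label, interval,
                            color = c(FIVE_PRIME_MYC = "RED",
                                      THREE_PRIME_MYC = "GREEN")[[label]]) {
  if (!label %in% c("FIVE_PRIME_MYC", "THREE_PRIME_MYC"))
    stop_validation("unknown probe label '%s'", label)
  if (!color %in% c("RED", "GREEN"))
    stop_validation("probe color must be RED or GREEN")
  if (!inherits(interval, "genomic_interval"))
    stop_validation("probe interval must be a genomic_interval")
  structure(list(label = label, color = color, interval = interval),
            class = "probe_footprint")
}

# Validate a probe pair: exactly one 5' red and one 3' green footprint,
# red centromeric to green, non-overlapping.
validate_probes <- function(probes) {
  labs <- vapply(probes, function(p) p$label, "")
  if (length(probes) != 2L || !setequal(labs, c("FIVE_PRIME_MYC", "THREE_PRIME_MYC")))
    stop_validation("probes must be one FIVE_PRIME_MYC and one THREE_PRIME_MYC footprint")
  five <- probes[[match("FIVE_PRIME_MYC", labs)]]
  three <- probes[[match("THREE_PRIME_MYC", labs)]]
  if (five$color != "RED" || three$color != "GREEN")
    stop_validation("FIVE_PRIME_MYC must be RED and THREE_PRIME_MYC must be GREEN")
  if (five$interval$chrom != three$interval$chrom)
    stop_validation("probe footprints must share a chromosome")
  if (interval_overlap(five$interval, three$interval) > 0)
    stop_validation("probe footprints must not overlap")
  if (five$interval$start >= three$interval$start)
    stop_validation("FIVE_PRIME_MYC (red) must lie centromeric to THREE_PRIME_MYC (green)")
  list(five = five, three = three)
}

#' Default MYC break-apart probe footprints
#'
#' Approximation of a commercial two-colour BAP design: ~400 kb red block
#' ending centromeric of *MYC* and ~400 kb green block starting telomeric of
#' *MYC* and the PVT1 region, on GRCh38-like chr8 coordinates. Vendor probe
#' coordinates are not published; only the relative layout (red centromeric,
#' green telomeric, gap spanning the gene) carries meaning here, and all
#' shipped analyses depend only on that layout.
#'
#' @return List of two [probe_footprint()] objects (5' red, 3' green).
#' @export
default_probes <- function() {
  list(
    probe_footprint("FIVE_PRIME_MYC",
                    genomic_interval("chr8", 127350000, 127710000)),
    probe_footprint("THREE_PRIME_MYC",
                    genomic_interval("chr8", 128100000, 128500000))
  )
}

#' Default modeled MYC locus landmarks
#'
#' Illustrative GRCh38-like coordinates for the modeled locus: the *MYC*
#' gene body, the PVT1 block telomeric of it, and the reference span used
#' for intact homologues (probe footprints plus 1 Mb flanks).
#'
#' @return Named list of [genomic_interval()] objects
#'   (`myc`, `pvt1`, `span`) plus `chrom`.
#' @export
default_locus <- function() {
  list(
    chrom = "chr8",
    myc = genomic_interval("chr8", 127735000, 127743000),
    pvt1 = genomic_interval("chr8", 127794000, 128080000),
    span = genomic_interval("chr8", 126350000, 129500000)
  )
}

#' Breakpoint junction between two reference flanks
#'
#' A junction joins two breakends. Each breakend is a (chrom, position,
#' side) triple where `side = "left"` means the reference bases to the left
#' of `position` (i.e. `[.., position)`) are retained into the join, and
#' `side = "right"` means the bases from `position` rightwards
#' (`[position, ..)`).
#'
#' @param chromA,posA,sideA First breakend.
#' @param chromB,posB,sideB Second breakend.
#' @param event_id Identifier for error messages and reports.
#' @param partner_label Optional partner gene/locus name.
#' @return An object of class `junction`.
#' @export
junction <- function(chromA, posA, sideA, chromB, posB, sideB,
                     event_id = "junction", partner_label = NA_character_) {
  for (s in list(sideA, sideB))
    if (!s %in% c("left", "right"))
      stop_validation("junction side must be 'left' or 'right'")
  if (!is_count1(posA) || !is_count1(posB))
    stop_validation("junction positions must be non-negative integers")
  structure(
    list(breakendA = list(chrom = chromA, pos = as.numeric(posA), side = sideA),
         breakendB = list(chrom = chromB, pos = as.numeric(posB), side = sideB),
         event_id = event_id, partner_label = partner_label),
    class = "junction"
  )
}

#' Copy-number segment
#'
#' @param interval A [genomic_interval()].
#' @param copy_number Non-negative integer total copy number.
#' @param event_id Optional identifier.
#' @return An object of class `cn_segment`.
#' @export
cn_segment <- function(interval, copy_number, event_id = "cn") {
  if (!inherits(interval, "genomic_interval"))
    stop_validation("cn_segment interval must be a genomic_interval")
  if (!is_count1(copy_number))
    stop_validation("copy_number must be a non-negative integer")
  structure(list(interval = interval, copy_number = as.integer(copy_number),
                 event_id = event_id),
            class = "cn_segment")
}

#' Oriented reference segment (building block of derivatives)
#'
#' @param interval A [genomic_interval()]; the segment's reference span.
#' @param orientation `"+"` (forward) or `"-"` (reverse).
#' @return An object of class `segment_ref`.
#' @export
segment_ref <- function(interval, orientation = "+") {
  if (!inherits(interval, "genomic_interval"))
    stop_validation("segment interval must be a genomic_interval")
  if (!orientation %in% c("+", "-"))
    stop_validation("orientation must be '+' or '-'")
  structure(list(interval = interval, orientation = orientation),
            class = "segment_ref")
}

#' Derivative chromosome
#'
#' An ordered, oriented list of reference segments read left to right.
#'
#' @param segments Non-empty list of [segment_ref()] objects.
#' @param name Identifier.
#' @return An object of class `derivative_chromosome`.
#' @export
derivative_chromosome <- function(segments, name = "der") {
  if (!is.list(segments) || length(segments) == 0L)
    stop_validation("derivative '%s' needs a non-empty segment list", name)
  ok <- vapply(segments, inherits, TRUE, what = "segment_ref")
  if (!all(ok)) stop_validation("derivative segments must be segment_ref objects")
  structure(list(name = name, segments = segments),
            class = "derivative_chromosome")
}

#' Genome configuration of one clone
#'
#' @param derivatives List of [derivative_chromosome()] objects.
#' @param clone_fraction Proportion of cells carrying this configuration,
#'   in (0, 1].
#' @param label Identifier.
#' @return An object of class `genome_configuration`.
#' @export
genome_configuration <- function(derivatives, clone_fraction = 1, label = "clone") {
  if (!is.list(derivatives))
    stop_validation("derivatives must be a list")
  ok <- vapply(derivatives, inherits, TRUE, what = "derivative_chromosome")
  if (length(derivatives) && !all(ok))
    stop_validation("derivatives must be derivative_chromosome objects")
  if (!is.numeric(clone_fraction) || length(clone_fraction) != 1L ||
      is.na(clone_fraction) || clone_fraction <= 0 || clone_fraction > 1)
    stop_validation("clone_fraction must be in (0, 1]")
  structure(list(label = label, clone_fraction = clone_fraction,
                 derivatives = derivatives),
            class = "genome_configuration")
}

#' Build a diploid reference configuration around the probe footprints
#'
#' @param probes Probe pair as from [default_probes()].
#' @param flank Bases of reference retained on each side of the footprints;
#'   must be positive.
#' @param clone_fraction Clone fraction of the configuration.
#' @return A [genome_configuration()] with two identical single-segment
#'   homologues spanning both footprints plus `flank` on each side.
#' @export
build_diploid_reference <- function(probes, flank = 1e6, clone_fraction = 1) {
  pr <- validate_probes(probes)
  if (!is.numeric(flank) || length(flank) != 1L || is.na(flank) || flank <= 0)
    stop_validation("flank must be a positive base count")
  span <- genomic_interval(
    pr$five$interval$chrom,
    max(0, pr$five$interval$start - flank),
    pr$three$interval$end + flank
  )
  genome_configuration(
    list(derivative_chromosome(list(segment_ref(span)), "hom1"),
         derivative_chromosome(list(segment_ref(span)), "hom2")),
    clone_fraction = clone_fraction, label = "diploid"
  )
}

# derivative-end descriptors used to check junction consistency:
# outgoing end of a segment (read left->right) and incoming end of the next.
segment_outgoing <- function(seg) {
  if (seg$orientation == "+")
    list(chrom = seg$interval$chrom, pos = seg$interval$end, side = "left")
  else
    list(chrom = seg$interval$chrom, pos = seg$interval$start, side = "right")
}

segment_incoming <- function(seg) {
  if (seg$orientation == "+")
    list(chrom = seg$interval$chrom, pos = seg$interval$start, side = "right")
  else
    list(chrom = seg$interval$chrom, pos = seg$interval$end, side = "left")
}

breakend_matches <- function(be, endpoint) {
  be$chrom == endpoint$chrom && be$pos == endpoint$pos && be$side == endpoint$side
}

#' Assemble a derivative chromosome from ordered segments and junctions
#'
#' The caller supplies the linear path explicitly: `reference_segments` in
#' derivative order and one junction per adjacency (so
#' `length(junctions) == length(reference_segments) - 1`). Each junction must
#' join the outgoing end of one segment to the incoming end of the next
#' (in either breakend order); an inconsistent junction raises an assembly
#' error naming its `event_id`. No genome-graph path inference is attempted.
#'
#' @param junctions List of [junction()] objects, one per adjacency (may be
#'   empty for a single-segment derivative).
#' @param reference_segments Ordered list of [segment_ref()] objects.
#' @param name Derivative name.
#' @return A [derivative_chromosome()].
#' @export
assemble_derivative <- function(junctions, reference_segments, name = "der") {
  der <- derivative_chromosome(reference_segments, name)
  n <- length(reference_segments)
  if (length(junctions) != n - 1L)
    stop_assembly("derivative '%s': %d segments need %d junctions, got %d",
                  name, n, n - 1L, length(junctions))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- junctions[[i]]
      if (!inherits(j, "junction"))
        stop_assembly("adjacency %d of derivative '%s' is not a junction", i, name)
      out <- segment_outgoing(reference_segments[[i]])
      inc <- segment_incoming(reference_segments[[i + 1L]])
      direct <- breakend_matches(j$breakendA, out) && breakend_matches(j$breakendB, inc)
      swapped <- breakend_matches(j$breakendB, out) && breakend_matches(j$breakendA, inc)
      if (!direct && !swapped)
        stop_assembly(
          "junction '%s' is inconsistent with segment ends at adjacency %d of derivative '%s'",
          j$event_id, i, name)
    }
  }
  der
}

#' Copy number of a probe footprint in a genome configuration
#'
#' Sums, over every derivative segment, the fraction of the footprint the
#' segment carries (overlap length / footprint length). Additive over
#' derivatives and invariant under segment subdivision; a footprint absent
#' from the configuration scores 0.
#'
#' @param config A [genome_configuration()].
#' @param footprint A [probe_footprint()].
#' @return Fractional copy count (e.g. 2.0 for an intact diploid locus).
#' @export
footprint_copy_number <- function(config, footprint) {
  if (!inherits(config, "genome_configuration"))
    stop_validation("config must be a genome_configuration")
  if (!inherits(footprint, "probe_footprint"))
    stop_validation("footprint must be a probe_footprint")
  fp <- footprint$interval
  w <- interval_width(fp)
  total <- 0
  for (der in config$derivatives)
    for (seg in der$segments)
      total <- total + interval_overlap(seg$interval, fp) / w
  total
}

#' @export
print.genome_configuration <- function(x, ...) {
  cat(sprintf("<genome_configuration '%s'> clone fraction %.2f, %d derivative(s)\n",
              x$label, x$clone_fraction, length(x$derivatives)))
  for (der in x$derivatives) {
    segs <- vapply(der$segments, function(s)
      sprintf("%s:%.0f-%.0f(%s)", s$interval$chrom, s$interval$start,
              s$interval$end, s$orientation), "")
    cat(sprintf("  %s: %s\n", der$name, paste(segs, collapse = " | ")))
  }
  invisible(x)
}
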