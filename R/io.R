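# Standard-format IO: VCF 4.2 breakends and symbolic DEL/DUP via vcfR,
# probe footprints as 4-column BED via rtracklayer, copy-number segments as
# SEG (plain TSV). VCF positions are 1-based; everything internal is
# 0-based half-open and converted here at the boundary.

# ---------------------------------------------------------------------------
# BND ALT bracket notation <-> breakend sides.
# For the record's own breakend: REF base before the brackets means its left
# flank is retained ("t[p[", "t]p]"); after means the right flank ("]p]t",
# "[p[t"). For the mate: "[" means its right flank joins, "]" its left.

parse_bnd_alt <- function(alt, line) {
  m <- regmatches(alt, regexec("^([ACGTNacgtn]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0L || m[3] != m[6] || (nzchar(m[2]) == nzchar(m[7])))
    stop_parse("malformed BND ALT '%s' at VCF record %d", alt, line)
  list(
    side_self = if (nzchar(m[2])) "left" else "right",
    mate_chrom = m[4],
    mate_pos = as.numeric(m[5]),
    side_mate = if (m[3] == "[") "right" else "left"
  )
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) == 0L) NA_character_ else m[2]
}

# convert a 1-based VCF breakend position + side to the internal 0-based
# half-open convention: "left" retains [.., pos) => boundary pos (the VCF
# base itself included); "right" retains [pos-1, ..)
vcf_pos_to_internal <- function(pos1, side) {
  if (side == "left") pos1 else pos1 - 1
}
internal_pos_to_vcf <- function(pos0, side) {
  if (side == "left") pos0 else pos0 + 1
}

#' Read structural variants from a VCF
#'
#' Supports breakend (BND) records in bracket notation -- each mate pair
#' becomes one [junction()] -- and symbolic `<DEL>`/`<DUP>` records with an
#' `END` INFO field, which become [cn_segment()]s relative to a diploid
#' baseline (DEL = copy number 1, DUP = 3: single-homologue interpretation).
#' Unmated breakends and malformed ALT alleles are errors naming the
#' offending record. Reconstruction hints written by [write_scenario_vcf()]
#' (`DERID`, `ORD`, `HOMREPL`, `PARTNER` INFO keys) are carried on the
#' returned junctions when present.
#'
#' @param path VCF path.
#' @return List with elements `junctions` and `cn_segments`, plus
#'   `contigs` (named lengths from the header, if declared).
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop_validation("no such VCF: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  meta <- vcf@meta
  contig_lines <- grep("^##contig=", meta, value = TRUE)
  contigs <- NULL
  if (length(contig_lines)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig_lines)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig_lines)))
    contigs <- stats::setNames(lens, ids)
  }

  junctions <- list()
  cn_segments <- list()
  bnd <- list()   # id -> record info, for mate pairing
  n <- nrow(fix)
  for (i in seq_len(n)) {
    alt <- unname(fix[i, "ALT"])
    info <- unname(fix[i, "INFO"])
    svtype <- info_field(info, "SVTYPE")
    chrom <- unname(fix[i, "CHROM"])
    pos <- as.numeric(fix[i, "POS"])
    id <- unname(fix[i, "ID"])
    if (!is.na(svtype) && svtype %in% c("DEL", "DUP") ||
        alt %in% c("<DEL>", "<DUP>")) {
      end <- as.numeric(info_field(info, "END"))
      if (is.na(end))
        stop_parse("symbolic %s record '%s' lacks END at VCF record %d",
                   alt, id, i)
      type <- if (alt == "<DEL>" || identical(svtype, "DEL")) "DEL" else "DUP"
      # symbolic SV: affected bases are POS+1..END 1-based = [POS, END) 0-based
      cn_segments[[length(cn_segments) + 1L]] <- cn_segment(
        genomic_interval(chrom, pos, end),
        copy_number = if (type == "DEL") 1L else 3L,
        event_id = id)
    } else if (grepl("\\[|\\]", alt)) {
      b <- parse_bnd_alt(alt, i)
      bnd[[id]] <- list(chrom = chrom, pos = pos, alt = b,
                        mateid = info_field(info, "MATEID"),
                        derid = info_field(info, "DERID"),
                        ord = suppressWarnings(as.integer(info_field(info, "ORD"))),
                        homrepl = identical(info_field(info, "HOMREPL"), "1"),
                        partner = info_field(info, "PARTNER"),
                        line = i)
    } else {
      stop_parse("unsupported ALT '%s' at VCF record %d (expected BND or <DEL>/<DUP>)",
                 alt, i)
    }
  }

  seen <- character()
  for (id in names(bnd)) {
    if (id %in% seen) next
    rec <- bnd[[id]]
    mate_id <- rec$mateid
    if (is.na(mate_id) || is.null(bnd[[mate_id]]))
      stop_parse("unmated breakend '%s' (MATEID %s not found)", id,
                 if (is.na(mate_id)) "absent" else mate_id)
    mate <- bnd[[mate_id]]
    seen <- c(seen, id, mate_id)
    # cross-check that the mate's ALT points back
    if (mate$alt$mate_chrom != rec$chrom || mate$alt$mate_pos != rec$pos)
      stop_parse("breakends '%s'/'%s' do not point at each other", id, mate_id)
    j <- junction(
      rec$chrom, vcf_pos_to_internal(rec$pos, rec$alt$side_self), rec$alt$side_self,
      mate$chrom, vcf_pos_to_internal(mate$pos, mate$alt$side_self), mate$alt$side_self,
      event_id = sub("_[ab]$", "", id),
      partner_label = rec$partner)
    j$derid <- rec$derid
    j$ord <- rec$ord
    j$homrepl <- isTRUE(rec$homrepl)
    junctions[[length(junctions) + 1L]] <- j
  }
  list(junctions = junctions, cn_segments = cn_segments, contigs = contigs)
}

#' Write junctions and copy-number segments as VCF 4.2
#'
#' Junctions are emitted as BND mate pairs in bracket notation; copy-number
#' segments with copy number 1 (0) as `<DEL>` and >= 3 as `<DUP>` symbolic
#' records. Reconstruction hints (`DERID`, `ORD`, `HOMREPL`, `PARTNER`) are
#' written when present on a junction so [config_from_events()] can rebuild
#' the derivative layout.
#'
#' @param junctions List of [junction()]s.
#' @param cn_segments List of [cn_segment()]s.
#' @param path Output path.
#' @param contigs Named numeric vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(junctions, cn_segments, path, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bapfish",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%.0f>", names(contigs), contigs),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of symbolic SV">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
    '##INFO=<ID=PARTNER,Number=1,Type=String,Description="Partner gene or locus label">',
    '##INFO=<ID=DERID,Number=1,Type=String,Description="Derivative chromosome the junction belongs to">',
    '##INFO=<ID=ORD,Number=1,Type=Integer,Description="Adjacency order within the derivative">',
    '##INFO=<ID=HOMREPL,Number=1,Type=Integer,Description="1 if the derivative replaces one intact homologue">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SIM", sep = "\t")
  )
  rows <- character()
  bnd_alt <- function(side_self, mate_chrom, mate_pos1, side_mate) {
    bracket <- if (side_mate == "right") "[" else "]"
    core <- sprintf("%s%s:%.0f%s", bracket, mate_chrom, mate_pos1, bracket)
    if (side_self == "left") paste0("N", core) else paste0(core, "N")
  }
  for (j in junctions) {
    tags <- c(
      if (!is.null(j$derid) && !is.na(j$derid)) sprintf("DERID=%s", j$derid),
      if (!is.null(j$ord) && !is.na(j$ord)) sprintf("ORD=%d", j$ord),
      if (isTRUE(j$homrepl)) "HOMREPL=1",
      if (!is.null(j$partner_label) && !is.na(j$partner_label))
        sprintf("PARTNER=%s", j$partner_label))
    tagstr <- if (length(tags)) paste0(";", paste(tags, collapse = ";")) else ""
    a <- j$breakendA
    b <- j$breakendB
    posA <- internal_pos_to_vcf(a$pos, a$side)
    posB <- internal_pos_to_vcf(b$pos, b$side)
    idA <- paste0(j$event_id, "_a")
    idB <- paste0(j$event_id, "_b")
    rows <- c(rows,
      paste(a$chrom, sprintf("%.0f", posA), idA, "N",
            bnd_alt(a$side, b$chrom, posB, b$side), ".", "PASS",
            sprintf("SVTYPE=BND;MATEID=%s%s", idB, tagstr), "GT", "0/1", sep = "\t"),
      paste(b$chrom, sprintf("%.0f", posB), idB, "N",
            bnd_alt(b$side, a$chrom, posA, a$side), ".", "PASS",
            sprintf("SVTYPE=BND;MATEID=%s%s", idA, tagstr), "GT", "0/1", sep = "\t"))
  }
  for (s in cn_segments) {
    type <- if (s$copy_number < 2L) "DEL" else "DUP"
    rows <- c(rows, paste(
      s$interval$chrom, sprintf("%.0f", s$interval$start), s$event_id, "N",
      sprintf("<%s>", type), ".", "PASS",
      sprintf("SVTYPE=%s;END=%.0f", type, s$interval$end), "GT", "0/1", sep = "\t"))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED / SEG

#' Read probe footprints from a 4-column BED
#'
#' @param path BED path; column 4 must be `FIVE_PRIME_MYC` or
#'   `THREE_PRIME_MYC`. The pair is validated (red centromeric to green,
#'   non-overlapping, non-empty intervals).
#' @return List of two [probe_footprint()]s.
#' @export
read_probe_bed <- function(path) {
  if (!file.exists(path)) stop_validation("no such BED: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  labels <- gr$name
  if (any(is.na(labels)) || !all(labels %in% c("FIVE_PRIME_MYC", "THREE_PRIME_MYC")))
    stop_validation("probe BED labels must be FIVE_PRIME_MYC / THREE_PRIME_MYC (got: %s)",
                    paste(unique(labels), collapse = ", "))
  probes <- lapply(seq_along(gr), function(i)
    probe_footprint(labels[i], genomic_interval(
      as.character(GenomicRanges::seqnames(gr)[i]),
      GenomicRanges::start(gr)[i] - 1L,   # BED import is 1-based in GRanges
      GenomicRanges::end(gr)[i])))
  validate_probes(probes)
  probes
}

#' Read copy-number segments from a SEG file
#'
#' SEG here is a headered TSV with columns `sample`, `chrom`, `start`,
#' `end`, `copy_number`; coordinates 1-based inclusive as conventional for
#' SEG, converted to the internal 0-based half-open form.
#'
#' @param path SEG path.
#' @return List of [cn_segment()]s.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop_validation("no such SEG: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "copy_number")
  if (!all(need %in% names(df)))
    stop_validation("SEG needs columns %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    cn_segment(genomic_interval(df$chrom[i], df$start[i] - 1, df$end[i]),
               df$copy_number[i],
               event_id = sprintf("%s_seg%d", df$sample[i], i)))
}

#' Write copy-number segments as SEG
#'
#' @param cn_segments List of [cn_segment()]s.
#' @param path Output path.
#' @param sample Sample label.
#' @return `path`, invisibly.
#' @export
write_seg <- function(cn_segments, path, sample = "SIM") {
  df <- do.call(rbind, lapply(cn_segments, function(s)
    data.frame(sample = sample, chrom = s$interval$chrom,
               start = s$interval$start + 1, end = s$interval$end,
               copy_number = s$copy_number)))
  if (is.null(df))
    df <- data.frame(sample = character(), chrom = character(),
                     start = numeric(), end = numeric(), copy_number = integer())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# rebuilding a configuration from events

# terminus span for a chromosome: the modeled locus span on the probe
# chromosome, the declared contig [0, length) elsewhere
chrom_span <- function(chrom, probes, flank, contigs) {
  pr <- validate_probes(probes)
  if (chrom == pr$five$interval$chrom) {
    genomic_interval(chrom, max(0, pr$five$interval$start - flank),
                     pr$three$interval$end + flank)
  } else if (!is.null(contigs) && chrom %in% names(contigs) &&
               !is.na(contigs[[chrom]])) {
    genomic_interval(chrom, 0, contigs[[chrom]])
  } else {
    stop_validation("no contig length declared for '%s'; cannot infer termini", chrom)
  }
}

# build one derivative from its ordered junction list: segment i runs from
# junction i-1's incoming breakend (or the chromosome terminus) to junction
# i's outgoing breakend (or the terminus). Only left->right junctions
# (outgoing side "left", incoming side "right") are supported; inversion
# paths must be supplied as explicit derivatives.
derivative_from_junctions <- function(juncs, probes, flank, contigs, name) {
  ords <- vapply(juncs, function(j) j$ord %||% NA_integer_, 1L)
  if (!any(is.na(ords))) juncs <- juncs[order(ords)]
  k <- length(juncs)
  segs <- vector("list", k + 1L)
  for (i in seq_len(k + 1L)) {
    if (i == 1L) {
      be <- juncs[[1L]]$breakendA
      if (be$side != "left")
        stop_assembly("junction '%s': unsupported orientation for reconstruction",
                      juncs[[1L]]$event_id)
      span <- chrom_span(be$chrom, probes, flank, contigs)
      segs[[i]] <- segment_ref(genomic_interval(be$chrom, span$start, be$pos))
    } else if (i == k + 1L) {
      be <- juncs[[k]]$breakendB
      if (be$side != "right")
        stop_assembly("junction '%s': unsupported orientation for reconstruction",
                      juncs[[k]]$event_id)
      span <- chrom_span(be$chrom, probes, flank, contigs)
      segs[[i]] <- segment_ref(genomic_interval(be$chrom, be$pos, span$end))
    } else {
      from <- juncs[[i - 1L]]$breakendB
      to <- juncs[[i]]$breakendA
      if (from$side != "right" || to$side != "left" || from$chrom != to$chrom ||
            from$pos >= to$pos)
        stop_assembly("junctions '%s'/'%s' do not bound a forward segment",
                      juncs[[i - 1L]]$event_id, juncs[[i]]$event_id)
      segs[[i]] <- segment_ref(genomic_interval(from$chrom, from$pos, to$pos))
    }
  }
  assemble_derivative(juncs, segs, name)
}

#' Rebuild a genome configuration from structural-variant events
#'
#' Builds the diploid reference around the probes, then applies junctions
#' grouped by their `DERID` reconstruction hint (each group becomes one
#' derivative; `HOMREPL` consumes an intact homologue) and copy-number
#' segments (copy number 1 replaces a homologue with a deleted derivative,
#' 0 both homologues; >= 3 adds extra copies of the segment). Junctions
#' without hints each become one additional derivative. No genome-graph
#' path inference is attempted: the hints, or one-junction derivatives, fix
#' the layout.
#'
#' @param junctions,cn_segments As returned by [read_sv_vcf()] / [read_seg()].
#' @param probes Probe pair.
#' @param flank Reference flank for intact homologues.
#' @param contigs Named contig lengths for partner-chromosome termini.
#' @param clone_fraction Clone fraction of the rebuilt configuration.
#' @return A [genome_configuration()].
#' @export
config_from_events <- function(junctions, cn_segments = list(),
                               probes = default_probes(), flank = 1e6,
                               contigs = NULL, clone_fraction = 1) {
  pr <- validate_probes(probes)
  locus_span <- chrom_span(pr$five$interval$chrom, probes, flank, contigs)
  n_hom <- 2L
  ders <- list()

  derids <- vapply(junctions, function(j) {
    d <- j$derid %||% NA_character_
    if (is.null(d) || is.na(d)) paste0("der_", j$event_id) else d
  }, "")
  for (d in unique(derids)) {
    group <- junctions[derids == d]
    der <- derivative_from_junctions(group, probes, flank, contigs, d)
    if (any(vapply(group, function(j) isTRUE(j$homrepl), TRUE))) {
      if (n_hom < 1L) stop_assembly("derivative '%s' replaces a homologue but none remain", d)
      n_hom <- n_hom - 1L
    }
    ders[[length(ders) + 1L]] <- der
  }

  junction_ids <- vapply(junctions, function(j) j$event_id, "")
  for (s in cn_segments) {
    if (s$event_id %in% junction_ids) next  # CN already realised by a junction
    if (s$copy_number >= 3L) {
      for (k in seq_len(s$copy_number - 2L))
        ders[[length(ders) + 1L]] <- derivative_chromosome(
          list(segment_ref(s$interval)), sprintf("%s_copy%d", s$event_id, k))
    } else if (s$copy_number < 2L) {
      n_del <- 2L - s$copy_number
      if (n_hom < n_del)
        stop_assembly("CN segment '%s' deletes more homologues than remain", s$event_id)
      n_hom <- n_hom - n_del
      for (k in seq_len(n_del)) {
        segs <- list()
        if (s$interval$start > locus_span$start)
          segs <- c(segs, list(segment_ref(genomic_interval(
            locus_span$chrom, locus_span$start, s$interval$start))))
        if (s$interval$end < locus_span$end)
          segs <- c(segs, list(segment_ref(genomic_interval(
            locus_span$chrom, s$interval$end, locus_span$end))))
        ders[[length(ders) + 1L]] <- derivative_chromosome(
          segs, sprintf("%s_del%d", s$event_id, k))
      }
    }
  }

  homs <- lapply(seq_len(n_hom), function(i)
    derivative_chromosome(list(segment_ref(locus_span)), sprintf("hom%d", i)))
  genome_configuration(c(homs, ders), clone_fraction = clone_fraction,
                       label = "from_events")
}

# ---------------------------------------------------------------------------
# scenario triplet (VCF + SEG + truth JSON)

#' Write a scenario as a VCF + SEG + truth-JSON triplet
#'
#' @param scenario A `scenario` from [generate_scenario()].
#' @param prefix Output path prefix; writes `<prefix>.vcf`, `<prefix>.seg`,
#'   `<prefix>.truth.json`.
#' @param probes Probe pair (for contig header lengths).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_scenario_vcf <- function(scenario, prefix, probes = default_probes()) {
  cfg <- scenario$config
  # Derivatives that replace an intact homologue: the scenario keeps
  # n_homs intact copies, so the first (2 - n_homs) rearranged derivatives
  # each consumed one.
  dnames <- vapply(cfg$derivatives, function(d) d$name, "")
  rearranged <- dnames[vapply(cfg$derivatives, function(d)
    length(d$segments) > 1L, TRUE)]
  n_homs <- sum(grepl("^hom", dnames))
  replacing <- utils::head(rearranged, max(0L, 2L - n_homs))
  # annotate junctions with reconstruction hints from the derivative layout
  juncs <- list()
  for (der in cfg$derivatives) {
    if (length(der$segments) < 2L) next
    for (i in seq_len(length(der$segments) - 1L)) {
      out <- segment_outgoing(der$segments[[i]])
      inc <- segment_incoming(der$segments[[i + 1L]])
      match_j <- NULL
      for (j in scenario$junctions) {
        if ((breakend_matches(j$breakendA, out) && breakend_matches(j$breakendB, inc)) ||
            (breakend_matches(j$breakendB, out) && breakend_matches(j$breakendA, inc))) {
          match_j <- j
          break
        }
      }
      if (is.null(match_j)) next
      j <- junction(out$chrom, out$pos, out$side, inc$chrom, inc$pos, inc$side,
                    event_id = match_j$event_id,
                    partner_label = match_j$partner_label)
      j$derid <- der$name
      j$ord <- i
      j$homrepl <- der$name %in% replacing
      juncs[[length(juncs) + 1L]] <- j
    }
  }
  cn_out <- scenario$cn_segments
  pr <- validate_probes(probes)
  contigs <- c(stats::setNames(2.5e8, pr$five$interval$chrom),
               stats::setNames(PARTNER_LEN, PARTNER_CHROM))
  paths <- c(vcf = paste0(prefix, ".vcf"), seg = paste0(prefix, ".seg"),
             truth = paste0(prefix, ".truth.json"))
  write_sv_vcf(juncs, cn_out, paths[["vcf"]], contigs = contigs)
  write_seg(cn_out, paths[["seg"]])
  writeLines(serialize_scenario(scenario), paths[["truth"]])
  invisible(paths)
}

#' Rebuild a genome configuration from a scenario VCF/SEG pair
#'
#' @param vcf_path,seg_path Paths written by [write_scenario_vcf()] (or any
#'   VCF/SEG pair with the documented reconstruction hints).
#' @param probes Probe pair.
#' @param flank Homologue flank.
#' @param clone_fraction Clone fraction.
#' @return A [genome_configuration()].
#' @export
config_from_vcf <- function(vcf_path, seg_path = NULL,
                            probes = default_probes(), flank = 1e6,
                            clone_fraction = 1) {
  sv <- read_sv_vcf(vcf_path)
  cn <- sv$cn_segments
  if (!is.null(seg_path) && file.exists(seg_path)) {
    # SEG rows duplicating a VCF symbolic record (same span and copy number)
    # are informational, not additional events
    seg_key <- function(s) sprintf("%s:%.0f-%.0f:%d", s$interval$chrom,
                                   s$interval$start, s$interval$end, s$copy_number)
    have <- vapply(cn, seg_key, "")
    for (s in read_seg(seg_path)) if (!seg_key(s) %in% have) cn <- c(cn, list(s))
  }
  config_from_events(sv$junctions, cn, probes = probes, flank = flank,
                     contigs = sv$contigs, clone_fraction = clone_fraction)
}
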