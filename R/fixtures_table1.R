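# Loader for the packaged 14-case validation set: verbatim nuc ish strings,
# group labels, and illustrative derivative-chromosome reconstructions of
# the described WGS events. Coordinates in the fixture are reconstructions
# consistent with the described breakpoint positions relative to MYC, not
# published coordinates; the JSON carries a provenance note saying so.

fixture_path <- function() {
  system.file("extdata", "table1_cases.json", package = "bapfish")
}

build_case_derivative <- function(dspec, case_id) {
  segs <- lapply(dspec$segments, function(s)
    segment_ref(genomic_interval(s[[1]], as.numeric(s[[2]]), as.numeric(s[[3]])),
                s[[4]]))
  # derive one junction per non-contiguous adjacency and re-check the path
  # through assemble_derivative, so every fixture reconstruction passes the
  # same consistency gate as user-supplied derivatives
  juncs <- list()
  if (length(segs) > 1L) {
    for (i in seq_len(length(segs) - 1L)) {
      out <- segment_outgoing(segs[[i]])
      inc <- segment_incoming(segs[[i + 1L]])
      juncs[[i]] <- junction(out$chrom, out$pos, out$side,
                             inc$chrom, inc$pos, inc$side,
                             event_id = sprintf("case%d_%s_adj%d",
                                                case_id, dspec$name, i))
    }
  }
  assemble_derivative(juncs, segs, dspec$name)
}

build_case_config <- function(cspec, case_id) {
  ders <- lapply(cspec$derivatives, build_case_derivative, case_id = case_id)
  genome_configuration(ders,
                       clone_fraction = cspec$cells_observed / cspec$cells_total,
                       label = cspec$label)
}

parse_case_events <- function(case) {
  evs <- list()
  for (e in case$sv_events) {
    evs[[length(evs) + 1L]] <- junction(
      e$chromA, as.numeric(e$posA), e$sideA,
      e$chromB, as.numeric(e$posB), e$sideB,
      event_id = e$event_id, partner_label = e$partner_label %||% NA_character_)
  }
  for (e in case$cn_events) {
    evs[[length(evs) + 1L]] <- cn_segment(
      genomic_interval(e$chrom, as.numeric(e$start), as.numeric(e$end)),
      e$copy_number, event_id = e$event_id)
  }
  evs
}

#' Load the packaged 14-case validation set
#'
#' Each record carries the printed group label (RF/GF/RGF), the verbatim
#' nuc ish string, the partner gene (if any), the breakpoint position class
#' relative to *MYC*, flags for gene juxtaposition (vs pure copy-number
#' change) and MYC overexpression by IHC, the encoded structural-variant
#' events, and a per-clone genome reconstruction.
#'
#' @param path Fixture JSON path (default: packaged file).
#' @return A list of 14 `case_record` objects, each with fields `case_id`,
#'   `group`, `nuc_ish`, `wgs_summary`, `myc_breakpoint_side`, `partner`,
#'   `juxtaposition`, `ihc_overexpressed`, `events`, `configs` (one
#'   [genome_configuration()] per clone), and `dominant_config`.
#' @export
load_cases <- function(path = fixture_path()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cs <- doc$checksum
  if (is.null(doc$cases) || length(doc$cases) != (cs$n_cases %||% -1L))
    stop_validation("fixture file corrupt: expected %s cases, found %d",
                    format(cs$n_cases %||% "?"), length(doc$cases))
  records <- lapply(doc$cases, function(case) {
    if (!case$group %in% c("RF", "GF", "RGF"))
      stop_validation("fixture case %d: bad group '%s'", case$case_id, case$group)
    configs <- lapply(case$clones, build_case_config, case_id = case$case_id)
    fracs <- vapply(configs, function(cfg) cfg$clone_fraction, 1)
    structure(list(
      case_id = case$case_id,
      group = case$group,
      nuc_ish = case$nuc_ish,
      wgs_summary = case$wgs_summary,
      myc_breakpoint_side = case$myc_breakpoint_side,
      partner = case$partner %||% NA_character_,
      juxtaposition = isTRUE(case$juxtaposition),
      ihc_overexpressed = isTRUE(case$ihc_overexpressed),
      events = parse_case_events(case),
      configs = configs,
      dominant_config = configs[[which.max(fracs)]],
      reconstruction_note = case$reconstruction_note %||% NA_character_
    ), class = "case_record")
  })
  groups <- table(factor(vapply(records, function(r) r$group, ""),
                         levels = c("RF", "GF", "RGF")))
  want <- cs$groups
  if (!is.null(want) &&
      !(groups[["RF"]] == want$RF && groups[["GF"]] == want$GF &&
          groups[["RGF"]] == want$RGF))
    stop_validation("fixture file corrupt: group tallies do not match checksum")
  for (r in records) parse_nuc_ish(r$nuc_ish)   # strings must parse
  records
}

#' Region of the modeled MYC locus (probe footprints plus flanks)
#'
#' @param path Fixture JSON path.
#' @return A [genomic_interval()].
#' @export
myc_region <- function(path = fixture_path()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  genomic_interval(doc$myc_region$chrom, as.numeric(doc$myc_region$start),
                   as.numeric(doc$myc_region$end))
}

# does any encoded event of a record touch an interval?
record_events_overlap <- function(record, region) {
  any(vapply(record$events, function(e) {
    if (inherits(e, "junction")) {
      (e$breakendA$chrom == region$chrom &&
         e$breakendA$pos >= region$start && e$breakendA$pos < region$end) ||
        (e$breakendB$chrom == region$chrom &&
           e$breakendB$pos >= region$start && e$breakendB$pos < region$end)
    } else {
      interval_overlap(e$interval, region) > 0
    }
  }, TRUE))
}

#' Validate one fixture case end to end
#'
#' Runs the full pipeline on the encoded reconstruction -- simulate the
#' signal pattern of the dominant abnormal clone, classify, and reconcile
#' against the verbatim nuc ish string.
#'
#' @param record A `case_record` from [load_cases()].
#' @param params [sim_params()].
#' @param probes Probe pair.
#' @return A `reconciliation_report` (see [reconcile()]) with the case's
#'   encoded events attached.
#' @export
validate_concordance <- function(record, params = sim_params(),
                                 probes = default_probes()) {
  if (!inherits(record, "case_record"))
    stop_validation("record must be a case_record")
  reconcile(record$nuc_ish, record$dominant_config, probes = probes,
            params = params, sv_events = record$events)
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %d> group %s, partner %s, juxtaposition %s, IHC %s\n",
              x$case_id, x$group,
              if (is.na(x$partner) || is.null(x$partner)) "-" else x$partner,
              x$juxtaposition, x$ihc_overexpressed))
  cat("  ", x$nuc_ish, "\n")
  invisible(x)
}
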