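# Reconciliation of observed vs predicted patterns and guarded clinical
# interpretation of unbalanced break-apart results. The interpretation
# branches are data-driven (a JSON decision table shipped in extdata and
# overridable by the user) because the published guidance is prose, not an
# exhaustive flowchart.

PATTERN_CLASSES <- c("NORMAL", "RGF", "RF", "GF", "FUSION_CN", "AMBIGUOUS")

INTERPRETATION_CATEGORIES <- c(
  "NEGATIVE_WITH_FN_CAVEAT", "POSITIVE_MYC_REARRANGEMENT",
  "LIKELY_POSITIVE_RECOMMEND_TESTING", "CN_ALTERATION_NOT_CLASSIFIED_AS_R",
  "AMBIGUOUS_RECOMMEND_TESTING")

#' Ancillary findings accompanying a break-apart result
#'
#' @param dfish_igh_positive IGH/MYC dual-fusion FISH positive? `TRUE`,
#'   `FALSE` or `NA` (not done / unknown).
#' @param ihc_overexpressed MYC overexpressed by immunohistochemistry at the
#'   conventional >= 40% threshold? Tri-state as above.
#' @param partner_is_ig Known immunoglobulin partner? Tri-state as above.
#' @return An object of class `ancillary_findings`.
#' @export
ancillary_findings <- function(dfish_igh_positive = NA,
                               ihc_overexpressed = NA,
                               partner_is_ig = NA) {
  for (v in list(dfish_igh_positive, ihc_overexpressed, partner_is_ig))
    if (!is_flag(v)) stop_validation("ancillary flags must be TRUE, FALSE or NA")
  structure(list(dfish_igh_positive = dfish_igh_positive,
                 ihc_overexpressed = ihc_overexpressed,
                 partner_is_ig = partner_is_ig),
            class = "ancillary_findings")
}

#' Default interpretation decision table
#'
#' Reads the shipped JSON table mapping (pattern class, juxtaposition
#' status) to an interpretation category, narrative template and
#' recommended follow-up tests. Users may edit a copy and pass it to
#' [interpret_result()] to adjust branches.
#'
#' @param path Path to a decision-table JSON (default: packaged table).
#' @return A data frame with columns `pattern`, `juxtaposition`, `category`,
#'   `narrative`, and a list column `recommended_tests`.
#' @export
default_decision_table <- function(path = system.file("extdata",
                                                      "decision_table.json",
                                                      package = "bapfish")) {
  tab <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  stopifnot(all(c("pattern", "juxtaposition", "category", "narrative") %in% names(tab)))
  if (!is.list(tab$recommended_tests))
    tab$recommended_tests <- as.list(tab$recommended_tests)
  tab
}

# juxtaposition status: "confirmed" (a gene-juxtaposing SV is known),
# "cn_only" (work-up showed a pure copy-number change), "unknown"
juxtaposition_status <- function(ancillary, has_confirmed_juxtaposition) {
  if (isTRUE(has_confirmed_juxtaposition) ||
      isTRUE(ancillary$dfish_igh_positive) ||
      isTRUE(ancillary$partner_is_ig)) return("confirmed")
  if (isFALSE(has_confirmed_juxtaposition)) return("cn_only")
  "unknown"
}

#' Interpret a break-apart pattern class
#'
#' Renders the guarded interpretation for a pattern: a normal pattern is
#' negative with a caveat that break-apart testing alone carries a false
#' negative rate of at least 4%; a balanced RGF pattern is positive for a
#' *MYC* rearrangement; an unbalanced RF or GF pattern without further data
#' is "likely positive" with recommended confirmatory testing (IG/MYC
#' dual-fusion FISH, MYC immunohistochemistry, WGS or RNA-seq); with a
#' confirmed gene juxtaposition it is positive, and with a confirmed pure
#' copy-number change it is a CN alteration not classified as a
#' rearrangement. A fusion-count change without isolated signals is likewise
#' a CN alteration.
#'
#' @param pattern A pattern class string (see [classify_pattern()]).
#' @param ancillary An [ancillary_findings()] object.
#' @param has_confirmed_juxtaposition `TRUE` if orthogonal testing confirmed
#'   a gene-juxtaposing SV, `FALSE` if it confirmed a pure copy-number
#'   change, `NA` if unknown. This is an input, not an inference.
#' @param table Decision table (see [default_decision_table()]).
#' @return An object of class `interpretation` with fields `category`,
#'   `narrative`, `recommended_tests`, `pattern`, `juxtaposition`.
#' @export
interpret_result <- function(pattern, ancillary = ancillary_findings(),
                             has_confirmed_juxtaposition = NA,
                             table = default_decision_table()) {
  if (!pattern %in% PATTERN_CLASSES)
    stop_validation("unknown pattern class '%s'", pattern)
  if (!inherits(ancillary, "ancillary_findings"))
    stop_validation("ancillary must be ancillary_findings")
  status <- juxtaposition_status(ancillary, has_confirmed_juxtaposition)
  hit <- which((table$pattern == pattern | table$pattern == "*") &
                 (table$juxtaposition == status | table$juxtaposition == "*"))
  if (length(hit) == 0L)
    stop_validation("decision table has no row for pattern %s / juxtaposition %s",
                    pattern, status)
  row <- hit[1L]
  tests <- table$recommended_tests[[row]]
  if (is.null(tests) || all(is.na(tests))) tests <- character()
  structure(list(category = table$category[row],
                 narrative = table$narrative[row],
                 recommended_tests = as.character(tests),
                 pattern = pattern, juxtaposition = status),
            class = "interpretation")
}

#' Reconcile an observed nuc ish result with a genome configuration
#'
#' Classifies the observed result (dominant abnormal clone), simulates the
#' pattern the supplied genome configuration would produce, compares the two
#' classes, and explains the unbalance direction through the copy numbers of
#' the two probe footprints. In reconciled unbalanced cases the side with
#' more isolated signals is the side at higher copy number: material 5' of
#' *MYC* for RF-type patterns, 3' for GF-type.
#'
#' @param observed A nuc ish string or [nuc_ish_result()].
#' @param config The WGS-derived [genome_configuration()].
#' @param probes Probe pair.
#' @param params [sim_params()].
#' @param sv_events Optional list of event descriptions carried through to
#'   the report.
#' @param ploidy Expected fusion count of an unrearranged genome.
#' @return An object of class `reconciliation_report` with fields
#'   `observed_class`, `predicted_class`, `concordant`, `cn_five_prime`,
#'   `cn_three_prime`, `cn_explanation`, `sv_events`.
#' @export
reconcile <- function(observed, config, probes = default_probes(),
                      params = sim_params(), sv_events = list(), ploidy = 2L) {
  if (is.character(observed)) observed <- parse_nuc_ish(observed)
  if (!inherits(observed, "nuc_ish_result"))
    stop_validation("observed must be a nuc_ish_result or string")
  pr <- validate_probes(probes)
  observed_class <- classify_result(observed, ploidy)
  pattern <- simulate_signals(config, probes, params)
  predicted_class <- classify_pattern(pattern, ploidy)
  cn5 <- footprint_copy_number(config, pr$five)
  cn3 <- footprint_copy_number(config, pr$three)
  direction <- if (cn5 > cn3) "CN(5') > CN(3')"
               else if (cn3 > cn5) "CN(3') > CN(5')"
               else "CN(5') = CN(3')"
  explanation <- sprintf(
    "5' (red) footprint copy number %.2f, 3' (green) footprint copy number %.2f: %s",
    cn5, cn3, direction)
  structure(list(observed_class = observed_class,
                 predicted_class = predicted_class,
                 concordant = identical(observed_class, predicted_class),
                 cn_five_prime = cn5, cn_three_prime = cn3,
                 cn_explanation = explanation,
                 predicted_pattern = pattern,
                 sv_events = sv_events),
            class = "reconciliation_report")
}

#' Survey percentages with half-up rounding
#'
#' @param items Data frame with columns `label`, `k`, `n` (or a list of
#'   such triples). Requires `0 <= k <= n`, `n > 0`.
#' @return Data frame with columns `label`, `k`, `n`, `percent`, where
#'   `percent = round-half-up(100 k / n)` as an integer.
#' @export
#' @examples
#' survey_percentages(data.frame(label = "BAP only", k = 23, n = 54))
survey_percentages <- function(items) {
  if (is.list(items) && !is.data.frame(items))
    items <- do.call(rbind, lapply(items, function(x)
      data.frame(label = x[[1]], k = as.numeric(x[[2]]), n = as.numeric(x[[3]]))))
  if (!all(c("label", "k", "n") %in% names(items)))
    stop_validation("items need columns label, k, n")
  if (any(items$n <= 0)) stop_validation("survey denominators must be positive")
  if (any(items$k < 0 | items$k > items$n))
    stop_validation("survey counts must satisfy 0 <= k <= n")
  items$percent <- as.integer(round_half_up(100 * items$k / items$n))
  items
}

#' Packaged survey counts
#'
#' Laboratory-practice survey tallies (54 respondents) shipped with the
#' package for the `survey` CLI subcommand and the worked examples.
#'
#' @return Data frame with columns `label`, `k`, `n`.
#' @export
packaged_survey_counts <- function() {
  read.delim(system.file("extdata", "survey_counts.tsv", package = "bapfish"),
             stringsAsFactors = FALSE)
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat(sprintf("<reconciliation_report> observed %s, predicted %s (%s)\n",
              x$observed_class, x$predicted_class,
              if (x$concordant) "concordant" else "DISCORDANT"))
  cat(" ", x$cn_explanation, "\n")
  invisible(x)
}

#' @export
print.interpretation <- function(x, ...) {
  cat(sprintf("<interpretation> %s (pattern %s, juxtaposition %s)\n",
              x$category, x$pattern, x$juxtaposition))
  cat(" ", x$narrative, "\n")
  if (length(x$recommended_tests))
    cat("  recommended:", paste(x$recommended_tests, collapse = ", "), "\n")
  invisible(x)
}
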