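# In-silico hybridisation of the break-apart probe pair against a genome
# configuration, fusion calling by colocalisation distance, and pattern
# classification.

#' Simulation parameters
#'
#' @param d_fuse Base distance on a derivative below which a red and a green
#'   spot merge into one fusion signal. Interphase colocalisation resolution
#'   is an assay property, not a published number; the default (1 Mb) is a
#'   documented assumption and all shipped reconstructions are insensitive
#'   to halving or doubling it.
#' @param min_visible_frac Minimum fraction of a probe footprint that must be
#'   present in one contiguous run to emit a visible spot (default 0.3).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(d_fuse = 1e6, min_visible_frac = 0.3) {
  if (!is.numeric(d_fuse) || length(d_fuse) != 1L || is.na(d_fuse) || d_fuse <= 0)
    stop_validation("d_fuse must be a positive base distance")
  if (!is.numeric(min_visible_frac) || length(min_visible_frac) != 1L ||
      is.na(min_visible_frac) || min_visible_frac <= 0 || min_visible_frac > 1)
    stop_validation("min_visible_frac must be in (0, 1]")
  structure(list(d_fuse = d_fuse, min_visible_frac = min_visible_frac),
            class = "sim_params")
}

#' Simulated break-apart signal pattern
#'
#' @param n_red_isolated,n_green_isolated,n_fusion Non-negative spot counts.
#' @param clone_fraction Fraction of cells carrying the configuration.
#' @param spots Optional data frame of emitted spots (one row per spot).
#' @return An object of class `simulated_pattern`.
#' @export
simulated_pattern <- function(n_red_isolated, n_green_isolated, n_fusion,
                              clone_fraction = 1, spots = NULL) {
  for (v in list(n_red_isolated, n_green_isolated, n_fusion))
    if (!is_count1(v)) stop_validation("signal counts must be non-negative integers")
  structure(list(n_red_isolated = as.integer(n_red_isolated),
                 n_green_isolated = as.integer(n_green_isolated),
                 n_fusion = as.integer(n_fusion),
                 clone_fraction = clone_fraction,
                 spots = spots),
            class = "simulated_pattern")
}

# Project the parts of `fp` carried by a derivative onto the derivative's
# own coordinate system and merge touching pieces into maximal runs.
# Returns a data frame with one row per run: start, end, bases.
project_footprint_runs <- function(der, fp) {
  pieces <- list()
  offset <- 0
  for (seg in der$segments) {
    w <- interval_width(seg$interval)
    ov_start <- max(seg$interval$start, fp$start)
    ov_end <- min(seg$interval$end, fp$end)
    if (seg$interval$chrom == fp$chrom && ov_start < ov_end) {
      if (seg$orientation == "+") {
        d0 <- offset + (ov_start - seg$interval$start)
        d1 <- offset + (ov_end - seg$interval$start)
      } else {
        d0 <- offset + (seg$interval$end - ov_end)
        d1 <- offset + (seg$interval$end - ov_start)
      }
      pieces[[length(pieces) + 1L]] <- c(d0, d1)
    }
    offset <- offset + w
  }
  if (length(pieces) == 0L)
    return(data.frame(start = numeric(), end = numeric(), bases = numeric()))
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1L]), , drop = FALSE]
  runs <- list(m[1L, ])
  if (nrow(m) > 1L) for (k in 2L:nrow(m)) {
    last <- runs[[length(runs)]]
    if (m[k, 1L] <= last[2L]) {
      runs[[length(runs)]] <- c(last[1L], max(last[2L], m[k, 2L]))
    } else {
      runs[[length(runs) + 1L]] <- m[k, ]
    }
  }
  out <- do.call(rbind, runs)
  # pieces from distinct segments occupy disjoint derivative ranges, so the
  # run width equals the probe bases it carries
  data.frame(start = out[, 1L], end = out[, 2L], bases = out[, 2L] - out[, 1L])
}

# gap between two spot spans on the same derivative (0 when they touch/overlap)
span_gap <- function(a_start, a_end, b_start, b_end) {
  max(0, max(a_start, b_start) - min(a_end, b_end))
}

#' Simulate the break-apart signal pattern of a genome configuration
#'
#' Every maximal contiguous run of probe-footprint bases on a derivative
#' whose length is at least `min_visible_frac` of the footprint emits one
#' spot. Within each derivative, red and green spots whose gap is at most
#' `d_fuse` are merged into fusion signals by greedy nearest-pair matching
#' (each spot used once; ties broken left-to-right on the red then the green
#' spot position, so the procedure is deterministic). Unmerged spots are
#' isolated signals.
#'
#' @param config A [genome_configuration()].
#' @param probes Probe pair (default [default_probes()]).
#' @param params A [sim_params()].
#' @return A [simulated_pattern()] carrying the emitted spot table.
#' @export
#' @examples
#' simulate_signals(build_diploid_reference(default_probes()))
simulate_signals <- function(config, probes = default_probes(),
                             params = sim_params()) {
  if (!inherits(config, "genome_configuration"))
    stop_validation("config must be a genome_configuration")
  pr <- validate_probes(probes)
  if (!inherits(params, "sim_params")) stop_validation("params must be sim_params")

  spot_rows <- list()
  for (der in config$derivatives) {
    for (p in list(pr$five, pr$three)) {
      runs <- project_footprint_runs(der, p$interval)
      if (nrow(runs) == 0L) next
      fpw <- interval_width(p$interval)
      for (k in seq_len(nrow(runs))) {
        frac <- runs$bases[k] / fpw
        if (frac >= params$min_visible_frac) {
          spot_rows[[length(spot_rows) + 1L]] <- data.frame(
            derivative = der$name, color = p$color,
            start = runs$start[k], end = runs$end[k],
            intensity_fraction = min(1, frac))
        }
      }
    }
  }
  spots <- if (length(spot_rows)) do.call(rbind, spot_rows)
           else data.frame(derivative = character(), color = character(),
                           start = numeric(), end = numeric(),
                           intensity_fraction = numeric())

  n_fusion <- 0L
  spots$fused <- rep(FALSE, nrow(spots))
  for (dname in unique(spots$derivative)) {
    reds <- which(spots$derivative == dname & spots$color == "RED")
    greens <- which(spots$derivative == dname & spots$color == "GREEN")
    repeat {
      free_r <- reds[!spots$fused[reds]]
      free_g <- greens[!spots$fused[greens]]
      if (length(free_r) == 0L || length(free_g) == 0L) break
      best <- NULL
      for (r in free_r) for (g in free_g) {
        gap <- span_gap(spots$start[r], spots$end[r], spots$start[g], spots$end[g])
        if (gap > params$d_fuse) next
        # smaller gap wins; ties broken by leftmost red, then leftmost green
        key <- c(gap, spots$start[r], spots$start[g])
        if (is.null(best) || lex_less(key, best$key))
          best <- list(r = r, g = g, key = key)
      }
      if (is.null(best)) break
      spots$fused[c(best$r, best$g)] <- TRUE
      n_fusion <- n_fusion + 1L
    }
  }
  n_red <- sum(!spots$fused & spots$color == "RED")
  n_green <- sum(!spots$fused & spots$color == "GREEN")
  simulated_pattern(n_red, n_green, n_fusion,
                    clone_fraction = config$clone_fraction, spots = spots)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# classification of scalar counts at one endpoint
classify_counts <- function(r_iso, g_iso, fusion, ploidy) {
  if (r_iso >= 1 && g_iso >= 1) return("RGF")
  if (r_iso >= 1) return("RF")
  if (g_iso >= 1) return("GF")
  if (fusion == ploidy) "NORMAL" else "FUSION_CN"
}

#' Classify a break-apart signal pattern
#'
#' Categories follow the RGF/RF/GF convention: `RGF` when both isolated red
#' and isolated green signals are present (classical balanced separation),
#' `RF` for isolated red without isolated green, `GF` the converse, `NORMAL`
#' when no isolated signals are present and the fusion count equals the
#' ploidy, `FUSION_CN` when only the fusion copy number deviates, and
#' `AMBIGUOUS` when the two endpoints of a count range classify differently.
#'
#' @param summary A `signal_summary` (from [summarize_clone()]) or a
#'   `simulated_pattern` (from [simulate_signals()]).
#' @param ploidy Expected fusion count of an unrearranged genome (default 2).
#' @return One of `"NORMAL"`, `"RGF"`, `"RF"`, `"GF"`, `"FUSION_CN"`,
#'   `"AMBIGUOUS"`.
#' @export
classify_pattern <- function(summary, ploidy = 2L) {
  if (inherits(summary, "simulated_pattern")) {
    return(classify_counts(summary$n_red_isolated, summary$n_green_isolated,
                           summary$n_fusion, ploidy))
  }
  if (!inherits(summary, "signal_summary"))
    stop_validation("summary must be a signal_summary or simulated_pattern")
  lo <- classify_counts(summary$r_isolated[1], summary$g_isolated[1],
                        summary$fusion[1], ploidy)
  hi <- classify_counts(summary$r_isolated[2], summary$g_isolated[2],
                        summary$fusion[2], ploidy)
  if (lo == hi) lo else "AMBIGUOUS"
}

#' Classify a whole nuc ish result by its dominant abnormal clone
#'
#' The dominant abnormal clone is the non-NORMAL clone observed in the most
#' cells (first wins on ties); a result whose clones are all normal
#' classifies `NORMAL`.
#'
#' @param result A [nuc_ish_result()] or a nuc ish string.
#' @param ploidy Passed to [classify_pattern()].
#' @return Pattern class string.
#' @export
classify_result <- function(result, ploidy = 2L) {
  if (is.character(result)) result <- parse_nuc_ish(result)
  cl <- dominant_abnormal_clone(result, ploidy)
  if (is.null(cl)) "NORMAL" else classify_pattern(summarize_clone(cl), ploidy)
}

# the abnormal clone with the largest cells_observed, or NULL
dominant_abnormal_clone <- function(result, ploidy = 2L) {
  classes <- vapply(result$clones, function(cl)
    classify_pattern(summarize_clone(cl), ploidy), "")
  abnormal <- which(classes != "NORMAL")
  if (length(abnormal) == 0L) return(NULL)
  obs <- vapply(result$clones[abnormal], function(cl) cl$cells_observed, 1L)
  result$clones[[abnormal[which.max(obs)]]]
}

#' Express a simulated pattern as nuc ish nomenclature
#'
#' Closes the simulate-to-nomenclature loop: the emitted result, when
#' summarised with [summarize_clone()], reproduces the pattern's isolated
#' and fusion counts. Balanced patterns (equal red and green totals) are
#' written in the `(MYCxN)(5'MYC sep 3'MYCxS)` form used for classical
#' rearrangements; unbalanced patterns in the explicit
#' `(5'MYCxR,3'MYCxG)(5'MYC con 3'MYCxF)` form.
#'
#' @param pattern A [simulated_pattern()].
#' @param cells_total Cells scored for the emitted clone (default 100).
#' @return A [nuc_ish_result()] with a single clone.
#' @export
pattern_to_iscn <- function(pattern, cells_total = 100L) {
  if (!inherits(pattern, "simulated_pattern"))
    stop_validation("pattern must be a simulated_pattern")
  r_total <- pattern$n_red_isolated + pattern$n_fusion
  g_total <- pattern$n_green_isolated + pattern$n_fusion
  if (r_total == 0L && g_total == 0L)
    stop_validation("pattern has no signals at all; nothing to express")
  observed <- max(1L, round_half_up(pattern$clone_fraction * cells_total))
  sep_n <- min(r_total, g_total) - pattern$n_fusion
  if (r_total == g_total) {
    counts <- list(probe_count("MYC_BOTH", count_interval(r_total)))
    relations <- if (sep_n > 0L)
      list(relation_term("SEP", count_interval(sep_n))) else list()
  } else {
    counts <- list(probe_count("FIVE_PRIME_MYC", count_interval(r_total)),
                   probe_count("THREE_PRIME_MYC", count_interval(g_total)))
    relations <- list(relation_term("CON", count_interval(pattern$n_fusion)))
  }
  nuc_ish_result(list(nuc_ish_clone(counts, relations, observed, cells_total)))
}

#' @export
print.simulated_pattern <- function(x, ...) {
  cat(sprintf("<simulated_pattern> %dR %dG %dF (clone fraction %.2f) -> %s\n",
              x$n_red_isolated, x$n_green_isolated, x$n_fusion,
              x$clone_fraction, classify_pattern(x)))
  invisible(x)
}
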