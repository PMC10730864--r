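# ISCN "nuc ish" layer for the two-probe MYC break-apart assay.
#
# The printed nomenclature mixes typographic variants (prime U+2032, right
# single quote U+2019, ASCII apostrophe; tilde U+223C vs ASCII ~ vs hyphen
# ranges; interior whitespace). parse_nuc_ish() normalises all of these to a
# canonical dialect before tokenising, so the verbatim published strings and
# their canonical re-emissions parse to identical structures.

PROBE_TOKENS <- c("5'MYC" = "FIVE_PRIME_MYC",
                  "3'MYC" = "THREE_PRIME_MYC",
                  "MYC"   = "MYC_BOTH")

#' Count interval
#'
#' Signal counts in nuc ish nomenclature may be ranges ("x2~3"); a plain
#' count is the degenerate interval `[n, n]`.
#'
#' @param lo,hi Non-negative integers with `lo <= hi`.
#' @return An object of class `count_interval`.
#' @export
count_interval <- function(lo, hi = lo) {
  if (!is_count1(lo) || !is_count1(hi))
    stop_validation("count interval endpoints must be non-negative integers")
  if (lo > hi)
    stop_validation("count interval lo (%d) exceeds hi (%d)", lo, hi)
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "count_interval")
}

#' Probe count term
#'
#' @param probe `"FIVE_PRIME_MYC"`, `"THREE_PRIME_MYC"` or `"MYC_BOTH"`
#'   (the printed bare token "MYC", meaning both probes share the count).
#' @param count A [count_interval()].
#' @return An object of class `probe_count`.
#' @export
probe_count <- function(probe, count) {
  if (!probe %in% PROBE_TOKENS)
    stop_validation("unknown probe '%s'", probe)
  if (!inherits(count, "count_interval"))
    stop_validation("count must be a count_interval")
  structure(list(probe = probe, count = count), class = "probe_count")
}

#' Relation term ("con" or "sep")
#'
#' @param kind `"CON"` (colocalised) or `"SEP"` (separated).
#' @param count A [count_interval()].
#' @return An object of class `relation_term`.
#' @export
relation_term <- function(kind, count) {
  if (!kind %in% c("CON", "SEP"))
    stop_validation("relation kind must be CON or SEP")
  if (!inherits(count, "count_interval"))
    stop_validation("count must be a count_interval")
  structure(list(kind = kind, count = count), class = "relation_term")
}

#' One clone of a nuc ish result
#'
#' @param probe_counts List of [probe_count()] terms.
#' @param relations List of [relation_term()]s (at most one; con and sep in
#'   the same clone are rejected).
#' @param cells_observed,cells_total Cells carrying this clone over cells
#'   scored, `0 < cells_observed <= cells_total`.
#' @return An object of class `nuc_ish_clone`.
#' @export
nuc_ish_clone <- function(probe_counts, relations = list(),
                          cells_observed = 100L, cells_total = 100L) {
  if (length(probe_counts) == 0L)
    stop_validation("a clone needs at least one probe count")
  kinds <- vapply(relations, function(r) r$kind, "")
  if ("CON" %in% kinds && "SEP" %in% kinds)
    stop_validation("a clone cannot carry both con and sep relation terms")
  if (!is_count1(cells_observed) || !is_count1(cells_total) ||
      cells_observed < 1 || cells_observed > cells_total)
    stop_validation("cells_observed (%s) must satisfy 0 < observed <= total (%s)",
                    format(cells_observed), format(cells_total))
  structure(list(probe_counts = probe_counts, relations = relations,
                 cells_observed = as.integer(cells_observed),
                 cells_total = as.integer(cells_total)),
            class = "nuc_ish_clone")
}

#' A parsed nuc ish result (one or more clones)
#'
#' @param clones Non-empty list of [nuc_ish_clone()]s.
#' @param raw_text The input string the result was parsed from, if any.
#' @return An object of class `nuc_ish_result`.
#' @export
nuc_ish_result <- function(clones, raw_text = NA_character_) {
  if (length(clones) == 0L)
    stop_validation("a nuc ish result needs at least one clone")
  total <- clones[[1L]]$cells_total
  observed <- sum(vapply(clones, function(cl) cl$cells_observed, 1L))
  if (observed > total)
    stop_validation("clone cell counts sum to %d, exceeding the %d cells scored",
                    observed, total)
  structure(list(clones = clones, raw_text = raw_text),
            class = "nuc_ish_result")
}

# ---------------------------------------------------------------------------
# normalisation

# Character normalisation: prime variants to ASCII apostrophe, tilde variants
# to "~", hyphen range separators between digits to "~", whitespace dropped.
normalize_nuc_ish <- function(text) {
  s <- text
  s <- gsub("′|’|´|ʹ", "'", s)
  s <- gsub("∼|~", "~", s)
  s <- gsub("(?<=[0-9])\\s*[-–]\\s*(?=[0-9])", "~", s, perl = TRUE)
  s <- gsub("\\s+", "", s)
  s
}

# ---------------------------------------------------------------------------
# recursive-descent parser over the normalised string

new_cursor <- function(s) {
  e <- new.env(parent = emptyenv())
  e$s <- s
  e$i <- 1L
  e
}

cur_eof <- function(cur) cur$i > nchar(cur$s)
cur_peek <- function(cur, n = 1L) substr(cur$s, cur$i, cur$i + n - 1L)
cur_take <- function(cur, n = 1L) {
  out <- cur_peek(cur, n); cur$i <- cur$i + n; out
}
cur_expect <- function(cur, token) {
  if (cur_peek(cur, nchar(token)) != token)
    stop_parse("expected '%s'", token, offset = cur$i)
  cur_take(cur, nchar(token))
}

take_integer <- function(cur) {
  m <- regmatches(substr(cur$s, cur$i, nchar(cur$s)),
                  regexpr("^[0-9]+", substr(cur$s, cur$i, nchar(cur$s))))
  if (length(m) == 0L) stop_parse("expected a number", offset = cur$i)
  cur$i <- cur$i + nchar(m)
  as.integer(m)
}

# "x2" or "x2~4"
take_count <- function(cur) {
  cur_expect(cur, "x")
  lo <- take_integer(cur)
  hi <- lo
  if (cur_peek(cur) == "~") { cur_take(cur); hi <- take_integer(cur) }
  if (lo > hi) stop_parse("count range %d~%d is decreasing", lo, hi, offset = cur$i)
  count_interval(lo, hi)
}

take_probe_name <- function(cur) {
  for (tok in names(PROBE_TOKENS)) {   # longest tokens listed first
    if (cur_peek(cur, nchar(tok)) == tok) {
      cur_take(cur, nchar(tok))
      return(PROBE_TOKENS[[tok]])
    }
  }
  stop_parse("expected a probe name (5'MYC, 3'MYC or MYC)", offset = cur$i)
}

# one parenthesised group, returned as either probe counts or a relation term
take_group <- function(cur) {
  cur_expect(cur, "(")
  first <- take_probe_name(cur)
  nxt <- cur_peek(cur, 3L)
  if (nxt %in% c("con", "sep")) {
    kind <- toupper(cur_take(cur, 3L))
    second <- take_probe_name(cur)
    if (second == first)
      stop_parse("relation term repeats probe '%s'", second, offset = cur$i)
    count <- take_count(cur)
    cur_expect(cur, ")")
    return(list(type = "relation", term = relation_term(kind, count)))
  }
  # probe-count group; members may omit the count if a shared multiplier
  # follows the closing parenthesis, as in "(5'MYC,3'MYC)x2~4"
  members <- list(list(probe = first,
                       count = if (cur_peek(cur) == "x") take_count(cur) else NULL))
  while (cur_peek(cur) == ",") {
    cur_take(cur)
    p <- take_probe_name(cur)
    members <- c(members, list(list(
      probe = p, count = if (cur_peek(cur) == "x") take_count(cur) else NULL)))
  }
  cur_expect(cur, ")")
  shared <- NULL
  if (cur_peek(cur) == "x") shared <- take_count(cur)
  counts <- lapply(members, function(m) {
    if (!is.null(m$count) && !is.null(shared))
      stop_parse("probe '%s' has both its own count and a shared multiplier",
                 m$probe, offset = cur$i)
    cnt <- m$count %||% shared
    if (is.null(cnt))
      stop_parse("probe '%s' has no count", m$probe, offset = cur$i)
    probe_count(m$probe, cnt)
  })
  list(type = "counts", counts = counts)
}

# "[97/100]" or "[100]" (all scored cells abnormal)
take_cells <- function(cur) {
  cur_expect(cur, "[")
  a <- take_integer(cur)
  b <- a
  if (cur_peek(cur) == "/") { cur_take(cur); b <- take_integer(cur) }
  cur_expect(cur, "]")
  if (a > b)
    stop_parse("cells observed (%d) exceed cells scored (%d)", a, b,
               offset = cur$i)
  list(observed = a, total = b)
}

take_clone <- function(cur) {
  counts <- list()
  relations <- list()
  while (cur_peek(cur) == "(") {
    g <- take_group(cur)
    if (g$type == "counts") counts <- c(counts, g$counts)
    else relations <- c(relations, list(g$term))
  }
  if (length(counts) == 0L)
    stop_parse("clone has no probe counts", offset = cur$i)
  cells <- if (cur_peek(cur) == "[") take_cells(cur)
           else list(observed = 100L, total = 100L)
  nuc_ish_clone(counts, relations, cells$observed, cells$total)
}

#' Parse an ISCN "nuc ish" string
#'
#' Accepts the published dialect mix: Unicode prime or right-quote or ASCII
#' apostrophe for the 5'/3' qualifier, `~` / `∼` / hyphen range
#' separators, interior whitespace, a stray comma after the `nuc ish`
#' prefix, shared-multiplier probe groups (`(5'MYC,3'MYC)x2~4`) and multiple
#' clones separated by `/`. A clone without a bracketed cell count defaults
#' to `[100]`.
#'
#' @param text A single nuc ish string.
#' @return A [nuc_ish_result()]; `raw_text` keeps the input.
#' @export
#' @examples
#' res <- parse_nuc_ish("nuc ish(5'MYCx2,3'MYCx1)(5'MYC con 3'MYCx1)[100]")
#' summarize_clone(res$clones[[1]])
parse_nuc_ish <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop_parse("input must be a non-empty string")
  s <- normalize_nuc_ish(text)
  cur <- new_cursor(s)
  if (cur_peek(cur, 6L) != "nucish")
    stop_parse("nuc ish results must start with 'nuc ish'", offset = 1L)
  cur_take(cur, 6L)
  if (cur_peek(cur) == ",") cur_take(cur)   # Table-style stray comma
  clones <- list(take_clone(cur))
  while (cur_peek(cur) == "/") {
    cur_take(cur)
    clones <- c(clones, list(take_clone(cur)))
  }
  if (!cur_eof(cur))
    stop_parse("unexpected trailing text '%s'",
               substr(cur$s, cur$i, nchar(cur$s)), offset = cur$i)
  nuc_ish_result(clones, raw_text = text)
}

# ---------------------------------------------------------------------------
# summaries

clone_color_total <- function(clone, which) {
  keep <- vapply(clone$probe_counts, function(pc)
    pc$probe %in% c(which, "MYC_BOTH"), TRUE)
  if (!any(keep)) return(c(0L, 0L))
  lo <- sum(vapply(clone$probe_counts[keep], function(pc) pc$count$lo, 1L))
  hi <- sum(vapply(clone$probe_counts[keep], function(pc) pc$count$hi, 1L))
  c(lo, hi)
}

#' Derive red/green/fusion signal totals for one clone
#'
#' The fusion count F is taken directly from a `con` term when present;
#' with a `sep` term, `F = min(R, G) - SEP`; with no relation term,
#' `F = min(R, G)` (an intact or purely copy-altered locus fuses whatever
#' it can). Isolated counts are `R - F` and `G - F`. All quantities are
#' evaluated at both interval endpoints, so a printed range such as
#' `x2~3` propagates to the summary as a range.
#'
#' @param clone A [nuc_ish_clone()].
#' @return An object of class `signal_summary` with fields `r_total`,
#'   `g_total`, `fusion`, `r_isolated`, `g_isolated`, each a length-2
#'   numeric `(lo endpoint, hi endpoint)`, plus the clone's cell fraction.
#'   A negative fusion or isolated count at either endpoint raises an
#'   inconsistent-nomenclature error.
#' @export
summarize_clone <- function(clone) {
  if (!inherits(clone, "nuc_ish_clone"))
    stop_validation("clone must be a nuc_ish_clone")
  r <- clone_color_total(clone, "FIVE_PRIME_MYC")
  g <- clone_color_total(clone, "THREE_PRIME_MYC")
  kinds <- vapply(clone$relations, function(t) t$kind, "")
  f <- if ("CON" %in% kinds) {
    con <- clone$relations[kinds == "CON"]
    c(sum(vapply(con, function(t) t$count$lo, 1L)),
      sum(vapply(con, function(t) t$count$hi, 1L)))
  } else if ("SEP" %in% kinds) {
    sep <- clone$relations[kinds == "SEP"]
    pmin(r, g) - c(sum(vapply(sep, function(t) t$count$lo, 1L)),
                   sum(vapply(sep, function(t) t$count$hi, 1L)))
  } else {
    pmin(r, g)
  }
  r_iso <- r - f
  g_iso <- g - f
  if (any(c(f, r_iso, g_iso) < 0))
    stop_validation(
      "inconsistent nomenclature: negative fusion or isolated count (R=%d~%d, G=%d~%d, F=%d~%d)",
      r[1], r[2], g[1], g[2], f[1], f[2])
  structure(list(r_total = r, g_total = g, fusion = f,
                 r_isolated = r_iso, g_isolated = g_iso,
                 cell_fraction = clone$cells_observed / clone$cells_total),
            class = "signal_summary")
}

# ---------------------------------------------------------------------------
# canonical writer

format_count <- function(ci) {
  if (ci$lo == ci$hi) sprintf("x%d", ci$lo) else sprintf("x%d~%d", ci$lo, ci$hi)
}

probe_display <- function(probe) {
  names(PROBE_TOKENS)[match(probe, PROBE_TOKENS)]
}

format_clone <- function(clone) {
  counts <- paste(vapply(clone$probe_counts, function(pc)
    paste0(probe_display(pc$probe), format_count(pc$count)), ""), collapse = ",")
  rel <- vapply(clone$relations, function(t)
    sprintf("(5'MYC %s 3'MYC%s)", tolower(t$kind), format_count(t$count)), "")
  cells <- if (clone$cells_observed == clone$cells_total)
    sprintf("[%d]", clone$cells_total)
  else sprintf("[%d/%d]", clone$cells_observed, clone$cells_total)
  paste0("(", counts, ")", paste(rel, collapse = ""), cells)
}

#' Re-emit a nuc ish result in the canonical dialect
#'
#' Canonical form uses the ASCII apostrophe for the prime mark, `~` for
#' ranges, no interior whitespace, and `[n]` when every scored cell carries
#' the clone. `parse_nuc_ish(format_nuc_ish(x))` is structurally equal to
#' `x` (ignoring `raw_text`).
#'
#' @param result A [nuc_ish_result()].
#' @return A single string.
#' @export
format_nuc_ish <- function(result) {
  if (!inherits(result, "nuc_ish_result"))
    stop_validation("result must be a nuc_ish_result")
  paste0("nuc ish",
         paste(vapply(result$clones, format_clone, ""), collapse = "/"))
}

# structural equality of parsed results, ignoring provenance text
nuc_ish_equal <- function(a, b) {
  a$raw_text <- b$raw_text <- NULL
  identical(unclass_deep(a), unclass_deep(b))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.nuc_ish_result <- function(x, ...) {
  cat(format_nuc_ish(x), "\n")
  invisible(x)
}

#' @export
print.signal_summary <- function(x, ...) {
  fmt <- function(v) if (v[1] == v[2]) sprintf("%d", v[1]) else sprintf("%d~%d", v[1], v[2])
  cat(sprintf("<signal_summary> R=%s G=%s F=%s (isolated R=%s, G=%s)\n",
              fmt(x$r_total), fmt(x$g_total), fmt(x$fusion),
              fmt(x$r_isolated), fmt(x$g_isolated)))
  invisible(x)
}
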