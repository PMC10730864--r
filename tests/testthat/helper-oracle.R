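# Independent naive oracles used to cross-check the interval-arithmetic
# implementation. Everything here works base by base on a miniature locus
# (a few kb), which is exact but far too slow for real coordinates -- the
# point is independence from the code under test, not speed.

# miniature locus: red [1000,1300), green [1700,2000) on "c" (span [0,3000)),
# abstract partner chromosome "p" of length 2000
tiny_probes <- function() {
  list(probe_footprint("FIVE_PRIME_MYC", genomic_interval("c", 1000, 1300)),
       probe_footprint("THREE_PRIME_MYC", genomic_interval("c", 1700, 2000)))
}

tiny_chrom_len <- c(c = 3000, p = 2000)

# per-base colour vector along a derivative (read left to right)
oracle_base_colors <- function(der, probes) {
  pr <- list(five = probes[[1]], three = probes[[2]])
  cols <- character(0)
  for (seg in der$segments) {
    iv <- seg$interval
    bases <- seq(iv$start, iv$end - 1)
    if (seg$orientation == "-") bases <- rev(bases)
    col <- rep("", length(bases))
    if (iv$chrom == pr$five$interval$chrom)
      col[bases >= pr$five$interval$start & bases < pr$five$interval$end] <- "RED"
    if (iv$chrom == pr$three$interval$chrom)
      col[bases >= pr$three$interval$start & bases < pr$three$interval$end] <- "GREEN"
    cols <- c(cols, col)
  }
  cols
}

# enumerate every maximal run of footprint bases, then merge red/green pairs
# by exhaustive pairwise search over a globally sorted candidate list
oracle_simulate <- function(config, probes, params) {
  widths <- c(RED = interval_width_(probes[[1]]$interval),
              GREEN = interval_width_(probes[[2]]$interval))
  spot_list <- list()
  for (der in config$derivatives) {
    cols <- oracle_base_colors(der, probes)
    r <- rle(cols)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (k in seq_along(r$values)) {
      v <- r$values[k]
      if (v == "") next
      frac <- r$lengths[k] / widths[[v]]
      if (frac >= params$min_visible_frac)
        spot_list[[length(spot_list) + 1L]] <- data.frame(
          derivative = der$name, color = v,
          start = starts[k], end = ends[k])
    }
  }
  if (length(spot_list) == 0L)
    return(list(red = 0L, green = 0L, fusion = 0L))
  spots <- do.call(rbind, spot_list)

  pairs <- list()
  for (r in which(spots$color == "RED")) for (g in which(spots$color == "GREEN")) {
    if (spots$derivative[r] != spots$derivative[g]) next
    gap <- max(0, max(spots$start[r], spots$start[g]) -
                  min(spots$end[r], spots$end[g]))
    if (gap <= params$d_fuse)
      pairs[[length(pairs) + 1L]] <- data.frame(r = r, g = g, gap = gap,
                                                rs = spots$start[r],
                                                gs = spots$start[g])
  }
  fusion <- 0L
  used <- rep(FALSE, nrow(spots))
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$gap, pairs$rs, pairs$gs), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      if (used[pairs$r[k]] || used[pairs$g[k]]) next
      used[c(pairs$r[k], pairs$g[k])] <- TRUE
      fusion <- fusion + 1L
    }
  }
  list(red = sum(!used & spots$color == "RED"),
       green = sum(!used & spots$color == "GREEN"),
       fusion = fusion)
}

interval_width_ <- function(iv) iv$end - iv$start

# base-by-base footprint copy number
oracle_copy_number <- function(config, footprint) {
  iv <- footprint$interval
  bases <- seq(iv$start, iv$end - 1)
  counts <- rep(0, length(bases))
  for (der in config$derivatives) for (seg in der$segments) {
    s <- seg$interval
    if (s$chrom != iv$chrom) next
    hit <- bases >= s$start & bases < s$end
    counts[hit] <- counts[hit] + 1
  }
  sum(counts) / length(bases)
}

# ordered reference bases carried by a derivative (chrom:pos keys)
oracle_derivative_bases <- function(der) {
  out <- character(0)
  for (seg in der$segments) {
    iv <- seg$interval
    bases <- seq(iv$start, iv$end - 1)
    if (seg$orientation == "-") bases <- rev(bases)
    out <- c(out, paste0(iv$chrom, ":", bases))
  }
  out
}

# seeded random tiny configuration: up to max_der derivatives of up to
# max_seg segments drawn from the miniature reference
random_tiny_config <- function(max_der = 4L, max_seg = 3L) {
  n_der <- sample.int(max_der, 1L)
  ders <- lapply(seq_len(n_der), function(i) {
    n_seg <- sample.int(max_seg, 1L)
    segs <- lapply(seq_len(n_seg), function(k) {
      chrom <- sample(names(tiny_chrom_len), 1L)
      len <- tiny_chrom_len[[chrom]]
      start <- sample.int(len - 60L, 1L) - 1L
      width <- sample(40:900, 1L)
      segment_ref(genomic_interval(chrom, start, min(len, start + width)),
                  sample(c("+", "-"), 1L))
    })
    derivative_chromosome(segs, sprintf("der%d", i))
  })
  genome_configuration(ders, clone_fraction = 1, label = "random")
}

random_tiny_params <- function() {
  sim_params(d_fuse = sample(c(100, 150, 300, 600), 1L),
             min_visible_frac = sample(c(0.2, 0.3, 0.5), 1L))
}

expect_matches_oracle <- function(config, probes, params) {
  got <- simulate_signals(config, probes, params)
  want <- oracle_simulate(config, probes, params)
  expect_equal(
    c(red = got$n_red_isolated, green = got$n_green_isolated,
      fusion = got$n_fusion),
    c(red = want$red, green = want$green, fusion = want$fusion),
    info = paste("config:", paste(utils::capture.output(print(config)), collapse = " ")))
}

# dialect fuzzer: rewrite a canonical nuc ish string with random character
# variants and whitespace that must not change the parse
fuzz_nuc_ish <- function(canonical) {
  chars <- strsplit(canonical, "")[[1]]
  out <- vapply(chars, function(ch) {
    if (ch == "'") sample(c("'", "′", "’"), 1L)
    else if (ch == "~") sample(c("~", "∼", " ~ ", "-"), 1L)
    else if (ch == "x") sample(c("x", "x ", " x"), 1L)
    else if (ch == ",") sample(c(",", ", "), 1L)
    else ch
  }, "")
  paste(out, collapse = "")
}
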