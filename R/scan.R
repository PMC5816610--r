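#' Extract intergenic regions with flanking extension
#'
#' One region per adjacent gene pair whose gap is at least `min_length`
#' (short gaps cannot hold a promoter or factor site). Each core region is
#' then extended into both flanking gene bodies by `extension` nt,
#' allowing for errors in the original open-reading-frame assignments;
#' the extension is clipped only at the replicon ends. Sequences are taken
#' from the + strand.
#'
#' @param genes Gene table sorted by `start`, single replicon.
#' @param replicon One-row replicon tibble from [read_annotation()]; its
#'   `sequence` must be present.
#' @param min_length Minimum core gap in bp (default 40).
#' @param extension Extension into the flanks in bp (default 100).
#' @return Tibble: `region_id` (e.g. `"yihV/yihW"`), `replicon_id`,
#'   `gene_left`, `gene_right`, `core_start`, `core_end`,
#'   `extended_start`, `extended_end` (0-based half-open) and `sequence`
#'   (the extended span, + strand).
#' @export
extract_intergenic <- function(genes, replicon, min_length = 40L,
                               extension = 100L) {
  stopifnot(is.data.frame(genes))
  if (is.na(replicon$sequence[1])) {
    abort("extract_intergenic requires the replicon sequence")
  }
  seq_chr <- replicon$sequence[1]
  rep_len <- nchar(seq_chr)
  if (nrow(genes) < 2) return(empty_region_table())
  if (is.unsorted(genes$start)) abort("genes must be sorted by start")
  i <- seq_len(nrow(genes) - 1)
  gap <- genes$start[i + 1] - genes$end[i]
  keep <- which(gap >= min_length)
  if (length(keep) == 0) return(empty_region_table())
  core_start <- genes$end[keep]
  core_end <- genes$start[keep + 1]
  ext_start <- pmax(0L, core_start - as.integer(extension))
  ext_end <- pmin(rep_len, core_end + as.integer(extension))
  tibble(
    region_id = paste(genes$gene_id[keep], genes$gene_id[keep + 1], sep = "/"),
    replicon_id = genes$replicon_id[keep],
    gene_left = genes$gene_id[keep],
    gene_right = genes$gene_id[keep + 1],
    core_start = core_start, core_end = core_end,
    extended_start = ext_start, extended_end = ext_end,
    sequence = substring(seq_chr, ext_start + 1, ext_end)
  )
}

empty_region_table <- function() {
  tibble(
    region_id = character(0), replicon_id = character(0),
    gene_left = character(0), gene_right = character(0),
    core_start = integer(0), core_end = integer(0),
    extended_start = integer(0), extended_end = integer(0),
    sequence = character(0)
  )
}

#' Transcription-start-relative coordinates
#'
#' Positions are numbered from the transcription start site: +1 is the
#' first transcribed base, upstream positions are negative, and there is
#' no position 0 (the promoter-literature convention). The mapping is a
#' bijection between replicon positions and non-zero integers.
#'
#' @param pos Replicon positions (0-based).
#' @param tss Replicon position (0-based) of the transcribed base (+1).
#' @param strand Transcription direction, `"+"` or `"-"`.
#' @return `tss_relative()` returns TSS-relative positions;
#'   `tss_to_replicon()` inverts it.
#' @examples
#' tss_relative(c(98, 99, 100, 101), tss = 100)
#' tss_to_replicon(c(-2, -1, 1, 2), tss = 100)
#' @export
tss_relative <- function(pos, tss, strand = "+") {
  if (strand == "+") {
    ifelse(pos >= tss, pos - tss + 1, pos - tss)
  } else {
    ifelse(pos <= tss, tss - pos + 1, tss - pos)
  }
}

#' @rdname tss_relative
#' @param rel TSS-relative positions (non-zero integers).
#' @export
tss_to_replicon <- function(rel, tss, strand = "+") {
  if (any(rel == 0)) abort("TSS-relative coordinates have no position 0")
  if (strand == "+") {
    ifelse(rel > 0, tss + rel - 1, tss + rel)
  } else {
    ifelse(rel > 0, tss - rel + 1, tss - rel)
  }
}

#' @rdname tss_relative
#' @param window_up,window_down Scan window bounds: the window runs from
#'   `-window_up` to `+window_down` in TSS-relative coordinates (defaults
#'   250 and 50, the classical region for bacterial transcription-factor
#'   sites).
#' @return `tss_anchor()` returns a one-row tibble describing the anchor.
#' @export
tss_anchor <- function(tss, strand = "+", window_up = 250L,
                       window_down = 50L) {
  stopifnot(window_up > 0, window_down > 0, strand %in% c("+", "-"))
  tibble(tss = as.integer(tss), strand = strand,
         window_up = as.integer(window_up),
         window_down = as.integer(window_down))
}

#' @rdname tss_relative
#' @param first,last TSS-relative inclusive span endpoints of a site.
#' @return `tss_span_center()` returns the site center: the midpoint of
#'   the span, computed on the gapless linear scale and mapped back so
#'   the missing position 0 is skipped -- a site spanning -52..-31 has
#'   center -41.5 (half-integer centers arise for even-length sites).
#' @export
tss_span_center <- function(first, last) {
  u1 <- ifelse(first > 0, first - 1, first)
  u2 <- ifelse(last > 0, last - 1, last)
  mid <- (u1 + u2) / 2
  ifelse(mid >= 0, mid + 1, mid)
}

#' Scan an intergenic region for motif hits around a transcription start
#'
#' Scores every window of the motif's length on both strands with the
#' log-odds sum, inside the TSS-anchored window (default -250/+50,
#' clipped to the region), and reports hits whose score reaches
#' `threshold` times the motif's maximum attainable score. Hit spans are
#' reported both as replicon coordinates and TSS-relative coordinates;
#' the site center is the midpoint of the span (half-integer for
#' even-length sites).
#'
#' @param region One-row tibble from [extract_intergenic()] (or any row
#'   with `region_id`, `extended_start` and `sequence`).
#' @param anchor One-row tibble from [tss_anchor()]; `tss` in replicon
#'   coordinates.
#' @param motif A `motif_model` (default [crp_motif()]).
#' @param threshold Fraction of the maximum bit score required to report a
#'   hit (default 0.6).
#' @return Tibble of class `site_hits`, one row per hit: `region_id`,
#'   `strand` (motif orientation), `offset` (0-based start within the
#'   region sequence), `rep_start`, `rep_end` (replicon, half-open),
#'   `tss_first`, `tss_last` (TSS-relative inclusive span), `center`,
#'   `pwm_score` (bits), plus `max_score` as an attribute.
#' @export
scan_pwm <- function(region, anchor, motif = crp_motif(), threshold = 0.6) {
  stopifnot(nrow(region) == 1, nrow(anchor) == 1)
  chars <- strsplit(toupper(region$sequence[1]), "", fixed = TRUE)[[1]]
  L <- ncol(motif$matrix)
  reg_start <- region$extended_start[1]
  reg_end <- reg_start + length(chars)
  tss <- anchor$tss[1]
  strand <- anchor$strand[1]

  # replicon span [w0, w1) covered by the TSS window
  if (strand == "+") {
    w0 <- tss - anchor$window_up[1]
    w1 <- tss + anchor$window_down[1]
  } else {
    w0 <- tss - anchor$window_down[1] + 1L
    w1 <- tss + anchor$window_up[1] + 1L
  }
  w0 <- max(w0, reg_start)
  w1 <- min(w1, reg_end)
  if (w1 - w0 < L) {
    abort("scan_pwm: motif longer than the (clipped) scan window")
  }

  sub_chars <- chars[(w0 - reg_start + 1):(w1 - reg_start)]
  fwd <- pwm_scores_along(sub_chars, motif)
  rev_scores <- rev(pwm_scores_along(revcomp_chars(sub_chars), motif))
  max_score <- max_pwm_score(motif)
  cut <- threshold * max_score

  hit_rows <- function(scores, hit_strand) {
    idx <- which(scores >= cut)
    if (length(idx) == 0) return(NULL)
    s <- w0 + idx - 1L                      # replicon start, 0-based
    rel_a <- tss_relative(s, tss, strand)
    rel_b <- tss_relative(s + L - 1L, tss, strand)
    tibble(
      region_id = region$region_id[1],
      strand = hit_strand,
      offset = s - reg_start,
      rep_start = s, rep_end = s + L,
      tss_first = pmin(rel_a, rel_b), tss_last = pmax(rel_a, rel_b),
      pwm_score = scores[idx]
    )
  }
  out <- bind_rows(hit_rows(fwd, "+"), hit_rows(rev_scores, "-"))
  if (nrow(out) == 0) {
    out <- tibble(
      region_id = character(0), strand = character(0), offset = integer(0),
      rep_start = integer(0), rep_end = integer(0), tss_first = integer(0),
      tss_last = integer(0), pwm_score = numeric(0)
    )
  }
  out <- out %>%
    mutate(center = tss_span_center(.data$tss_first, .data$tss_last)) %>%
    select("region_id", "strand", "offset", "rep_start", "rep_end",
           "tss_first", "tss_last", "center", "pwm_score") %>%
    arrange(.data$tss_first, .data$strand)
  attr(out, "max_score") <- max_score
  attr(out, "motif") <- motif$name
  class(out) <- c("site_hits", class(out))
  out
}

#' Rank candidate sites by score and conservation
#'
#' Each hit's conservation is the mean column identity of the reference
#' conservation profile over the hit's span. Hits are ranked by the sum of
#' their score rank and conservation rank (smaller is better); ties are
#' broken by higher PWM score, then by the more upstream position, so
#' highly conserved sites with the best scores come first.
#'
#' @param hits A `site_hits` tibble from [scan_pwm()].
#' @param profile A `conservation_profile` from [conservation_profile()]
#'   computed on the same reference region the hits were scanned on.
#' @return `hits` with added `conservation` and `combined_rank` columns,
#'   sorted by rank.
#' @export
rank_sites <- function(hits, profile) {
  stopifnot(inherits(hits, "data.frame"), inherits(profile, "data.frame"))
  if (nrow(hits) == 0) {
    hits$conservation <- numeric(0)
    hits$combined_rank <- integer(0)
    return(hits)
  }
  L <- hits$rep_end - hits$rep_start
  if (any(hits$offset < 0) || any(hits$offset + L > nrow(profile))) {
    abort("rank_sites: hit span outside the conservation profile")
  }
  cons <- vapply(seq_len(nrow(hits)), function(i) {
    mean(profile$identity[(hits$offset[i] + 1):(hits$offset[i] + L[i])])
  }, numeric(1))
  at <- attributes(hits)
  out <- hits %>%
    mutate(
      conservation = cons,
      .rank_pwm = rank(-.data$pwm_score, ties.method = "min"),
      .rank_cons = rank(-.data$conservation, ties.method = "min")
    ) %>%
    arrange(.data$.rank_pwm + .data$.rank_cons,
            dplyr::desc(.data$pwm_score), .data$tss_first) %>%
    mutate(combined_rank = row_number()) %>%
    select(-".rank_pwm", -".rank_cons")
  attr(out, "max_score") <- at$max_score
  attr(out, "motif") <- at$motif
  out
}
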