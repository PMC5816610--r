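#' Distance between two genes on a replicon
#'
#' The intergenic gap is measured from the end of the upstream gene to the
#' start of the downstream gene on chromosome coordinates, regardless of
#' strand; overlapping genes give a negative gap.
#'
#' @param a,b One-row data frames (or lists) with `start`, `end`,
#'   `replicon_id`; `a` must not start after `b`.
#' @return Integer gap in bp: `b$start - a$end`.
#' @examples
#' a <- tibble::tibble(replicon_id = "r", start = 0L, end = 500L)
#' b <- tibble::tibble(replicon_id = "r", start = 799L, end = 1000L)
#' gene_gap(a, b)  # 299
#' @export
gene_gap <- function(a, b) {
  if (!identical(a$replicon_id[1], b$replicon_id[1])) {
    abort("gene_gap: genes lie on different replicons")
  }
  if (a$start[1] > b$start[1]) {
    abort("gene_gap: 'a' must not start after 'b'")
  }
  as.integer(b$start[1] - a$end[1])
}

#' Partition a replicon's genes into cassettes by the proximity rule
#'
#' Genes are chained left to right: a gene joins the current cassette iff
#' its gap to the previous gene (end of the previous list member to its own
#' start) is strictly less than `max_gap`; otherwise a new cassette starts.
#' The threshold is strict -- a 299 bp gap joins under the default, a
#' 300 bp gap splits. Strand and gene order within the cassette play no
#' role, and overlapping or nested genes (negative gaps) always join. Runs
#' shorter than `min_genes` are dropped.
#'
#' @param genes Gene table sorted by `start`, single replicon. A `labels`
#'   list-column (from [add_fingerprint()]) is carried through into the
#'   cassette fingerprints when present.
#' @param max_gap Exclusive gap threshold in bp (default 300).
#' @param min_genes Minimum genes per cassette (default 2).
#' @param circular If `TRUE`, the wrap-around gap between the last and the
#'   first gene is also tested (requires `replicon_length`) and the two
#'   terminal runs are merged when it passes.
#' @param replicon_length Replicon length in bp; only needed when
#'   `circular = TRUE`.
#' @return Tibble of cassettes: `cassette_id`, `replicon_id`, `species`,
#'   `taxon_group`, `start`, `end`, `n_genes`, `genes` (list-column of gene
#'   tibbles in chromosomal order) and `fingerprint` (list-column of
#'   per-gene label sets, present when `genes` carried `labels`).
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = paste0("g", 1:5), replicon_id = "r",
#'   species = "sp", taxon_group = "grp",
#'   start = c(0L, 600L, 1199L, 2000L, 2550L),
#'   end   = c(500L, 900L, 1700L, 2500L, 3000L),
#'   strand = "+"
#' )
#' assemble_cassettes(genes)$n_genes  # gaps 100, 299, 300, 50 -> 3 and 2
#' @export
assemble_cassettes <- function(genes, max_gap = 300L, min_genes = 2L,
                               circular = FALSE, replicon_length = NULL) {
  stopifnot(is.data.frame(genes), max_gap >= 0, min_genes >= 1)
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) return(empty_cassette_table(genes))
  if (length(unique(genes$replicon_id)) > 1) {
    abort("assemble_cassettes expects genes from a single replicon")
  }
  if (is.unsorted(genes$start)) {
    abort("assemble_cassettes expects genes sorted by start")
  }
  gaps <- genes$start[-1] - genes$end[-nrow(genes)]
  run <- cumsum(c(1L, as.integer(!(gaps < max_gap))))
  if (circular && nrow(genes) >= 2 && max(run) > 1) {
    if (is.null(replicon_length)) {
      abort("circular assembly requires replicon_length")
    }
    wrap_gap <- (replicon_length - genes$end[nrow(genes)]) + genes$start[1]
    if (wrap_gap < max_gap) {
      run[run == max(run)] <- 1L  # merge terminal runs across the origin
    }
  }
  pieces <- split(seq_len(nrow(genes)), run)
  keep <- pieces[vapply(pieces, length, integer(1)) >= min_genes]
  if (length(keep) == 0) return(empty_cassette_table(genes))
  rows <- purrr::imap(unname(keep), function(idx, i) {
    g <- genes[idx, , drop = FALSE]
    tibble(
      cassette_id = paste0(g$replicon_id[1], "_cas", i),
      replicon_id = g$replicon_id[1],
      species = if ("species" %in% names(g)) g$species[1] else NA_character_,
      taxon_group = if ("taxon_group" %in% names(g)) g$taxon_group[1] else NA_character_,
      start = min(g$start), end = max(g$end),
      n_genes = nrow(g),
      genes = list(g),
      fingerprint = list(if ("labels" %in% names(g)) g$labels else NULL)
    )
  })
  out <- bind_rows(rows)
  if (all(vapply(out$fingerprint, is.null, logical(1)))) {
    out$fingerprint <- NULL
  }
  out
}

empty_cassette_table <- function(genes) {
  tibble(
    cassette_id = character(0), replicon_id = character(0),
    species = character(0), taxon_group = character(0),
    start = integer(0), end = integer(0), n_genes = integer(0),
    genes = list()
  )
}

#' Build a cassette database from one or more annotated replicons
#'
#' Fingerprints every gene (truncated EC numbers, keyword roles, COGs) and
#' assembles cassettes per replicon, producing the on-disk "cassette
#' database" table used by [search_conserved_combinations()].
#'
#' @param genes Gene table covering one or more replicons (rows from
#'   [read_annotation()] calls bound together).
#' @param role_rules Keyword rules, as [default_role_rules()].
#' @inheritParams assemble_cassettes
#' @return Cassette tibble as [assemble_cassettes()], all replicons bound
#'   together, with fingerprints.
#' @export
build_cassette_db <- function(genes, role_rules = default_role_rules(),
                              max_gap = 300L, min_genes = 2L) {
  genes <- add_fingerprint(genes, role_rules)
  genes %>%
    arrange(.data$replicon_id, .data$start) %>%
    group_by(.data$replicon_id) %>%
    dplyr::group_split() %>%
    purrr::map(assemble_cassettes, max_gap = max_gap, min_genes = min_genes) %>%
    bind_rows()
}
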