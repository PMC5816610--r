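#' Packaged example cassettes: the yih cassette and the Bacilli lac cassette
#'
#' Two gene cassettes shipped with the package: the ten-gene *yih*
#' (sulphoquinovose degradation) cassette of *Escherichia coli* K-12
#' MG1655 and the lactose-catabolism cassette of *Staphylococcus aureus*
#' (*Bacilli*). Per-gene annotations encode the six matching function
#' labels -- hydrolase (EC 3.2.1), aldolase (EC 4.1.2, COG3684), kinase
#' (EC 2.7.1), isomerase (EC 2.3.1), transporter, and transcription
#' factor -- so `match_cassettes(fx$yih, fx$lac)` yields the six-gene
#' functional match that predicts lactose-degradation capability for the
#' *yih* cassette. Coordinates are schematic (all intra-cassette gaps
#' below 300 bp); annotations follow the published cassette content.
#'
#' @param role_rules Keyword rules used to fingerprint the genes.
#' @return Named list with cassette rows `yih` and `lac` (each a one-row
#'   cassette tibble with fingerprints) and `genes` (the underlying gene
#'   table).
#' @examples
#' fx <- cassette_fixtures()
#' match_cassettes(fx$yih, fx$lac)$match_size  # 6
#' @export
cassette_fixtures <- function(role_rules = default_role_rules()) {
  path <- system.file("extdata", "yih_lac_cassettes.tsv",
                      package = "cassettecompare", mustWork = TRUE)
  genes <- read_gene_table(path) %>%
    add_fingerprint(role_rules)
  as_row <- function(id) {
    g <- genes %>% filter(.data$cassette_id == id) %>% arrange(.data$start)
    tibble(
      cassette_id = id,
      replicon_id = g$replicon_id[1],
      species = g$species[1],
      taxon_group = g$taxon_group[1],
      start = min(g$start), end = max(g$end),
      n_genes = nrow(g),
      genes = list(g),
      fingerprint = list(g$labels)
    )
  }
  list(yih = as_row("yih"), lac = as_row("lac"), genes = genes)
}
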