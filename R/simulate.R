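#' Default annotation pools for the genome simulator
#'
#' Background genes draw EC numbers and product descriptions from small
#' curated pools. The EC pool includes the four carbohydrate-metabolism
#' reaction types that matter for cassette comparison (hydrolases 3.2.1,
#' aldolases 4.1.2, kinases 2.7.1, and the 2.3.1 class) alongside
#' unrelated classes, so simulated databases interoperate with the
#' packaged cassette fixtures. The default product pool deliberately
#' avoids transporter / transcription-factor keywords so that planted role
#' genes are the only role carriers.
#'
#' @return Character vectors.
#' @export
default_ec_pool <- function() {
  c("3.2.1.85", "4.1.2.40", "2.7.1.144", "2.3.1.54", "1.1.1.1",
    "5.3.1.9", "2.7.2.1", "3.1.3.2", "6.3.2.4", "5.1.3.3",
    "1.2.1.12", "4.2.1.2", "2.4.1.7", "3.5.1.5", "1.6.5.3",
    "6.1.1.1", "2.1.1.13", "3.6.1.1", "5.4.2.2", "4.3.1.1")
}

#' @rdname default_ec_pool
#' @export
default_product_pool <- function() {
  c("hypothetical protein", "membrane protein", "ribosomal protein",
    "DNA polymerase subunit", "tRNA ligase", "cell division protein",
    "outer membrane lipoprotein", "chaperone protein", "elongation factor",
    "peptidase", "oxidoreductase subunit", "acyl carrier protein")
}

#' Describe a cassette to plant in simulated genomes
#'
#' @param genes Tibble with columns `product`, `ec` (single EC string or
#'   `""`), `cog` (COG id or `""`); one row per planted gene, in order.
#' @param species Character vector of simulated species names (e.g.
#'   `"sp01"`) that receive a copy of the cassette.
#' @return List of class `planted_cassette`.
#' @export
planted_cassette <- function(genes, species) {
  stopifnot(is.data.frame(genes),
            all(c("product", "ec", "cog") %in% names(genes)),
            is.character(species), length(species) >= 1)
  structure(list(genes = as_tibble(genes), species = species),
            class = "planted_cassette")
}

#' Simulate a random gene layout on a linear replicon
#'
#' Gene lengths are uniform over `gene_length_range`; the gap after each
#' gene is drawn from a two-component mixture -- with probability
#' `gap_small_frac` a "within-cassette" gap uniform over
#' `gap_small_range` (below the 300 bp threshold), otherwise a
#' "between-cassette" gap uniform over `gap_large_range`.
#'
#' @param n_genes Number of genes.
#' @param replicon_id,species,taxon_group Identifiers stamped on the rows.
#' @param gap_small_frac Mixture weight of the small-gap component.
#' @param gap_small_range,gap_large_range Inclusive integer ranges (bp).
#' @param gene_length_range Inclusive integer range of gene lengths (bp).
#' @param start_offset First gene start (bp).
#' @return Gene tibble (no annotation columns filled: `product` is `NA`,
#'   `ec_numbers` empty), sorted by start.
#' @export
simulate_gene_layout <- function(n_genes, replicon_id = "simrep",
                                 species = "simsp", taxon_group = "simgrp",
                                 gap_small_frac = 0.6,
                                 gap_small_range = c(20L, 299L),
                                 gap_large_range = c(300L, 2000L),
                                 gene_length_range = c(300L, 1500L),
                                 start_offset = 200L) {
  stopifnot(n_genes >= 1, gap_small_frac >= 0, gap_small_frac <= 1,
            gap_small_range[1] <= gap_small_range[2],
            gap_large_range[1] <= gap_large_range[2])
  lens <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                 replace = TRUE)
  small <- runif(n_genes - 1) < gap_small_frac
  gaps <- ifelse(
    small,
    sample(gap_small_range[1]:gap_small_range[2], n_genes, replace = TRUE)[seq_len(max(n_genes - 1, 0))],
    sample(gap_large_range[1]:gap_large_range[2], n_genes, replace = TRUE)[seq_len(max(n_genes - 1, 0))]
  )
  starts <- start_offset + c(0L, cumsum(lens[-n_genes] + gaps))
  tibble(
    gene_id = sprintf("%s_g%04d", replicon_id, seq_len(n_genes)),
    locus_tag = sprintf("%s_g%04d", replicon_id, seq_len(n_genes)),
    replicon_id = replicon_id, species = species, taxon_group = taxon_group,
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    product = NA_character_,
    ec_numbers = rep(list(character(0)), n_genes),
    cog = NA_character_
  )
}

#' Simulate annotated genomes with planted cassettes
#'
#' Generates one linear replicon per species: background genes laid out by
#' [simulate_gene_layout()] and annotated from the EC/product pools, plus
#' any planted cassettes inserted as a consecutive run with
#' within-cassette gaps below 300 bp and flanked on both sides by gaps of
#' at least 300 bp. Writes GFF3 + FASTA per species (standard formats the
#' readers consume) and returns the ground truth needed by recovery
#' tests. Fully deterministic given `seed`.
#'
#' @param n_species Number of simulated species.
#' @param genes_per_replicon Background genes per replicon.
#' @param taxon_groups Character vector; species are assigned to groups
#'   round-robin.
#' @param planted List of [planted_cassette()] objects.
#' @param annotate_frac Fraction of background genes that receive an EC
#'   number from `ec_pool`.
#' @param ec_pool,product_pool Annotation pools.
#' @param dir Output directory for GFF3/FASTA (created if needed);
#'   `NULL` skips file writing.
#' @param seed Mandatory integer seed.
#' @param write_sequence If `TRUE` (default) random replicon sequences
#'   are generated and written to FASTA; disable for speed when only gene
#'   tables are needed.
#' @inheritParams simulate_gene_layout
#' @return List: `genes` (ground-truth gene table over all species, with
#'   a `planted` column naming the planted cassette or `NA`), `files`
#'   (tibble: species, taxon_group, replicon_id, gff, fasta), and
#'   `truth` (list with the planted fingerprints per cassette, computed
#'   from the planted annotations).
#' @export
simulate_genomes <- function(seed, n_species = 5L, genes_per_replicon = 40L,
                             taxon_groups = c("groupA", "groupB"),
                             planted = list(),
                             gap_small_frac = 0.6,
                             gap_small_range = c(20L, 299L),
                             gap_large_range = c(300L, 2000L),
                             gene_length_range = c(300L, 1500L),
                             annotate_frac = 0.7,
                             ec_pool = default_ec_pool(),
                             product_pool = default_product_pool(),
                             dir = NULL, write_sequence = !is.null(dir)) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  species_names <- sprintf("sp%02d", seq_len(n_species))
  groups <- rep(taxon_groups, length.out = n_species)
  for (pc in planted) {
    unknown <- setdiff(pc$species, species_names)
    if (length(unknown) > 0) {
      abort(paste0("planted cassette names unknown species: ",
                   paste(unknown, collapse = ", ")))
    }
  }

  all_genes <- list()
  files <- list()
  for (i in seq_len(n_species)) {
    sp <- species_names[i]
    rep_id <- paste0(sp, "_chr")
    g <- simulate_gene_layout(
      genes_per_replicon, replicon_id = rep_id, species = sp,
      taxon_group = groups[i], gap_small_frac = gap_small_frac,
      gap_small_range = gap_small_range, gap_large_range = gap_large_range,
      gene_length_range = gene_length_range
    )
    ann <- runif(nrow(g)) < annotate_frac
    g$ec_numbers[ann] <- lapply(sample(ec_pool, sum(ann), replace = TRUE), identity)
    g$product <- sample(product_pool, nrow(g), replace = TRUE)
    g$planted <- NA_character_

    # insert planted cassettes destined for this species
    mine <- Filter(function(pc) sp %in% pc$species, planted)
    for (k in seq_along(mine)) {
      pc <- mine[[k]]
      np <- nrow(pc$genes)
      lens <- sample(gene_length_range[1]:gene_length_range[2], np,
                     replace = TRUE)
      in_gaps <- sample(gap_small_range[1]:min(gap_small_range[2], 299L),
                        max(np - 1, 0), replace = TRUE)
      flank <- sample(gap_large_range[1]:gap_large_range[2], 1)
      base <- max(g$end) + flank
      starts <- base + c(0L, cumsum(lens[-np] + in_gaps))
      prow <- tibble(
        gene_id = sprintf("%s_p%d_%02d", rep_id, k, seq_len(np)),
        locus_tag = sprintf("%s_p%d_%02d", rep_id, k, seq_len(np)),
        replicon_id = rep_id, species = sp, taxon_group = groups[i],
        start = as.integer(starts), end = as.integer(starts + lens),
        strand = sample(c("+", "-"), np, replace = TRUE),
        product = pc$genes$product,
        ec_numbers = lapply(pc$genes$ec, function(e)
          if (nzchar(e)) e else character(0)),
        cog = ifelse(nzchar(pc$genes$cog), pc$genes$cog, NA_character_),
        planted = paste0("planted", k)
      )
      g <- bind_rows(g, prow)
    }
    g <- arrange(g, .data$start)
    rep_len <- max(g$end) + 200L

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      gff <- file.path(dir, paste0(sp, ".gff3"))
      fasta <- if (write_sequence) file.path(dir, paste0(sp, ".fasta")) else NA
      seq_chr <- if (write_sequence) {
        paste(sample(c("A", "C", "G", "T"), rep_len, replace = TRUE),
              collapse = "")
      } else NULL
      write_sim_gff3(g, rep_id, rep_len, sp, groups[i], gff)
      if (write_sequence) write_sim_fasta(rep_id, seq_chr, fasta)
      files[[length(files) + 1]] <- tibble(
        species = sp, taxon_group = groups[i], replicon_id = rep_id,
        length = rep_len, gff = gff, fasta = fasta
      )
    }
    all_genes[[length(all_genes) + 1]] <- g
  }
  genes <- bind_rows(all_genes)
  planted_fp <- lapply(planted, function(pc) {
    fake <- tibble(
      gene_id = paste0("p", seq_len(nrow(pc$genes))),
      product = pc$genes$product,
      ec_numbers = lapply(pc$genes$ec, function(e)
        if (nzchar(e)) e else character(0)),
      cog = ifelse(nzchar(pc$genes$cog), pc$genes$cog, NA_character_)
    )
    cassette_fingerprint(fake)
  })
  list(
    genes = genes,
    files = if (length(files) > 0) bind_rows(files) else NULL,
    truth = list(planted_fingerprints = planted_fp,
                 taxon_groups = setNames(groups, species_names))
  )
}

write_sim_gff3 <- function(genes, replicon_id, rep_len, species,
                           taxon_group, path) {
  attrs <- vapply(seq_len(nrow(genes)), function(i) {
    a <- c(
      paste0("ID=", genes$gene_id[i]),
      paste0("locus_tag=", genes$locus_tag[i]),
      paste0("product=", genes$product[i])
    )
    ecs <- genes$ec_numbers[[i]]
    if (length(ecs) > 0) a <- c(a, paste0("ec_number=", paste(ecs, collapse = ",")))
    if (!is.na(genes$cog[i])) a <- c(a, paste0("cog=", genes$cog[i]))
    paste(a, collapse = ";")
  }, character(1))
  body <- paste(replicon_id, "sim", "CDS",
                genes$start + 1L, genes$end,   # GFF3 is 1-based inclusive
                ".", genes$strand, "0", attrs, sep = "\t")
  writeLines(c(
    "##gff-version 3",
    paste("##sequence-region", replicon_id, 1, rep_len),
    paste("##species", species),
    paste("##taxon-group", taxon_group),
    body
  ), path)
  invisible(path)
}

write_sim_fasta <- function(id, seq_chr, path) {
  chunks <- substring(seq_chr, seq(1, nchar(seq_chr), 70),
                      pmin(seq(1, nchar(seq_chr), 70) + 69, nchar(seq_chr)))
  writeLines(c(paste0(">", id), chunks), path)
  invisible(path)
}

#' Simulate orthologous intergenic regions with a planted motif
#'
#' Star-phylogeny model: the first sequence is the unmutated ancestral
#' reference; each further ortholog is an independently mutated copy, with
#' per-site substitution probability `divergence_outside` everywhere
#' except the planted motif span, which mutates at `divergence_inside`
#' (the stronger conservation a functional site shows in phylogenetic
#' footprinting). Substitutions replace a base by one of the other three,
#' uniformly; no indels are introduced.
#'
#' The transcription start sits at region offset `tss_offset`, so with the
#' defaults the -250/+50 scan window covers the whole 300 nt region and a
#' 16 nt site planted at TSS-relative span \[-49, -34\] has center -41.5.
#'
#' @param seed Mandatory integer seed.
#' @param n_orthologs Number of sequences including the reference.
#' @param region_length Region length in nt.
#' @param divergence_outside,divergence_inside Per-site substitution
#'   probabilities.
#' @param motif A `motif_model` with an IUPAC consensus (default
#'   [crp_motif()]); the planted instance resolves ambiguous positions
#'   randomly.
#' @param planted_span TSS-relative inclusive span of the planted site;
#'   its length must equal the motif length.
#' @param tss_offset 0-based region offset of the transcription start.
#' @param fasta Optional path: write the orthologs as multi-FASTA.
#' @return List: `seqs` (named character vector, reference first),
#'   `region` (one-row tibble usable by [scan_pwm()], `extended_start` 0),
#'   `anchor` ([tss_anchor()] at `tss_offset`), and `truth` (list:
#'   `planted_span`, `planted_center`, `planted_offsets` (0-based region
#'   offsets), `motif_instance`).
#' @export
simulate_ortholog_regions <- function(seed, n_orthologs = 6L,
                                      region_length = 300L,
                                      divergence_outside = 0.2,
                                      divergence_inside = 0.02,
                                      motif = crp_motif(),
                                      planted_span = c(-49L, -34L),
                                      tss_offset = 250L,
                                      fasta = NULL) {
  stopifnot(is.numeric(seed), n_orthologs >= 2,
            divergence_outside >= 0, divergence_outside <= 1,
            divergence_inside >= 0, divergence_inside <= 1)
  set.seed(as.integer(seed))
  L <- ncol(motif$matrix)
  span_len <- planted_span[2] - planted_span[1] + 1 -
    (planted_span[1] < 0 && planted_span[2] > 0)   # no position 0
  if (span_len != L) {
    abort("planted_span length must equal the motif length")
  }
  offs <- sort(tss_to_replicon(setdiff(planted_span[1]:planted_span[2], 0L),
                               tss_offset, "+"))
  if (offs[1] < 0 || offs[length(offs)] >= region_length) {
    abort("planted span lies outside the region")
  }

  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, region_length, replace = TRUE)
  instance <- vapply(strsplit(toupper(motif$consensus %||% stop_no_consensus()),
                              "", fixed = TRUE)[[1]],
                     function(ch) {
                       allowed <- IUPAC_MAP[[ch]]
                       if (length(allowed) == 1) allowed else sample(allowed, 1)
                     }, character(1), USE.NAMES = FALSE)
  anc[offs + 1] <- instance

  rate <- rep(divergence_outside, region_length)
  rate[offs + 1] <- divergence_inside
  seqs <- c(paste(anc, collapse = ""))
  for (k in seq_len(n_orthologs - 1)) {
    mut <- runif(region_length) < rate
    derived <- anc
    if (any(mut)) {
      derived[mut] <- vapply(anc[mut], function(b) sample(setdiff(bases, b), 1),
                             character(1))
    }
    seqs <- c(seqs, paste(derived, collapse = ""))
  }
  names(seqs) <- c("ref", sprintf("ortho%02d", seq_len(n_orthologs - 1)))
  if (!is.null(fasta)) {
    writeLines(unlist(lapply(names(seqs), function(nm)
      c(paste0(">", nm), seqs[[nm]]))), fasta)
  }
  region <- tibble(
    region_id = "sim_region", replicon_id = "sim",
    gene_left = "gl", gene_right = "gr",
    core_start = 0L, core_end = region_length,
    extended_start = 0L, extended_end = region_length,
    sequence = seqs[[1]]
  )
  list(
    seqs = seqs,
    region = region,
    anchor = tss_anchor(tss_offset),
    truth = list(
      planted_span = planted_span,
      planted_center = tss_span_center(planted_span[1], planted_span[2]),
      planted_offsets = offs,
      motif_instance = paste(instance, collapse = "")
    )
  )
}

stop_no_consensus <- function() {
  abort("simulate_ortholog_regions needs a motif with an IUPAC consensus")
}

#' Simulate a replicate Ct table with planted fold changes
#'
#' Reference genes have condition-independent expected Ct; each target
#' gene's Ct in a non-reference condition is shifted by
#' `-log2(true fold)`. Gaussian technical noise of `noise_sd` cycles is
#' added to every measurement. The replicate structure is
#' `n_biological x n_technical` (default 3 x 3, the usual qPCR design).
#'
#' @param seed Optional integer seed (set for reproducibility).
#' @param true_folds Named numeric vector: target gene -> fold change in
#'   every non-reference condition (default plants a 4-fold activation, a
#'   2-fold repression and no change).
#' @param conditions Conditions; the first is the reference condition.
#' @param reference_genes Control genes with constant expression.
#' @param n_biological,n_technical Replicate structure.
#' @param noise_sd Technical noise, sd in cycles.
#' @return Ct tibble (`gene`, `condition`, `replicate_id`, `ct`,
#'   `is_reference_gene`) with the true folds stored in the
#'   `"true_folds"` attribute.
#' @export
simulate_ct_table <- function(seed = NULL,
                              true_folds = c(yihT = 4, yihW = 0.5, yihU = 1),
                              conditions = c("glucose", "lactose"),
                              reference_genes = c("hns", "ysaA"),
                              n_biological = 3L, n_technical = 3L,
                              noise_sd = 0.2) {
  stopifnot(length(conditions) >= 2, noise_sd >= 0,
            !is.null(names(true_folds)), all(true_folds > 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  reps <- as.vector(outer(seq_len(n_technical), seq_len(n_biological),
                          function(t, b) paste0("b", b, ".t", t)))
  genes <- c(names(true_folds), reference_genes)
  base_ct <- setNames(runif(length(genes), 15, 25), genes)
  rows <- list()
  for (g in genes) {
    is_ref <- g %in% reference_genes
    for (cond in conditions) {
      shift <- if (!is_ref && cond != conditions[1]) {
        -log2(true_folds[[g]])
      } else 0
      rows[[length(rows) + 1]] <- tibble(
        gene = g, condition = cond, replicate_id = reps,
        ct = base_ct[[g]] + shift + rnorm(length(reps), 0, noise_sd),
        is_reference_gene = is_ref
      )
    }
  }
  out <- bind_rows(rows)
  attr(out, "true_folds") <- true_folds
  attr(out, "reference_condition") <- conditions[1]
  out
}
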