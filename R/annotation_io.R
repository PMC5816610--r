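#' Read an annotated replicon into a uniform gene table
#'
#' Parses a GenBank flat file, or a GFF3 file paired with a FASTA file, into
#' a replicon descriptor plus an ordered gene table. Internal coordinates
#' are 0-based half-open (`start` inclusive, `end` exclusive), so the gap
#' between adjacent genes is simply `start[i+1] - end[i]`; GFF3's 1-based
#' inclusive coordinates are converted on input.
#'
#' A "gene" is any feature of type `gene` or `CDS` with a distinct locus
#' tag; where both exist for the same locus tag the CDS coordinates and
#' qualifiers win, since intergenic distances concern coding regions.
#'
#' @param path Path to the annotation file (GenBank, or GFF3).
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta For `format = "gff3"`, optional path to the matching FASTA
#'   with the replicon sequence.
#' @param species,taxon_group Optional overrides; otherwise taken from the
#'   file (`ORGANISM` line for GenBank; `##species` / `##taxon-group`
#'   directives for GFF3).
#' @return A list with elements `replicon` (one-row tibble: `replicon_id`,
#'   `species`, `taxon_group`, `length`, `topology`, and `sequence`, a
#'   plain character string or `NA`) and `genes` (tibble sorted by `start`
#'   with columns `gene_id`, `locus_tag`, `replicon_id`, `species`,
#'   `taxon_group`, `start`, `end`, `strand`, `product`, `ec_numbers`
#'   (list-column), `cog`).
#' @seealso [write_table()], [read_gene_table()]
#' @export
read_annotation <- function(path, format = c("gff3", "genbank"), fasta = NULL,
                            species = NULL, taxon_group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("annotation file does not exist: ", path))
  }
  res <- switch(format,
    gff3 = read_gff3_annotation(path, fasta),
    genbank = read_genbank_annotation(path)
  )
  if (!is.null(species)) {
    res$replicon$species <- species
    res$genes$species <- species
  }
  if (!is.null(taxon_group)) {
    res$replicon$taxon_group <- taxon_group
    res$genes$taxon_group <- taxon_group
  }
  res$genes <- arrange(res$genes, .data$start, .data$end)
  validate_gene_table(res$genes, res$replicon)
  res
}

read_gff3_annotation <- function(path, fasta = NULL) {
  header <- readLines(path, n = 50L)
  dir_val <- function(key) {
    ln <- grep(paste0("^##", key, "[ \t]"), header, value = TRUE)
    if (length(ln) == 0) return(NA_character_)
    stringr::str_trim(sub(paste0("^##", key, "[ \t]+"), "", ln[1]))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("malformed GFF3 '", path, "': ",
                                     conditionMessage(e)))
  )
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  gr <- gr[keep]
  md <- as.data.frame(gr)
  getcol <- function(nm, default = NA_character_) {
    if (nm %in% names(md)) as.character(md[[nm]]) else
      rep(default, nrow(md))
  }
  # EC numbers may come as a CharacterList attribute (multi-valued)
  ec_col <- intersect(c("ec_number", "EC_number"), names(md))
  ecs <- if (length(ec_col) > 0) {
    raw <- md[[ec_col[1]]]
    if (is.list(raw)) lapply(raw, as.character) else
      lapply(as.character(raw), function(x) if (is.na(x)) character(0) else
        strsplit(x, ";", fixed = TRUE)[[1]])
  } else {
    rep(list(character(0)), nrow(md))
  }
  locus <- getcol("locus_tag")
  ids <- getcol("ID")
  locus <- ifelse(is.na(locus), ids, locus)
  tab <- tibble(
    locus_tag = locus,
    type = as.character(md$type),
    start = as.integer(md$start) - 1L,   # GFF3 is 1-based inclusive
    end = as.integer(md$end),
    strand = ifelse(as.character(md$strand) == "-", "-", "+"),
    product = getcol("product"),
    ec_numbers = ecs,
    cog = getcol("cog"),
    replicon_id = as.character(md$seqnames)
  )
  # CDS coordinates win over gene features sharing a locus tag
  tab <- tab %>%
    group_by(.data$locus_tag) %>%
    arrange(match(.data$type, c("CDS", "gene")), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"type")

  seq_chr <- NA_character_
  rep_len <- NA_integer_
  sr <- dir_val("sequence-region")
  if (!is.na(sr)) {
    parts <- strsplit(sr, "[ \t]+")[[1]]
    if (length(parts) >= 3) rep_len <- as.integer(parts[3])
  }
  if (!is.null(fasta)) {
    if (!file.exists(fasta)) {
      abort(paste0("GFF3 annotation '", path,
                   "' names a FASTA that does not exist: ", fasta))
    }
    ss <- Biostrings::readDNAStringSet(fasta)
    seq_chr <- as.character(ss[[1]])
    rep_len <- nchar(seq_chr)
  }
  replicon_id <- if (nrow(tab) > 0) tab$replicon_id[1] else
    sub("\\.[^.]*$", "", basename(path))
  species <- dir_val("species")
  taxon_group <- dir_val("taxon-group")
  replicon <- tibble(
    replicon_id = replicon_id, species = species,
    taxon_group = taxon_group,
    length = rep_len, topology = "linear", sequence = seq_chr
  )
  genes <- tab %>%
    mutate(
      gene_id = .data$locus_tag,
      species = species, taxon_group = taxon_group
    ) %>%
    select("gene_id", "locus_tag", "replicon_id", "species", "taxon_group",
           "start", "end", "strand", "product", "ec_numbers", "cog")
  list(replicon = replicon, genes = genes)
}

# Minimal GenBank flat-file parser: LOCUS/ORGANISM, gene + CDS features with
# simple or complement() spans, locus_tag/gene/product/EC_number qualifiers,
# COG via /db_xref, ORIGIN sequence.
read_genbank_annotation <- function(path) {
  lines <- readLines(path)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0) {
    abort(paste0("malformed GenBank file '", path, "': no LOCUS line"))
  }
  locus_fields <- strsplit(stringr::str_trim(locus_line[1]), "[ \t]+")[[1]]
  replicon_id <- locus_fields[2]
  rep_len <- suppressWarnings(as.integer(locus_fields[3]))
  topology <- if (any(grepl("circular", locus_line[1]))) "circular" else "linear"
  org_line <- grep("^ {2}ORGANISM", lines, value = TRUE)
  species <- if (length(org_line) > 0) {
    stringr::str_trim(sub("^ {2}ORGANISM", "", org_line[1]))
  } else NA_character_

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  terminator <- grep("^//", lines)
  feat_end <- min(c(origin, terminator, length(lines) + 1L)) - 1L
  if (length(feat_start) == 0) {
    abort(paste0("malformed GenBank file '", path, "': no FEATURES table"))
  }
  block <- lines[(feat_start[1] + 1L):feat_end]

  # a feature header has its key in columns 6-20
  is_header <- grepl("^ {5}\\S", block)
  starts <- which(is_header)
  feats <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(block)
    chunk <- block[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
    if (!key %in% c("gene", "CDS")) next
    loc <- stringr::str_trim(sub("^ {5}\\S+\\s+", "", chunk[1]))
    # continuation lines before the first qualifier extend the location
    qual_at <- grep("^ {21}/", chunk)
    if (length(qual_at) > 0 && qual_at[1] > 2) {
      loc <- paste0(loc, stringr::str_trim(chunk[2:(qual_at[1] - 1)]))
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(unlist(stringr::str_extract_all(loc, "[0-9]+")))
    if (length(nums) < 2) {
      abort(paste0("malformed GenBank feature location '", loc,
                   "' in ", path, " (line ", feat_start[1] + from, ")"))
    }
    quals <- parse_gb_qualifiers(chunk[grep("^ {21}/", chunk)])
    feats[[length(feats) + 1]] <- list(
      key = key,
      start = min(nums) - 1L,   # GenBank is 1-based inclusive
      end = max(nums),
      strand = strand,
      quals = quals
    )
  }
  seq_chr <- NA_character_
  if (length(origin) > 0) {
    seq_lines <- lines[(origin[1] + 1L):(min(terminator, length(lines)) - 1L)]
    seq_chr <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(seq_chr)) seq_chr <- NA_character_
  }
  if (!is.na(seq_chr) && is.na(rep_len)) rep_len <- nchar(seq_chr)

  rows <- purrr::map(feats, function(f) {
    q <- f$quals
    cog <- NA_character_
    if (!is.null(q$db_xref)) {
      hit <- grep("^COG:", q$db_xref, value = TRUE)
      if (length(hit) > 0) cog <- sub("^COG:", "", hit[1])
    }
    tibble(
      locus_tag = q$locus_tag[1] %||% q$gene[1] %||% NA_character_,
      type = f$key, start = f$start, end = f$end, strand = f$strand,
      product = q$product[1] %||% NA_character_,
      ec_numbers = list(q$EC_number %||% character(0)),
      cog = cog
    )
  })
  tab <- bind_rows(rows)
  if (nrow(tab) > 0) {
    tab <- tab %>%
      group_by(.data$locus_tag) %>%
      arrange(match(.data$type, c("CDS", "gene")), .by_group = TRUE) %>%
      slice(1) %>%
      ungroup() %>%
      select(-"type")
  } else {
    tab <- tibble(locus_tag = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  product = character(0), ec_numbers = list(),
                  cog = character(0))
  }
  replicon <- tibble(
    replicon_id = replicon_id, species = species,
    taxon_group = NA_character_, length = rep_len,
    topology = topology, sequence = seq_chr
  )
  genes <- tab %>%
    mutate(gene_id = .data$locus_tag, replicon_id = replicon_id,
           species = species, taxon_group = NA_character_) %>%
    select("gene_id", "locus_tag", "replicon_id", "species", "taxon_group",
           "start", "end", "strand", "product", "ec_numbers", "cog")
  list(replicon = replicon, genes = genes)
}

parse_gb_qualifiers <- function(qlines) {
  quals <- list()
  for (ln in qlines) {
    m <- stringr::str_match(stringr::str_trim(ln), '^/([A-Za-z_]+)=?"?([^"]*)"?$')
    if (is.na(m[1, 1])) next
    nm <- m[1, 2]
    val <- m[1, 3]
    quals[[nm]] <- c(quals[[nm]], val)
  }
  quals
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

validate_gene_table <- function(genes, replicon = NULL) {
  if (nrow(genes) == 0) return(invisible(genes))
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    abort("gene table violates 0 <= start < end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (anyDuplicated(genes[, c("replicon_id", "gene_id")]) > 0) {
    abort("gene_id must be unique within a replicon")
  }
  if (!is.null(replicon) && !is.na(replicon$length[1]) &&
      any(genes$end > replicon$length[1])) {
    abort("gene coordinates exceed replicon length")
  }
  invisible(genes)
}

#' Write and re-read result tables as tab-delimited text
#'
#' All downstream tables (gene tables, cassette databases, site hits, fold
#' changes) are written as TSV with a header row. List-columns (such as
#' `ec_numbers` and `labels`) are serialised as `;`-joined strings and
#' split again on read, so `read_gene_table(write_table(x, p))` recovers
#' `x`.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `write_table()` returns `path` invisibly; `read_gene_table()`
#'   returns a tibble with `start`/`end` as integers and `ec_numbers` /
#'   `labels` as list-columns when present.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  flat <- as_tibble(records)
  for (nm in names(flat)) {
    if (is.list(flat[[nm]])) {
      flat[[nm]] <- vapply(flat[[nm]], function(x) paste(x, collapse = ";"),
                           character(1))
    }
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_gene_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (nm in intersect(c("ec_numbers", "labels"), names(tab))) {
    tab[[nm]] <- lapply(tab[[nm]], function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else
        strsplit(x, ";", fixed = TRUE)[[1]]
    })
  }
  for (nm in intersect(c("start", "end"), names(tab))) {
    tab[[nm]] <- as.integer(tab[[nm]])
  }
  tab
}
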