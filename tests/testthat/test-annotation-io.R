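test_that("GFF3 1-based coordinates convert to 0-based half-open", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "x.gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region rep1 1 5000",
    "##species Testus testus",
    "##taxon-group TestGroup",
    paste("rep1", "src", "CDS", 101, 200, ".", "+", "0",
          "ID=gA;locus_tag=gA;product=widget;ec_number=4.1.2.17",
          sep = "\t"),
    paste("rep1", "src", "CDS", 500, 900, ".", "-", "0",
          "ID=gB;locus_tag=gB;product=thing", sep = "\t")
  ), gff)
  res <- read_annotation(gff, format = "gff3")
  expect_equal(res$genes$start, c(100L, 499L))
  expect_equal(res$genes$end, c(200L, 900L))
  expect_equal(res$genes$ec_numbers[[1]], "4.1.2.17")
  expect_equal(res$genes$strand, c("+", "-"))
  expect_equal(res$replicon$species, "Testus testus")
  expect_equal(res$replicon$taxon_group, "TestGroup")
  expect_equal(res$replicon$length, 5000L)
})

test_that("a simulated replicon reads back with the ground-truth gene table", {
  dir <- withr::local_tempdir()
  sim <- simulate_genomes(seed = 11, n_species = 1, genes_per_replicon = 10,
                          dir = dir)
  res <- read_annotation(sim$files$gff[1], format = "gff3",
                         fasta = sim$files$fasta[1])
  truth <- sim$genes[order(sim$genes$start), ]
  expect_equal(res$genes$gene_id, truth$gene_id)
  expect_equal(res$genes$start, truth$start)
  expect_equal(res$genes$end, truth$end)
  expect_equal(res$genes$strand, truth$strand)
  expect_equal(res$genes$product, truth$product)
  expect_equal(res$genes$ec_numbers, truth$ec_numbers)
  expect_equal(res$replicon$length, nchar(res$replicon$sequence))
})

test_that("gene lists come back sorted by start regardless of input order", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "y.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("rep1", "src", "CDS", 900, 1200, ".", "+", "0", "ID=g2", sep = "\t"),
    paste("rep1", "src", "CDS", 10, 400, ".", "+", "0", "ID=g1", sep = "\t")
  ), gff)
  res <- read_annotation(gff, format = "gff3")
  expect_equal(res$genes$gene_id, c("g1", "g2"))
  expect_false(is.unsorted(res$genes$start))
})

test_that("CDS coordinates win over gene features with the same locus tag", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "z.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("rep1", "src", "gene", 90, 1300, ".", "+", ".",
          "ID=gene-gA;locus_tag=gA", sep = "\t"),
    paste("rep1", "src", "CDS", 101, 1200, ".", "+", "0",
          "ID=cds-gA;locus_tag=gA;product=widget", sep = "\t")
  ), gff)
  res <- read_annotation(gff, format = "gff3")
  expect_equal(nrow(res$genes), 1L)
  expect_equal(res$genes$start, 100L)
  expect_equal(res$genes$end, 1200L)
  expect_equal(res$genes$product, "widget")
})

test_that("GenBank flat files parse features, qualifiers and sequence", {
  dir <- withr::local_tempdir()
  gb <- file.path(dir, "t.gb")
  writeLines(c(
    "LOCUS       TESTREP                  120 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  test record.",
    "SOURCE      Testus testus",
    "  ORGANISM  Testus testus",
    "FEATURES             Location/Qualifiers",
    "     gene            1..60",
    "                     /locus_tag=\"tg001\"",
    "     CDS             1..60",
    "                     /locus_tag=\"tg001\"",
    "                     /product=\"sugar aldolase\"",
    "                     /EC_number=\"4.1.2.17\"",
    "                     /db_xref=\"COG:COG3684\"",
    "     CDS             complement(70..114)",
    "                     /locus_tag=\"tg002\"",
    "                     /product=\"putative permease\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"
  ), gb)
  res <- read_annotation(gb, format = "genbank")
  expect_equal(nrow(res$genes), 2L)
  expect_equal(res$genes$start, c(0L, 69L))
  expect_equal(res$genes$end, c(60L, 114L))
  expect_equal(res$genes$strand, c("+", "-"))
  expect_equal(res$genes$ec_numbers[[1]], "4.1.2.17")
  expect_equal(res$genes$cog[1], "COG3684")
  expect_equal(res$replicon$species, "Testus testus")
  expect_equal(nchar(res$replicon$sequence), 120L)
})

test_that("malformed or missing files raise named errors", {
  expect_error(read_annotation("no/such/file.gff3"), "does not exist")
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.gb")
  writeLines("not a genbank record", bad)
  expect_error(read_annotation(bad, format = "genbank"), "LOCUS")
  gff <- file.path(dir, "ok.gff3")
  writeLines(c("##gff-version 3",
               paste("r", "s", "CDS", 1, 50, ".", "+", "0", "ID=g1",
                     sep = "\t")), gff)
  expect_error(read_annotation(gff, format = "gff3", fasta = "nope.fa"),
               "FASTA")
})

test_that("tables round-trip through TSV including list-columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tab.tsv")
  genes <- tibble::tibble(
    gene_id = c("a", "b"), locus_tag = c("a", "b"), replicon_id = "r",
    species = "sp", taxon_group = "grp",
    start = c(0L, 600L), end = c(500L, 1000L), strand = c("+", "-"),
    product = c("kinase", "unknown"),
    ec_numbers = list(c("2.7.1.1", "2.7.1.2"), character(0)),
    cog = c(NA_character_, NA_character_)
  )
  write_table(genes, path)
  back <- read_gene_table(path)
  expect_equal(back$ec_numbers, genes$ec_numbers)
  expect_equal(back$start, genes$start)
  expect_equal(back$gene_id, genes$gene_id)

  # empty table writes a header-only file
  empty <- genes[0, ]
  write_table(empty, path)
  expect_equal(length(readLines(path)), 1L)
})
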