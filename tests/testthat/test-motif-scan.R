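test_that("consensus expansion gives the documented log-odds values", {
  crp <- crp_motif()
  expect_equal(ncol(crp$matrix), 16L)
  # fully specified column: match log2(0.625/0.25), mismatch log2(0.125/0.25)
  expect_equal(crp$matrix["T", 1], log2(0.625 / 0.25))
  expect_equal(crp$matrix["A", 1], log2(0.125 / 0.25))
  # N columns are exactly zero for every base
  expect_true(all(crp$matrix[, 6:11] == 0))
  expect_equal(max_pwm_score(crp), 10 * log2(2.5))
  # degenerate IUPAC letters split the count
  m <- consensus_to_pwm("ACGR")
  expect_equal(m$matrix["A", 4], m$matrix["G", 4])
  expect_gt(m$matrix["A", 4], m$matrix["C", 4])
  expect_error(consensus_to_pwm("ACZ9"), "IUPAC")
})

test_that("motif files round-trip as consensus or matrix", {
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "cons.txt")
  writeLines(c("# myTF", "TGTGANNNNNNTCACA"), cpath)
  m1 <- read_motif(cpath)
  expect_equal(m1$name, "myTF")
  expect_equal(m1$matrix, crp_motif()$matrix)
  mpath <- file.path(dir, "mat.txt")
  writeLines(c("# numeric", apply(crp_motif()$matrix, 1, paste, collapse = " ")),
             mpath)
  m2 <- read_motif(mpath)
  expect_equal(unname(m2$matrix), unname(crp_motif()$matrix))
  # packaged default motif file parses to the CRP model
  pkg_motif <- read_motif(system.file("extdata", "crp_consensus.txt",
                                      package = "cassettecompare"))
  expect_equal(pkg_motif$matrix, crp_motif()$matrix)
})

test_that("TSS-relative coordinates skip zero and invert exactly", {
  expect_equal(tss_relative(c(98, 99, 100, 101), tss = 100),
               c(-2, -1, 1, 2))
  expect_error(tss_to_replicon(0, tss = 100), "no position 0")
  # bijection on both strands
  for (strand in c("+", "-")) {
    pos <- 0:400
    rel <- tss_relative(pos, tss = 200, strand = strand)
    expect_false(any(rel == 0))
    expect_equal(tss_to_replicon(rel, tss = 200, strand = strand), pos)
    expect_equal(length(unique(rel)), length(pos))
  }
})

test_that("site centers follow the half-integer midpoint convention", {
  expect_equal(tss_span_center(-52, -31), -41.5)
  expect_equal(tss_span_center(-10, -2), -6)      # odd length, integer center
  expect_equal(tss_span_center(1, 16), 8.5)
  # spans crossing the (absent) zero use the gapless scale: -4..3 covers
  # seven positions whose middle one is -1; -3..3 covers six, so the
  # center falls on the -1/+1 boundary, reported as -0.5
  expect_equal(tss_span_center(-3, 3), -0.5)
  expect_equal(tss_span_center(-4, 3), -1)
})

test_that("intergenic extraction applies the length filter and extension", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    locus_tag = c("gA", "gB", "gC", "gD"), replicon_id = "rep",
    species = "sp", taxon_group = "grp",
    start = c(0L, 560L, 950L, 1200L), end = c(500L, 900L, 1180L, 1500L),
    strand = "+"
  )
  seq_chr <- paste(rep("ACGT", 500), collapse = "")
  replicon <- tibble::tibble(replicon_id = "rep", length = 2000L,
                             sequence = substr(seq_chr, 1, 2000))
  regions <- extract_intergenic(genes, replicon, min_length = 40,
                                extension = 100)
  # gaps: 60, 50, 20 -> only the first two qualify
  expect_equal(regions$region_id, c("gA/gB", "gB/gC"))
  expect_equal(regions$core_start[1], 500L)
  expect_equal(regions$core_end[1], 560L)
  expect_equal(regions$extended_start[1], 400L)
  expect_equal(regions$extended_end[1], 660L)
  expect_equal(nchar(regions$sequence[1]), 260L)
  expect_equal(regions$sequence[1],
               substr(replicon$sequence, 401, 660))
  # extension clips at replicon ends
  g2 <- genes
  g2$start[1] <- 0L; g2$end[1] <- 50L; g2$start[2] <- 120L
  r2 <- extract_intergenic(g2, replicon, min_length = 40, extension = 100)
  expect_equal(r2$extended_start[1], 0L)
  # overlapping genes yield no region
  g3 <- tibble::tibble(
    gene_id = c("x", "y"), locus_tag = c("x", "y"), replicon_id = "rep",
    species = "sp", taxon_group = "grp",
    start = c(0L, 400L), end = c(500L, 900L), strand = "+"
  )
  expect_equal(nrow(extract_intergenic(g3, replicon)), 0L)
  # missing sequence errors
  norep <- tibble::tibble(replicon_id = "rep", length = 2000L,
                          sequence = NA_character_)
  expect_error(extract_intergenic(genes, norep), "sequence")
})

test_that("intergenic coordinates agree with an interval oracle on simulated annotations", {
  set.seed(604)
  for (rep in 1:20) {
    g <- random_gene_table(sample(5:20, 1), p_small = 0.7)
    rep_len <- max(g$end) + 300L
    replicon <- tibble::tibble(
      replicon_id = "oracle_rep", length = rep_len,
      sequence = paste(sample(c("A", "C", "G", "T"), rep_len, replace = TRUE),
                       collapse = "")
    )
    regions <- extract_intergenic(g, replicon, min_length = 40, extension = 100)
    # oracle: enumerate qualifying adjacent pairs independently
    expected <- 0L
    for (i in seq_len(nrow(g) - 1)) {
      gap_positions <- sum(seq(0, rep_len) >= g$end[i] &
                             seq(0, rep_len) < g$start[i + 1])
      qualifies <- g$start[i + 1] >= g$end[i] && gap_positions >= 40
      if (qualifies) {
        expected <- expected + 1L
        row <- regions[regions$gene_left == g$gene_id[i], ]
        expect_equal(row$core_end - row$core_start, gap_positions)
        expect_equal(row$extended_start, max(0L, g$end[i] - 100L))
        expect_equal(row$extended_end, min(rep_len, g$start[i + 1] + 100L))
      }
    }
    expect_equal(nrow(regions), expected)
  }
})

test_that("a planted consensus is the unique top hit at the maximum score", {
  set.seed(605)
  bases <- c("A", "C", "G", "T")
  consensus <- "TGTGACCGGTATCACA"   # CRP consensus with concrete spacer
  seq_chars <- sample(bases, 300, replace = TRUE)
  seq_chars[101:116] <- strsplit(consensus, "")[[1]]
  region <- tibble::tibble(
    region_id = "r", replicon_id = "rep", gene_left = "a", gene_right = "b",
    core_start = 0L, core_end = 300L, extended_start = 0L,
    extended_end = 300L, sequence = paste(seq_chars, collapse = "")
  )
  anchor <- tss_anchor(tss = 250, strand = "+")
  hits <- scan_pwm(region, anchor, crp_motif(), threshold = 0.9)
  top <- hits[hits$pwm_score == max(hits$pwm_score), ]
  expect_true(all(top$offset == 100L))
  expect_equal(max(hits$pwm_score), max_pwm_score(crp_motif()))
  # the palindromic CRP motif scores identically on both strands
  expect_setequal(top$strand, c("+", "-"))
})

test_that("reverse-complementing the region mirrors the hit list", {
  set.seed(606)
  bases <- c("A", "C", "G", "T")
  n <- 300
  seq_chars <- sample(bases, n, replace = TRUE)
  # non-palindromic motif so strand labels matter
  motif <- consensus_to_pwm("TGTGACGTAAGGCCTA", name = "asym")
  seq_chars[81:96] <- strsplit(motif$consensus, "")[[1]]
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[seq_chars])
  region_fwd <- tibble::tibble(
    region_id = "r", replicon_id = "rep", gene_left = "a", gene_right = "b",
    core_start = 0L, core_end = n, extended_start = 0L, extended_end = n,
    sequence = paste(seq_chars, collapse = "")
  )
  region_rc <- region_fwd
  region_rc$sequence <- paste(rc, collapse = "")
  # anchors mirrored: TSS at p on + maps to n-1-p on the flipped region
  anchor_fwd <- tss_anchor(tss = 250, strand = "+")
  anchor_rc <- tss_anchor(tss = n - 1 - 250, strand = "-")
  h_fwd <- scan_pwm(region_fwd, anchor_fwd, motif, threshold = 0.55)
  h_rc <- scan_pwm(region_rc, anchor_rc, motif, threshold = 0.55)
  expect_equal(nrow(h_fwd), nrow(h_rc))
  key_fwd <- h_fwd[order(h_fwd$tss_first, h_fwd$strand),
                   c("tss_first", "tss_last", "pwm_score")]
  key_rc <- h_rc[order(h_rc$tss_first, h_rc$strand),
                 c("tss_first", "tss_last", "pwm_score")]
  expect_equal(as.data.frame(key_fwd), as.data.frame(key_rc))
  # strand labels swap
  expect_equal(sort(table(h_fwd$strand)), sort(table(h_rc$strand)),
               ignore_attr = TRUE)
})

test_that("scan_pwm rejects a window shorter than the motif", {
  region <- tibble::tibble(
    region_id = "r", replicon_id = "rep", gene_left = "a", gene_right = "b",
    core_start = 0L, core_end = 10L, extended_start = 0L, extended_end = 10L,
    sequence = "ACGTACGTAC"
  )
  expect_error(scan_pwm(region, tss_anchor(5), crp_motif()), "longer")
})

test_that("rank_sites combines score and conservation ranks with documented tie-breaks", {
  prof <- tibble::tibble(position = 1:300, ref_base = "A",
                         identity = rep(1, 300))
  hits <- tibble::tibble(
    region_id = "r", strand = "+",
    offset = c(10L, 50L, 90L),
    rep_start = c(10L, 50L, 90L), rep_end = c(26L, 66L, 106L),
    tss_first = c(-240L, -200L, -160L), tss_last = c(-225L, -185L, -145L),
    center = c(-232.5, -192.5, -152.5),
    pwm_score = c(5, 9, 7)
  )
  ranked <- rank_sites(hits, prof)
  # equal conservation: order by score
  expect_equal(ranked$pwm_score[ranked$combined_rank], c(9, 7, 5))
  # single hit gets rank 1
  one <- rank_sites(hits[1, ], prof)
  expect_equal(one$combined_rank, 1L)
  # conservation dominates when scores tie
  prof2 <- prof
  prof2$identity[51:66] <- 0.2
  hits2 <- hits
  hits2$pwm_score <- c(7, 7, 7)
  ranked2 <- rank_sites(hits2, prof2)
  expect_equal(ranked2$offset[ranked2$combined_rank == 3], 50L)
  # equal everything: most upstream first
  hits3 <- hits
  hits3$pwm_score <- c(7, 7, 7)
  ranked3 <- rank_sites(hits3, prof)
  expect_equal(ranked3$tss_first, sort(hits3$tss_first))
  # span outside the profile errors
  expect_error(rank_sites(dplyr::mutate(hits, offset = c(290L, 50L, 90L)),
                          prof), "outside")
  expect_equal(ranked$conservation, rep(1, 3))
})
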