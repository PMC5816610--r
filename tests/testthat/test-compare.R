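label_tbl <- function(labels, id = "cas", species = "sp", group = "grp") {
  n <- length(labels)
  g <- tibble::tibble(
    gene_id = sprintf("%s_g%d", id, seq_len(n)),
    locus_tag = sprintf("%s_g%d", id, seq_len(n)),
    replicon_id = paste0(id, "_rep"), species = species, taxon_group = group,
    start = as.integer(seq_len(n) * 1000L),
    end = as.integer(seq_len(n) * 1000L + 500L),
    strand = "+", product = NA_character_,
    ec_numbers = rep(list(character(0)), n), cog = NA_character_,
    labels = labels
  )
  tibble::tibble(
    cassette_id = id, replicon_id = paste0(id, "_rep"), species = species,
    taxon_group = group, start = min(g$start), end = max(g$end),
    n_genes = n, genes = list(g), fingerprint = list(labels)
  )
}

test_that("gene_compatible reports a shared label with kind priority ec3 > cog > role", {
  expect_equal(gene_compatible("ec3:4.1.2", c("ec3:4.1.2", "cog:COG3684")),
               "ec3:4.1.2")
  expect_true(is.na(gene_compatible("ec3:3.2.1", "ec3:2.7.1")))
  # enumerate all kind pairs: the higher-priority shared kind always wins
  kinds <- c(ec3 = "ec3:1.1.1", cog = "cog:COG1", role = "role:transporter")
  for (k1 in names(kinds)) {
    for (k2 in names(kinds)) {
      shared <- unique(c(kinds[[k1]], kinds[[k2]]))
      got <- gene_compatible(shared, shared)
      want <- kinds[[c("ec3", "cog", "role")[min(match(c(k1, k2), c("ec3", "cog", "role")))]]]
      expect_equal(got, want)
    }
  }
  expect_true(is.na(gene_compatible(character(0), "ec3:1.1.1")))
})

test_that("matching requires equal label values, not just kinds", {
  a <- label_tbl(list("role:transporter"), id = "a")
  b <- label_tbl(list("role:transcription_factor"), id = "b")
  expect_equal(match_cassettes(a, b)$match_size, 0L)
  c1 <- label_tbl(list("ec3:4.1.2"), id = "c")
  c2 <- label_tbl(list("ec3:4.1.3"), id = "d")
  expect_equal(match_cassettes(c1, c2)$match_size, 0L)
})

test_that("a cassette matched against itself pairs every labelled gene", {
  labels <- list("ec3:4.1.2", character(0), c("role:transporter"),
                 "ec3:2.7.1", character(0))
  cas <- label_tbl(labels, id = "self")
  m <- match_cassettes(cas, cas)
  expect_equal(m$match_size, 3L)
  expect_equal(tidy(m)$index_a, tidy(m)$index_b)
})

test_that("maximum matching beats greedy pairing on multi-label genes", {
  # gene a1 matches both b-genes, a2 only matches b1: greedy left-to-right
  # pairing of a1-b1 would block a2; the maximum matching finds both pairs
  a <- label_tbl(list(c("ec3:1.1.1", "ec3:2.2.2"), "ec3:1.1.1"), id = "a")
  b <- label_tbl(list("ec3:1.1.1", "ec3:2.2.2"), id = "b")
  m <- match_cassettes(a, b)
  expect_equal(m$match_size, 2L)
})

test_that("match size equals brute force over injective assignments, and is symmetric and monotone", {
  set.seed(501)
  pool <- c(paste0("ec3:", c("1.1.1", "2.7.1", "3.2.1", "4.1.2", "5.3.1")),
            "role:transporter", "role:transcription_factor", "cog:COG1")
  for (i in 1:120) {
    la <- random_label_sets(sample(1:7, 1), pool)
    lb <- random_label_sets(sample(1:7, 1), pool)
    a <- label_tbl(la, id = "a")
    b <- label_tbl(lb, id = "b")
    m <- match_cassettes(a, b)
    expect_equal(m$match_size, brute_force_match_size(la, lb))
    # symmetry
    expect_equal(match_cassettes(b, a)$match_size, m$match_size)
    # bound
    expect_lte(m$match_size, min(length(la), length(lb)))
    # monotonicity: deleting a gene never increases the match size
    if (length(la) > 1) {
      drop <- sample(length(la), 1)
      a2 <- label_tbl(la[-drop], id = "a")
      expect_lte(match_cassettes(a2, b)$match_size, m$match_size)
    }
  }
})

test_that("matching agrees with igraph maximum bipartite matching", {
  skip_if_not_installed("igraph")
  set.seed(502)
  pool <- c("ec3:1.1.1", "ec3:2.7.1", "ec3:3.2.1", "role:transporter")
  for (i in 1:50) {
    la <- random_label_sets(sample(2:7, 1), pool)
    lb <- random_label_sets(sample(2:7, 1), pool)
    m <- match_cassettes(label_tbl(la, id = "a"), label_tbl(lb, id = "b"))
    edges <- integer(0)
    for (u in seq_along(la)) {
      for (v in seq_along(lb)) {
        if (length(intersect(la[[u]], lb[[v]])) > 0) {
          edges <- c(edges, u, length(la) + v)
        }
      }
    }
    g <- igraph::make_bipartite_graph(
      c(rep(FALSE, length(la)), rep(TRUE, length(lb))),
      edges = edges
    )
    expect_equal(m$match_size,
                 igraph::max_bipartite_match(g)$matching_size)
  }
})

test_that("identical fingerprints reach the match bound", {
  labels <- list("ec3:1.1.1", "ec3:2.7.1", "role:transporter")
  a <- label_tbl(labels, id = "a")
  b <- label_tbl(labels, id = "b")
  expect_equal(match_cassettes(a, b)$match_size, 3L)
})

test_that("conserved-combination search recovers a planted combination across groups", {
  planted <- c("ec3:2.7.1", "ec3:3.2.1", "ec3:4.1.2", "role:transporter",
               "role:transcription_factor")
  db <- dplyr::bind_rows(
    label_tbl(as.list(planted), id = "c1", species = "sp1", group = "grpA"),
    label_tbl(as.list(c(planted, "ec3:9.9.9")), id = "c2", species = "sp2",
              group = "grpB"),
    label_tbl(as.list(planted), id = "c3", species = "sp3", group = "grpC"),
    # noise cassettes with partial overlaps
    label_tbl(list("ec3:2.7.1", "ec3:5.5.5"), id = "n1", species = "sp4",
              group = "grpA"),
    label_tbl(list("ec3:6.6.6", "role:transporter"), id = "n2",
              species = "sp5", group = "grpB")
  )
  res <- search_conserved_combinations(db, min_size = 5, min_groups = 3)
  expect_equal(nrow(res), 1L)
  expect_equal(res$combination[[1]], sort(planted))
  expect_equal(res$group_count, 3L)
  expect_equal(sort(res$support[[1]]$cassette_id), c("c1", "c2", "c3"))
  # no false maximal combination of size >= 5: verify every reported
  # combination against an independent per-cassette subset check
  for (k in seq_len(nrow(res))) {
    comb <- res$combination[[k]]
    for (ci in seq_len(nrow(db))) {
      fp <- db$fingerprint[[ci]]
      covered_oracle <- brute_force_match_size(as.list(comb), fp) == length(comb)
      expect_equal(db$cassette_id[ci] %in% res$support[[k]]$cassette_id,
                   covered_oracle)
    }
  }
})

test_that("search returns nothing for disjoint-label databases and empty input", {
  db <- dplyr::bind_rows(
    label_tbl(list("ec3:1.1.1", "ec3:2.2.2"), id = "a", group = "grpA"),
    label_tbl(list("ec3:3.3.3", "ec3:4.4.4"), id = "b", group = "grpB")
  )
  expect_equal(nrow(search_conserved_combinations(db, min_size = 1)), 0L)
  empty <- db[0, ]
  expect_equal(nrow(search_conserved_combinations(empty)), 0L)
})

test_that("the fixture database yields the six-label combination at min_size 6", {
  fx <- cassette_fixtures()
  db <- dplyr::bind_rows(fx$yih, fx$lac)
  res <- search_conserved_combinations(db, min_size = 6, min_groups = 2)
  expect_gte(nrow(res), 1L)
  expect_equal(res$combination[[1]],
               sort(c("ec3:2.3.1", "ec3:2.7.1", "ec3:3.2.1", "ec3:4.1.2",
                      "role:transcription_factor", "role:transporter")))
  expect_equal(res$group_count[1], 2L)
})
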