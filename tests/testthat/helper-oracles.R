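# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, exhaustive property
# checks, and (where available) igraph as a third-party cross-check.

# maximum matching size by brute force over all injective assignments of
# genes of a to genes of b (labels_a/labels_b: lists of label vectors)
brute_force_match_size <- function(labels_a, labels_b) {
  na <- length(labels_a)
  nb <- length(labels_b)
  compat <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j) {
    length(intersect(labels_a[[i]], labels_b[[j]])) > 0
  }))
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (na - i + 1) <= best) return()   # prune
    if (i > na) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count)                 # leave gene i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && compat[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nb), 0L)
  best
}

# exhaustive boundary check: does a cassette partition satisfy the gap rule,
# maximality, and coverage of every run of length >= min_genes?
check_cassette_partition <- function(genes, cassettes, max_gap, min_genes) {
  gaps <- genes$start[-1] - genes$end[-nrow(genes)]
  member <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(cassettes))) {
    idx <- match(cassettes$genes[[i]]$gene_id, genes$gene_id)
    if (any(is.na(idx))) return(FALSE)
    if (any(diff(sort(idx)) != 1)) return(FALSE)        # contiguity
    if (!is.na(member[idx[1]])) return(FALSE)           # disjointness
    member[idx] <- cassettes$cassette_id[i]
    if (length(idx) < min_genes) return(FALSE)
    idx <- sort(idx)
    internal <- gaps[idx[-length(idx)]]
    if (length(internal) > 0 && any(internal >= max_gap)) return(FALSE)
    # maximality at both flanks
    if (idx[1] > 1 && gaps[idx[1] - 1] < max_gap) return(FALSE)
    if (idx[length(idx)] < nrow(genes) &&
        gaps[idx[length(idx)]] < max_gap) return(FALSE)
  }
  # every gene inside a qualifying run must be covered
  run <- cumsum(c(1L, as.integer(!(gaps < max_gap))))
  for (r in unique(run)) {
    in_run <- which(run == r)
    if (length(in_run) >= min_genes) {
      if (any(is.na(member[in_run]))) return(FALSE)
      if (length(unique(member[in_run])) != 1) return(FALSE)
    } else {
      if (any(!is.na(member[in_run]))) return(FALSE)
    }
  }
  TRUE
}

# number of qualifying cassettes via igraph connected components
igraph_cassette_count <- function(genes, max_gap, min_genes) {
  gaps <- genes$start[-1] - genes$end[-nrow(genes)]
  joined <- which(gaps < max_gap)
  g <- igraph::make_empty_graph(n = nrow(genes), directed = FALSE)
  if (length(joined) > 0) {
    g <- igraph::add_edges(g, rbind(joined, joined + 1L))
  }
  comp <- igraph::components(g)
  sum(comp$csize >= min_genes)
}

# score a pair of gapped strings under the affine convention
# gap(L) = gap_open + (L - 1) * gap_extend
score_gapped_pair <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  score <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (i in seq_along(ca)) {
    if (ca[i] == "-") {
      score <- score + if (in_gap_a) gap_extend else gap_open
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (cb[i] == "-") {
      score <- score + if (in_gap_b) gap_extend else gap_open
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      score <- score + if (ca[i] == cb[i]) match else mismatch
      in_gap_a <- FALSE
      in_gap_b <- FALSE
    }
  }
  score
}

# brute-force optimal global alignment score by enumerating all alignments
# of two short strings (exponential; keep lengths <= 8)
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = -5, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, ga, gb) {
    if (i > length(ca) && j > length(cb)) {
      s <- score_gapped_pair(paste(ga, collapse = ""),
                             paste(gb, collapse = ""),
                             match, mismatch, gap_open, gap_extend)
      best <<- max(best, s)
      return()
    }
    if (i <= length(ca) && j <= length(cb)) {
      recurse(i + 1L, j + 1L, c(ga, ca[i]), c(gb, cb[j]))
    }
    if (i <= length(ca)) recurse(i + 1L, j, c(ga, ca[i]), c(gb, "-"))
    if (j <= length(cb)) recurse(i, j + 1L, c(ga, "-"), c(gb, cb[j]))
  }
  recurse(1L, 1L, character(0), character(0))
  best
}

# random gene table with a configurable mix of small/large/edge-case gaps
random_gene_table <- function(n_genes, p_small = 0.5, edge_cases = TRUE) {
  lens <- sample(100:800, n_genes, replace = TRUE)
  pool <- function() {
    r <- runif(1)
    if (edge_cases && r < 0.1) return(sample(c(299L, 300L), 1))
    if (r < p_small) sample(c(-50:298), 1) else sample(300:1500, 1)
  }
  gaps <- if (n_genes > 1) vapply(seq_len(n_genes - 1), function(i) pool(),
                                  integer(1)) else integer(0)
  starts <- 100L + c(0L, cumsum(lens[-n_genes] + gaps))
  # negative gaps can push starts out of order; sort and recompute ids
  tab <- tibble::tibble(
    start = as.integer(starts), end = as.integer(starts + lens)
  )
  tab <- tab[order(tab$start, tab$end), ]
  tab$gene_id <- sprintf("g%03d", seq_len(n_genes))
  tab$locus_tag <- tab$gene_id
  tab$replicon_id <- "oracle_rep"
  tab$species <- "sp"
  tab$taxon_group <- "grp"
  tab$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tab[, c("gene_id", "locus_tag", "replicon_id", "species", "taxon_group",
          "start", "end", "strand")]
}

# random label sets for matching oracles
random_label_sets <- function(n_genes, pool, max_labels = 2) {
  lapply(seq_len(n_genes), function(i) {
    k <- sample(0:max_labels, 1)
    if (k == 0) character(0) else sample(pool, k)
  })
}
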