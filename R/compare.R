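#' Shared function label between two genes
#'
#' Two genes are compatible when their label sets intersect. When several
#' labels are shared, one is reported with kind priority
#' `ec3` > `cog` > `role` (alphabetical within a kind), so the reported
#' label is deterministic.
#'
#' @param labels_a,labels_b Character vectors of encoded labels (see
#'   [function_label()]).
#' @return The shared label string, or `NA_character_` if the sets are
#'   disjoint.
#' @examples
#' gene_compatible(c("ec3:4.1.2"), c("ec3:4.1.2", "cog:COG3684"))
#' @export
gene_compatible <- function(labels_a, labels_b) {
  shared <- intersect(labels_a, labels_b)
  if (length(shared) == 0) return(NA_character_)
  pri <- match(label_kind(shared), c("ec3", "cog", "role"))
  shared[order(pri, shared)][1]
}

# Kuhn's augmenting-path maximum bipartite matching. `adj` is a list over
# left vertices of ascending integer vectors of right neighbours. Left
# vertices are processed in index order and neighbours tried in ascending
# order, so the result is deterministic.
kuhn_matching <- function(adj, n_right) {
  env <- new.env(parent = emptyenv())
  env$match_right <- rep(0L, n_right)   # right -> left
  for (u in seq_along(adj)) {
    env$seen <- rep(FALSE, n_right)
    augment(u, adj, env)
  }
  match_left <- rep(0L, length(adj))
  for (v in seq_len(n_right)) {
    if (env$match_right[v] > 0L) match_left[env$match_right[v]] <- v
  }
  match_left
}

# depth-first augmenting search; mutates match_right/seen in `env`
augment <- function(u, adj, env) {
  for (v in adj[[u]]) {
    if (!env$seen[v]) {
      env$seen[v] <- TRUE
      if (env$match_right[v] == 0L || augment(env$match_right[v], adj, env)) {
        env$match_right[v] <- u
        return(TRUE)
      }
    }
  }
  FALSE
}

# extract label-set list + gene ids from a cassette row or a gene table
as_cassette_genes <- function(x, role_rules = default_role_rules()) {
  if (is.data.frame(x) && "genes" %in% names(x) && is.list(x$genes)) {
    if (nrow(x) != 1) abort("expected a single cassette row")
    g <- x$genes[[1]]
    id <- x$cassette_id[1]
  } else if (is.data.frame(x)) {
    g <- x
    id <- if ("cassette_id" %in% names(g) && !all(is.na(g$cassette_id))) {
      g$cassette_id[1]
    } else "cassette"
  } else {
    abort("expected a cassette row or a gene table")
  }
  if (!"labels" %in% names(g)) g <- add_fingerprint(g, role_rules)
  list(id = id, gene_id = g$gene_id, labels = g$labels)
}

#' Maximum functional-content match between two cassettes
#'
#' Builds the compatibility graph (gene of `a` x gene of `b`, edge iff the
#' genes share a function label) and computes a maximum bipartite matching
#' by augmenting-path search, so genes carrying several labels are paired
#' optimally rather than greedily. Genes of `a` are processed in
#' chromosomal order and partners tried in order, making the reported
#' pairing deterministic.
#'
#' @param a,b Cassette rows (from [assemble_cassettes()] /
#'   [build_cassette_db()]) or gene tables; fingerprints are computed with
#'   `role_rules` if absent.
#' @param role_rules Keyword rules used when fingerprints must be computed.
#' @return An object of class `cassette_match` with elements `cassette_a`,
#'   `cassette_b`, `pairs` (tibble: `index_a`, `index_b`, `gene_a`,
#'   `gene_b`, `shared_label`), `match_size` and `matched_combination`
#'   (sorted label multiset). Use [tidy()] for the pairs and [glance()]
#'   for the one-row summary.
#' @export
match_cassettes <- function(a, b, role_rules = default_role_rules()) {
  ca <- as_cassette_genes(a, role_rules)
  cb <- as_cassette_genes(b, role_rules)
  na <- length(ca$labels)
  nb <- length(cb$labels)
  adj <- lapply(seq_len(na), function(i) {
    which(vapply(seq_len(nb), function(j) {
      !is.na(gene_compatible(ca$labels[[i]], cb$labels[[j]]))
    }, logical(1)))
  })
  match_left <- if (na > 0) kuhn_matching(adj, nb) else integer(0)
  paired <- which(match_left > 0L)
  pairs <- tibble(
    index_a = paired,
    index_b = match_left[paired],
    gene_a = ca$gene_id[paired],
    gene_b = cb$gene_id[match_left[paired]],
    shared_label = vapply(paired, function(i) {
      gene_compatible(ca$labels[[i]], cb$labels[[match_left[i]]])
    }, character(1))
  )
  structure(
    list(
      cassette_a = ca$id, cassette_b = cb$id,
      n_genes_a = na, n_genes_b = nb,
      pairs = pairs,
      match_size = nrow(pairs),
      matched_combination = sort(pairs$shared_label)
    ),
    class = "cassette_match"
  )
}

#' @export
print.cassette_match <- function(x, ...) {
  cat("Cassette match: ", x$cassette_a, " vs ", x$cassette_b, "\n", sep = "")
  cat("  match size: ", x$match_size, " (", x$n_genes_a, " x ",
      x$n_genes_b, " genes)\n", sep = "")
  if (x$match_size > 0) {
    cat("  matched combination: ",
        paste(x$matched_combination, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname match_cassettes
#' @param x A `cassette_match` object.
#' @param ... Unused.
#' @export
tidy.cassette_match <- function(x, ...) {
  x$pairs
}

#' @rdname match_cassettes
#' @export
glance.cassette_match <- function(x, ...) {
  tibble(
    cassette_a = x$cassette_a, cassette_b = x$cassette_b,
    match_size = x$match_size,
    n_genes_a = x$n_genes_a, n_genes_b = x$n_genes_b,
    matched_combination = paste(x$matched_combination, collapse = ",")
  )
}

# TRUE iff the label multiset `combination` can be matched one-to-one onto
# distinct genes of a cassette whose label sets contain them
covers_combination <- function(fingerprint, combination) {
  k <- length(combination)
  if (k == 0) return(TRUE)
  if (length(fingerprint) < k) return(FALSE)
  adj <- lapply(combination, function(lab) {
    which(vapply(fingerprint, function(ls) lab %in% ls, logical(1)))
  })
  sum(kuhn_matching(adj, length(fingerprint)) > 0L) == k
}

#' Search a cassette database for conserved function combinations
#'
#' Finds maximal function-label multisets that are carried (via one-to-one
#' gene matching) by cassettes in several distinct taxonomic groups --
#' the cross-taxon signal used to transfer pathway annotations between
#' unrelated species. Candidate combinations are generated by intersecting
#' observed cassette fingerprints (the maximum-matching intersection of
#' every cross-group cassette pair), never by enumerating a blind powerset;
#' each candidate's support is then verified against every cassette in the
#' database.
#'
#' @param db Cassette tibble from [build_cassette_db()] (must carry
#'   fingerprints).
#' @param min_size Minimum combination size (default 4).
#' @param min_groups Minimum number of distinct `taxon_group`s that must
#'   support a combination (default 2).
#' @return Tibble sorted by (size desc, group count desc, label order):
#'   `combination` (list-column of sorted label multisets),
#'   `combination_str`, `size`, `group_count`, `n_cassettes`, and
#'   `support` (list-column of tibbles `cassette_id`, `species`,
#'   `taxon_group`).
#' @export
search_conserved_combinations <- function(db, min_size = 4L, min_groups = 2L) {
  stopifnot(min_size >= 1, min_groups >= 1)
  if (nrow(db) == 0) return(empty_combination_table())
  if (!"fingerprint" %in% names(db)) {
    abort("cassette db lacks fingerprints; build it with build_cassette_db()")
  }
  fps <- db$fingerprint
  groups <- db$taxon_group
  n <- nrow(db)

  cand <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (identical(groups[i], groups[j]) && !is.na(groups[i])) next
      m <- match_cassettes(db[i, ], db[j, ])
      if (m$match_size >= min_size) {
        key <- paste(m$matched_combination, collapse = "\t")
        assign(key, m$matched_combination, envir = cand)
      }
    }
  }
  combos <- mget(ls(cand), envir = cand)
  if (length(combos) == 0) return(empty_combination_table())

  rows <- purrr::map(unname(combos), function(comb) {
    covered <- vapply(fps, covers_combination, logical(1),
                      combination = comb)
    sup <- db[covered, c("cassette_id", "species", "taxon_group")]
    tibble(
      combination = list(comb),
      combination_str = paste(comb, collapse = ","),
      size = length(comb),
      group_count = length(unique(sup$taxon_group)),
      n_cassettes = nrow(sup),
      support = list(sup)
    )
  })
  out <- bind_rows(rows) %>% filter(.data$group_count >= min_groups)
  if (nrow(out) == 0) return(empty_combination_table())

  # drop combinations that are strict sub-multisets of another kept one
  is_sub <- function(a, b) {
    ta <- table(a); tb <- table(b)
    all(names(ta) %in% names(tb)) &&
      all(ta <= tb[names(ta)])
  }
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(vapply(seq_len(nrow(out)), function(j) {
      i != j && out$size[j] > out$size[i] &&
        is_sub(out$combination[[i]], out$combination[[j]])
    }, logical(1)))
  }, logical(1))
  out[keep, ] %>%
    arrange(dplyr::desc(.data$size), dplyr::desc(.data$group_count),
            .data$combination_str)
}

empty_combination_table <- function() {
  tibble(
    combination = list(), combination_str = character(0),
    size = integer(0), group_count = integer(0), n_cassettes = integer(0),
    support = list()
  )
}
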