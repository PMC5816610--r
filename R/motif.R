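IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a position weight matrix from an IUPAC consensus
#'
#' Each consensus position distributes one count equally over its allowed
#' bases; a pseudocount is added to every base and the column normalised,
#' then converted to log-odds (bits) against the background. With the
#' default pseudocount 0.25 and uniform background, a fully specified
#' position scores `log2(0.625/0.25) = 1.32` bits on a match and -1 bit on
#' a mismatch, while an `N` position scores 0 for every base.
#'
#' @param consensus IUPAC consensus string, e.g. `"TGTGANNNNNNTCACA"`.
#' @param name Motif name.
#' @param pseudocount Added to each base count per column (default 0.25).
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1. Default uniform.
#' @return Object of class `motif_model`: list with `name`, `matrix`
#'   (4 x L log-odds in bits, rows A, C, G, T), `background`, `consensus`.
#' @examples
#' crp <- consensus_to_pwm("TGTGANNNNNNTCACA", name = "CRP")
#' max_pwm_score(crp)
#' @export
consensus_to_pwm <- function(consensus, name = "motif", pseudocount = 0.25,
                             background = rep(0.25, 4)) {
  stopifnot(abs(sum(background) - 1) < 1e-8, pseudocount >= 0)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (length(chars) < 4) abort("motif consensus shorter than 4 nt")
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    abort(paste0("invalid IUPAC characters in consensus: ",
                 paste(unique(bad), collapse = ", ")))
  }
  bases <- c("A", "C", "G", "T")
  mat <- vapply(chars, function(ch) {
    allowed <- IUPAC_MAP[[ch]]
    counts <- setNames(rep(0, 4), bases)
    counts[allowed] <- 1 / length(allowed)
    p <- (counts + pseudocount) / (1 + 4 * pseudocount)
    log2(p / background)
  }, numeric(4))
  rownames(mat) <- bases
  structure(
    list(name = name, matrix = mat, background = background,
         consensus = consensus),
    class = "motif_model"
  )
}

#' Default CRP binding-site model
#'
#' The palindromic CRP consensus `TGTGA-N6-TCACA` expanded to a position
#' weight matrix with pseudocount 0.25 against a uniform background.
#' Fully replaceable via [read_motif()].
#'
#' @inheritParams consensus_to_pwm
#' @return A `motif_model`.
#' @export
crp_motif <- function(pseudocount = 0.25, background = rep(0.25, 4)) {
  consensus_to_pwm("TGTGANNNNNNTCACA", name = "CRP",
                   pseudocount = pseudocount, background = background)
}

#' Read a motif model from a text file
#'
#' Two formats are accepted: a single-line IUPAC consensus, or a
#' whitespace-delimited matrix of four rows (log-odds weights for A, C, G,
#' T). Lines starting with `#` are comments; the first comment may carry
#' the motif name (`# name`).
#'
#' @param path File path.
#' @inheritParams consensus_to_pwm
#' @return A `motif_model`.
#' @export
read_motif <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  name <- "motif"
  cm <- grep("^#", lines, value = TRUE)
  if (length(cm) > 0) name <- stringr::str_trim(sub("^#+", "", cm[1]))
  lines <- stringr::str_trim(lines[!grepl("^#", lines) & nzchar(stringr::str_trim(lines))])
  if (length(lines) == 1 && grepl("^[A-Za-z]+$", lines)) {
    return(consensus_to_pwm(lines, name = name, pseudocount = pseudocount,
                            background = background))
  }
  if (length(lines) != 4) {
    abort(paste0("motif file '", path,
                 "' must be a one-line IUPAC consensus or 4 numeric rows"))
  }
  rows <- lapply(lines, function(l) as.numeric(strsplit(l, "[ \t]+")[[1]]))
  if (length(unique(lengths(rows))) != 1) {
    abort("motif matrix rows have unequal lengths")
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- c("A", "C", "G", "T")
  if (ncol(mat) < 4) abort("motif shorter than 4 positions")
  structure(
    list(name = name, matrix = mat, background = background,
         consensus = NULL),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif '", x$name, "': ", ncol(x$matrix), " positions, max score ",
      round(max_pwm_score(x), 2), " bits\n", sep = "")
  invisible(x)
}

#' @rdname consensus_to_pwm
#' @param motif A `motif_model`.
#' @return `max_pwm_score()` returns the maximum attainable log-odds score
#'   in bits (sum of per-column maxima).
#' @export
max_pwm_score <- function(motif) {
  sum(apply(motif$matrix, 2, max))
}

# log-odds score of every window of length L along `chars` (+ strand);
# returns numeric vector of length length(chars) - L + 1
pwm_scores_along <- function(chars, motif) {
  mat <- motif$matrix
  L <- ncol(mat)
  n <- length(chars)
  if (n < L) return(numeric(0))
  idx <- match(chars, rownames(mat))   # NA for ambiguous/N bases
  scores <- numeric(n - L + 1)
  for (k in seq_len(L)) {
    col <- mat[, k]
    v <- col[idx[k:(k + n - L)]]
    v[is.na(v)] <- min(col)   # unknown base scores as the worst base
    scores <- scores + unname(v)
  }
  scores
}

revcomp_chars <- function(chars) {
  unname(rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]))
}
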