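#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment of two nucleotide strings. A gap
#' of length L costs `gap_open + (L - 1) * gap_extend`. The traceback is
#' deterministic: ties prefer the diagonal, then a gap in `b`, then a gap
#' in `a`.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   +1/-1/-5/-1).
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings) and `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = -5, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) abort("align_pair: empty sequence")
  align_pair_cpp(a, b, match, mismatch, gap_open, gap_extend)
}

#' Center-star multiple alignment of orthologous regions
#'
#' Progressive multiple alignment with the first sequence as the star
#' center (the designated reference): every other sequence is globally
#' aligned to the reference with affine gap penalties, and the pairwise
#' alignments are merged on reference coordinates under "once a gap,
#' always a gap". Suited to closely related orthologous intergenic
#' regions, where the star topology loses little against full progressive
#' methods.
#'
#' @param seqs Character vector of two or more non-empty nucleotide
#'   strings, each at most 5000 nt; the first is the reference. Names are
#'   kept (unnamed sequences are called `seq1`, `seq2`, ...).
#' @inheritParams align_pair
#' @return Object of class `star_alignment`: list with `aligned` (named
#'   character vector of equal-length gapped strings), `reference` (name
#'   of the first sequence) and `scores` (pairwise alignment scores vs the
#'   reference).
#' @export
align_orthologous_regions <- function(seqs, match = 1, mismatch = -1,
                                      gap_open = -5, gap_extend = -1) {
  stopifnot(is.character(seqs), length(seqs) >= 2)
  if (any(!nzchar(seqs))) abort("align_orthologous_regions: empty sequence")
  if (any(nchar(seqs) > 5000)) {
    abort("align_orthologous_regions: sequences longer than 5000 nt")
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ref <- seqs[[1]]
  others <- seqs[-1]
  pw <- lapply(others, function(s) {
    align_pair(ref, s, match, mismatch, gap_open, gap_extend)
  })

  L <- nchar(ref)
  # ins[[k]][j + 1] = gap run in the reference row before ref position j + 1
  ins_counts <- lapply(pw, function(al) {
    refrow <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    counts <- integer(L + 1)
    slot <- 1L
    for (ch in refrow) {
      if (ch == "-") counts[slot] <- counts[slot] + 1L else slot <- slot + 1L
    }
    counts
  })
  ins <- Reduce(pmax, ins_counts, accumulate = FALSE)
  if (length(ins_counts) == 0) ins <- integer(L + 1)

  pad_row <- function(refrow, otherrow) {
    # redistribute `otherrow` characters into the global insertion slots
    out <- character(0)
    slot <- 1L
    buf <- character(0)
    flush <- function(buf, slot) {
      c(buf, rep("-", ins[slot] - length(buf)))
    }
    for (i in seq_along(refrow)) {
      if (refrow[i] == "-") {
        buf <- c(buf, otherrow[i])
      } else {
        out <- c(out, flush(buf, slot), otherrow[i])
        buf <- character(0)
        slot <- slot + 1L
      }
    }
    c(out, flush(buf, slot))
  }

  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  ref_row <- pad_row(ref_chars, ref_chars)
  rows <- c(list(paste(ref_row, collapse = "")),
            lapply(pw, function(al) {
              a <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
              b <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
              paste(pad_row(a, b), collapse = "")
            }))
  aligned <- setNames(unlist(rows), names(seqs))
  structure(
    list(aligned = aligned, reference = names(seqs)[1],
         scores = vapply(pw, function(al) al$score, numeric(1))),
    class = "star_alignment"
  )
}

#' @export
print.star_alignment <- function(x, ...) {
  cat("Center-star alignment of ", length(x$aligned), " sequences (",
      nchar(x$aligned[[1]]), " columns), reference: ", x$reference,
      "\n", sep = "")
  invisible(x)
}

#' Per-column conservation of a multiple alignment
#'
#' For every reference (ungapped) column, the identity fraction is the
#' number of sequences whose residue equals the reference residue (the
#' reference itself included) divided by the total number of sequences;
#' a gap counts as a mismatch. Columns where the reference is gapped
#' (insertions relative to the reference) carry no reference position and
#' are skipped.
#'
#' @param alignment A `star_alignment` from [align_orthologous_regions()],
#'   or a named character vector of equal-length gapped strings whose
#'   first element is the reference.
#' @return Tibble of class `conservation_profile`: `position` (1-based
#'   ungapped reference position), `ref_base`, `identity` in \[0, 1\].
#' @export
conservation_profile <- function(alignment) {
  aligned <- if (inherits(alignment, "star_alignment")) {
    alignment$aligned
  } else {
    alignment
  }
  stopifnot(is.character(aligned), length(aligned) >= 1)
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  ref <- mat[1, ]
  keep <- ref != "-"
  ident <- colMeans(mat[, keep, drop = FALSE] ==
                      matrix(ref[keep], nrow = nrow(mat), ncol = sum(keep),
                             byrow = TRUE))
  out <- tibble(
    position = seq_len(sum(keep)),
    ref_base = ref[keep],
    identity = as.numeric(ident)
  )
  class(out) <- c("conservation_profile", class(out))
  out
}
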