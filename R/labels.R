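#' Function labels
#'
#' A cassette's functional fingerprint is built from three kinds of per-gene
#' function labels, encoded as `"kind:value"` strings:
#'
#' * `ec3` -- an Enzyme Commission number truncated to its first three
#'   fields, e.g. `"ec3:4.1.2"` (aldolases). Two enzymes sharing the first
#'   three EC fields catalyse the same reaction type.
#' * `role` -- a coarse functional role inferred from the annotated product
#'   text, e.g. `"role:transporter"` or `"role:transcription_factor"`.
#' * `cog` -- a cluster-of-orthologous-genes identifier, e.g.
#'   `"cog:COG3684"`, used as an optional refinement when both genes carry
#'   one.
#'
#' @param kind One of `"ec3"`, `"role"`, `"cog"`.
#' @param value Label value, e.g. `"4.1.2"`.
#' @return `function_label()` returns the encoded label string;
#'   `label_kind()` and `label_value()` split it back apart.
#' @examples
#' function_label("ec3", "4.1.2")
#' label_kind("role:transporter")
#' label_value("cog:COG3684")
#' @export
function_label <- function(kind, value) {
  kind <- match.arg(kind, c("ec3", "role", "cog"), several.ok = FALSE)
  paste0(kind, ":", value)
}

#' @rdname function_label
#' @param label An encoded `"kind:value"` label string.
#' @export
label_kind <- function(label) {
  sub(":.*$", "", label)
}

#' @rdname function_label
#' @export
label_value <- function(label) {
  sub("^[^:]*:", "", label)
}

#' Truncate an EC number to its first three fields
#'
#' Enzyme Commission numbers have four fields
#' (class.subclass.sub-subclass.serial); the first three identify the
#' reaction type. Truncation keeps the first three fields when all three are
#' defined numerals and drops the label otherwise (IMG-style annotations use
#' `"-"` for undetermined fields).
#'
#' @param ec Character vector of EC number strings, e.g. `"4.1.2.17"`.
#' @return Character vector the same length as `ec`: the `"ec3:"`-encoded
#'   truncated label, or `NA` where the first three fields are not all
#'   numeric.
#' @examples
#' truncate_ec(c("4.1.2.17", "3.2.1", "2.7.-.-"))
#' @export
truncate_ec <- function(ec) {
  stopifnot(is.character(ec))
  out <- rep(NA_character_, length(ec))
  fields <- stringr::str_split(stringr::str_trim(ec), stringr::fixed("."))
  ok <- vapply(fields, function(f) {
    length(f) >= 3 && all(grepl("^[0-9]+$", f[1:3]))
  }, logical(1))
  out[ok] <- vapply(fields[ok], function(f) {
    function_label("ec3", paste(f[1:3], collapse = "."))
  }, character(1))
  out
}

#' Default keyword rules mapping product text to functional roles
#'
#' Case-insensitive substring keywords per role. The default vocabulary
#' covers the two roles that matter for carbohydrate-metabolism cassette
#' comparison -- transporters and transcription factors -- with keyword
#' lists spanning the six major local-regulator families of enteric sugar
#' metabolism (LacI, ROK, DeoR, AraC, GntR, TetR). Fully overridable.
#'
#' @return Named list: role name -> character vector of keywords.
#' @examples
#' names(default_role_rules())
#' @export
default_role_rules <- function() {
  list(
    transporter = c("transporter", "permease", "PTS", "symporter"),
    transcription_factor = c(
      "transcriptional regulator", "transcription factor", "repressor",
      "activator", "DeoR", "LacI", "GntR", "AraC", "TetR", "ROK"
    )
  )
}

#' Assign functional roles from annotated product text
#'
#' @param product Character vector of free-text product descriptions.
#' @param role_rules Named list of keyword vectors, as
#'   [default_role_rules()].
#' @return List (length of `product`) of character vectors of encoded
#'   `"role:"` labels; empty where no keyword matches.
#' @examples
#' assign_roles("DeoR-family transcriptional regulator")
#' @export
assign_roles <- function(product, role_rules = default_role_rules()) {
  stopifnot(is.character(product), is.list(role_rules))
  lapply(product, function(p) {
    if (is.na(p)) return(character(0))
    hit <- vapply(role_rules, function(kw) {
      any(stringr::str_detect(
        stringr::str_to_lower(p),
        stringr::fixed(stringr::str_to_lower(kw))
      ))
    }, logical(1))
    vapply(names(role_rules)[hit], function(r) function_label("role", r),
           character(1), USE.NAMES = FALSE)
  })
}

#' Fingerprint genes with function labels
#'
#' Adds a `labels` list-column to a gene table: per gene, the union of its
#' truncated-EC labels, keyword-derived role labels, and COG label (if any).
#' A cassette's fingerprint is the ordered list of these per-gene label
#' sets.
#'
#' @param genes Gene table (see [read_annotation()]) with at least columns
#'   `product`, `ec_numbers` (list-column of EC strings) and optionally
#'   `cog`.
#' @param role_rules Keyword rules, as [default_role_rules()].
#' @return The input tibble with a `labels` list-column of sorted label
#'   vectors (possibly empty).
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("a", "b"),
#'   product = c("sugar kinase", "hypothetical protein"),
#'   ec_numbers = list("2.7.1.210", character(0)),
#'   cog = c(NA, NA)
#' )
#' add_fingerprint(genes)$labels
#' @export
add_fingerprint <- function(genes, role_rules = default_role_rules()) {
  stopifnot(is.data.frame(genes), "product" %in% names(genes),
            "ec_numbers" %in% names(genes))
  cogs <- if ("cog" %in% names(genes)) genes$cog else rep(NA_character_, nrow(genes))
  roles <- assign_roles(genes$product, role_rules)
  labels <- purrr::pmap(
    list(genes$ec_numbers, roles, cogs),
    function(ecs, rls, cg) {
      ec3 <- truncate_ec(as.character(ecs))
      ec3 <- ec3[!is.na(ec3)]
      cog <- if (!is.na(cg) && nzchar(cg)) function_label("cog", cg) else character(0)
      sort(unique(c(ec3, rls, cog)))
    }
  )
  out <- as_tibble(genes)
  out$labels <- labels
  out
}

#' @rdname add_fingerprint
#' @return `cassette_fingerprint()` returns just the list of per-gene label
#'   sets, in gene order.
#' @export
cassette_fingerprint <- function(genes, role_rules = default_role_rules()) {
  add_fingerprint(genes, role_rules)$labels
}
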