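#' Read a replicate Ct table
#'
#' Expects tab-delimited text with header columns `gene`, `condition`,
#' `replicate_id`, `ct`, `is_reference_gene` (logical or 0/1).
#'
#' @param path File path.
#' @return Tibble with those columns, `is_reference_gene` as logical.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "condition", "replicate_id", "ct", "is_reference_gene")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Ct table lacks columns: ", paste(missing, collapse = ", ")))
  }
  tab$is_reference_gene <- as.logical(tab$is_reference_gene)
  tab$replicate_id <- as.character(tab$replicate_id)
  if (any(tab$ct <= 0)) abort("Ct values must be positive")
  as_tibble(tab)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Classical relative quantification with amplification efficiency fixed
#' at 2. Per replicate, the target's Ct is normalised against the
#' arithmetic mean Ct of the reference genes measured in the same
#' replicate (delta Ct); the condition's mean delta Ct is then referenced
#' to the reference condition (delta-delta Ct) and the fold change is
#' `2^-ddCt`. The standard deviation combines the replicate delta-Ct
#' standard deviations of the condition and the reference condition in
#' quadrature and is mapped through the exponential at first order
#' (`sd_fold = fold * ln(2) * sd_ddct`).
#'
#' @param table Ct tibble with columns `gene`, `condition`,
#'   `replicate_id`, `ct`, `is_reference_gene` (see [read_ct_table()]).
#' @param reference_condition Condition all fold changes are expressed
#'   relative to (default `"glucose"`).
#' @return Tibble of class `fold_changes`: `gene`, `condition`,
#'   `fold_change`, `sd` (`NA` when a condition has a single replicate),
#'   `n_replicates`, `reference_condition`. Fold changes in the reference
#'   condition are 1 by construction.
#' @examples
#' ct <- simulate_ct_table(noise_sd = 0)
#' ddct_fold_changes(ct)
#' @export
ddct_fold_changes <- function(table, reference_condition = "glucose") {
  stopifnot(is.data.frame(table))
  table <- as_tibble(table)
  if (!reference_condition %in% table$condition) {
    abort(paste0("reference condition '", reference_condition,
                 "' absent from the Ct table"))
  }
  conds <- unique(table$condition)
  refs <- table %>% filter(.data$is_reference_gene)
  no_ref <- setdiff(conds, unique(refs$condition))
  if (length(no_ref) > 0) {
    abort(paste0("no reference gene measured in condition(s): ",
                 paste(no_ref, collapse = ", ")))
  }
  ref_ct <- refs %>%
    group_by(.data$condition, .data$replicate_id) %>%
    summarise(ref_ct = mean(.data$ct), .groups = "drop")

  dct <- table %>%
    left_join(ref_ct, by = c("condition", "replicate_id")) %>%
    mutate(dct = .data$ct - .data$ref_ct)
  if (any(is.na(dct$dct))) {
    abort("some replicates lack a reference-gene measurement")
  }
  per_cond <- dct %>%
    group_by(.data$gene, .data$condition) %>%
    summarise(
      mean_dct = mean(.data$dct),
      sd_dct = if (n() > 1) sd(.data$dct) else NA_real_,
      n_replicates = n(),
      .groups = "drop"
    )
  baseline <- per_cond %>%
    filter(.data$condition == reference_condition) %>%
    select("gene", base_dct = "mean_dct", base_sd = "sd_dct")
  out <- per_cond %>%
    left_join(baseline, by = "gene") %>%
    mutate(
      ddct = .data$mean_dct - .data$base_dct,
      fold_change = 2^(-.data$ddct),
      sd_ddct = sqrt(.data$sd_dct^2 + .data$base_sd^2),
      sd = .data$fold_change * log(2) * .data$sd_ddct,
      reference_condition = reference_condition
    ) %>%
    select("gene", "condition", "fold_change", "sd", "n_replicates",
           "reference_condition") %>%
    arrange(.data$gene, .data$condition)
  class(out) <- c("fold_changes", class(out))
  out
}
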