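#' Validated configuration for an end-to-end run
#'
#' Collects the parameters of every stage in one validated object.
#' Unknown keys are rejected so typos fail before any stage runs.
#'
#' @param annotations Data frame with columns `path`, `format` and
#'   optionally `fasta`, `species`, `taxon_group` -- one row per
#'   annotated replicon. `NULL` to skip the cassette stages.
#' @param max_gap,min_genes Cassette assembly parameters
#'   (see [assemble_cassettes()]).
#' @param min_size,min_groups Conserved-combination search thresholds
#'   (see [search_conserved_combinations()]).
#' @param match_pair Optional character vector of two cassette ids to
#'   match explicitly.
#' @param role_rules Keyword rules (see [default_role_rules()]).
#' @param ortholog_fasta Optional multi-FASTA of orthologous regions
#'   (reference first) for the footprint stage.
#' @param motif_path Optional motif file ([read_motif()]); the CRP
#'   default is used when absent.
#' @param tss,tss_strand,window_up,window_down Transcription-start anchor
#'   for the footprint stage (offset within the reference region).
#' @param scan_threshold Hit threshold as a fraction of the maximum bit
#'   score.
#' @param ct_path Optional Ct table for the expression stage.
#' @param reference_condition Reference condition for fold changes.
#' @param seed Integer seed recorded in the run report.
#' @param out_dir Output directory for stage tables.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations = NULL, max_gap = 300L,
                            min_genes = 2L, min_size = 4L, min_groups = 2L,
                            match_pair = NULL,
                            role_rules = default_role_rules(),
                            ortholog_fasta = NULL, motif_path = NULL,
                            tss = NULL, tss_strand = "+",
                            window_up = 250L, window_down = 50L,
                            scan_threshold = 0.6,
                            ct_path = NULL,
                            reference_condition = "glucose",
                            seed = 1L, out_dir = tempfile("run")) {
  cfg <- as.list(environment())
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("path", "format") %in% names(annotations)))
    missing <- !file.exists(annotations$path)
    if (any(missing)) {
      abort(paste0("annotation file(s) not found: ",
                   paste(annotations$path[missing], collapse = ", ")))
    }
  }
  stopifnot(cfg$max_gap >= 0, cfg$min_genes >= 1, cfg$min_size >= 1,
            cfg$min_groups >= 1, cfg$scan_threshold > 0,
            cfg$scan_threshold <= 1)
  if (!is.null(match_pair)) stopifnot(length(match_pair) == 2)
  if (!is.null(ortholog_fasta) && is.null(tss)) {
    abort("footprint stage needs a tss offset")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys are `pipeline_config()`
#'   arguments (unknown keys are rejected by the constructor).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$annotations)) {
    vals$annotations <- bind_rows(lapply(vals$annotations, as_tibble))
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the declared stages in order -- annotation reading, cassette
#' database construction, conserved-combination search (plus an optional
#' explicit cassette match), regulatory-region footprinting, and
#' delta-delta-Ct quantification -- writing each stage's table to
#' `out_dir` and returning a run report with parameters, seed and
#' per-stage record counts. Reruns with an identical configuration
#' produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(as.integer(config$seed))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  counts <- list()
  outputs <- character(0)

  db <- NULL
  if (!is.null(config$annotations)) {
    ann <- config$annotations
    genes <- run_stage("read-annotations", {
      bind_rows(lapply(seq_len(nrow(ann)), function(i) {
        read_annotation(
          ann$path[i], format = ann$format[i],
          fasta = if ("fasta" %in% names(ann)) ann$fasta[i] else NULL,
          species = if ("species" %in% names(ann)) ann$species[i] else NULL,
          taxon_group = if ("taxon_group" %in% names(ann)) ann$taxon_group[i] else NULL
        )$genes
      }))
    })
    counts$genes <- nrow(genes)
    db <- run_stage("build-db", {
      build_cassette_db(genes, role_rules = config$role_rules,
                        max_gap = config$max_gap,
                        min_genes = config$min_genes)
    })
    counts$cassettes <- nrow(db)
    db_path <- file.path(config$out_dir, "cassettes.tsv")
    write_table(
      db %>% mutate(
        gene_list = vapply(.data$genes, function(g)
          paste(g$gene_id, collapse = ";"), character(1)),
        label_list = vapply(.data$fingerprint, function(fp)
          paste(vapply(fp, paste, character(1), collapse = "|"),
                collapse = ";"), character(1))
      ) %>% select(-"genes", -"fingerprint"),
      db_path
    )
    outputs <- c(outputs, db_path)

    combos <- run_stage("search", {
      search_conserved_combinations(db, min_size = config$min_size,
                                    min_groups = config$min_groups)
    })
    counts$conserved_combinations <- nrow(combos)
    combo_path <- file.path(config$out_dir, "conserved_combinations.tsv")
    write_table(combos %>% select(-"combination", -"support"), combo_path)
    outputs <- c(outputs, combo_path)

    if (!is.null(config$match_pair)) {
      m <- run_stage("match", {
        ia <- which(db$cassette_id == config$match_pair[1])
        ib <- which(db$cassette_id == config$match_pair[2])
        if (length(ia) != 1 || length(ib) != 1) {
          abort("match_pair ids not found in the cassette db")
        }
        match_cassettes(db[ia, ], db[ib, ])
      })
      counts$match_size <- m$match_size
      match_path <- file.path(config$out_dir, "match.tsv")
      write_table(tidy(m), match_path)
      outputs <- c(outputs, match_path)
    }
  }

  if (!is.null(config$ortholog_fasta)) {
    hits <- run_stage("footprint", {
      ss <- Biostrings::readDNAStringSet(config$ortholog_fasta)
      seqs <- setNames(as.character(ss), names(ss))
      aln <- align_orthologous_regions(seqs)
      profile <- conservation_profile(aln)
      motif <- if (is.null(config$motif_path)) crp_motif() else
        read_motif(config$motif_path)
      region <- tibble(region_id = names(seqs)[1], replicon_id = "region",
                       gene_left = NA_character_, gene_right = NA_character_,
                       core_start = 0L, core_end = nchar(seqs[[1]]),
                       extended_start = 0L, extended_end = nchar(seqs[[1]]),
                       sequence = seqs[[1]])
      anchor <- tss_anchor(config$tss, config$tss_strand,
                           config$window_up, config$window_down)
      rank_sites(scan_pwm(region, anchor, motif,
                          threshold = config$scan_threshold), profile)
    })
    counts$site_hits <- nrow(hits)
    hits_path <- file.path(config$out_dir, "site_hits.tsv")
    write_table(hits, hits_path)
    outputs <- c(outputs, hits_path)
  }

  if (!is.null(config$ct_path)) {
    fc <- run_stage("ddct", {
      ddct_fold_changes(read_ct_table(config$ct_path),
                        reference_condition = config$reference_condition)
    })
    counts$fold_changes <- nrow(fc)
    fc_path <- file.path(config$out_dir, "fold_changes.tsv")
    write_table(fc, fc_path)
    outputs <- c(outputs, fc_path)
  }

  report <- structure(
    list(
      package_version = as.character(utils::packageVersion("cassettecompare")),
      seed = config$seed,
      parameters = config[setdiff(names(config), c("role_rules"))],
      counts = counts,
      outputs = outputs
    ),
    class = "pipeline_report"
  )
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (package ", x$package_version, ", seed ", x$seed, ")\n",
      sep = "")
  for (nm in names(x$counts)) {
    cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  }
  cat("  outputs: ", length(x$outputs), " file(s) in ",
      dirname(x$outputs[1] %||% ""), "\n", sep = "")
  invisible(x)
}
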