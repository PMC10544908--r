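DEFAULT_GROUPING <- c(Fp = "Festuca-type", Fp2x = "Festuca-type",
                      Fp4x = "Festuca-type", Fg = "Festuca-type",
                      Lm = "Lolium-type", Lp = "Lolium-type")

#' Build a pipeline run configuration
#'
#' Collects the dataset paths and every stage parameter, with defaults
#' matching the package's documented contracts. Configurations serialise
#' losslessly to JSON ([save_config()] / [load_config()]).
#'
#' @param dir Dataset directory (layout as written by [generate_dataset()]).
#'   Alternatively give the individual paths.
#' @param outdir Output directory for tables and reports.
#' @param reads_r1,reads_r2 Named character vectors (by region) of FASTQ
#'   paths; derived from `dir` when NULL.
#' @param references,ref_metadata,sample_sheet Paths; derived from `dir`.
#' @param grouping Named map species -> parental type.
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @param ... Stage parameter overrides (see Details in the vignette):
#'   `min_overlap`, `max_mismatch_frac`, `delta_q`, `max_bc_mismatch`,
#'   `max_primer_mismatch`, `filter_min_identity`, `filter_min_cov`,
#'   `min_len`, `margin_step`, `n_draws`, `dominance_threshold`,
#'   `codominance_threshold`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dir = NULL, outdir = NULL,
                       reads_r1 = NULL, reads_r2 = NULL,
                       references = NULL, ref_metadata = NULL,
                       sample_sheet = NULL,
                       grouping = DEFAULT_GROUPING, seed = 1L, ...) {
  params <- list(min_overlap = 20L, max_mismatch_frac = 0.25, delta_q = 6L,
                 max_bc_mismatch = 0L, max_primer_mismatch = 2L,
                 filter_min_identity = 0.75, filter_min_cov = 0.5,
                 min_len = 200L, margin_step = 0.005, n_draws = 1L,
                 dominance_threshold = 0.99, codominance_threshold = 0.60)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  params <- modifyList(params, dots)
  cfg <- list(dir = dir, outdir = outdir, reads_r1 = reads_r1,
              reads_r2 = reads_r2, references = references,
              ref_metadata = ref_metadata, sample_sheet = sample_sheet,
              grouping = grouping, seed = as.integer(seed), params = params)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$grouping <- as.list(x$grouping)  # keep species names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$grouping <- unlist(x$grouping)
  do.call(run_config, c(x[setdiff(names(x), "params")], as.list(x$params)))
}

# Hash of the analysis configuration (parameters, grouping, seed) — output
# and input locations deliberately excluded so identical analyses stamp
# identically wherever they run.
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(config[c("params", "grouping", "seed")], tf,
                       auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(tf)), 1, 8)
}

run_stamp <- function(config) {
  sprintf("ribodom %s config=%s seed=%d",
          as.character(utils::packageVersion("ribodom")),
          config_hash(config), config$seed)
}

#' Preprocess one region's reads into a ribotype table
#'
#' Chains merge -> demultiplex -> trim -> reference filter -> dereplicate
#' for the reads of one region, with exact per-stage read accounting.
#'
#' @param pairs Read-pair tibble (`id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`).
#' @param sheet Sample sheet rows of this region.
#' @param db A [ref_db()].
#' @param region Region label.
#' @param params Parameter list as in [run_config()].
#' @return A list: `ribotypes` (a `ribotype_tbl`), `reads` (per-read stage
#'   outcomes), `accounting` (tibble of per-stage counts).
#' @export
preprocess_reads <- function(pairs, sheet, db, region,
                             params = run_config()$params) {
  sheet <- sheet[sheet$region == region, , drop = FALSE]
  p <- params
  merged <- merge_read_pairs(pairs, min_overlap = p$min_overlap,
                             max_mismatch_frac = p$max_mismatch_frac,
                             delta_q = p$delta_q)
  contigs <- merged |> filter(.data$merged)
  dmx <- demultiplex(contigs, sheet, max_bc_mismatch = p$max_bc_mismatch)
  assigned <- dmx |> filter(.data$demux_status == "assigned")
  trm <- trim_barcodes_and_primers(
    assigned, fwd_primer = sheet$fwd_primer[1],
    rev_primer = sheet$rev_primer[1],
    max_primer_mismatch = p$max_primer_mismatch)
  trimmed <- trm |> filter(.data$trimmed)
  flt <- reference_filter(trimmed, db, region,
                          min_identity = p$filter_min_identity,
                          min_cov = p$filter_min_cov)
  kept <- flt |> filter(.data$kept)
  ribo <- dereplicate(mutate(kept, region = region))

  accounting <- tibble::tibble(
    region = region,
    stage = c("input_pairs", "merged", "merge_rejected",
              "demux_assigned", "demux_unassigned", "demux_ambiguous",
              "trimmed", "trim_rejected", "filter_kept", "filter_discarded",
              "ribotypes"),
    n = c(nrow(pairs), nrow(contigs), nrow(pairs) - nrow(contigs),
          nrow(assigned), sum(dmx$demux_status == "unassigned"),
          sum(dmx$demux_status == "ambiguous"),
          nrow(trimmed), nrow(assigned) - nrow(trimmed),
          nrow(kept), nrow(trimmed) - nrow(kept),
          n_distinct(ribo$ribotype_id)))
  list(ribotypes = ribo, reads = flt, accounting = accounting)
}

#' Run the full analysis pipeline
#'
#' Executes reference database -> divergence & thresholds -> preprocessing
#' -> classification & singleton removal -> dominance -> diversity for every
#' region of a dataset, optionally writing all tables (stamped with the
#' package version and a configuration hash) plus a JSON run report.
#'
#' @param config A [run_config()]. When `config$dir` is set, file names
#'   follow the [generate_dataset()] layout.
#' @return A list with every stage result: `db`, `divergence`, `thresholds`,
#'   `ribotypes`, `classified`, `proportions`, `summary`, `report`,
#'   `diversity`, `correlation`, `anova`, `accounting`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  path_of <- function(given, default) {
    given %||% file.path(config$dir, default)
  }
  sheet_path <- path_of(config$sample_sheet, "sample_sheet.tsv")
  if (!file.exists(sheet_path)) {
    abort(sprintf("sample sheet not found: %s", sheet_path))
  }
  sheet <- stage("sample_sheet", read_sample_sheet(sheet_path))
  db <- stage("refdb", load_references(
    path_of(config$references, "references.fasta"),
    path_of(config$ref_metadata, "references_metadata.tsv")))
  regions <- sort(unique(sheet$region))

  divergence <- stage("divergence", bind_rows(
    purrr::map(regions, ~ between_group_mean_distance(db, .x))))
  thresholds <- stage("thresholds",
                      derive_identity_thresholds(divergence,
                                                 config$params$margin_step))

  per_region <- purrr::map(setNames(regions, regions), function(rg) {
    r1 <- path_of(config$reads_r1[[rg]], sprintf("%s_R1.fastq", rg))
    r2 <- path_of(config$reads_r2[[rg]], sprintf("%s_R2.fastq", rg))
    f1 <- stage("read_fastq", read_fastq(r1))
    f2 <- stage("read_fastq", read_fastq(r2))
    pairs <- tibble::tibble(id = f1$id, r1_seq = f1$seq, r1_qual = f1$qual,
                            r2_seq = f2$seq, r2_qual = f2$qual)
    pre <- stage("preprocess", preprocess_reads(pairs, sheet, db, rg,
                                                config$params))
    cls <- stage("classify", classify_ribotypes(
      pre$ribotypes, db, thresholds, config$grouping,
      min_len = config$params$min_len))
    cls <- remove_global_singletons(cls)
    list(pre = pre, classified = cls)
  })

  classified <- purrr::map(per_region, "classified")
  accounting <- bind_rows(purrr::map(per_region, ~ .x$pre$accounting))

  proportions <- stage("dominance", bind_rows(
    purrr::map(classified, sample_proportions, samples = sheet)))
  summary <- aggregate_proportions(proportions)
  report <- dominance_report(
    summary, dominance_threshold = config$params$dominance_threshold,
    codominance_threshold = config$params$codominance_threshold)

  seeds <- derive_seeds(config$seed, length(regions))
  diversity <- stage("diversity", bind_rows(purrr::map(
    seq_along(regions),
    ~ rarefied_diversity(classified[[regions[.x]]], seed = seeds[.x],
                         n_draws = config$params$n_draws, samples = sheet))))
  correlation <- stage("correlation", depth_bias_correlation(diversity))
  anova_tbl <- stage("anova", diversity |>
    group_by(.data$homeolog, .data$region) |>
    dplyr::group_modify(function(d, key) {
      if (n_distinct(d$generation) < 2 ||
          nrow(d) - n_distinct(d$generation) < 1) {
        return(tibble::tibble(F = NA_real_, df_between = NA_integer_,
                              df_within = NA_integer_, p_value = NA_real_,
                              flag = "insufficient_groups"))
      }
      glance(anova_one_way(d, D ~ generation))
    }) |>
    ungroup())

  res <- list(db = db, divergence = divergence, thresholds = thresholds,
              ribotypes = purrr::map(per_region, ~ .x$pre$ribotypes),
              classified = classified, proportions = proportions,
              summary = summary, report = report, diversity = diversity,
              correlation = correlation, anova = anova_tbl,
              accounting = accounting)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- run_stamp(config)
    out <- function(df, name) {
      write_tsv_stamped(df, file.path(config$outdir, name), stamp)
    }
    out(divergence, "divergence.tsv")
    out(thresholds, "thresholds.tsv")
    out(bind_rows(purrr::map(classified, ~ select(.x, -dplyr::any_of("mix")))),
        "classified.tsv")
    out(proportions, "proportions.tsv")
    out(summary, "dominance_summary.tsv")
    out(report, "dominance_report.tsv")
    out(diversity, "diversity.tsv")
    out(correlation, "correlation.tsv")
    out(anova_tbl, "anova.tsv")
    out(accounting, "read_accounting.tsv")
    jsonlite::write_json(
      list(stamp = stamp, seed = config$seed, params = config$params,
           accounting = accounting),
      file.path(config$outdir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
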