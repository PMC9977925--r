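#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Provide either a
#' simulation block (an [rrhp_sim_config()] or a list of its arguments) or
#' real inputs: a genome FASTA, per-library SAM/BAM alignments and a sample
#' sheet. Can also be loaded from a YAML file with the same field names.
#'
#' @param out_dir Output directory for all artifacts.
#' @param simulate Optional [rrhp_sim_config()] (or argument list) enabling
#'   the synthetic branch.
#' @param genome,alignments,sample_sheet Real-data inputs: FASTA path, a
#'   named vector of alignment paths (names = sample ids), and a sample
#'   sheet path or tibble.
#' @param gff Optional GFF3 gene models for DhmC annotation.
#' @param filter A [filter_params()].
#' @param q_max DhmC significance threshold on the adjusted p value.
#' @param span Lowess span of the voom-style mean-variance trend.
#' @param top_sites Leading sites per pair in the MDS diagnostic.
#' @param promoter_window,tts_window Annotation windows in bp.
#' @param seed Integer seed fixed before any stochastic stage.
#' @return A list of class `rrhp_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            genome = NULL, alignments = NULL,
                            sample_sheet = NULL, gff = NULL,
                            filter = filter_params(),
                            q_max = 0.05, span = 0.5, top_sites = 500,
                            promoter_window = c(-1000, 100),
                            tts_window = c(-100, 1000),
                            seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(genome) || is.null(alignments) || is.null(sample_sheet)) {
      abort("provide either `simulate` or all of `genome`, `alignments`, `sample_sheet`")
    }
    for (p in c(genome, unname(alignments))) {
      if (!file.exists(p)) abort(sprintf("input path does not exist: %s", p))
    }
  } else if (!inherits(simulate, "rrhp_sim_config")) {
    simulate$seed <- simulate$seed %||% seed
    simulate <- do.call(rrhp_sim_config, simulate)
  }
  if (!is.null(gff) && !file.exists(gff)) {
    abort(sprintf("gff path does not exist: %s", gff))
  }
  structure(
    list(out_dir = out_dir, simulate = simulate, genome = genome,
         alignments = alignments, sample_sheet = sample_sheet, gff = gff,
         filter = filter, q_max = q_max, span = span, top_sites = top_sites,
         promoter_window = promoter_window, tts_window = tts_window,
         seed = as.integer(seed)),
    class = "rrhp_pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return An `rrhp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_params, raw$filter)
  if (!is.null(raw$alignments)) raw$alignments <- unlist(raw$alignments)
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
}

# Write a results tibble with floating-point columns at 6 significant digits.
write_results_tsv <- function(tbl, path) {
  out <- mutate(tbl, across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Run the full RRHP pipeline
#'
#' Executes simulate (optional) -> quantify -> filter -> differential test ->
#' MDS -> annotate (optional) -> track export, writing every artifact under
#' `config$out_dir` and a machine-readable run report (`report.json`). Any
#' stage failure aborts with the stage name; artifacts of completed stages
#' are retained.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, the run report list (filter report, call counts,
#'   empirical-Bayes hyperparameters, per-library summaries, seed).
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", simulate_rrhp_experiment(
      config$simulate, out_dir = file.path(out, "sim")
    ))
    catalog <- sim$catalog
    sheet <- sim$sample_sheet
    aln_paths <- setNames(
      file.path(out, "sim", paste0(sheet$sample_id, ".sam")), sheet$sample_id
    )
  } else {
    catalog <- run_stage("digest", {
      sites <- scan_recognition_sites(config$genome)
      enumerate_junctions(sites)
    })
    sheet <- if (is.character(config$sample_sheet)) {
      read_sample_sheet(config$sample_sheet)
    } else {
      config$sample_sheet
    }
    aln_paths <- config$alignments
  }

  quant <- run_stage("quantify", {
    per_lib <- purrr::map(aln_paths[sheet$sample_id], count_junction_reads,
                          catalog = catalog)
    counts <- assemble_matrix(purrr::map(per_lib, "counts"), sheet,
                              catalog = catalog)
    summaries <- bind_rows(purrr::map(per_lib, "summary"), .id = "sample_id")
    write_count_matrix(counts, file.path(out, "counts.tsv"))
    list(counts = counts, summaries = summaries)
  })

  filt <- run_stage("filter", {
    res <- apply_filters(quant$counts, sheet, config$filter)
    write_count_matrix(res$counts, file.path(out, "counts_filtered.tsv"))
    readr::write_tsv(res$report, file.path(out, "filter_report.tsv"))
    res
  })

  fit <- run_stage("diff", {
    fit <- diff_hmc_test(filt$counts, sheet, span = config$span)
    write_results_tsv(tidy(fit), file.path(out, "results.tsv"))
    fit
  })
  calls <- call_dhmc(fit, q_max = config$q_max)

  mds <- run_stage("mds", {
    mds <- mds_coordinates(quant$counts, sheet, top_sites = config$top_sites)
    write_results_tsv(as_tibble(mds), file.path(out, "mds.tsv"))
    mds
  })

  annotation <- NULL
  if (!is.null(config$gff) && nrow(calls) > 0) {
    annotation <- run_stage("annotate", {
      bed <- file.path(out, "dhmc.bed")
      write_bed6(calls, bed)
      ann <- batch_annotate(calls, config$gff,
                            promoter_window = config$promoter_window,
                            tts_window = config$tts_window)
      readr::write_tsv(ann$annotations, file.path(out, "annotation.tsv"))
      jsonlite::write_json(
        setNames(as.list(ann$tally$n_sites), as.character(ann$tally$category)),
        file.path(out, "annotation_tally.json"), auto_unbox = TRUE
      )
      ann
    })
  }

  run_stage("tracks", write_igv_tracks(quant$counts, sheet, dhmcs = calls,
                                       dir = file.path(out, "tracks")))

  report <- list(
    seed = config$seed,
    n_libraries = nrow(sheet),
    library_summaries = quant$summaries,
    filter_report = filt$report,
    d0 = fit$d0, s0_sq = fit$s0_sq,
    n_dhmc = nrow(calls),
    n_higher_in_large = sum(calls$logFC > 0),
    n_higher_in_small = sum(calls$logFC < 0)
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(report, list(fit = fit, calls = calls, mds = mds,
                           annotation = annotation)))
}
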