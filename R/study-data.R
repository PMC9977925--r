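study_file <- function(name) {
  system.file("extdata", name, package = "rrhp", mustWork = TRUE)
}

#' Packaged tables of the profiled tilapia study
#'
#' Transcriptions of the study's published design and audit tables, shipped
#' so worked examples and desk-scale checks run without downloads:
#' `rrhp_study_morphometrics()` gives the ten full-sib Nile tilapia females
#' (five large `B`, five small `S`) with body weight and length at sampling;
#' `rrhp_study_libraries()` the per-library sequencing output (raw reads,
#' junction-assigned 5hmC reads, unique covered sites) for the ten
#' biological libraries and the two control sequencing runs;
#' `rrhp_study_cascade()` the dataset-level counts (total CCGG sites in the
#' reference assembly, captured unique sites across samples, the two filter
#' stages, the realised median threshold `Ymax`, and DhmC totals).
#'
#' @return A tibble.
#' @export
rrhp_study_morphometrics <- function() {
  readr::read_tsv(study_file("study_morphometrics.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname rrhp_study_morphometrics
#' @export
rrhp_study_libraries <- function() {
  readr::read_tsv(study_file("study_library_summary.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname rrhp_study_morphometrics
#' @export
rrhp_study_cascade <- function() {
  readr::read_tsv(study_file("study_cascade.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}
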