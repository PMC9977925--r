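#' Export genome-browser tracks
#'
#' Writes one bedGraph per library (junction counts at the strand-specific
#' 5' base of each junction: the first C of the motif for `+`, the last G
#' for `-`, so intervals never overlap) and, when DhmC calls are supplied, a
#' BED6 of the calls. All coordinates follow the junction catalog (0-based
#' half-open).
#'
#' @param counts Wide count matrix from [assemble_matrix()].
#' @param sample_sheet Sample sheet tibble.
#' @param dhmcs Optional DhmC table from [call_dhmc()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_igv_tracks <- function(counts, sample_sheet, dhmcs = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base_pos <- ifelse(counts$strand == "+", counts$site_start,
                     counts$site_start + 3L)
  paths <- character()
  for (sid in sample_sheet$sample_id) {
    nz <- counts[[sid]] > 0
    path <- file.path(dir, paste0(sid, ".bedGraph"))
    lines <- c(
      sprintf("track type=bedGraph name=\"%s 5hmC counts\"", sid),
      sprintf("%s\t%d\t%d\t%d", counts$contig[nz], base_pos[nz],
              base_pos[nz] + 1L, counts[[sid]][nz])
    )
    writeLines(lines, path)
    paths[sid] <- path
  }
  if (!is.null(dhmcs)) {
    bed <- file.path(dir, "dhmc.bed")
    write_bed6(dhmcs, bed)
    paths["dhmc"] <- bed
  }
  invisible(paths)
}
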