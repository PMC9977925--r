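#' Write DhmC calls as a BED6 file
#'
#' Single-nucleotide records (`end = start + 1`, 0-based half-open) with
#' sequential numeric peak IDs (`"1"`, `"2"`, ...), a carried-through score
#' slot (the adjusted p value when available, `"."` otherwise) and the
#' junction strand in column 6.
#'
#' @param dhmcs DhmC tibble (from [call_dhmc()]) with columns `contig`,
#'   `site_start`, `strand`, optionally `q_value`.
#' @param path Output path.
#' @param score_col Column carried into the score slot; `NULL` uses
#'   `q_value` when present.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(dhmcs, path, score_col = NULL) {
  score_col <- score_col %||% (if ("q_value" %in% names(dhmcs)) "q_value")
  score <- if (is.null(score_col)) rep(".", nrow(dhmcs))
           else format(dhmcs[[score_col]], digits = 6, trim = TRUE)
  bed <- tibble(
    chrom = dhmcs$contig,
    start = dhmcs$site_start,
    end = dhmcs$site_start + 1L,
    peak_id = as.character(seq_len(nrow(dhmcs))),
    score = if (nrow(dhmcs)) score else character(),
    strand = dhmcs$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file in the DhmC dialect
#'
#' Accepts strand codes `+`/`-` as well as the numeric convention `0` = `+`
#' and `1` = `-`.
#'
#' @param path BED6 path.
#' @return A tibble `contig`, `start`, `end`, `peak_id`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  peak_id = character(), score = character(),
                  strand = character()))
  }
  bed <- readr::read_tsv(
    path, col_names = c("contig", "start", "end", "peak_id", "score", "strand"),
    col_types = "ciiccc", progress = FALSE
  )
  decoded <- dplyr::recode(bed$strand, "0" = "+", "1" = "-",
                           "\u2212" = "-", .default = bed$strand)
  if (!all(decoded %in% c("+", "-"))) {
    abort("BED strand column must be one of +, -, 0, 1")
  }
  mutate(bed, strand = decoded, peak_id = as.character(.data$peak_id))
}

first_chr <- function(x) {
  vapply(x, function(v) if (length(v)) as.character(v[[1]]) else NA_character_,
         character(1))
}

#' Parse gene models from GFF3
#'
#' Reads gene/mRNA/exon features, converts 1-based GFF coordinates to
#' 0-based half-open, and derives the transcription start (TSS) and end
#' (TES) coordinates strand-awarely: for a `+` gene TSS is the span start,
#' for a `-` gene the last base of the span. Transcripts without exon
#' features contribute their whole span as a single exon.
#'
#' @param gff Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open), `tss`, `tes`, and a list-column `exons` of
#'   tibbles with `start`/`end` (0-based half-open, merged across
#'   transcripts).
#' @export
parse_gene_models <- function(gff) {
  gr <- rtracklayer::import(gff)
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  tx <- gr[type %in% c("mRNA", "transcript")]
  ex <- gr[type == "exon"]
  if (length(genes) == 0L) genes <- tx

  gene_ids <- first_chr(genes$ID)
  if (anyNA(gene_ids)) gene_ids <- first_chr(genes$Name)
  if (anyNA(gene_ids)) abort("gene features must carry an ID or Name attribute")

  tx_parent <- setNames(first_chr(tx$Parent), first_chr(tx$ID))
  ex_tx <- first_chr(ex$Parent)
  ex_gene <- ifelse(ex_tx %in% names(tx_parent), tx_parent[ex_tx], ex_tx)

  models <- tibble(
    gene_id = gene_ids,
    contig = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = BiocGenerics::start(genes) - 1L,
    end = BiocGenerics::end(genes)
  ) |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    )

  models$exons <- purrr::map(seq_len(nrow(models)), function(i) {
    gid <- models$gene_id[i]
    gex <- ex[!is.na(ex_gene) & ex_gene == gid]
    if (length(gex) == 0L) {
      return(tibble(start = models$start[i], end = models$end[i]))
    }
    merged <- GenomicRanges::reduce(gex)
    tibble(start = BiocGenerics::start(merged) - 1L,
           end = BiocGenerics::end(merged))
  })
  models
}

strand_window_ranges <- function(models, anchor, window) {
  # window is strand-relative (negative = upstream); returns 1-based IRanges
  lo <- ifelse(models$strand == "+", anchor + window[1], anchor - window[2])
  hi <- ifelse(models$strand == "+", anchor + window[2], anchor - window[1])
  GenomicRanges::GRanges(
    models$contig, IRanges::IRanges(start = lo + 1L, end = hi + 1L)
  )
}

#' Annotate sites with genomic features
#'
#' Assigns every site one category by the fixed priority
#' `promoter-TSS > TTS > exon > intron > intergenic`. The promoter and TTS
#' windows are strand-relative around the TSS/TES (negative = upstream of
#' the anchor in the gene's orientation). Each record also reports the gene
#' with the nearest TSS on the same contig and the signed, strand-aware
#' distance to that TSS (negative = upstream of the gene).
#'
#' @param sites Tibble with columns `contig` and `site_start` (or `start`),
#'   e.g. a DhmC table or a [read_bed6()] result.
#' @param models Gene models from [parse_gene_models()].
#' @param promoter_window Window around the TSS, in bp.
#' @param tts_window Window around the TES, in bp.
#' @return A tibble with `peak_id`, `contig`, `position`, `category`,
#'   `nearest_gene`, `distance_to_tss`.
#' @export
annotate_sites <- function(sites, models,
                           promoter_window = c(-1000, 100),
                           tts_window = c(-100, 1000)) {
  pos_col <- if ("site_start" %in% names(sites)) "site_start" else "start"
  pos <- as.integer(sites[[pos_col]])
  peak_id <- if ("peak_id" %in% names(sites)) as.character(sites$peak_id)
             else as.character(seq_along(pos))
  pts <- GenomicRanges::GRanges(sites$contig,
                                IRanges::IRanges(pos + 1L, pos + 1L))

  exon_gr <- GenomicRanges::GRanges(
    rep(models$contig, vapply(models$exons, nrow, integer(1))),
    IRanges::IRanges(
      start = unlist(purrr::map(models$exons, "start")) + 1L,
      end = unlist(purrr::map(models$exons, "end"))
    )
  )
  span_gr <- GenomicRanges::GRanges(
    models$contig, IRanges::IRanges(models$start + 1L, models$end)
  )
  prom_gr <- strand_window_ranges(models, models$tss, promoter_window)
  tts_gr <- strand_window_ranges(models, models$tes, tts_window)

  hits <- function(subject) {
    IRanges::overlapsAny(pts, subject)
  }
  in_prom <- hits(prom_gr)
  in_tts <- hits(tts_gr)
  in_exon <- hits(exon_gr)
  in_span <- hits(span_gr)

  category <- dplyr::case_when(
    in_prom ~ "promoter-TSS",
    in_tts ~ "TTS",
    in_exon ~ "exon",
    in_span ~ "intron",
    .default = "intergenic"
  )

  nearest_gene <- rep(NA_character_, length(pos))
  dist_tss <- rep(NA_integer_, length(pos))
  for (ctg in unique(sites$contig)) {
    g <- models[models$contig == ctg, ]
    idx <- which(sites$contig == ctg)
    if (nrow(g) == 0L) next
    g <- arrange(g, .data$gene_id)
    signed <- outer(pos[idx], g$tss, "-")
    signed[, g$strand == "-"] <- -signed[, g$strand == "-", drop = FALSE]
    best <- apply(abs(signed), 1L, which.min)
    nearest_gene[idx] <- g$gene_id[best]
    dist_tss[idx] <- signed[cbind(seq_along(idx), best)]
  }

  tibble(
    peak_id = peak_id, contig = sites$contig, position = pos,
    category = factor(category, levels = annotation_categories()),
    nearest_gene = nearest_gene, distance_to_tss = dist_tss
  )
}

annotation_categories <- function() {
  c("promoter-TSS", "TTS", "exon", "intron", "intergenic")
}

#' Annotate a BED of DhmCs and tally categories
#'
#' @param bed Path to a BED6 file (DhmC dialect) or a site tibble.
#' @param gff Path to a GFF3 file, or a parsed model tibble.
#' @param ... Passed to [annotate_sites()] (window arguments).
#' @return A list with `annotations` (per-peak tibble) and `tally` (tibble
#'   `category`, `n` over the full category vocabulary; sums to the peak
#'   count).
#' @export
batch_annotate <- function(bed, gff, ...) {
  sites <- if (is.character(bed)) read_bed6(bed) else bed
  models <- if (is.character(gff)) parse_gene_models(gff) else gff
  ann <- annotate_sites(sites, models, ...)
  tally <- ann |>
    count(.data$category, .drop = FALSE) |>
    rename(n_sites = "n")
  list(annotations = ann, tally = tally)
}
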