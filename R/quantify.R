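# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

read_alignment_file <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
  }
  bf <- Rsamtools::BamFile(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = NA)
  )
  rec <- Rsamtools::scanBam(bf, param = param)[[1]]
  tibble(
    query_id = rec$qname,
    contig = as.character(rec$rname),
    pos = rec$pos,
    reverse = bitwAnd(rec$flag, 16L) > 0L,
    sequence = as.character(rec$seq),
    cigar = rec$cigar,
    mapped = bitwAnd(rec$flag, 4L) == 0L & !is.na(rec$pos)
  )
}

#' Count junction reads against a catalog
#'
#' Implements the strand-aware extraction of aligned reads starting with
#' CCGG. A mapped forward read increments junction `(contig, s, +)` iff its
#' leftmost aligned base sits at 0-based coordinate `s` of a catalogued site
#' and its first four bases are `CCGG`; a mapped reverse read increments
#' `(contig, s, -)` iff its 5' end (rightmost reference coordinate) equals
#' `s + 3` and its biological first four bases (reverse complement of the
#' stored sequence's last four) are `CCGG`. Reads whose CIGAR clips the
#' biological 5' end are disqualified (the junction base must be aligned).
#' Every read increments at most one junction; duplicates are counted, since
#' RRHP signal is read abundance at the junction. Unmapped, clipped and
#' non-CCGG-start reads count only toward `raw_reads`.
#'
#' @param alignments Path to a SAM or BAM file, or a tibble with columns
#'   `query_id`, `contig`, `pos` (1-based leftmost), `reverse`, `sequence`
#'   (SAM orientation), `mapped`, and optionally `cigar`.
#' @param catalog Junction catalog from [enumerate_junctions()].
#' @return A list with `counts` (tibble `contig`, `site_start`, `strand`,
#'   `count`, one row per catalog junction) and `summary` (tibble
#'   `raw_reads`, `counted_5hmc`, `unique_sites`).
#' @export
count_junction_reads <- function(alignments, catalog) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignment_file(alignments)
  }
  aln <- as_tibble(alignments)
  if (!"cigar" %in% names(aln)) {
    aln$cigar <- paste0(nchar(aln$sequence), "M")
  }
  raw_reads <- nrow(aln)

  bad_contig <- setdiff(unique(aln$contig[aln$mapped]), unique(catalog$contig))
  if (length(bad_contig)) {
    abort(sprintf("alignment references contig(s) absent from catalog: %s",
                  paste(bad_contig, collapse = ", ")))
  }

  malformed <- aln$mapped & (is.na(aln$pos) | is.na(aln$sequence) |
                               aln$sequence == "" | is.na(aln$cigar))
  if (any(malformed)) {
    warn(sprintf("skipping %d malformed alignment record(s)", sum(malformed)))
  }
  ok <- aln$mapped & !malformed
  fwd <- ok & !aln$reverse
  rev <- ok & aln$reverse

  # biological 5' end must be aligned (no soft/hard clip on that side)
  clip5 <- rep(FALSE, nrow(aln))
  clip5[fwd] <- grepl("^[0-9]+[SH]", aln$cigar[fwd])
  clip5[rev] <- grepl("[0-9]+[SH]$", aln$cigar[rev])

  key <- rep(NA_character_, nrow(aln))
  starts_ccgg <- substr(aln$sequence, 1L, 4L) == "CCGG"
  use_f <- fwd & !clip5[seq_len(nrow(aln))] & starts_ccgg
  key[use_f] <- paste(aln$contig[use_f], aln$pos[use_f] - 1L, "+")

  if (any(rev)) {
    ref_w <- cigar_ref_width(aln$cigar)
    right0 <- aln$pos - 1L + ref_w - 1L  # 0-based rightmost ref coordinate
    # stored last four == CCGG  <=>  biological first four == CCGG
    ends_ccgg <- substr(aln$sequence, pmax(nchar(aln$sequence) - 3L, 1L),
                        nchar(aln$sequence)) == "CCGG"
    use_r <- rev & !clip5 & ends_ccgg
    key[use_r] <- paste(aln$contig[use_r], right0[use_r] - 3L, "-")
  }

  cat_key <- paste(catalog$contig, catalog$site_start, catalog$strand)
  hit <- factor(key[!is.na(key)], levels = cat_key)
  cnt <- as.integer(table(hit))
  counts <- tibble(
    contig = catalog$contig, site_start = catalog$site_start,
    strand = catalog$strand, count = cnt
  )
  list(
    counts = counts,
    summary = tibble(
      raw_reads = raw_reads,
      counted_5hmc = sum(cnt),
      unique_sites = sum(cnt > 0L)
    )
  )
}

#' Assemble the per-site count matrix
#'
#' Joins per-library junction counts into a wide site-by-library tibble.
#' Sites absent from a library get 0; site ordering is genomic (catalog
#' order); column order follows the sample sheet.
#'
#' @param columns Named list of per-library count tibbles (as returned by
#'   [simulate_counts()] or `count_junction_reads()$counts`).
#' @param sample_sheet Tibble with columns `sample_id`, `group`, `is_control`.
#' @param catalog Optional junction catalog fixing the site universe and
#'   order; defaults to the union of sites seen across libraries.
#' @return A tibble with key columns `contig`, `site_start`, `strand` and one
#'   integer count column per sample, in sample-sheet order.
#' @export
assemble_matrix <- function(columns, sample_sheet, catalog = NULL) {
  missing_cols <- setdiff(sample_sheet$sample_id, names(columns))
  if (length(missing_cols)) {
    abort(sprintf("no counts supplied for sample(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.null(catalog)) {
    catalog <- purrr::map(columns, ~ select(.x, "contig", "site_start", "strand")) |>
      bind_rows() |>
      distinct() |>
      arrange(.data$contig, .data$site_start, .data$strand)
  }
  out <- select(catalog, "contig", "site_start", "strand")
  for (sid in sample_sheet$sample_id) {
    col <- columns[[sid]]
    m <- left_join(out, col, by = c("contig", "site_start", "strand"))
    out[[sid]] <- as.integer(tidyr::replace_na(m$count, 0L))
  }
  out
}

#' Library summaries of a count matrix
#'
#' Per-library totals matching the study's audit columns: total
#' junction-assigned reads (`counted_5hmc`) and sites with at least one read
#' (`unique_sites`), plus the across-library union of covered sites, both
#' strand-resolved and strand-merged.
#'
#' @param counts Wide count matrix from [assemble_matrix()].
#' @param sample_sheet Sample sheet tibble.
#' @return A list with `per_library` (tibble `sample_id`, `counted_5hmc`,
#'   `unique_sites`) and `union` (tibble `unique_sites_across`,
#'   `unique_sites_across_strand_merged`).
#' @export
library_summaries <- function(counts, sample_sheet) {
  m <- count_matrix_values(counts, sample_sheet$sample_id)
  per <- tibble(
    sample_id = sample_sheet$sample_id,
    counted_5hmc = unname(colSums(m)),
    unique_sites = unname(colSums(m > 0))
  )
  covered <- rowSums(m) > 0
  merged <- counts[covered, c("contig", "site_start")] |> distinct()
  list(
    per_library = per,
    union = tibble(
      unique_sites_across = sum(covered),
      unique_sites_across_strand_merged = nrow(merged)
    )
  )
}

# Integer matrix of the sample columns of a wide count tibble.
count_matrix_values <- function(counts, sample_ids) {
  m <- as.matrix(counts[, sample_ids, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Write / read a wide count matrix as TSV
#'
#' @param counts Wide count matrix tibble.
#' @param path File path.
#' @return `path` (writer, invisibly) or the count tibble (reader).
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a sample sheet TSV
#'
#' Expects columns `sample_id`, `group`, `is_control`.
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample_id", "group", "is_control") %in% names(sheet)))
  mutate(sheet, is_control = as.logical(.data$is_control))
}
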