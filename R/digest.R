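#' Enumerate MspI (CCGG) recognition sites in a genome
#'
#' Performs a full step-1 sliding-window scan of every contig for the MspI
#' recognition motif CCGG. Coordinates are 0-based: `start` is the offset of
#' the first C on the plus strand, and the genome substring
#' `[start, start + 4)` equals `CCGG`. `N` bases never match (the enzyme is
#' sequence-exact; no IUPAC expansion).
#'
#' @param genome Genome in any form accepted by [as_genome()].
#' @return A tibble with columns `contig` and `start` (0-based), ordered by
#'   contig (genome order) then ascending coordinate.
#' @examples
#' scan_recognition_sites(c(chrT = "ACCGGTCCGGA"))
#' @export
scan_recognition_sites <- function(genome) {
  genome <- as_genome(genome)
  hits <- Biostrings::vmatchPattern("CCGG", genome, fixed = TRUE)
  purrr::imap(as.list(hits), function(ir, ctg) {
    tibble(contig = ctg, start = BiocGenerics::start(ir) - 1L)
  }) |>
    bind_rows() |>
    arrange(match(.data$contig, names(genome)), .data$start)
}

#' Build the strand-resolved junction catalog
#'
#' Each CCGG recognition site yields exactly two RRHP junctions, one per
#' strand. On the plus strand a junction read's leftmost aligned base is the
#' site's first C (`five_prime = start`); on the minus strand the read's
#' biological 5' end sits on the last G of the motif (`five_prime =
#' start + 3`). Because CCGG is its own reverse complement, reads from both
#' junctions begin with CCGG in their biological orientation.
#'
#' @param sites Tibble of recognition sites from [scan_recognition_sites()].
#' @return A tibble with columns `contig`, `site_start`, `strand`
#'   (`"+"`/`"-"`), and `five_prime` (0-based genome coordinate of the read's
#'   5' base). Keys `(contig, site_start, strand)` are unique; rows are in
#'   genomic order with `+` before `-` at each site.
#' @export
enumerate_junctions <- function(sites) {
  if (nrow(sites) == 0L) {
    return(tibble(
      contig = character(), site_start = integer(),
      strand = character(), five_prime = integer()
    ))
  }
  tidyr::crossing(sites, strand = c("+", "-")) |>
    mutate(
      site_start = as.integer(.data$start),
      five_prime = ifelse(.data$strand == "+", .data$site_start,
                          .data$site_start + 3L)
    ) |>
    select("contig", "site_start", "strand", "five_prime") |>
    arrange(match(.data$contig, unique(sites$contig)), .data$site_start,
            .data$strand)
}

#' In-silico MspI digestion
#'
#' Cuts every recognition site between the first C and the CGG (MspI cuts
#' C^CGG on the plus strand), returning the resulting fragments. The
#' concatenation of a contig's fragments in order reproduces the contig.
#'
#' @inheritParams scan_recognition_sites
#' @param sites Recognition sites from [scan_recognition_sites()] on the same
#'   genome.
#' @return A tibble with columns `contig`, `start`, `end` (0-based half-open)
#'   and `sequence`.
#' @examples
#' g <- c(chrT = "AACCGGTT")
#' digest_fragments(g, scan_recognition_sites(g))
#' @export
digest_fragments <- function(genome, sites) {
  genome <- as_genome(genome)
  purrr::imap(as.list(as.character(genome)), function(seq_chr, ctg) {
    cuts <- sites$start[sites$contig == ctg] + 1L
    bounds <- c(0L, cuts, nchar(seq_chr))
    tibble(
      contig = ctg,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      sequence = substring(seq_chr, bounds[-length(bounds)] + 1L, bounds[-1L])
    )
  }) |>
    bind_rows()
}

#' Write a junction catalog as BED6
#'
#' One record per junction covering the 4-base motif interval
#' `[site_start, site_start + 4)`, 0-based half-open, with placeholder name
#' and score and the junction strand in column 6.
#'
#' @param catalog Junction catalog from [enumerate_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(catalog, path) {
  bed <- tibble(
    chrom = catalog$contig,
    start = catalog$site_start,
    end = catalog$site_start + 4L,
    name = ".",
    score = ".",
    strand = catalog$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a junction catalog back from BED6
#'
#' @param path BED6 path written by [write_junction_bed()].
#' @return A junction catalog tibble (see [enumerate_junctions()]).
#' @export
read_junction_bed <- function(path) {
  if (file.size(path) == 0) {
    return(enumerate_junctions(tibble(contig = character(), start = integer())))
  }
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciiccc", progress = FALSE
  )
  tibble(
    contig = bed$chrom,
    site_start = as.integer(bed$start),
    strand = bed$strand,
    five_prime = ifelse(bed$strand == "+", bed$start, bed$start + 3L) |>
      as.integer()
  )
}
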