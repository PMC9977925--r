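#' Coerce a genome to a DNAStringSet
#'
#' Accepts a [Biostrings::DNAStringSet], a named character vector of contig
#' sequences, or the path to a (possibly line-wrapped, multi-contig) FASTA
#' file. Sequences are uppercased and validated against the `{A,C,G,T,N}`
#' alphabet; `N` is tolerated but never matches the CCGG motif.
#'
#' @param genome Genome in any of the accepted forms.
#' @return A `DNAStringSet` with unique contig names.
#' @export
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
      abort("character genomes must be a named vector of contig sequences")
    }
    seqs <- toupper(genome)
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0)) {
      i <- which(bad > 0)[1L]
      abort(sprintf(
        "contig '%s' contains non-nucleotide character '%s' at position %d (1-based)",
        names(seqs)[i], substr(seqs[i], bad[i], bad[i]), bad[i]
      ))
    }
    genome <- Biostrings::DNAStringSet(seqs)
  } else if (!methods::is(genome, "DNAStringSet")) {
    abort("genome must be a DNAStringSet, a named character vector, or a FASTA path")
  }
  if (anyDuplicated(names(genome))) {
    abort("contig names must be unique within a genome")
  }
  validate_genome_alphabet(genome)
  genome
}

validate_genome_alphabet <- function(genome) {
  freq <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    seq_chr <- as.character(genome[[i]])
    pos <- regexpr("[^ACGTN]", seq_chr)[1L]
    abort(sprintf(
      "contig '%s' contains non-nucleotide character '%s' at position %d (1-based)",
      names(genome)[i], substr(seq_chr, pos, pos), pos
    ))
  }
  invisible(genome)
}

#' Write a genome to FASTA
#'
#' @param genome Genome in any form accepted by [as_genome()].
#' @param path Output FASTA path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = width)
  invisible(path)
}
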