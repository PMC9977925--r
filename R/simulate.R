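# Raw-read depths of the study design (ten biological libraries sequenced at
# equal volume, so depths differ several-fold, plus one merged control library
# sequenced at roughly double depth). Used only to derive default per-library
# size multipliers so simulated libraries show the same depth imbalance.
study_depth_profile <- function() {
  c(
    BL1 = 29951172, BL2 = 64951163, BL3 = 46520470, BL4 = 65123992,
    BL5 = 56155408,
    SL1 = 21105349, SL2 = 27287570, SL3 = 7105158, SL4 = 24225784,
    SL5 = 12690867,
    C1 = 45994060 + 34339125
  )
}

#' Configuration for the RRHP simulator
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the profiled study design: two groups of five libraries plus one
#' 5hmC-irrelevant control, 75 bp single-end reads beginning with CCGG, and
#' per-library depth multipliers proportional to the study's raw-read depths
#' (which span roughly 7-65 million reads across libraries).
#'
#' @param genome_length Total genome length in bp across contigs.
#' @param n_contigs Number of contigs.
#' @param target_site_count Minimum number of CCGG recognition sites planted
#'   into the genome (random background occurrences add more).
#' @param n_per_group Biological libraries per group.
#' @param read_length Read length in bp (sequencer cycles).
#' @param depth_factor Expected read count at a fully hydroxymethylated
#'   junction in a library with multiplier 1.
#' @param library_size_multipliers Named positive scalars, one per library
#'   (including the control). `NULL` derives them from the study's raw-read
#'   depth profile, normalised so biological libraries average 1.
#' @param baseline_level_params Shape parameters `c(a, b)` of the Beta law for
#'   the per-site hydroxymethylation level `pi`.
#' @param diff_fraction Fraction of recognition sites made differential.
#' @param diff_up_fraction Fraction of the differential sites whose large
#'   group is shifted *up*; the rest are shifted down. The default matches
#'   the direction split observed in the profiled study (2,237 of 2,677
#'   DhmCs higher in large fish).
#' @param effect_logit_shift Group effect added to `logit(pi)` at
#'   differential sites (sign per site set by `diff_up_fraction`).
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (`variance = mu + phi * mu^2`); values below `1e-12` fall back to
#'   Poisson sampling.
#' @param error_rate Per-base uniform substitution rate applied to emitted
#'   reads (0 disables; qualities are constant Phred 35 regardless).
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it, so identical configurations give byte-identical outputs.
#' @return A list of class `rrhp_sim_config`.
#' @export
rrhp_sim_config <- function(genome_length = 200000L,
                            n_contigs = 2L,
                            target_site_count = 400L,
                            n_per_group = 5L,
                            read_length = 75L,
                            depth_factor = 60,
                            library_size_multipliers = NULL,
                            baseline_level_params = c(2, 2),
                            diff_fraction = 0.1,
                            diff_up_fraction = 2237 / 2677,
                            effect_logit_shift = log(4),
                            nb_dispersion = 0.3,
                            error_rate = 0,
                            seed = 1L) {
  stopifnot(
    genome_length > 0, n_contigs >= 1, target_site_count >= 1,
    n_per_group >= 2, read_length >= 20, depth_factor > 0,
    length(baseline_level_params) == 2, all(baseline_level_params > 0),
    diff_fraction >= 0, diff_fraction <= 1,
    diff_up_fraction >= 0, diff_up_fraction <= 1,
    nb_dispersion >= 0, error_rate >= 0, error_rate < 1
  )
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    target_site_count = as.integer(target_site_count),
    n_per_group = as.integer(n_per_group),
    read_length = as.integer(read_length),
    depth_factor = depth_factor,
    library_size_multipliers = library_size_multipliers,
    baseline_level_params = baseline_level_params,
    diff_fraction = diff_fraction,
    diff_up_fraction = diff_up_fraction,
    effect_logit_shift = effect_logit_shift,
    nb_dispersion = nb_dispersion,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  if (is.null(cfg$library_size_multipliers)) {
    prof <- study_depth_profile()
    bio <- rep_len(prof[1:5], n_per_group)
    names(bio) <- paste0("BL", seq_len(n_per_group))
    small <- rep_len(prof[6:10], n_per_group)
    names(small) <- paste0("SL", seq_len(n_per_group))
    mult <- c(bio, small, C1 = unname(prof["C1"]))
    cfg$library_size_multipliers <- mult / mean(mult[seq_len(2 * n_per_group)])
  }
  mult <- cfg$library_size_multipliers
  if (is.null(names(mult)) || any(mult <= 0)) {
    abort("library_size_multipliers must be a named vector of positive scalars")
  }
  structure(cfg, class = "rrhp_sim_config")
}

#' Sample sheet implied by a simulator configuration
#'
#' @param config An [rrhp_sim_config()].
#' @return A tibble with columns `sample_id`, `group`
#'   (`large`/`small`/`control`) and `is_control`, one row per library in the
#'   order of `library_size_multipliers`.
#' @export
sim_sample_sheet <- function(config) {
  ids <- names(config$library_size_multipliers)
  n <- config$n_per_group
  group <- c(rep("large", n), rep("small", n),
             rep("control", length(ids) - 2L * n))
  tibble(sample_id = ids, group = group, is_control = group == "control")
}

#' Simulate a genome with a guaranteed minimum of CCGG sites
#'
#' Draws uniform random nucleotides and plants at least `target_site_count`
#' CCGG motifs at well-separated positions (spacing >= 150 bp, so most
#' junction reads fit inside their fragment). Random background CCGG
#' occurrences add further sites, hence scanning the result yields at least
#' the target count.
#'
#' @param config An [rrhp_sim_config()].
#' @return A [Biostrings::DNAStringSet] with contigs named `ctg1`, `ctg2`, ...
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed + 101L, {
    n_ctg <- config$n_contigs
    len <- config$genome_length %/% n_ctg
    per_ctg <- diff(round(seq(0, config$target_site_count, length.out = n_ctg + 1)))
    seqs <- vapply(seq_len(n_ctg), function(i) {
      bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      cand <- seq(10L, len - config$read_length - 10L, by = 150L)
      k <- per_ctg[i]
      if (length(cand) < k) {
        abort("genome_length too small for target_site_count at 150 bp spacing")
      }
      pos <- sort(sample(cand, k))
      for (p in pos) bases[(p + 1L):(p + 4L)] <- c("C", "C", "G", "G")
      paste(bases, collapse = "")
    }, character(1))
    names(seqs) <- paste0("ctg", seq_len(n_ctg))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Plant ground-truth hydroxymethylation levels
#'
#' Assigns each recognition site a baseline level `pi ~ Beta(a, b)` shared by
#' both of its junctions (hydroxymethylation protects the CCGG duplex, not a
#' strand). A fraction `diff_fraction` of sites (rounded) is made
#' differential by shifting `logit(pi)` of the large group by
#' `effect_logit_shift`; a fraction `diff_up_fraction` of them is shifted
#' up, the rest down.
#'
#' @param catalog Junction catalog from [enumerate_junctions()].
#' @param config An [rrhp_sim_config()].
#' @return A tibble with one row per junction: the catalog key columns plus
#'   `pi_large`, `pi_small` and `is_differential`.
#' @export
plant_truth <- function(catalog, config) {
  sites <- distinct(catalog, .data$contig, .data$site_start)
  n <- nrow(sites)
  withr::with_seed(config$seed + 202L, {
    a <- config$baseline_level_params[1]
    b <- config$baseline_level_params[2]
    pi_base <- pmin(pmax(rbeta(n, a, b), 1e-6), 1 - 1e-6)
    n_diff <- round(config$diff_fraction * n)
    idx <- if (n_diff > 0) sample.int(n, n_diff) else integer()
    n_up <- round(config$diff_up_fraction * n_diff)
    sign_shift <- rep(-1, n_diff)
    sign_shift[seq_len(n_up)] <- 1
    pi_large <- pi_base
    pi_large[idx] <- stats::plogis(stats::qlogis(pi_base[idx]) +
                                     sign_shift * config$effect_logit_shift)
    sites$pi_large <- pi_large
    sites$pi_small <- pi_base
    sites$is_differential <- pi_large != pi_base
  })
  left_join(catalog, sites, by = c("contig", "site_start"))
}

#' Simulate per-junction counts for one library
#'
#' Protocol mode draws `count ~ NB(mean = multiplier * depth_factor *
#' pi_group, dispersion = phi)`; in control mode (second MspI digestion
#' omitted, so amplification is unrelated to 5hmC content) the mean is
#' `multiplier * depth_factor` at every junction.
#'
#' @param truth Truth table from [plant_truth()].
#' @param sample_id Library identifier; must name an entry of
#'   `config$library_size_multipliers`.
#' @param group `"large"` or `"small"` (ignored in control mode).
#' @param control Logical; simulate the 5hmC-irrelevant control library.
#' @param config An [rrhp_sim_config()].
#' @return A tibble `contig`, `site_start`, `strand`, `count`.
#' @export
simulate_counts <- function(truth, sample_id, group, control = FALSE, config) {
  if (!sample_id %in% names(config$library_size_multipliers)) {
    abort(
      sprintf("no library_size_multiplier configured for sample '%s'", sample_id),
      class = "rrhp_config_error"
    )
  }
  mult <- config$library_size_multipliers[[sample_id]]
  pi <- if (control) rep(1, nrow(truth))
        else switch(group,
                    large = truth$pi_large,
                    small = truth$pi_small,
                    abort(sprintf("unknown group '%s'", group),
                          class = "rrhp_config_error"))
  mu <- mult * config$depth_factor * pi
  lib_index <- match(sample_id, names(config$library_size_multipliers))
  withr::with_seed(config$seed + 5000L + 7L * lib_index, {
    cnt <- if (config$nb_dispersion < 1e-12) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
    }
  })
  tibble(
    contig = truth$contig, site_start = truth$site_start,
    strand = truth$strand, count = as.integer(cnt)
  )
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Per-junction read template: starts with CCGG at the junction and extends
# into the fragment on the junction's strand; truncated at the neighbouring
# cut (natural fragment length), with a 20 bp minimum. Returns templates in
# the row order of `counts_keys`.
junction_read_templates <- function(counts_keys, genome, config) {
  genome <- as_genome(genome)
  genome_chr <- as.character(genome)
  clen <- setNames(nchar(genome_chr), names(genome))
  L <- config$read_length

  out <- character(nrow(counts_keys))
  for (ctg in unique(counts_keys$contig)) {
    rows <- which(counts_keys$contig == ctg)
    s <- counts_keys$site_start[rows]
    strand <- counts_keys$strand[rows]
    starts <- sort(unique(s))
    idx <- match(s, starts)
    nxt <- c(starts[-1], NA_integer_)[idx]
    prv <- c(NA_integer_, starts[-length(starts)])[idx]
    cl <- clen[[ctg]]

    lim_plus <- ifelse(is.na(nxt), cl, nxt + 1L)
    len_plus <- pmin(pmax(pmin(L, lim_plus - s), 20L), cl - s)
    e <- s + 3L
    lim_minus <- ifelse(is.na(prv), 0L, prv + 3L)
    len_minus <- pmin(pmax(pmin(L, e - lim_minus + 1L), 20L), e + 1L)

    seq_chr <- genome_chr[[ctg]]
    plus_rows <- strand == "+"
    tmpl <- character(length(rows))
    if (any(plus_rows)) {
      tmpl[plus_rows] <- substring(seq_chr, s[plus_rows] + 1L,
                                   s[plus_rows] + len_plus[plus_rows])
    }
    if (any(!plus_rows)) {
      windows <- substring(seq_chr, e[!plus_rows] - len_minus[!plus_rows] + 2L,
                           e[!plus_rows] + 1L)
      tmpl[!plus_rows] <- reverse_complement_chr(windows)
    }
    out[rows] <- tmpl
  }
  out
}

#' Emit simulated reads as FASTQ plus a ground-truth SAM
#'
#' Writes `count` copies of each junction's read template. Reads are emitted
#' in biological orientation in the FASTQ (every read begins with CCGG) with
#' constant Phred 35 qualities; the truth SAM stores minus-strand reads
#' reverse-complemented with FLAG 16 and the correct 1-based leftmost
#' position, a full-length match CIGAR and MAPQ 255.
#'
#' @param counts Per-junction counts from [simulate_counts()].
#' @param genome The simulated genome.
#' @param config An [rrhp_sim_config()].
#' @param fastq Output FASTQ path.
#' @param sam Optional output SAM path (`NULL` skips the truth alignments).
#' @param sample_id Library identifier used in read names and error seeding.
#' @return Invisibly, a tibble of emitted alignments (`qname`, `contig`,
#'   `pos` 1-based leftmost, `strand`, `read`).
#' @export
emit_reads <- function(counts, genome, config, fastq, sam = NULL,
                       sample_id = "sim") {
  genome <- as_genome(genome)
  keys <- counts |>
    arrange(match(.data$contig, names(genome)), .data$site_start, .data$strand)
  tmpl <- junction_read_templates(keys, genome, config)
  nz <- keys$count > 0
  reads <- rep(tmpl[nz], keys$count[nz])
  ctg <- rep(keys$contig[nz], keys$count[nz])
  s <- rep(keys$site_start[nz], keys$count[nz])
  strand <- rep(keys$strand[nz], keys$count[nz])
  rep_idx <- sequence(keys$count[nz])
  qname <- sprintf("%s:%s:%d:%s:%d", sample_id, ctg, s, strand, rep_idx)

  if (config$error_rate > 0 && length(reads)) {
    offset <- 7000L + sum(utf8ToInt(sample_id)) %% 997L
    withr::with_seed(config$seed + offset, {
      reads <- vapply(reads, function(r) {
        hit <- which(runif(nchar(r)) < config$error_rate)
        if (!length(hit)) return(r)
        ch <- strsplit(r, "")[[1]]
        ch[hit] <- vapply(ch[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    })
  }

  qual <- strrep("D", nchar(reads))  # Phred 35 + 33 offset
  writeLines(
    if (length(reads)) {
      as.vector(rbind(paste0("@", qname), reads, "+", qual))
    } else character(),
    fastq
  )

  pos <- ifelse(strand == "+", s + 1L, s + 3L - nchar(reads) + 2L)
  if (!is.null(sam)) {
    header <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", names(genome), BiocGenerics::width(genome)),
      "@PG\tID:rrhp\tPN:rrhp"
    )
    stored <- ifelse(strand == "+", reads, reverse_complement_chr(reads))
    rec <- sprintf(
      "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
      qname, ifelse(strand == "+", 0L, 16L), ctg, pos,
      nchar(reads), stored, qual
    )
    writeLines(c(header, rec), sam)
  }
  invisible(tibble(qname = qname, contig = ctg, pos = as.integer(pos),
                   strand = strand, read = reads))
}

#' Run the full simulator
#'
#' Generates a genome, scans and catalogs its CCGG junctions, plants ground
#' truth, simulates every library of the configured design, and (optionally)
#' writes all artifacts to disk: `genome.fa`, `junctions.bed`, `truth.tsv`,
#' `sample_sheet.tsv`, `counts.tsv` and per-library FASTQ/SAM.
#'
#' @param config An [rrhp_sim_config()].
#' @param out_dir Output directory, or `NULL` for an in-memory run without
#'   read emission (much faster; counts and truth are still produced).
#' @return A list with elements `genome`, `sites`, `catalog`, `truth`,
#'   `sample_sheet`, `counts` (wide tibble, one column per library) and
#'   `files` (named paths, when `out_dir` is given).
#' @export
simulate_rrhp_experiment <- function(config, out_dir = NULL) {
  genome <- simulate_genome(config)
  sites <- scan_recognition_sites(genome)
  catalog <- enumerate_junctions(sites)
  truth <- plant_truth(catalog, config)
  sheet <- sim_sample_sheet(config)

  per_lib <- purrr::pmap(sheet, function(sample_id, group, is_control) {
    simulate_counts(truth, sample_id, group, control = is_control,
                    config = config)
  })
  names(per_lib) <- sheet$sample_id
  counts <- assemble_matrix(per_lib, sheet, catalog = catalog)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      genome = file.path(out_dir, "genome.fa"),
      junctions = file.path(out_dir, "junctions.bed"),
      truth = file.path(out_dir, "truth.tsv"),
      sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
      counts = file.path(out_dir, "counts.tsv")
    )
    write_genome_fasta(genome, files$genome)
    write_junction_bed(catalog, files$junctions)
    readr::write_tsv(truth, files$truth)
    readr::write_tsv(sheet, files$sample_sheet)
    write_count_matrix(counts, files$counts)
    for (i in seq_len(nrow(sheet))) {
      sid <- sheet$sample_id[i]
      fq <- file.path(out_dir, paste0(sid, ".fastq"))
      sm <- file.path(out_dir, paste0(sid, ".sam"))
      emit_reads(per_lib[[sid]], genome, config, fastq = fq, sam = sm,
                 sample_id = sid)
      files[[paste0("fastq_", sid)]] <- fq
      files[[paste0("sam_", sid)]] <- sm
    }
  }
  list(genome = genome, sites = sites, catalog = catalog, truth = truth,
       sample_sheet = sheet, counts = counts, files = files)
}
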