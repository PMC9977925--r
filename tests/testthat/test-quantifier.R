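toy_catalog <- function() {
  enumerate_junctions(scan_recognition_sites(c(ctg = "ACCGGTCCGGA")))
}

aln <- function(contig = "ctg", pos, reverse = FALSE, sequence,
                mapped = TRUE, cigar = NULL, query_id = "r") {
  out <- tibble::tibble(query_id = query_id, contig = contig, pos = pos,
                        reverse = reverse, sequence = sequence, mapped = mapped)
  if (!is.null(cigar)) out$cigar <- cigar
  out
}

test_that("forward junction reads are counted only at exact CCGG starts", {
  cat <- toy_catalog()
  # 0-based start 1 -> 1-based pos 2; first four bases CCGG
  res <- count_junction_reads(aln(pos = 2L, sequence = "CCGGTCCGGA"), cat)
  expect_equal(sum(res$counts$count), 1L)
  expect_equal(res$counts$count[res$counts$site_start == 1 &
                                  res$counts$strand == "+"], 1L)

  # motif mismatch at the read start
  res2 <- count_junction_reads(aln(pos = 2L, sequence = "CCGATCCGGA"), cat)
  expect_equal(sum(res2$counts$count), 0L)
  expect_equal(res2$summary$raw_reads, 1L)

  # CCGG start but wrong coordinate
  res3 <- count_junction_reads(aln(pos = 3L, sequence = "CCGG"), cat)
  expect_equal(sum(res3$counts$count), 0L)
})

test_that("reverse reads are matched by their biological five-prime end", {
  cat <- toy_catalog()
  # junction (1, -): read 5' end at 0-based 4, stored sequence ends with CCGG
  # (stored = reverse complement of the biological read); pos 1-based leftmost
  res <- count_junction_reads(
    aln(pos = 1L, reverse = TRUE, sequence = "ACCGG"), cat
  )
  expect_equal(res$counts$count[res$counts$site_start == 1 &
                                  res$counts$strand == "-"], 1L)
  # same position, stored sequence not ending in CCGG -> biological start not CCGG
  res2 <- count_junction_reads(
    aln(pos = 1L, reverse = TRUE, sequence = "ACCGA"), cat
  )
  expect_equal(sum(res2$counts$count), 0L)
})

test_that("soft-clipped five-prime ends and unmapped reads are not counted", {
  cat <- toy_catalog()
  res <- count_junction_reads(
    aln(pos = 2L, sequence = "CCGGTCCGG", cigar = "2S7M"), cat
  )
  expect_equal(sum(res$counts$count), 0L)

  # clip at the 3' end of a forward read does not disqualify
  res2 <- count_junction_reads(
    aln(pos = 2L, sequence = "CCGGTCCGG", cigar = "7M2S"), cat
  )
  expect_equal(sum(res2$counts$count), 1L)

  res3 <- count_junction_reads(
    aln(pos = NA_integer_, sequence = "CCGG", mapped = FALSE), cat
  )
  expect_equal(sum(res3$counts$count), 0L)
  expect_equal(res3$summary$raw_reads, 1L)
})

test_that("library summary reflects counted reads and covered sites", {
  cat <- toy_catalog()
  reads <- dplyr::bind_rows(
    aln(pos = 2L, sequence = "CCGGT"),
    aln(pos = 2L, sequence = "CCGGT"),
    aln(pos = 2L, sequence = "CCGGT"),
    aln(pos = 7L, sequence = "CCGGA")
  )
  res <- count_junction_reads(reads, cat)
  expect_equal(sort(res$counts$count), c(0L, 0L, 1L, 3L))
  expect_equal(res$summary$counted_5hmc, 4L)
  expect_equal(res$summary$unique_sites, 2L)
})

test_that("alignments on contigs absent from the catalog raise an error", {
  expect_error(
    count_junction_reads(aln(contig = "chrMissing", pos = 2L, sequence = "CCGG"),
                         toy_catalog()),
    "chrMissing"
  )
})

test_that("malformed mapped records are skipped with a warning", {
  cat <- toy_catalog()
  reads <- dplyr::bind_rows(
    aln(pos = 2L, sequence = "CCGGT"),
    aln(pos = 2L, sequence = NA_character_)
  )
  expect_warning(res <- count_junction_reads(reads, cat), "malformed")
  expect_equal(sum(res$counts$count), 1L)
})

test_that("quantifying the truth SAM reproduces simulated counts exactly", {
  cfg <- tiny_cfg(seed = 10)
  dir <- withr::local_tempdir()
  sim <- simulate_rrhp_experiment(cfg, out_dir = dir)
  for (sid in c("BL2", "SL4", "C1")) {
    res <- count_junction_reads(file.path(dir, paste0(sid, ".sam")), sim$catalog)
    expect_identical(res$counts$count, sim$counts[[sid]], label = sid)
    expect_equal(res$summary$counted_5hmc, sum(sim$counts[[sid]]))
  }
})

test_that("matrix assembly zero-fills, conserves sums and ignores input order", {
  sheet <- tibble::tibble(sample_id = c("s1", "s2"),
                          group = c("large", "small"), is_control = FALSE)
  c1 <- tibble::tibble(contig = "c", site_start = c(1L, 5L), strand = "+",
                       count = c(3L, 0L))
  c2 <- tibble::tibble(contig = "c", site_start = c(5L, 9L), strand = "+",
                       count = c(2L, 4L))
  m <- assemble_matrix(list(s1 = c1, s2 = c2), sheet)
  expect_equal(m$s1, c(3L, 0L, 0L))
  expect_equal(m$s2, c(0L, 2L, 4L))
  expect_equal(colSums(m[, c("s1", "s2")]), c(s1 = 3, s2 = 6))

  m2 <- assemble_matrix(list(s2 = c2, s1 = c1), sheet)
  expect_identical(m, m2)

  expect_error(assemble_matrix(list(s1 = c1), sheet), "s2")
})

test_that("plus and minus counts at a site are exchangeable in distribution", {
  cfg <- rrhp_sim_config(genome_length = 100000, n_contigs = 1,
                         target_site_count = 600, seed = 13)
  sim <- simulate_rrhp_experiment(cfg)
  wide <- tidyr::pivot_wider(
    sim$counts[, c("contig", "site_start", "strand", "BL1")],
    names_from = "strand", values_from = "BL1"
  )
  informative <- wide$`+` != wide$`-`
  n_plus <- sum(wide$`+`[informative] > wide$`-`[informative])
  m <- sum(informative)
  expect_lt(abs(n_plus / m - 0.5), 3 * sqrt(0.25 / m))
})

test_that("library summaries report per-library totals and across-library unions", {
  sheet <- tibble::tibble(sample_id = c("s1", "s2"),
                          group = c("large", "small"), is_control = FALSE)
  counts <- tibble::tibble(
    contig = "c", site_start = c(1L, 1L, 9L, 9L),
    strand = c("+", "-", "+", "-"),
    s1 = c(3L, 0L, 0L, 0L), s2 = c(0L, 2L, 0L, 4L)
  )
  ls <- library_summaries(counts, sheet)
  expect_equal(ls$per_library$counted_5hmc, c(3, 6))
  expect_equal(ls$per_library$unique_sites, c(1, 2))
  # three junctions covered overall, at two distinct recognition sites
  expect_equal(ls$union$unique_sites_across, 3)
  expect_equal(ls$union$unique_sites_across_strand_merged, 2)
})
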