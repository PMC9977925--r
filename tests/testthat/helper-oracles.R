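# Independent oracles and small fixture builders shared across tests.

# Brute-force motif scan by regular expression (0-based starts).
regex_scan_oracle <- function(seq_chr) {
  hits <- gregexpr("CCGG", seq_chr, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits) - 1L
}

random_sequence <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Weighted least squares by explicit normal equations.
wls_oracle <- function(y, X, w) {
  W <- diag(w)
  xtwx <- t(X) %*% W %*% X
  beta <- solve(xtwx, t(X) %*% W %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  list(
    coef = unname(drop(beta)),
    stdev_unscaled = unname(sqrt(diag(solve(xtwx)))),
    sigma = sqrt(sum(w * res^2) / df)
  )
}

# A small two-group count matrix with deterministic content.
toy_counts <- function(n_sites = 50, n_per_group = 5, seed = 99, mu = 50,
                       size = 3) {
  withr::with_seed(seed, {
    ids <- c(paste0("BL", seq_len(n_per_group)), paste0("SL", seq_len(n_per_group)))
    counts <- tibble::tibble(
      contig = "ctg1",
      site_start = seq_len(n_sites) * 10L,
      strand = rep(c("+", "-"), length.out = n_sites)
    )
    for (id in ids) {
      counts[[id]] <- as.integer(rnbinom(n_sites, mu = mu, size = size))
    }
    sheet <- tibble::tibble(
      sample_id = ids,
      group = rep(c("large", "small"), each = n_per_group),
      is_control = FALSE
    )
    list(counts = counts, sheet = sheet)
  })
}

# Small simulator configuration for fast tests.
tiny_cfg <- function(...) {
  rrhp_sim_config(
    genome_length = 30000, n_contigs = 2, target_site_count = 60, ...
  )
}

# Minimal GFF3 fixture with a two-exon + gene and an exonless - gene.
write_toy_gff <- function(path = withr::local_tempfile(fileext = ".gff3",
                                                       .local_envir = parent.frame())) {
  writeLines(c(
    "##gff-version 3",
    "ctg1\ttoy\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "ctg1\ttoy\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "ctg1\ttoy\texon\t1001\t1200\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "ctg1\ttoy\texon\t1801\t2000\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "ctg1\ttoy\tgene\t5001\t6000\t.\t-\t.\tID=gB"
  ), path)
  path
}

# Linear-scan annotation oracle (no interval machinery).
annotation_oracle <- function(contig, pos, models,
                              promoter_window = c(-1000, 100),
                              tts_window = c(-100, 1000)) {
  g <- models[models$contig == contig, ]
  g <- g[order(g$gene_id), ]
  offset <- function(anchor) {
    ifelse(g$strand == "+", pos - anchor, anchor - pos)
  }
  in_win <- function(off, win) off >= win[1] & off <= win[2]
  off_tss <- offset(g$tss)
  category <- "intergenic"
  if (nrow(g)) {
    in_exon <- any(vapply(seq_len(nrow(g)), function(i) {
      any(g$exons[[i]]$start <= pos & pos < g$exons[[i]]$end)
    }, logical(1)))
    if (any(in_win(off_tss, promoter_window))) {
      category <- "promoter-TSS"
    } else if (any(in_win(offset(g$tes), tts_window))) {
      category <- "TTS"
    } else if (in_exon) {
      category <- "exon"
    } else if (any(g$start <= pos & pos < g$end)) {
      category <- "intron"
    }
  }
  if (nrow(g)) {
    best <- which.min(abs(off_tss))
    list(category = category, nearest_gene = g$gene_id[best],
         distance_to_tss = off_tss[best])
  } else {
    list(category = category, nearest_gene = NA_character_,
         distance_to_tss = NA_integer_)
  }
}

junction_key <- function(x) paste(x$contig, x$site_start, x$strand)
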