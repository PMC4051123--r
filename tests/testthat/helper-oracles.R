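# Shared fixtures and independent brute-force oracles used across tests.

# small CallSet built directly from genotype-string rows
toy_callset <- function(geno_strings, breeds_per_sample,
                        chrom = "chr1", starts = NULL, lens = 1000) {
  g <- do.call(rbind, geno_strings)
  n <- nrow(g)
  if (is.null(starts)) starts <- seq(1000, by = 10000, length.out = n)
  lens <- rep_len(lens, n)
  records <- data.frame(
    cnv_id = sprintf("cnv%03d", seq_len(n)), chrom = chrom,
    start = starts, end = starts + lens - 1, stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_along(breeds_per_sample)),
    breed = breeds_per_sample, stringsAsFactors = FALSE
  )
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  d <- matrix(codes[g], nrow = n)
  CallSet(records, samples, d)
}

# dosage-matrix CallSet on random intervals
random_callset <- function(n_cnv, breeds_per_sample, seed, p = 0.3,
                           genome_len = 1e6, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  n_s <- length(breeds_per_sample)
  records <- data.frame(
    cnv_id = sprintf("cnv%04d", seq_len(n_cnv)),
    chrom = sample(chroms, n_cnv, replace = TRUE),
    start = st <- sample.int(genome_len, n_cnv, replace = TRUE),
    end = st + sample.int(5000, n_cnv, replace = TRUE),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n_s)),
                        breed = breeds_per_sample, stringsAsFactors = FALSE)
  g <- matrix(rbinom(n_cnv * n_s, 2, p), nrow = n_cnv)
  CallSet(records, samples, g)
}

# O(n*m) all-pairs interval intersection oracle (1-based inclusive)
bf_overlap <- function(features, cnvs) {
  out <- list()
  for (i in seq_len(nrow(features))) {
    hits <- character(0)
    for (j in seq_len(nrow(cnvs))) {
      if (features$chrom[i] == cnvs$chrom[j] &&
          cnvs$start[j] <= features$end[i] &&
          features$start[i] <= cnvs$end[j]) {
        hits <- c(hits, cnvs$cnv_id[j])
      }
    }
    if (length(hits)) out[[features[[1]][i]]] <- hits
  }
  out
}

# brute-force Benjamini-Hochberg step-up with cumulative minimum
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# write a genotype table + sample sheet pair for I/O tests; the caller
# owns `dir` (pass a withr::local_tempdir() from the test body)
write_toy_tables <- function(callset, dir) {
  cnv <- file.path(dir, "cnv.tsv")
  sheet <- file.path(dir, "samples.tsv")
  write_cnv_table(callset, cnv, sheet)
  list(cnv = cnv, sheet = sheet, dir = dir)
}
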