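# Central container: CNV intervals + deletion genotype dosage matrix +
# sample-to-breed map. Coordinates are 1-based inclusive throughout the
# package; BED I/O converts at the boundary.

GENO_CODES <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
MISSING_CODE <- "./."

#' Construct a CallSet
#'
#' A CallSet bundles CNV records, samples with breed labels, and a deletion
#' genotype matrix. Genotypes are stored as integer deletion-allele dosages
#' (0 = 0/0, 1 = 0/1, 2 = 1/1, NA = missing "./.") with one row per CNV and
#' one column per sample.
#'
#' @param records data.frame with columns `cnv_id`, `chrom`, `start`, `end`
#'   (1-based inclusive). A `length` column (end - start + 1) is added.
#' @param samples data.frame with columns `sample_id`, `breed`.
#' @param genotypes integer matrix of dosages (nrow = CNVs, ncol = samples),
#'   values in {0, 1, 2, NA}.
#' @return An object of class `CallSet`.
#' @export
CallSet <- function(records, samples, genotypes) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(
    all(c("cnv_id", "chrom", "start", "end") %in% names(records)),
    all(c("sample_id", "breed") %in% names(samples))
  )
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(records) || ncol(genotypes) != nrow(samples)) {
    stop("genotype matrix dimensions (", nrow(genotypes), " x ",
         ncol(genotypes), ") do not match ", nrow(records), " CNVs x ",
         nrow(samples), " samples")
  }
  if (anyDuplicated(records$cnv_id)) {
    stop("duplicate cnv_id: ",
         paste(unique(records$cnv_id[duplicated(records$cnv_id)]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  records$start <- as.numeric(records$start)
  records$end <- as.numeric(records$end)
  bad <- which(records$end < records$start)
  if (length(bad)) {
    stop("end < start for CNV(s): ", paste(records$cnv_id[bad], collapse = ", "))
  }
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  records$length <- records$end - records$start + 1
  rownames(genotypes) <- records$cnv_id
  colnames(genotypes) <- samples$sample_id
  structure(
    list(records = records, samples = samples, genotypes = genotypes),
    class = "CallSet"
  )
}

#' @export
print.CallSet <- function(x, ...) {
  br <- table(x$samples$breed)
  cat("CallSet: ", nrow(x$records), " CNVs x ", nrow(x$samples), " samples (",
      paste(sprintf("%s n=%d", names(br), as.integer(br)), collapse = ", "),
      ")\n", sep = "")
  n_miss <- sum(is.na(x$genotypes))
  if (n_miss > 0) cat("  missing genotype cells: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.CallSet <- function(x) dim(x$genotypes)

#' Number of CNVs in a CallSet
#' @param x a CallSet
#' @return integer count of CNV records
#' @export
n_cnvs <- function(x) nrow(x$records)

#' Breed labels present in a CallSet
#' @param x a CallSet
#' @return character vector of breed labels in order of first appearance
#' @export
breeds <- function(x) unique(x$samples$breed)

#' Subset a CallSet by CNV and/or sample index
#'
#' @param x a CallSet
#' @param i CNV (row) index: integer, logical, or cnv_id character vector
#' @param j sample (column) index
#' @param ... ignored
#' @return a CallSet
#' @export
`[.CallSet` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$records))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  if (is.character(i)) i <- match(i, x$records$cnv_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  CallSet(
    records = x$records[i, , drop = FALSE],
    samples = x$samples[j, , drop = FALSE],
    genotypes = x$genotypes[i, j, drop = FALSE]
  )
}

# dosage matrix -> genotype strings ("0/0", "0/1", "1/1", "./.")
dosage_to_string <- function(m) {
  s <- names(GENO_CODES)[match(m, GENO_CODES)]
  s[is.na(s)] <- MISSING_CODE
  matrix(s, nrow = nrow(m), dimnames = dimnames(m))
}

# strict genotype-string parser; returns integer dosage or stops with the
# offending cnv/sample coordinates
parse_genotypes <- function(strings, cnv_ids, sample_ids) {
  m <- as.matrix(strings)
  d <- GENO_CODES[m]
  bad <- is.na(d) & m != MISSING_CODE
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("unparseable genotype \"", m[idx[1], idx[2]], "\" at CNV '",
         cnv_ids[idx[1]], "', sample '", sample_ids[idx[2]], "'")
  }
  out <- matrix(unname(d), nrow = nrow(m))
  storage.mode(out) <- "integer"
  out
}
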