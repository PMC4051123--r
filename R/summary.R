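# Call-set level summaries: counts, lengths, genome fraction, and the
# shared / one-breed / zero-carrier / monomorphic accounting.

#' Summarize a CallSet
#'
#' Computes the call-set headline statistics: CNV count, mean and total
#' length, optional percent of genome (needs chromosome sizes), the number
#' of CNVs whose deletion allele is observed in every breed ("shared"),
#' the number observed in exactly one breed, the number with no carrier at
#' all, the number with identical genotype across all samples
#' ("monomorphic"), and per-chromosome counts. Shared + one-breed +
#' zero-carrier = total.
#'
#' @param callset a complete-genotype [CallSet].
#' @param chrom_sizes optional named numeric vector of chromosome lengths
#'   (e.g. from [read_chrom_sizes()]); every callset chromosome must be
#'   present.
#' @param length_mode "inclusive" (end - start + 1, default) or "span"
#'   (end - start).
#' @return object of class `cnv_summary` (a list) with fields `n_cnvs`,
#'   `mean_length`, `total_bases`, `pct_genome` (NA without sizes),
#'   `n_shared`, `n_one_breed`, `n_zero_carrier`, `n_monomorphic`,
#'   `per_chromosome`.
#' @export
summarize_callset <- function(callset, chrom_sizes = NULL,
                              length_mode = c("inclusive", "span")) {
  length_mode <- match.arg(length_mode)
  g <- callset$genotypes
  if (anyNA(g)) {
    stop("CallSet contains missing genotypes; apply complete_genotype_filter() first")
  }
  r <- callset$records
  lens <- if (length_mode == "inclusive") r$end - r$start + 1 else r$end - r$start
  total <- sum(lens)

  pct <- NA_real_
  if (!is.null(chrom_sizes)) {
    miss <- setdiff(unique(r$chrom), names(chrom_sizes))
    if (length(miss)) {
      stop("chromosome(s) in callset missing from chrom_sizes: ",
           paste(miss, collapse = ", "))
    }
    pct <- 100 * total / sum(chrom_sizes)
  }

  brs <- breeds(callset)
  present <- vapply(brs, function(b) {
    rowSums(g[, callset$samples$breed == b, drop = FALSE]) > 0
  }, logical(nrow(g)))
  present <- matrix(present, nrow = nrow(g))
  n_breeds_present <- rowSums(present)

  mono <- apply(g, 1, function(x) length(unique(x)) == 1L)

  structure(list(
    n_cnvs = nrow(r),
    mean_length = if (nrow(r)) total / nrow(r) else NA_real_,
    total_bases = total,
    pct_genome = pct,
    n_shared = sum(n_breeds_present == length(brs)),
    n_one_breed = sum(n_breeds_present == 1L),
    n_zero_carrier = sum(n_breeds_present == 0L),
    n_monomorphic = sum(mono),
    per_chromosome = table(r$chrom)
  ), class = "cnv_summary")
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat("CNV call-set summary\n")
  cat(sprintf("  CNVs:            %d\n", x$n_cnvs))
  cat(sprintf("  mean length:     %.1f bp\n", x$mean_length))
  cat(sprintf("  total:           %.2f Mbp\n", x$total_bases / 1e6))
  if (!is.na(x$pct_genome)) {
    cat(sprintf("  %% of genome:     %.2f%%\n", x$pct_genome))
  }
  cat(sprintf("  shared (all breeds):  %d\n", x$n_shared))
  cat(sprintf("  one breed only:       %d\n", x$n_one_breed))
  cat(sprintf("  zero carriers:        %d\n", x$n_zero_carrier))
  cat(sprintf("  monomorphic:          %d\n", x$n_monomorphic))
  invisible(x)
}

#' Convert a cnv_summary to a one-row data.frame
#' @param x a `cnv_summary`
#' @param ... ignored
#' @return one-row data.frame of the scalar summary fields
#' @export
as.data.frame.cnv_summary <- function(x, ...) {
  data.frame(n_cnvs = x$n_cnvs, mean_length = x$mean_length,
             total_bases = x$total_bases, pct_genome = x$pct_genome,
             n_shared = x$n_shared, n_one_breed = x$n_one_breed,
             n_zero_carrier = x$n_zero_carrier,
             n_monomorphic = x$n_monomorphic)
}
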