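# Breed-specific CNVs: deletion allele observed in exactly one of the two
# breeds (putative), then confirmed by a minimum frequency in the carrier
# breed (> 0.1 by default) to limit false positives at small sample sizes.

#' Putative breed-specific CNVs
#'
#' A CNV is putatively breed-specific when its deletion allele is observed
#' (>= 1 allele) in exactly one breed and in zero copies in the other.
#' Specificity is defined on the observed genotypes of the sampled animals,
#' not on an inferred population frequency.
#'
#' @param callset a complete-genotype [CallSet] with exactly 2 breeds.
#' @param freq_mode "allele" (deletion alleles / 2n, default; the same p_j
#'   used by the F_ST scan) or "carrier" (carrier individuals / n).
#' @return data.frame (`cnv_id`, `breed`, `freq`, `status` = "putative")
#'   with one row per putative call, in CallSet order; `breed` is the breed
#'   carrying the deletion and `freq` its deletion frequency there.
#' @export
putative_breed_specific <- function(callset, freq_mode = c("allele", "carrier")) {
  freq_mode <- match.arg(freq_mode)
  brs <- breeds(callset)
  if (length(brs) != 2L) {
    stop("breed-specific detection requires exactly 2 breeds; found ",
         length(brs))
  }
  g <- callset$genotypes
  if (anyNA(g)) {
    stop("CallSet contains missing genotypes; apply complete_genotype_filter() first")
  }
  alleles <- vapply(brs, function(b) {
    rowSums(g[, callset$samples$breed == b, drop = FALSE])
  }, numeric(nrow(g)))
  alleles <- matrix(alleles, nrow = nrow(g))
  present <- alleles > 0
  one_breed <- rowSums(present) == 1L
  which_breed <- max.col(present, ties.method = "first")
  idx <- which(one_breed)
  b_idx <- which_breed[idx]
  n_b <- vapply(brs, function(b) sum(callset$samples$breed == b), numeric(1))
  freq <- if (freq_mode == "allele") {
    alleles[cbind(idx, b_idx)] / (2 * n_b[b_idx])
  } else {
    carriers <- vapply(brs, function(b) {
      rowSums(g[, callset$samples$breed == b, drop = FALSE] >= 1L)
    }, numeric(nrow(g)))
    carriers <- matrix(carriers, nrow = nrow(g))
    carriers[cbind(idx, b_idx)] / n_b[b_idx]
  }
  data.frame(
    cnv_id = callset$records$cnv_id[idx],
    breed = brs[b_idx],
    freq = freq,
    status = rep("putative", length(idx)),
    stringsAsFactors = FALSE
  )
}

#' Confirm breed-specific CNVs by a minimum deletion frequency
#'
#' Retains putative calls whose deletion frequency in the carrier breed
#' strictly exceeds `min_freq` (default 0.1).
#'
#' @param putative output of [putative_breed_specific()].
#' @param min_freq strict lower bound on `freq` (default 0.1).
#' @return the retained rows with `status` = "confirmed".
#' @export
confirm_breed_specific <- function(putative, min_freq = 0.1) {
  out <- putative[putative$freq > min_freq, , drop = FALSE]
  if (nrow(out)) out$status <- "confirmed"
  rownames(out) <- NULL
  out
}

#' Assign genes to breed-specific CNV calls
#'
#' A gene is assigned when the CNV interval, extended by `flank` bases on
#' both sides, overlaps the gene span. CNVs with no assignment are reported
#' with an empty gene field.
#'
#' @param calls breed-specific calls ([confirm_breed_specific()] output).
#' @param callset the [CallSet] the calls came from (interval source).
#' @param genes gene annotation data.frame.
#' @param flank extension in bases applied to each CNV side (default 0 =
#'   direct overlap only).
#' @return data.frame (`cnv_id`, `breed`, `freq`, `genes`) where `genes` is
#'   a comma-separated gene id list ("" when none).
#' @export
assign_genes <- function(calls, callset, genes, flank = 0) {
  out <- calls[c("cnv_id", "breed", "freq")]
  out$genes <- rep("", nrow(out))
  if (nrow(out) == 0L || nrow(genes) == 0L) return(out)
  rec <- callset$records[match(calls$cnv_id, callset$records$cnv_id), ,
                         drop = FALSE]
  ext <- data.frame(cnv_id = rec$cnv_id, chrom = rec$chrom,
                    start = pmax(1, rec$start - flank),
                    end = rec$end + flank, stringsAsFactors = FALSE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(ext), as_granges(genes))
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  gl <- split(genes$gene_id[s], q)
  for (k in names(gl)) {
    out$genes[as.integer(k)] <- paste(gl[[k]], collapse = ",")
  }
  rownames(out) <- NULL
  out
}
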