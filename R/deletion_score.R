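# Gene deletion scores: per-CNV carrier counts summed over the CNVs that
# overlap each gene, with upper-tail probabilities under a normal fitted to
# the genome-wide score vector.

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

#' Count deletion carriers in one genotype row
#'
#' A carrier is an individual with at least one deleted allele (genotype
#' 0/1 or 1/1); with N individuals the count ranges 0..N.
#'
#' @param genotype_row integer dosage vector (0/1/2); must be complete.
#' @return integer carrier count.
#' @export
deletion_carrier_count <- function(genotype_row) {
  if (anyNA(genotype_row)) {
    stop("missing genotypes in row; apply complete_genotype_filter() first")
  }
  sum(genotype_row >= 1L)
}

# per-CNV counts for the whole matrix; mode "carrier" counts individuals
# with dosage >= 1, mode "allele" sums allele dosages (range 0..2N)
cnv_deletion_counts <- function(callset, mode = c("carrier", "allele")) {
  mode <- match.arg(mode)
  g <- callset$genotypes
  if (anyNA(g)) {
    stop("CallSet contains missing genotypes; apply complete_genotype_filter() first")
  }
  if (mode == "carrier") rowSums(g >= 1L) else rowSums(g)
}

#' Map features to the CNVs they overlap
#'
#' A CNV overlaps a feature iff they share a chromosome and their 1-based
#' inclusive intervals intersect in at least one base
#' (`cnv$start <= feature$end && feature$start <= cnv$end`). Features with
#' no overlapping CNV are omitted from the result.
#'
#' @param callset a [CallSet].
#' @param features data.frame of intervals with an id in its first column
#'   and `chrom`, `start`, `end` columns (gene or QTL table).
#' @return named list: feature id -> character vector of overlapping
#'   cnv_ids (in CallSet row order).
#' @export
overlap_features <- function(callset, features) {
  if (nrow(features) == 0L || nrow(callset$records) == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  ids <- features[[1]]
  # disjoint chromosome sets between the two tracks are a legitimate
  # no-overlap case, not a user error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(features),
                                as_granges(callset$records))
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  out <- split(callset$records$cnv_id[s], ids[q])
  # restore feature order, drop empties
  out[intersect(ids, names(out))]
}

#' Score genes by population deletion burden
#'
#' Each gene overlapping at least one CNV receives
#' score = sum over its overlapping CNVs of that CNV's deletion count
#' (carriers by default). A CNV spanning k genes contributes to all k.
#' Tail probabilities come from [normal_tail_pvalues()] applied to the
#' score vector of all scored genes.
#'
#' @param callset a complete-genotype [CallSet].
#' @param genes gene annotation data.frame from [read_gene_annotation()].
#' @param score_mode "carrier" (individuals with >= 1 deleted allele, the
#'   default) or "allele" (summed allele dosage) per CNV.
#' @return data.frame (`gene_id`, `symbol`, `l`, `score`, `p_value`) with
#'   one row per gene that overlaps >= 1 CNV, in gene-table order; `l` is
#'   the number of overlapping CNVs.
#' @export
gene_deletion_scores <- function(callset, genes,
                                 score_mode = c("carrier", "allele")) {
  score_mode <- match.arg(score_mode)
  counts <- cnv_deletion_counts(callset, score_mode)
  names(counts) <- callset$records$cnv_id
  ov <- overlap_features(callset, genes)
  if (length(ov) == 0L) {
    return(data.frame(gene_id = character(0), symbol = character(0),
                      l = integer(0), score = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  symbol <- if ("symbol" %in% names(genes)) {
    genes$symbol[match(names(ov), genes$gene_id)]
  } else {
    rep(NA_character_, length(ov))
  }
  out <- data.frame(
    gene_id = names(ov),
    symbol = symbol,
    l = lengths(ov),
    score = vapply(ov, function(ids) sum(counts[ids]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$p_value <- tryCatch(normal_tail_pvalues(out$score), error = function(e) {
    warning("tail probabilities unavailable: ", conditionMessage(e))
    rep(NA_real_, nrow(out))
  })
  out
}

#' Upper-tail probabilities under a normal fitted to the scores
#'
#' Fits mean and standard deviation (sample sd, denominator n - 1) to the
#' score vector and returns `1 - Phi((score - mu) / sigma)` for each entry,
#' order preserved. This is the score-distribution "empirical p-value":
#' the tail probability of each score under the genome-wide fit.
#'
#' @param scores numeric vector, length >= 3, nonzero spread.
#' @return numeric vector of tail probabilities in (0, 1).
#' @export
normal_tail_pvalues <- function(scores) {
  if (length(scores) < 3L) stop("need >= 3 scores to fit a normal")
  mu <- mean(scores)
  sigma <- stats::sd(scores)
  if (!is.finite(sigma) || sigma == 0) {
    stop("zero variance in scores; tail probabilities undefined")
  }
  stats::pnorm(scores, mean = mu, sd = sigma, lower.tail = FALSE)
}

#' Select genes in the extreme deletion-score tail
#'
#' @param gene_scores output of [gene_deletion_scores()].
#' @param alpha tail-probability cutoff (default 0.01); genes with
#'   `p_value < alpha` are retained.
#' @return the selected rows sorted by descending score, ties broken by
#'   gene_id.
#' @export
select_significant_genes <- function(gene_scores, alpha = 0.01) {
  hit <- gene_scores[which(gene_scores$p_value < alpha), , drop = FALSE]
  hit <- hit[order(-hit$score, hit$gene_id), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}
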