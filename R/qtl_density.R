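# QTL deletion density. QTL lengths vary over orders of magnitude and long
# QTL accumulate deletion score by length alone, so density is measured as
# the average distance between deletions: QTL length / deletion score.
# Small values = dense deletion burden.

#' Deletion density per QTL
#'
#' For every QTL overlapping at least one CNV (same overlap rule as
#' [overlap_features()]): score = summed per-CNV deletion counts, and
#' `avg_distance = length / score` in bases per deletion. QTL without any
#' overlapping CNV are excluded.
#'
#' @param callset a complete-genotype [CallSet].
#' @param qtls QTL table from [read_qtl_table()].
#' @param score_mode passed to the per-CNV count ("carrier" or "allele").
#' @return data.frame (`qtl_id`, `trait`, `length`, `n_cnvs`, `score`,
#'   `avg_distance`).
#' @export
qtl_deletion_density <- function(callset, qtls,
                                 score_mode = c("carrier", "allele")) {
  score_mode <- match.arg(score_mode)
  counts <- cnv_deletion_counts(callset, score_mode)
  names(counts) <- callset$records$cnv_id
  ov <- overlap_features(callset, qtls)
  if (length(ov) == 0L) {
    return(data.frame(qtl_id = character(0), trait = character(0),
                      length = numeric(0), n_cnvs = integer(0),
                      score = numeric(0), avg_distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  m <- match(names(ov), qtls$qtl_id)
  out <- data.frame(
    qtl_id = names(ov),
    trait = qtls$trait[m],
    length = qtls$length[m],
    n_cnvs = lengths(ov),
    score = vapply(ov, function(ids) sum(counts[ids]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$avg_distance <- out$length / out$score
  out
}

#' Top-k QTL by deletion density
#'
#' Returns the k QTL with the smallest average distance between deletions
#' (densest deletion coverage), in ascending order of `avg_distance`; ties
#' broken by larger score, then by qtl_id.
#'
#' @param densities output of [qtl_deletion_density()].
#' @param k number of QTL to return (default 30).
#' @return the top k rows, with a `rank` column added.
#' @export
top_qtl <- function(densities, k = 30) {
  if (k <= 0) stop("k must be a positive integer")
  if (k > nrow(densities)) {
    warning("k = ", k, " exceeds the ", nrow(densities),
            " available QTL; returning all")
    k <- nrow(densities)
  }
  ord <- order(densities$avg_distance, -densities$score, densities$qtl_id)
  out <- densities[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
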