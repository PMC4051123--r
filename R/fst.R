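# Per-CNV selection scan between two breeds using Nei's heterozygosity
# form of Wright's fixation index:
#   H_obs = sum_j c_j * 2 p_j q_j   (within-subpopulation expected het.)
#   H_exp = 2 p_bar q_bar           (pooled expected heterozygosity)
#   F     = (H_exp - H_obs) / H_exp
# with subpopulation weights c_j and deletion-allele frequencies p_j.

#' Per-breed deletion-allele frequencies for every CNV
#'
#' p_j is the deletion-allele frequency in breed j: (het + 2 * hom-del)
#' over 2 n_j alleles. c_j is the relative subpopulation size n_j / N.
#'
#' @param callset a complete-genotype [CallSet].
#' @return data.frame in long format: `cnv_id`, `breed`, `n`, `c`, `p`, `q`
#'   with one row per CNV x breed.
#' @export
breed_allele_frequencies <- function(callset) {
  bf <- breed_freq_matrix(callset)
  long <- do.call(rbind, lapply(seq_along(bf$breeds), function(j) {
    data.frame(
      cnv_id = callset$records$cnv_id,
      breed = bf$breeds[j],
      n = bf$n[j],
      c = bf$c[j],
      p = bf$p[, j],
      stringsAsFactors = FALSE
    )
  }))
  long$q <- 1 - long$p
  long <- long[order(match(long$cnv_id, callset$records$cnv_id),
                     match(long$breed, bf$breeds)), , drop = FALSE]
  rownames(long) <- NULL
  long
}

# internal wide form: p matrix (cnv x breed), n and c per breed
breed_freq_matrix <- function(callset, weights = c("sample", "equal")) {
  weights <- match.arg(weights)
  g <- callset$genotypes
  if (anyNA(g)) {
    stop("CallSet contains missing genotypes; apply complete_genotype_filter() first")
  }
  brs <- breeds(callset)
  n <- vapply(brs, function(b) sum(callset$samples$breed == b), numeric(1))
  if (any(n == 0)) stop("breed with zero samples: ", brs[n == 0][1])
  p <- vapply(brs, function(b) {
    cols <- callset$samples$breed == b
    rowSums(g[, cols, drop = FALSE]) / (2 * sum(cols))
  }, numeric(nrow(g)))
  p <- matrix(p, nrow = nrow(g), dimnames = list(callset$records$cnv_id, brs))
  cw <- if (weights == "sample") n / sum(n) else rep(1 / length(brs), length(brs))
  list(breeds = brs, n = n, c = cw, p = p)
}

#' Nei's F from subpopulation allele frequencies
#'
#' Computes H_obs = sum_j c_j 2 p_j q_j, H_exp = 2 p_bar q_bar with the
#' c-weighted (default) or unweighted mean frequency p_bar, and
#' F = (H_exp - H_obs) / H_exp. When H_exp = 0 (no variation in the pooled
#' population) F is undefined and flagged.
#'
#' @param p numeric vector of subpopulation deletion frequencies, or a
#'   matrix with one row per locus and one column per subpopulation.
#' @param c subpopulation weights (relative sizes), summing to 1; defaults
#'   to equal weights.
#' @param p_bar_mode "weighted" (c-weighted mean, default; guarantees
#'   0 <= F <= 1) or "unweighted" (simple mean across subpopulations).
#' @return data.frame with columns `H_obs`, `H_exp`, `fst`, `defined`
#'   (one row per locus).
#' @export
nei_fst <- function(p, c = NULL, p_bar_mode = c("weighted", "unweighted")) {
  p_bar_mode <- match.arg(p_bar_mode)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  J <- ncol(p)
  if (is.null(c)) c <- rep(1 / J, J)
  if (length(c) != J) stop("length(c) must equal the number of subpopulations")
  if (abs(sum(c) - 1) > 1e-8) stop("subpopulation weights c must sum to 1")
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop("frequencies must lie in [0, 1]")

  h_obs <- drop(2 * (p * (1 - p)) %*% c)
  p_bar <- if (p_bar_mode == "weighted") drop(p %*% c) else rowMeans(p)
  h_exp <- 2 * p_bar * (1 - p_bar)
  defined <- h_exp > 0
  f <- ifelse(defined, (h_exp - h_obs) / h_exp, NA_real_)
  data.frame(H_obs = h_obs, H_exp = h_exp, fst = f, defined = defined)
}

#' Per-CNV F_ST scan between two breeds
#'
#' @param callset a complete-genotype [CallSet] with exactly 2 breed
#'   labels.
#' @param weights "sample" (c_j = n_j / N, default) or "equal" (c_j = 1/2).
#' @param p_bar_mode passed to [nei_fst()].
#' @return data.frame with one row per CNV: `cnv_id`, `chrom`, `start`,
#'   `end`, per-breed frequency columns `p_<breed>`, `H_obs`, `H_exp`,
#'   `fst`, `defined`. Monomorphic CNVs (H_exp = 0) carry `defined = FALSE`
#'   and NA fst.
#' @export
fst_scan <- function(callset, weights = c("sample", "equal"),
                     p_bar_mode = c("weighted", "unweighted")) {
  weights <- match.arg(weights)
  p_bar_mode <- match.arg(p_bar_mode)
  brs <- breeds(callset)
  if (length(brs) != 2L) {
    stop("fst_scan requires exactly 2 breeds; found ", length(brs), ": ",
         paste(brs, collapse = ", "))
  }
  bf <- breed_freq_matrix(callset, weights)
  res <- nei_fst(bf$p, c = bf$c, p_bar_mode = p_bar_mode)
  out <- cbind(
    callset$records[c("cnv_id", "chrom", "start", "end")],
    stats::setNames(as.data.frame(bf$p), paste0("p_", bf$breeds)),
    res
  )
  rownames(out) <- NULL
  out
}

#' Empirical significance and FDR control for an F_ST scan
#'
#' Upper-tail p-values over the defined F values, by either a normal fit
#' (mean/sd of the F vector, mirroring the deletion-score procedure;
#' default) or by rank (`p_i` = fraction of defined F values >= F_i).
#' Benjamini-Hochberg adjustment is applied across the defined CNVs and
#' the significant set is `q <= alpha`. Undefined-F CNVs are excluded from
#' the p-value pool (NA p and q, never significant).
#'
#' @param results output of [fst_scan()].
#' @param method "normal" or "rank".
#' @param alpha FDR level (default 0.01).
#' @return `results` with columns `p_value`, `q_value`, `significant`
#'   added.
#' @export
fst_significance <- function(results, method = c("normal", "rank"),
                             alpha = 0.01) {
  method <- match.arg(method)
  def <- which(results$defined)
  if (length(def) < 3L) stop("need >= 3 defined F values")
  f <- results$fst[def]
  if (method == "normal") {
    sigma <- stats::sd(f)
    if (!is.finite(sigma) || sigma == 0) {
      stop("zero variance in F values; use method = \"rank\"")
    }
    p <- stats::pnorm(f, mean = mean(f), sd = sigma, lower.tail = FALSE)
  } else {
    # count of F >= F_i (including self) over the defined count
    p <- (length(f) + 1 - rank(f, ties.method = "min")) / length(f)
  }
  q <- stats::p.adjust(p, method = "BH")
  results$p_value <- NA_real_
  results$q_value <- NA_real_
  results$p_value[def] <- p
  results$q_value[def] <- q
  results$significant <- !is.na(results$q_value) & results$q_value <= alpha
  results
}

#' Report significant CNVs with gene context and per-breed genotype tallies
#'
#' @param results output of [fst_significance()].
#' @param callset the [CallSet] the scan was run on.
#' @param genes optional gene annotation; overlapping gene ids are joined
#'   (comma-separated, empty when none).
#' @return data.frame with one row per significant CNV: `cnv_id`, `chrom`,
#'   `start`, `end`, `fst`, `p_value`, `q_value`, `genes`, and per breed
#'   the counts `n_homref_<breed>`, `n_het_<breed>`, `n_homdel_<breed>`.
#' @export
annotate_selected <- function(results, callset, genes = NULL) {
  sel <- results[results$significant, , drop = FALSE]
  out <- sel[c("cnv_id", "chrom", "start", "end", "fst", "p_value", "q_value")]
  gene_str <- rep("", nrow(out))
  if (!is.null(genes) && nrow(out) > 0) {
    ov <- overlap_features(callset[out$cnv_id, ], genes)
    # invert: cnv -> genes
    for (gid in names(ov)) {
      hit <- match(ov[[gid]], out$cnv_id)
      hit <- hit[!is.na(hit)]
      gene_str[hit] <- ifelse(gene_str[hit] == "", gid,
                              paste(gene_str[hit], gid, sep = ","))
    }
  }
  out$genes <- gene_str
  for (b in breeds(callset)) {
    cols <- callset$samples$breed == b
    g <- callset$genotypes[match(out$cnv_id, callset$records$cnv_id),
                           cols, drop = FALSE]
    out[[paste0("n_homref_", b)]] <- rowSums(g == 0L)
    out[[paste0("n_het_", b)]] <- rowSums(g == 1L)
    out[[paste0("n_homdel_", b)]] <- rowSums(g == 2L)
  }
  rownames(out) <- NULL
  out
}
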