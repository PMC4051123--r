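# Ground-truth simulator for the two-breed deletion-CNV study design:
# Hardy-Weinberg genotypes within breed, with planted differentiated,
# breed-specific, and monomorphic CNVs on top of a shared Beta-distributed
# background frequency.

#' Approximate cattle autosome lengths (UMD3.1-like)
#'
#' Approximate lengths of the 29 bovine autosomes (total ~2.51 Gbp), used as
#' the default simulation genome. Values are rounded approximations suitable
#' for interval placement, not an authoritative assembly index.
#'
#' @return data.frame with columns `chrom` and `length` (bases).
#' @export
cattle_autosomes <- function() {
  len_mb <- c(158.3, 137.1, 121.4, 120.8, 121.2, 119.5, 112.6, 113.4, 105.7,
              104.3, 107.3, 91.2, 84.2, 84.6, 85.3, 81.7, 75.2, 66.0, 64.1,
              72.0, 71.6, 61.4, 52.5, 62.7, 42.9, 51.7, 45.4, 46.3, 51.5)
  data.frame(chrom = paste0("chr", seq_along(len_mb)),
             length = round(len_mb * 1e6), stringsAsFactors = FALSE)
}

#' Simulation configuration for a two-breed CNV call set
#'
#' Defaults emulate the two-breed study design this package targets: 22
#' Hanwoo and 10 Holstein samples, 6,811 deletion CNVs with log-normal
#' lengths averaging ~2.7 kb on the 29 cattle autosomes, a shared
#' Beta(0.8, 0.8) background deletion-allele frequency per CNV, and small
#' planted fractions of differentiated, breed-specific, and monomorphic
#' CNVs.
#'
#' @param n_breed1,n_breed2 sample counts per breed.
#' @param breed_names labels for the two breeds.
#' @param n_cnvs total number of CNVs.
#' @param beta_shape1,beta_shape2 shape parameters of the shared Beta
#'   background frequency distribution.
#' @param frac_differentiated fraction of CNVs with a planted between-breed
#'   frequency gap of `delta`.
#' @param delta planted allele-frequency gap for differentiated CNVs.
#' @param frac_specific_b1,frac_specific_b2 fractions of CNVs whose deletion
#'   allele exists only in breed 1 (resp. breed 2); the present-breed
#'   frequency is drawn uniformly from `specific_freq_range`.
#' @param frac_monomorphic fraction of CNVs fixed for the deletion
#'   (all samples 1/1).
#' @param specific_freq_range range of the true frequency in the carrier
#'   breed for planted breed-specific CNVs; the default straddles the 0.1
#'   confirmation threshold so both outcomes are exercised.
#' @param missing_rate independent per-cell probability of a missing
#'   genotype.
#' @param genome data.frame (`chrom`, `length`) on which CNVs are placed.
#' @param length_meanlog,length_sdlog log-normal CNV length parameters;
#'   defaults give a mean length of ~2,732 bp.
#' @param seed integer seed driving all randomness; sub-tasks (frequencies,
#'   genotypes, interval placement, missingness) use separate derived
#'   streams so enlarging one does not perturb the others.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_breed1 = 22, n_breed2 = 10,
                       breed_names = c("Hanwoo", "Holstein"),
                       n_cnvs = 6811,
                       beta_shape1 = 0.8, beta_shape2 = 0.8,
                       frac_differentiated = 0.015, delta = 0.8,
                       frac_specific_b1 = 0.11, frac_specific_b2 = 0.03,
                       frac_monomorphic = 0.0003,
                       specific_freq_range = c(0.02, 0.6),
                       missing_rate = 0,
                       genome = cattle_autosomes(),
                       length_meanlog = log(2732.2) - 0.75^2 / 2,
                       length_sdlog = 0.75,
                       seed = 1L) {
  cfg <- list(
    n_breed1 = as.integer(n_breed1), n_breed2 = as.integer(n_breed2),
    breed_names = breed_names, n_cnvs = as.integer(n_cnvs),
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    frac_differentiated = frac_differentiated, delta = delta,
    frac_specific_b1 = frac_specific_b1, frac_specific_b2 = frac_specific_b2,
    frac_monomorphic = frac_monomorphic,
    specific_freq_range = specific_freq_range,
    missing_rate = missing_rate, genome = genome,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$frac_differentiated, cfg$frac_specific_b1,
             cfg$frac_specific_b2, cfg$frac_monomorphic)
  probs <- c(fracs, cfg$missing_rate, cfg$delta)
  if (any(probs < 0) || any(probs > 1)) {
    stop("fractions, missing_rate and delta must lie in [0, 1]")
  }
  if (sum(fracs) > 1 + 1e-12) {
    stop("planted fractions sum to ", sum(fracs), " > 1; infeasible config")
  }
  if (cfg$n_breed1 < 1L || cfg$n_breed2 < 1L) stop("each breed needs >= 1 sample")
  if (cfg$n_cnvs < 1L) stop("n_cnvs must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# named pseudo-random sub-streams derived from one global seed, so each
# simulation sub-task draws from its own stream
derive_seed <- function(seed, stream) {
  offs <- c(freqs = 1L, geno = 2L, intervals = 3L, missing = 4L,
            features = 5L, lengths = 6L)
  if (!stream %in% names(offs)) stop("unknown stream: ", stream)
  (as.integer(seed) * 97L + offs[[stream]]) %% .Machine$integer.max
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' Simulate a two-breed CallSet with known ground truth
#'
#' Genotypes are Hardy-Weinberg draws from each breed's true deletion-allele
#' frequency p (dosage probabilities q^2, 2pq, p^2 for 0, 1, 2 copies of the
#' deleted allele); missing cells are applied independently afterwards. CNV
#' intervals are placed uniformly on the configured genome with no overlap
#' constraint. Fully reproducible for a given config (including its seed).
#'
#' @param config a [sim_config()].
#' @return list with elements `callset` (a [CallSet]) and `truth`
#'   (data.frame: `cnv_id`, `class` in background/differentiated/
#'   specific_b1/specific_b2/monomorphic, `p_breed1`, `p_breed2`).
#' @export
simulate_callset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cnvs
  n1 <- config$n_breed1
  n2 <- config$n_breed2

  counts <- c(
    differentiated = round(config$frac_differentiated * n),
    specific_b1 = round(config$frac_specific_b1 * n),
    specific_b2 = round(config$frac_specific_b2 * n),
    monomorphic = round(config$frac_monomorphic * n)
  )
  if (sum(counts) > n) stop("planted class counts exceed n_cnvs; infeasible config")
  class_lab <- rep("background", n)
  idx <- seq_len(sum(counts))
  class_lab[idx] <- rep(names(counts), counts)

  p1 <- p2 <- numeric(n)
  with_stream(config$seed, "freqs", {
    bg <- class_lab == "background"
    p_shared <- rbeta(sum(bg), config$beta_shape1, config$beta_shape2)
    p1[bg] <- p_shared
    p2[bg] <- p_shared

    di <- which(class_lab == "differentiated")
    if (length(di)) {
      lo <- runif(length(di), 0, 1 - config$delta)
      hi_in_b1 <- runif(length(di)) < 0.5
      p1[di] <- ifelse(hi_in_b1, lo + config$delta, lo)
      p2[di] <- ifelse(hi_in_b1, lo, lo + config$delta)
    }
    s1 <- which(class_lab == "specific_b1")
    p1[s1] <- runif(length(s1), config$specific_freq_range[1],
                    config$specific_freq_range[2])
    p2[s1] <- 0
    s2 <- which(class_lab == "specific_b2")
    p2[s2] <- runif(length(s2), config$specific_freq_range[1],
                    config$specific_freq_range[2])
    p1[s2] <- 0
    mono <- class_lab == "monomorphic"
    p1[mono] <- 1
    p2[mono] <- 1
  })

  geno <- with_stream(config$seed, "geno", {
    g1 <- matrix(rbinom(n * n1, size = 2L, prob = rep(p1, n1)), nrow = n)
    g2 <- matrix(rbinom(n * n2, size = 2L, prob = rep(p2, n2)), nrow = n)
    cbind(g1, g2)
  })

  if (config$missing_rate > 0) {
    with_stream(config$seed, "missing", {
      geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
    })
  }

  lens <- with_stream(config$seed, "lengths", {
    pmax(50, round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  })
  records <- with_stream(config$seed, "intervals", {
    place_intervals(n, lens, config$genome,
                    ids = sprintf("simCNV%05d", seq_len(n)))
  })

  samples <- data.frame(
    sample_id = c(sprintf("%s_%02d", config$breed_names[1], seq_len(n1)),
                  sprintf("%s_%02d", config$breed_names[2], seq_len(n2))),
    breed = rep(config$breed_names, c(n1, n2)),
    stringsAsFactors = FALSE
  )
  callset <- CallSet(records, samples, geno)
  truth <- data.frame(cnv_id = records$cnv_id, class = class_lab,
                      p_breed1 = p1, p_breed2 = p2, stringsAsFactors = FALSE)
  list(callset = callset, truth = truth)
}

# uniform interval placement: chromosome chosen proportional to length,
# start uniform such that the interval fits; intervals sorted by position
place_intervals <- function(n, lens, genome, ids) {
  fit <- outer(genome$length, lens, ">=")
  if (any(colSums(fit) == 0)) {
    stop("an interval is longer than every chromosome in the genome")
  }
  chrom_idx <- vapply(seq_len(n), function(i) {
    ok <- which(fit[, i])
    ok[sample.int(length(ok), 1L, prob = genome$length[ok])]
  }, integer(1))
  start <- floor(runif(n, min = 1,
                       max = genome$length[chrom_idx] - lens + 1 + 1))
  rec <- data.frame(cnv_id = ids, chrom = genome$chrom[chrom_idx],
                    start = start, end = start + lens - 1,
                    stringsAsFactors = FALSE)
  rec <- rec[order(match(rec$chrom, genome$chrom), rec$start), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Simulate gene/QTL tracks with planted CNV overlaps
#'
#' Builds gene and QTL intervals such that each feature named in
#' `overlap_plan` overlaps exactly its planned CNVs and no others; the
#' remaining features are placed inside CNV-free gaps of the genome.
#' Feature ids not in the plan are auto-named `gene<k>` / `qtl<k>`.
#'
#' @param callset a [CallSet] whose CNV intervals constrain placement.
#' @param n_genes,n_qtl total feature counts (must cover the planned ones).
#' @param overlap_plan named list: feature id -> character vector of cnv_ids
#'   it must overlap. Gene features are those whose name appears in the
#'   first `n_genes` positions of the plan-plus-filler ordering; in practice
#'   name planned genes and QTL distinctly and split via `plan_types`.
#' @param plan_types optional named character vector giving "gene" or "qtl"
#'   for each planned feature id (default: all "gene").
#' @param genome data.frame (`chrom`, `length`); defaults to the span of the
#'   callset's chromosomes.
#' @param seed integer seed.
#' @return list with `genes` (gene_id/symbol/chrom/start/end), `qtls`
#'   (qtl_id/trait/chrom/start/end/length), and `truth` (named list of
#'   realized feature -> cnv_id overlaps, empty features omitted).
#' @export
simulate_features <- function(callset, n_genes = 10, n_qtl = 5,
                              overlap_plan = list(), plan_types = NULL,
                              genome = NULL, seed = 1L) {
  if (is.null(genome)) {
    agg <- stats::aggregate(end ~ chrom, data = callset$records, FUN = max)
    genome <- data.frame(chrom = agg$chrom, length = agg$end + 1e6,
                         stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unlist(overlap_plan), callset$records$cnv_id)
  if (length(unknown)) {
    stop("overlap_plan references unknown CNV(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(plan_types)) {
    plan_types <- stats::setNames(rep("gene", length(overlap_plan)),
                                  names(overlap_plan))
  }
  n_plan_gene <- sum(plan_types == "gene")
  n_plan_qtl <- sum(plan_types == "qtl")
  if (n_plan_gene > n_genes || n_plan_qtl > n_qtl) {
    stop("overlap_plan contains more planned features than n_genes/n_qtl")
  }

  rec <- callset$records
  with_stream(seed, "features", {
    planned <- lapply(names(overlap_plan), function(fid) {
      place_planned_feature(fid, overlap_plan[[fid]], rec, genome)
    })
    planned_df <- do.call(rbind, planned)
    if (is.null(planned_df)) {
      planned_df <- data.frame(id = character(0), chrom = character(0),
                               start = numeric(0), end = numeric(0),
                               stringsAsFactors = FALSE)
    }
    n_free <- (n_genes - n_plan_gene) + (n_qtl - n_plan_qtl)
    free_df <- place_free_features(n_free, rec, genome)

    gene_rows <- rbind(
      planned_df[plan_types[planned_df$id] == "gene", , drop = FALSE],
      free_df[seq_len(n_genes - n_plan_gene), , drop = FALSE]
    )
    qtl_rows <- rbind(
      planned_df[plan_types[planned_df$id] == "qtl", , drop = FALSE],
      free_df[seq_len(n_qtl - n_plan_qtl) + (n_genes - n_plan_gene), ,
              drop = FALSE]
    )
    auto_g <- is.na(gene_rows$id)
    gene_rows$id[auto_g] <- sprintf("gene%03d", which(auto_g))
    auto_q <- is.na(qtl_rows$id)
    qtl_rows$id[auto_q] <- sprintf("qtl%03d", which(auto_q))

    genes <- data.frame(gene_id = gene_rows$id,
                        symbol = rep(NA_character_, nrow(gene_rows)),
                        chrom = gene_rows$chrom, start = gene_rows$start,
                        end = gene_rows$end, stringsAsFactors = FALSE)
    qtls <- data.frame(qtl_id = qtl_rows$id,
                       trait = rep("simulated", nrow(qtl_rows)),
                       chrom = qtl_rows$chrom, start = qtl_rows$start,
                       end = qtl_rows$end,
                       length = qtl_rows$end - qtl_rows$start + 1,
                       stringsAsFactors = FALSE)
    list(genes = genes, qtls = qtls,
         truth = overlap_plan[lengths(overlap_plan) > 0])
  })
}

# minimal interval overlapping every planned CNV and no other, padded
# randomly up to the nearest conflicting CNV or chromosome edge
place_planned_feature <- function(fid, cnv_ids, rec, genome) {
  hit <- rec[match(cnv_ids, rec$cnv_id), , drop = FALSE]
  chr <- unique(hit$chrom)
  if (length(chr) != 1L) {
    stop("planned feature '", fid, "' spans multiple chromosomes: ",
         paste(chr, collapse = ", "))
  }
  a <- min(min(hit$end), max(hit$start))
  b <- max(min(hit$end), max(hit$start))
  others <- rec[rec$chrom == chr & !(rec$cnv_id %in% cnv_ids), , drop = FALSE]
  clash <- others$start <= b & others$end >= a
  if (any(clash)) {
    stop("overlap_plan unsatisfiable: feature '", fid, "' covering ",
         paste(cnv_ids, collapse = ","), " would also overlap ",
         paste(others$cnv_id[clash], collapse = ","))
  }
  chrom_len <- genome$length[match(chr, genome$chrom)]
  left_lim <- max(c(1, others$end[others$end < a] + 1))
  right_lim <- min(c(chrom_len, others$start[others$start > b] - 1))
  start <- floor(runif(1, left_lim, a + 1))
  end <- floor(runif(1, b, right_lim + 1))
  data.frame(id = fid, chrom = chr, start = start, end = min(end, right_lim),
             stringsAsFactors = FALSE)
}

# features placed inside CNV-free gaps (no overlap with any CNV)
place_free_features <- function(n, rec, genome) {
  if (n == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  gaps <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    chr <- genome$chrom[i]
    len <- genome$length[i]
    r <- rec[rec$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    gs <- c(1, r$end + 1)
    ge <- c(r$start - 1, len)
    keep <- ge - gs + 1 >= 1000 # usable gaps only
    data.frame(chrom = chr, start = gs[keep], end = ge[keep],
               stringsAsFactors = FALSE)
  }))
  # prune gaps that still intersect a CNV (possible with overlapping CNVs)
  ok <- vapply(seq_len(nrow(gaps)), function(i) {
    r <- rec[rec$chrom == gaps$chrom[i], , drop = FALSE]
    !any(r$start <= gaps$end[i] & r$end >= gaps$start[i])
  }, logical(1))
  gaps <- gaps[ok, , drop = FALSE]
  if (nrow(gaps) < 1L) stop("no CNV-free gaps available for feature placement")
  pick <- sample.int(nrow(gaps), n, replace = TRUE,
                     prob = gaps$end - gaps$start + 1)
  out <- lapply(pick, function(g) {
    glen <- gaps$end[g] - gaps$start[g] + 1
    flen <- max(100, min(glen, round(stats::rlnorm(1, log(2e4), 0.6))))
    s <- floor(runif(1, gaps$start[g], gaps$end[g] - flen + 1 + 1))
    data.frame(id = NA_character_, chrom = gaps$chrom[g], start = s,
               end = s + flen - 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
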