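# End-to-end composition: filter -> summarize -> gene scores -> QTL density
# -> F_ST scan -> breed-specific calls, with TSV/BED outputs and a run
# manifest (input checksums + parameters) for reproducibility.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_defaults <- function() {
  list(alpha_genes = 0.01, alpha_fst = 0.01, fst_method = "normal",
       fst_weights = "sample", min_freq = 0.1, flank = 0, top_k = 30,
       score_mode = "carrier", length_mode = "inclusive")
}

run_stage <- function(name, expr) {
  message("[", name, "] running")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full CNV population-analysis pipeline
#'
#' Executes every stage on the configured inputs and writes all outputs to
#' the configured directory: `summary.tsv`, `gene_scores.tsv`,
#' `significant_genes.tsv`, `qtl_density.tsv`, `top_qtl.tsv`, `fst.tsv`,
#' `fst_significant.tsv`, `breed_specific.tsv`, `breed_specific.bed`,
#' `callset.bed`, and `manifest.yaml` (input checksums, parameters,
#' package version). Stages whose inputs are not configured (genes, qtls)
#' are skipped with a log message. Outputs are a pure function of the
#' inputs and parameters.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Required fields: `cnv_table`, `sample_sheet`, `out_dir`. Optional:
#'   `genes`, `qtls`, `chrom_sizes`, and the parameters `alpha_genes`,
#'   `alpha_fst`, `fst_method` (normal/rank), `fst_weights`
#'   (sample/equal), `min_freq`, `flank`, `top_k`, `score_mode`
#'   (carrier/allele), `length_mode` (inclusive/span).
#' @return the output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("cnv_table", "sample_sheet", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) {
    stop("pipeline config lacks required field(s): ", paste(miss, collapse = ", "))
  }
  par <- utils::modifyList(pipeline_defaults(),
                           config[setdiff(names(config), c(req, "genes", "qtls", "chrom_sizes"))])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  cs <- run_stage("read", read_cnv_table(config$cnv_table, config$sample_sheet))
  cs <- run_stage("filter", complete_genotype_filter(cs))
  message("[filter] ", n_cnvs(cs), " CNVs retained")

  genes <- NULL
  if (!is.null(config$genes)) {
    genes <- run_stage("read-genes", read_gene_annotation(config$genes))
  }
  qtls <- NULL
  if (!is.null(config$qtls)) {
    qtls <- run_stage("read-qtls", read_qtl_table(config$qtls))
  }
  sizes <- NULL
  if (!is.null(config$chrom_sizes)) {
    sizes <- run_stage("read-sizes", read_chrom_sizes(config$chrom_sizes))
  }

  smry <- run_stage("summarize",
                    summarize_callset(cs, sizes, length_mode = par$length_mode))
  outputs <- c(outputs, write_tsv(as.data.frame(smry),
                                  file.path(out_dir, "summary.tsv")))

  if (!is.null(genes)) {
    gs <- run_stage("gene-scores",
                    gene_deletion_scores(cs, genes, score_mode = par$score_mode))
    outputs <- c(outputs, write_tsv(gs, file.path(out_dir, "gene_scores.tsv")))
    sig <- select_significant_genes(gs, alpha = par$alpha_genes)
    outputs <- c(outputs,
                 write_tsv(sig, file.path(out_dir, "significant_genes.tsv")))
    message("[gene-scores] ", nrow(gs), " genes scored, ", nrow(sig),
            " significant at alpha = ", par$alpha_genes)
  } else {
    message("[gene-scores] skipped (no gene annotation configured)")
  }

  if (!is.null(qtls)) {
    qd <- run_stage("qtl-density",
                    qtl_deletion_density(cs, qtls, score_mode = par$score_mode))
    outputs <- c(outputs, write_tsv(qd, file.path(out_dir, "qtl_density.tsv")))
    top <- if (nrow(qd)) {
      run_stage("qtl-density", top_qtl(qd, k = min(par$top_k, nrow(qd))))
    } else {
      cbind(qd, rank = integer(0))
    }
    outputs <- c(outputs, write_tsv(top, file.path(out_dir, "top_qtl.tsv")))
    message("[qtl-density] ", nrow(qd), " QTL overlap CNVs; top ", nrow(top),
            " reported")
  } else {
    message("[qtl-density] skipped (no QTL table configured)")
  }

  fst <- run_stage("fst", {
    res <- fst_scan(cs, weights = par$fst_weights)
    fst_significance(res, method = par$fst_method, alpha = par$alpha_fst)
  })
  outputs <- c(outputs, write_tsv(fst, file.path(out_dir, "fst.tsv")))
  sel <- run_stage("fst", annotate_selected(fst, cs, genes))
  outputs <- c(outputs,
               write_tsv(sel, file.path(out_dir, "fst_significant.tsv")))
  message("[fst] ", sum(fst$significant), " CNVs significant at FDR <= ",
          par$alpha_fst, " (method = ", par$fst_method, ")")

  bs <- run_stage("breed-specific", {
    put <- putative_breed_specific(cs)
    confirm_breed_specific(put, min_freq = par$min_freq)
  })
  if (!is.null(genes)) {
    bs <- run_stage("breed-specific",
                    assign_genes(bs, cs, genes, flank = par$flank))
  }
  outputs <- c(outputs, write_tsv(bs, file.path(out_dir, "breed_specific.tsv")))
  message("[breed-specific] ", nrow(bs), " confirmed calls")

  outputs <- c(outputs, write_bed(cs, file.path(out_dir, "callset.bed")))
  if (nrow(bs) > 0) {
    labels <- stats::setNames(paste(bs$cnv_id, bs$breed, sep = "|"), bs$cnv_id)
    outputs <- c(outputs,
                 write_bed(cs[bs$cnv_id, ],
                           file.path(out_dir, "breed_specific.bed"),
                           labels = labels))
  }

  inputs <- unlist(config[intersect(names(config),
                                    c("cnv_table", "sample_sheet", "genes",
                                      "qtls", "chrom_sizes"))])
  manifest <- list(
    package = "cnvpop",
    version = as.character(utils::packageVersion("cnvpop")),
    parameters = par,
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)),
    outputs = basename(outputs)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
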