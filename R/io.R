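# Readers/writers for the tabular and track formats the pipeline touches.
# Internal coordinates are 1-based inclusive (Ensembl/QTLdb convention);
# BED files are 0-based half-open and converted at the boundary.

# delimiter auto-detection between tab and comma, based on the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab == 0 && n_com == 0) {
    stop("cannot detect delimiter (no tab or comma in header) in ", path)
  }
  if (n_tab >= n_com) "\t" else ","
}

read_delim_strict <- function(path) {
  utils::read.table(path, sep = detect_sep(path), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "", stringsAsFactors = FALSE)
}

# numeric coordinate parser reporting 1-based data line numbers on failure
parse_coord <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop("cannot parse ", what, " \"", x[bad[1]], "\" at line ", bad[1] + 1L,
         " of ", path)
  }
  v
}

#' Read a CNV deletion genotype table with its sample sheet
#'
#' The table layout is: header line, then one row per CNV with columns
#' CNV id, chromosome, start, end (1-based inclusive), followed by one
#' genotype column per sample holding `0/0`, `0/1`, `1/1` (non-deletion,
#' single-deletion, double-deletion) or `./.` (missing). Tab or comma
#' delimited (auto-detected). The sample sheet is a two-column table
#' (`sample_id`, `breed`) that must cover every genotype column.
#'
#' @param path path to the genotype table.
#' @param sample_sheet path to the sample sheet.
#' @return a [CallSet] preserving the file's row and column order.
#' @export
read_cnv_table <- function(path, sample_sheet) {
  tab <- read_delim_strict(path)
  if (ncol(tab) < 5L) {
    stop("genotype table needs >= 5 columns (cnv_id, chrom, start, end, ",
         ">= 1 sample); found ", ncol(tab), " in ", path)
  }
  sheet <- read_sample_sheet(sample_sheet)
  sample_cols <- names(tab)[-(1:4)]

  missing_breed <- setdiff(sample_cols, sheet$sample_id)
  if (length(missing_breed)) {
    stop("genotype column(s) without a breed assignment in the sample sheet: ",
         paste(missing_breed, collapse = ", "))
  }
  absent <- setdiff(sheet$sample_id, sample_cols)
  if (length(absent)) {
    stop("sample sheet lists sample(s) absent from the genotype table: ",
         paste(absent, collapse = ", "))
  }

  records <- data.frame(
    cnv_id = tab[[1]],
    chrom = tab[[2]],
    start = parse_coord(tab[[3]], "start position", path),
    end = parse_coord(tab[[4]], "end position", path),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(records$cnv_id)) {
    stop("duplicate cnv_id in ", path, ": ",
         paste(unique(records$cnv_id[duplicated(records$cnv_id)]), collapse = ", "))
  }
  geno <- parse_genotypes(tab[sample_cols], records$cnv_id, sample_cols)
  samples <- data.frame(
    sample_id = sample_cols,
    breed = sheet$breed[match(sample_cols, sheet$sample_id)],
    stringsAsFactors = FALSE
  )
  CallSet(records, samples, geno)
}

#' Read a sample sheet (sample_id, breed)
#' @param path path to a delimited table with columns `sample_id` and `breed`.
#' @return data.frame with columns `sample_id`, `breed`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_delim_strict(path)
  if (!all(c("sample_id", "breed") %in% names(sheet))) {
    stop("sample sheet must have columns 'sample_id' and 'breed'; found: ",
         paste(names(sheet), collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  }
  sheet[c("sample_id", "breed")]
}

#' Write a CallSet back to the genotype-table layout
#'
#' Inverse of [read_cnv_table()]: writes a tab-delimited table with columns
#' cnv_id, chrom, start, end and one genotype-string column per sample
#' (missing cells as `./.`), and optionally the matching sample sheet.
#'
#' @param callset a [CallSet].
#' @param path output path for the genotype table.
#' @param sample_sheet optional output path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(callset, path, sample_sheet = NULL) {
  gs <- dosage_to_string(callset$genotypes)
  tab <- cbind(
    callset$records[c("cnv_id", "chrom", "start", "end")],
    as.data.frame(gs, stringsAsFactors = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    utils::write.table(callset$samples[c("sample_id", "breed")], sample_sheet,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Keep only CNVs with complete genotype information
#'
#' Drops every CNV with at least one missing (`./.`) genotype, mirroring the
#' genotype-completeness step applied to the raw Genome STRiP call set. Row
#' order is preserved and the number of removed CNVs is reported via
#' `message()` and attached as attribute `n_removed`.
#'
#' @param callset a [CallSet].
#' @return the filtered [CallSet]; idempotent.
#' @export
complete_genotype_filter <- function(callset) {
  keep <- rowSums(is.na(callset$genotypes)) == 0L
  out <- callset[which(keep), ]
  n_removed <- sum(!keep)
  message("complete_genotype_filter: removed ", n_removed, " of ",
          length(keep), " CNVs with missing genotypes")
  attr(out, "n_removed") <- n_removed
  out
}

#' Read a gene annotation table (TSV/CSV or BED)
#'
#' A `.bed` file (no header, columns chrom/start/end/name, 0-based
#' half-open) is converted to 1-based inclusive coordinates; any other
#' extension is read as a delimited table with header columns `gene_id`,
#' `chrom`, `start`, `end` and optional `symbol`, already 1-based inclusive.
#'
#' @param path annotation file path.
#' @return data.frame (`gene_id`, `symbol`, `chrom`, `start`, `end`) sorted
#'   by (chrom, start).
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read_bed(path)
    genes <- data.frame(
      gene_id = bed$name, symbol = NA_character_,
      chrom = bed$chrom, start = bed$start, end = bed$end,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- read_delim_strict(path)
    need <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop("gene annotation ", path, " lacks column(s): ",
           paste(miss, collapse = ", "))
    }
    genes <- data.frame(
      gene_id = tab$gene_id,
      symbol = if ("symbol" %in% names(tab)) tab$symbol else NA_character_,
      chrom = tab$chrom,
      start = parse_coord(tab$start, "gene start", path),
      end = parse_coord(tab$end, "gene end", path),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- which(genes$end < genes$start)
  if (length(bad)) {
    stop("gene end < start at line ", bad[1], " of ", path)
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Read a QTL annotation table
#'
#' Delimited table (Animal QTLdb-style export) with header columns
#' `qtl_id`, `trait`, `chrom`, `start`, `end` (1-based inclusive).
#'
#' @param path QTL table path.
#' @return data.frame (`qtl_id`, `trait`, `chrom`, `start`, `end`, `length`)
#'   with `length = end - start + 1`.
#' @export
read_qtl_table <- function(path) {
  tab <- read_delim_strict(path)
  need <- c("qtl_id", "trait", "chrom", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("QTL table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  qtls <- data.frame(
    qtl_id = tab$qtl_id, trait = tab$trait, chrom = tab$chrom,
    start = parse_coord(tab$start, "QTL start", path),
    end = parse_coord(tab$end, "QTL end", path),
    stringsAsFactors = FALSE
  )
  if (nrow(qtls) == 0L) {
    warning("QTL table ", path, " has no rows")
    qtls$length <- numeric(0)
    return(qtls)
  }
  bad <- which(qtls$end < qtls$start)
  if (length(bad)) stop("QTL end < start at line ", bad[1], " of ", path)
  qtls$length <- qtls$end - qtls$start + 1
  qtls
}

#' Read a chromosome-sizes table
#' @param path delimited table with header columns `chrom` and `length`.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read_delim_strict(path)
  if (!all(c("chrom", "length") %in% names(tab))) {
    stop("chromosome sizes file must have columns 'chrom' and 'length'")
  }
  stats::setNames(parse_coord(tab$length, "chromosome length", path), tab$chrom)
}

#' Export CNV intervals as a BED4 track
#'
#' Writes one line per CNV in 0-based half-open coordinates
#' (start - 1, end), name column = `cnv_id` or its entry in `labels`.
#'
#' @param callset a [CallSet] (must be nonempty).
#' @param path output BED path.
#' @param labels optional named character vector mapping cnv_id to a label.
#' @return `path`, invisibly.
#' @export
write_bed <- function(callset, path, labels = NULL) {
  if (nrow(callset$records) == 0L) stop("cannot write BED for an empty CallSet")
  r <- callset$records
  name <- r$cnv_id
  if (!is.null(labels)) {
    hit <- match(r$cnv_id, names(labels))
    name <- ifelse(is.na(hit), r$cnv_id, unname(labels)[hit])
  }
  bed <- data.frame(r$chrom, format(r$start - 1, scientific = FALSE, trim = TRUE),
                    format(r$end, scientific = FALSE, trim = TRUE), name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 interval track into 1-based inclusive coordinates
#' @param path BED path (no header; >= 4 columns).
#' @return data.frame (`chrom`, `start`, `end`, `name`), 1-based inclusive.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("BED file ", path, " needs >= 4 columns")
  data.frame(
    chrom = tab[[1]],
    start = parse_coord(tab[[2]], "BED start", path) + 1,
    end = parse_coord(tab[[3]], "BED end", path),
    name = tab[[4]],
    stringsAsFactors = FALSE
  )
}
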