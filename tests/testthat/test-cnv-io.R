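# Reading/writing genotype tables, annotation tables and BED tracks, plus
# the genotype-completeness filter.

test_that("a toy genotype table parses into a CallSet preserving order", {
  dir <- withr::local_tempdir()
  cnv <- file.path(dir, "cnv.tsv")
  writeLines(c(
    "cnv_id\tchrom\tstart\tend\tsA\tsB",
    "c1\tchr1\t100\t200\t0/0\t0/1",
    "c2\tchr2\t500\t900\t1/1\t./.",
    "c3\tchr1\t50\t60\t0/1\t0/1"
  ), cnv)
  sheet <- file.path(dir, "samples.tsv")
  writeLines(c("sample_id\tbreed", "sA\tHanwoo", "sB\tHolstein"), sheet)

  cs <- read_cnv_table(cnv, sheet)
  expect_s3_class(cs, "CallSet")
  expect_equal(cs$records$cnv_id, c("c1", "c2", "c3"))
  expect_equal(cs$samples$sample_id, c("sA", "sB"))
  expect_equal(cs$samples$breed, c("Hanwoo", "Holstein"))
  expect_equal(unname(cs$genotypes[1, ]), c(0L, 1L))
  expect_true(is.na(cs$genotypes[2, 2]))
  expect_equal(cs$records$length, c(101, 401, 11))
})

test_that("comma-delimited tables are auto-detected", {
  dir <- withr::local_tempdir()
  cnv <- file.path(dir, "cnv.csv")
  writeLines(c("cnv_id,chrom,start,end,sA", "c1,chr1,10,20,0/1"), cnv)
  sheet <- file.path(dir, "samples.csv")
  writeLines(c("sample_id,breed", "sA,Hanwoo"), sheet)
  cs <- read_cnv_table(cnv, sheet)
  expect_equal(n_cnvs(cs), 1L)
  expect_equal(unname(cs$genotypes[1, 1]), 1L)
})

test_that("malformed inputs are rejected with informative errors", {
  dir <- withr::local_tempdir()
  sheet <- file.path(dir, "samples.tsv")
  writeLines(c("sample_id\tbreed", "sA\tHanwoo", "sB\tHolstein"), sheet)

  bad_geno <- file.path(dir, "bad_geno.tsv")
  writeLines(c("cnv_id\tchrom\tstart\tend\tsA\tsB",
               "c1\tchr1\t100\t200\t0/0\t2/2"), bad_geno)
  expect_error(read_cnv_table(bad_geno, sheet), "2/2.*c1.*sB")

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("cnv_id\tchrom\tstart\tend\tsA\tsB",
               "c1\tchr1\t1\t2\t0/0\t0/0",
               "c1\tchr1\t5\t6\t0/0\t0/0"), dup)
  expect_error(read_cnv_table(dup, sheet), "duplicate cnv_id")

  extra <- file.path(dir, "extra.tsv")
  writeLines(c("cnv_id\tchrom\tstart\tend\tsA\tsB\tsC",
               "c1\tchr1\t1\t2\t0/0\t0/0\t0/0"), extra)
  expect_error(read_cnv_table(extra, sheet), "sC")

  short_sheet <- file.path(dir, "short.tsv")
  writeLines(c("sample_id\tbreed", "sA\tHanwoo"), short_sheet)
  two <- file.path(dir, "two.tsv")
  writeLines(c("cnv_id\tchrom\tstart\tend\tsA\tsB",
               "c1\tchr1\t1\t2\t0/0\t0/0"), two)
  expect_error(read_cnv_table(two, short_sheet), "sB")

  bad_coord <- file.path(dir, "coord.tsv")
  writeLines(c("cnv_id\tchrom\tstart\tend\tsA\tsB",
               "c1\tchr1\t1\t2\t0/0\t0/0",
               "c2\tchr1\txx\t9\t0/0\t0/0"), bad_coord)
  expect_error(read_cnv_table(bad_coord, sheet), "line 3")
})

test_that("genotype tables round-trip exactly through write/read", {
  cs <- random_callset(100, c(rep("Hanwoo", 5), rep("Holstein", 3)), seed = 42)
  cs$genotypes[sample(length(cs$genotypes), 30)] <- NA_integer_
  paths <- write_toy_tables(cs, withr::local_tempdir())
  back <- read_cnv_table(paths$cnv, paths$sheet)
  expect_equal(back$records, cs$records)
  expect_equal(back$samples, cs$samples)
  expect_equal(back$genotypes, cs$genotypes)
})

test_that("complete_genotype_filter removes exactly the rows with missing cells", {
  cs <- toy_callset(list(c("0/0", "0/1"), c("1/1", "./."), c("0/1", "0/1"),
                         c("./.", "./."), c("0/0", "0/0")),
                    c("Hanwoo", "Holstein"))
  filt <- suppressMessages(complete_genotype_filter(cs))
  expect_equal(n_cnvs(filt), 3L)
  expect_equal(attr(filt, "n_removed"), 2L)
  expect_equal(filt$records$cnv_id, c("cnv001", "cnv003", "cnv005"))

  # identity on complete data, and idempotence
  again <- suppressMessages(complete_genotype_filter(filt))
  expect_equal(again$records, filt$records)
  expect_equal(again$genotypes, filt$genotypes)
  expect_equal(attr(again, "n_removed"), 0L)
})

test_that("filter retention matches a brute-force row scan on seeded data", {
  sim <- simulate_callset(sim_config(n_cnvs = 1000, missing_rate = 0.05,
                                     genome = data.frame(chrom = "chr1",
                                                         length = 5e7),
                                     seed = 99))
  cs <- sim$callset
  filt <- suppressMessages(complete_genotype_filter(cs))
  keep_bf <- vapply(seq_len(nrow(cs$genotypes)), function(i) {
    all(!is.na(cs$genotypes[i, ]))
  }, logical(1))
  expect_equal(n_cnvs(filt), sum(keep_bf))
  expect_equal(filt$records$cnv_id, cs$records$cnv_id[keep_bf])
})

test_that("gene annotation reads TSV and BED with correct coordinate conventions", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "genes.tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tsymbol",
               "gB\tchr1\t5000\t6000\tSYMB",
               "gA\tchr1\t100\t300\tSYMA"), tsv)
  genes <- read_gene_annotation(tsv)
  expect_equal(genes$gene_id, c("gA", "gB"))  # sorted by (chrom, start)
  expect_equal(genes$symbol, c("SYMA", "SYMB"))

  bed <- file.path(dir, "genes.bed")
  writeLines("chr1\t99\t200\tgAA", bed)
  gb <- read_gene_annotation(bed)
  expect_equal(gb$start, 100)  # 0-based half-open -> 1-based inclusive
  expect_equal(gb$end, 200)

  dupf <- file.path(dir, "dup.tsv")
  writeLines(c("gene_id\tchrom\tstart\tend",
               "g1\tchr1\t1\t10", "g1\tchr1\t5\t20"), dupf)
  expect_error(read_gene_annotation(dupf), "duplicate gene_id")
})

test_that("QTL tables compute lengths and tolerate zero rows", {
  dir <- withr::local_tempdir()
  q <- file.path(dir, "qtl.tsv")
  writeLines(c("qtl_id\ttrait\tchrom\tstart\tend",
               "q1\tmilk\tchr1\t1001\t101000"), q)
  qtls <- read_qtl_table(q)
  expect_equal(qtls$length, 100000)

  empty <- file.path(dir, "empty.tsv")
  writeLines("qtl_id\ttrait\tchrom\tstart\tend", empty)
  expect_warning(q0 <- read_qtl_table(empty), "no rows")
  expect_equal(nrow(q0), 0L)
})

test_that("BED export shifts start by one, honors labels, and round-trips", {
  cs <- toy_callset(list(c("0/1", "0/0")), c("Hanwoo", "Holstein"),
                    chrom = "chr5", starts = 1001, lens = 1000)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "out.bed")
  write_bed(cs, bed)
  line <- readLines(bed)
  expect_equal(line, "chr5\t1000\t2000\tcnv001")

  write_bed(cs, bed, labels = c(cnv001 = "special"))
  expect_match(readLines(bed), "special$")

  big <- random_callset(100, c("Hanwoo", "Holstein"), seed = 7)
  write_bed(big, bed)
  back <- read_bed(bed)
  expect_equal(back$chrom, big$records$chrom)
  expect_equal(back$start, big$records$start)
  expect_equal(back$end, big$records$end)
  expect_equal(back$name, big$records$cnv_id)
})
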