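# Nei heterozygosity-based F between two breeds: frequencies, the F
# statistic, empirical significance and BH FDR control.

test_that("breed allele frequencies come from allele dosages over 2n", {
  # Holstein: 3 heterozygotes of 10 -> p = 3/20; Hanwoo: 13 hom + 9 het of
  # 22 -> p = 35/44
  geno <- c(rep("1/1", 13), rep("0/1", 9), rep("0/1", 3), rep("0/0", 7))
  cs <- toy_callset(list(geno), c(rep("Hanwoo", 22), rep("Holstein", 10)))
  bf <- breed_allele_frequencies(cs)
  expect_equal(bf$p[bf$breed == "Hanwoo"], 35 / 44)
  expect_equal(bf$p[bf$breed == "Holstein"], 0.15)
  expect_equal(bf$c, c(22, 10) / 32)
  expect_equal(bf$q, 1 - bf$p)

  all_ref <- toy_callset(list(rep("0/0", 4)),
                         c("Hanwoo", "Hanwoo", "Holstein", "Holstein"))
  expect_true(all(breed_allele_frequencies(all_ref)$p == 0))
})

test_that("nei_fst reproduces the hand-computed worked example", {
  res <- nei_fst(c(35 / 44, 3 / 20), c = c(22, 10) / 32)
  expect_lt(abs(res$H_obs - 0.303410), 1e-5)
  expect_lt(abs(res$H_exp - 0.482422), 1e-5)
  expect_lt(abs(res$fst - 0.37107), 1e-5)
})

test_that("F is 0 with identical frequencies and 1 for a fixed difference", {
  expect_equal(nei_fst(c(0.3, 0.3), c = c(0.7, 0.3))$fst, 0)
  fixed <- nei_fst(c(1, 0), c = c(0.5, 0.5))
  expect_equal(fixed$H_obs, 0)
  expect_equal(fixed$fst, 1)
  undef <- nei_fst(c(0, 0))
  expect_false(undef$defined)
  expect_true(is.na(undef$fst))
})

test_that("heterozygosity-form F equals the c-weighted variance ratio", {
  set.seed(55)
  for (i in 1:200) {
    p <- runif(2)
    w <- runif(1, 0.05, 0.95)
    cw <- c(w, 1 - w)
    res <- nei_fst(p, c = cw)
    p_bar <- sum(cw * p)
    var_c <- sum(cw * (p - p_bar)^2)
    if (res$defined) {
      expect_lt(abs(res$fst - var_c / (p_bar * (1 - p_bar))), 1e-12)
      expect_gte(res$fst, 0)
      expect_lte(res$fst, 1)
    }
    # allele relabeling invariance: p -> q
    flip <- nei_fst(1 - p, c = cw)
    if (res$defined) expect_lt(abs(flip$fst - res$fst), 1e-12)
  }
})

test_that("fst_scan composes the trivial cases and flags undefined rows", {
  cs <- toy_callset(list(
    c(rep("0/1", 11), rep("0/0", 11), rep("0/1", 5), rep("0/0", 5)), # p=p
    c(rep("1/1", 22), rep("0/0", 10)),                               # fixed
    rep("0/0", 32)                                                   # undefined
  ), c(rep("Hanwoo", 22), rep("Holstein", 10)))
  scan <- fst_scan(cs)
  expect_equal(scan$fst[1], 0)
  expect_equal(scan$fst[2], 1)
  expect_false(scan$defined[3])
  expect_equal(scan$p_Hanwoo, c(0.25, 1, 0))
  expect_equal(scan$p_Holstein, c(0.25, 0, 0))

  one_breed <- cs[, cs$samples$breed == "Hanwoo"]
  expect_error(fst_scan(one_breed), "exactly 2 breeds")
})

test_that("null simulation concentrates F near zero", {
  sim <- simulate_callset(sim_config(
    n_cnvs = 1000, frac_differentiated = 0, frac_specific_b1 = 0,
    frac_specific_b2 = 0, frac_monomorphic = 0,
    genome = data.frame(chrom = "chr1", length = 5e7), seed = 41))
  scan <- fst_scan(sim$callset)
  expect_lt(mean(scan$fst[scan$defined]), 0.05)
})

test_that("BH adjustment matches the hand-computed step-up example and a
           brute-force implementation on random vectors", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  expect_equal(stats::p.adjust(p, "BH"), c(0.004, 0.016, 0.041, 0.041))
  expect_equal(bf_bh(p), c(0.004, 0.016, 0.041, 0.041))
  set.seed(66)
  for (i in 1:50) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(pv, "BH"), bf_bh(pv), tolerance = 1e-14)
  }
})

test_that("fst_significance: rank p-values, q monotone in p, undefined excluded", {
  cs <- toy_callset(list(
    c(rep("0/1", 11), rep("0/0", 11), rep("0/1", 5), rep("0/0", 5)),
    c(rep("1/1", 22), rep("0/0", 10)),
    c(rep("0/1", 22), rep("0/0", 10)),
    rep("0/0", 32)
  ), c(rep("Hanwoo", 22), rep("Holstein", 10)))
  scan <- fst_scan(cs)
  sig <- fst_significance(scan, method = "rank")
  def <- sig[sig$defined, ]
  # largest F has rank p 1/3, smallest has p 1
  expect_equal(sort(def$p_value), c(1 / 3, 2 / 3, 1))
  expect_true(is.na(sig$p_value[4]))
  expect_false(sig$significant[4])
  # q monotone in p
  expect_false(is.unsorted(def$q_value[order(def$p_value)]))

  # identical F values under rank method -> all p = 1
  cs2 <- toy_callset(list(
    c(rep("1/1", 22), rep("0/0", 10)),
    c(rep("1/1", 22), rep("0/0", 10)),
    c(rep("1/1", 22), rep("0/0", 10))
  ), c(rep("Hanwoo", 22), rep("Holstein", 10)))
  sig2 <- fst_significance(fst_scan(cs2), method = "rank")
  expect_true(all(sig2$p_value == 1))
  # and the normal method refuses the zero-variance fit
  expect_error(fst_significance(fst_scan(cs2), method = "normal"),
               "rank")
})

test_that("planted divergent CNVs dominate the top of the scan", {
  sim <- simulate_callset(sim_config(
    n_cnvs = 1000, frac_differentiated = 0.02, delta = 0.8,
    frac_specific_b1 = 0, frac_specific_b2 = 0, frac_monomorphic = 0,
    genome = data.frame(chrom = "chr1", length = 5e7), seed = 43))
  scan <- fst_scan(sim$callset)
  planted <- sim$truth$cnv_id[sim$truth$class == "differentiated"]
  top30 <- scan$cnv_id[order(-scan$fst)][1:30]
  expect_true(all(planted %in% top30))

  # the normal-fit FDR call recovers most planted CNVs
  sig <- fst_significance(scan, method = "normal", alpha = 0.01)
  expect_gte(sum(planted %in% sig$cnv_id[sig$significant]), 18)
})

test_that("annotate_selected joins genes and per-breed genotype tallies", {
  geno_hot <- c(rep("1/1", 13), rep("0/1", 9), rep("0/1", 3), rep("0/0", 7))
  cs <- toy_callset(list(
    geno_hot,
    c(rep("1/1", 22), rep("0/0", 10)),
    c(rep("0/1", 11), rep("0/0", 11), rep("0/1", 5), rep("0/0", 5))
  ), c(rep("Hanwoo", 22), rep("Holstein", 10)))
  scan <- fst_scan(cs)
  scan$p_value <- c(0.5, 0.001, 0.9)
  scan$q_value <- c(0.5, 0.003, 0.9)
  scan$significant <- c(FALSE, TRUE, FALSE)
  genes <- data.frame(gene_id = "GALK2", chrom = "chr1",
                      start = 11000, end = 12100)
  ann <- annotate_selected(scan, cs, genes)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$cnv_id, "cnv002")
  expect_equal(ann$genes, "GALK2")
  expect_equal(ann$n_homdel_Hanwoo, 22)
  expect_equal(ann$n_homref_Holstein, 10)
  expect_equal(ann$n_het_Hanwoo, 0)

  # significant CNV with no gene overlap gets an empty field
  ann2 <- annotate_selected(scan, cs,
                            data.frame(gene_id = "gFar", chrom = "chr9",
                                       start = 1, end = 10))
  expect_equal(ann2$genes, "")

  # tallies equal direct genotype counting for every breed
  g2 <- cs$genotypes[2, ]
  expect_equal(ann$n_homdel_Hanwoo,
               sum(g2[cs$samples$breed == "Hanwoo"] == 2))
  expect_equal(ann$n_het_Holstein,
               sum(g2[cs$samples$breed == "Holstein"] == 1))
})
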