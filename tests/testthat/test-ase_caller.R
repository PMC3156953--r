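test_that("the cumulative binomial matches closed forms and full support", {
  expect_equal(binom_cdf(0, 21, 0.5), 0.5^21)          # 4.768e-7
  expect_equal(binom_cdf(1, 4, 0.3), 0.7^4 + 4 * 0.3 * 0.7^3)  # 0.6517
  expect_equal(binom_cdf(12, 12, 0.37), 1.0)
  expect_error(binom_cdf(5, 4, 0.5), "exceed")
  expect_error(binom_cdf(1, 4, 0), "strictly inside")
  expect_error(binom_cdf(1, 4, 1), "strictly inside")
})

test_that("the cumulative binomial equals exhaustive outcome enumeration", {
  # oracle: enumerate all 2^n allele assignments is equivalent to summing
  # the probability mass term by term from factorials
  enum_cdf <- function(x, n, p) {
    sum(vapply(0:x, function(y) {
      exp(lfactorial(n) - lfactorial(y) - lfactorial(n - y)) *
        p^y * (1 - p)^(n - y)
    }, 0))
  }
  for (n in 1:12) {
    for (x in 0:n) {
      for (p in seq(0.1, 0.9, by = 0.2)) {
        expect_equal(binom_cdf(x, n, p), enum_cdf(x, n, p),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the fair-coin cumulative binomial is symmetric", {
  for (n in c(5, 12, 33)) {
    for (x in 0:(n - 1)) {
      expect_equal(binom_cdf(x, n, 0.5), 1 - binom_cdf(n - x - 1, n, 0.5),
                   tolerance = 1e-12)
    }
  }
})

test_that("the null success probability follows the sample's ploidy model", {
  expect_equal(adjust_ps(0.5, "diploid"), 0.5)
  expect_equal(adjust_ps(0.73, "vaf"), 0.73)
  expect_equal(adjust_ps(0.20, "vaf"), 0.20)
  expect_equal(adjust_ps(0.01, "vaf"), 0.05)   # clamped
  expect_equal(adjust_ps(0.99, "vaf"), 0.95)
  expect_error(adjust_ps(1.2, "vaf"), "0, 1")
})

test_that("the drift ratio and its biased band use strict boundaries", {
  expect_equal(drift_ratio(0, 404), 1.0)
  expect_equal(drift_ratio(10, 10), 0.5)
  expect_equal(drift_ratio(223, 16), 16 / 239)  # 0.0669
  band <- function(r, a) alleledrift:::in_drift_band(drift_ratio(r, a))
  expect_true(band(0, 404))
  expect_true(band(223, 16))
  expect_false(band(10, 10))
  expect_false(band(8, 2))    # drift exactly 0.8: not biased
  expect_false(band(2, 8))    # drift exactly 0.2: not biased
  expect_true(is.na(drift_ratio(0, 0)))
})

test_that("a monoallelic locus reproduces the worked corrected P-value", {
  # 21 reads on one allele, balanced genome, family of 2,534 tested loci
  rna <- ac(pos = 100, assay = "RNA", ref_reads = 21, alt_reads = 0)
  exome <- snv(pos = 100, ref_reads = 10, alt_reads = 10)
  res <- test_ase_loci(rna, exome, m = 2534)
  expect_equal(res$status, "tested")
  expect_equal(res$p_s_used, 0.5)
  expect_equal(res$p_raw, 0.5^21)               # 4.768e-7
  expect_equal(res$p_corrected, 2534 * 0.5^21)  # 0.00121
  expect_equal(round(res$p_corrected, 3), 0.001)
  expect_true(res$biased)
  expect_equal(res$preferred_allele, "ref")
})

test_that("the coverage gate and the drift band gate the test independently", {
  exome <- snv(pos = 1:3, ref_reads = 10, alt_reads = 10)
  rna <- dplyr::bind_rows(
    ac(pos = 1, assay = "RNA", ref_reads = 19, alt_reads = 0),  # < 20 reads
    ac(pos = 2, assay = "RNA", ref_reads = 36, alt_reads = 24), # drift 0.4
    ac(pos = 3, assay = "RNA", ref_reads = 55, alt_reads = 2)
  )
  res <- test_ase_loci(rna, exome)
  expect_equal(res$status[res$pos == 1], "low_coverage")
  expect_true(is.na(res$p_raw[res$pos == 1]))
  expect_false(res$biased[res$pos == 2])       # band rule, regardless of P
  expect_true(res$biased[res$pos == 3])
  expect_equal(res$m[1], 2)                    # loci passing the gate
})

test_that("the copy-number-adjusted null uses the rare RNA allele's exome VAF", {
  # tumor exome VAF 0.75 at a 3+1 locus; rare RNA allele is ref
  exome <- snv(pos = 1, ref_reads = 5, alt_reads = 15)
  rna <- ac(pos = 1, assay = "RNA", ref_reads = 4, alt_reads = 46)
  res <- test_ase_loci(rna, exome, m = 1)
  expect_equal(res$p_s_used, 0.25)             # 1 - 0.75
  expect_equal(res$p_raw, binom_cdf(4, 50, 0.25))
  # diploid mode ignores the exome VAF
  res_dip <- test_ase_loci(rna, exome, m = 1, ps_mode = "diploid")
  expect_equal(res_dip$p_s_used, 0.5)
})

test_that("correction never lowers a P-value and is monotone in m", {
  rna <- ac(pos = 1, assay = "RNA", ref_reads = 30, alt_reads = 1)
  exome <- snv(pos = 1, ref_reads = 10, alt_reads = 10)
  p <- vapply(c(1, 10, 100, 5000),
              function(m) test_ase_loci(rna, exome, m = m)$p_corrected,
              numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= test_ase_loci(rna, exome, m = 1)$p_raw))
  expect_lte(max(p), 1)
  expect_error(test_ase_loci(rna, exome, m = 0), "m must be")
})

test_that("gene aggregation classifies concordant, ambiguous and gated genes", {
  genes <- gm("G1", "chr1", 1, 1000)
  exome <- snv(pos = c(100, 200), ref_reads = 10, alt_reads = 10)
  # two biased loci: ase with the most significant corrected P
  rna2 <- dplyr::bind_rows(
    ac(pos = 100, assay = "RNA", ref_reads = 30, alt_reads = 0),
    ac(pos = 200, assay = "RNA", ref_reads = 24, alt_reads = 1)
  )
  g <- aggregate_ase_genes(test_ase_loci(rna2, exome, m = 2534), genes)
  expect_equal(g$status, "ase")
  locus_p <- g$loci[[1]]$p_value
  expect_equal(g$gene_p, min(locus_p))

  # one monoallelic + one balanced well-covered locus: ambiguous
  rna_mix <- dplyr::bind_rows(
    ac(pos = 100, assay = "RNA", ref_reads = 30, alt_reads = 0),
    ac(pos = 200, assay = "RNA", ref_reads = 25, alt_reads = 25)
  )
  g_mix <- aggregate_ase_genes(test_ase_loci(rna_mix, exome), genes)
  expect_equal(g_mix$status, "ambiguous")

  # single biased locus is enough for an ase call
  one <- snv(pos = 100, ref_reads = 10, alt_reads = 10)
  rna1 <- ac(pos = 100, assay = "RNA", ref_reads = 30, alt_reads = 0)
  g1 <- aggregate_ase_genes(test_ase_loci(rna1, one, m = 10), genes)
  expect_equal(g1$status, "ase")

  # all loci under the coverage gate
  rna_low <- ac(pos = 100, assay = "RNA", ref_reads = 5, alt_reads = 5)
  g_low <- aggregate_ase_genes(test_ase_loci(rna_low, one), genes)
  expect_equal(g_low$status, "low_coverage")

  # no heterozygous locus at all
  g_none <- aggregate_ase_genes(test_ase_loci(rna1, one[0, ], m = 1), genes)
  expect_equal(g_none$status, "no_genotype")
})

test_that("cross-sample comparison classifies genes by the other sample's state", {
  mk_gene <- function(status, pref, pos = 100, biased = TRUE) {
    tibble::tibble(
      gene_id = "G1", chrom = "chr1", status = status, gene_p = 1e-4,
      preferred_allele = pref, n_loci = 1L, n_tested = 1L,
      n_biased = as.integer(biased),
      loci = list(tibble::tibble(
        pos = pos, ref = "A", alt = "G", major_reads = 30, minor_reads = 0,
        drift = 0, p_value = 1e-4, status = "tested", biased = biased,
        preferred_allele = pref, variant_id = NA_character_
      ))
    )
  }
  a <- mk_gene("ase", "ref")
  expect_equal(compare_ase_across_samples(a, mk_gene("ase", "ref"))$class,
               "shared_same_allele")
  expect_equal(compare_ase_across_samples(a, mk_gene("ase", "alt"))$class,
               "shared_opposite_allele")
  expect_equal(compare_ase_across_samples(a, mk_gene("not_ase", NA,
                                                     biased = FALSE))$class,
               "a_only")
  expect_equal(compare_ase_across_samples(a,
                 mk_gene("low_coverage", NA, biased = FALSE))$class,
               "undetermined_low_expression")
  expect_equal(compare_ase_across_samples(a,
                 mk_gene("no_genotype", NA, biased = FALSE))$class,
               "undetermined_no_genotype")
  expect_equal(compare_ase_across_samples(mk_gene("not_ase", NA,
                                                  biased = FALSE), a)$class,
               "b_only")
  # agreement is judged per shared locus, so opposite ref/alt labels at
  # different loci do not fake a conflict
  a2 <- mk_gene("ase", "ref", pos = 100)
  b2 <- mk_gene("ase", "alt", pos = 200)   # different locus, no overlap
  b2$loci[[1]]$preferred_allele <- "alt"
  expect_equal(compare_ase_across_samples(a2, b2)$class,
               "shared_opposite_allele")   # falls back to gene majority
})
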