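test_that("the simulators are fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_genes = 40, n_het_loci = 400,
                    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth$loci, b$truth$loci)
  expect_identical(a$exome, b$exome)
  expect_identical(a$rna, b$rna)
})

test_that("truth construction follows the copy-number segment list", {
  # no LOH segments: no LOH genes in truth
  none <- simulate_genome(sim_config(seed = 5, loh_segments = list(),
                                     n_genes = 40, n_het_loci = 400,
                                     chrom_lengths = c(chr1 = 2e6)))
  expect_equal(sum(none$genes$is_loh), 0)

  # a whole-chromosome (2,0) segment puts every chr1 gene into LOH truth
  all_loh <- simulate_genome(sim_config(
    seed = 5, n_genes = 40, n_het_loci = 400,
    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
    loh_segments = list(list(chrom = "chr1", frac = 1, copies = c(2, 0)))
  ))
  chr1_genes <- all_loh$genes$chrom == "chr1"
  expect_true(all(all_loh$genes$is_loh[chr1_genes]))
  expect_false(any(all_loh$genes$is_loh[!chr1_genes]))
  # and the lost allele has zero copies at every locus inside
  inside <- !is.na(all_loh$loci$gene_id) &
    all_loh$loci$chrom == "chr1"
  expect_true(all(pmin(all_loh$loci$cn_ref,
                       all_loh$loci$cn_alt)[inside] == 0))
})

test_that("simulated exome depth matches the configured mean", {
  cfg <- sim_config(seed = 7, n_het_loci = 12000, n_genes = 50,
                    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6))
  truth <- simulate_genome(cfg)
  counts <- simulate_exome_counts(truth, cfg)
  normal <- counts[counts$sample == "normal", ]
  expect_gte(nrow(normal), 1e4)
  mean_depth <- mean(normal$ref_reads + normal$alt_reads)
  expect_lt(abs(mean_depth - cfg$exome_depth_mean) / cfg$exome_depth_mean,
            0.05)
})

test_that("allelic imbalance segments shift the tumor VAF to the copy fraction", {
  cfg <- sim_config(
    seed = 13, n_genes = 40, n_het_loci = 2000,
    chrom_lengths = c(chr1 = 2e6), error_rate = 0,
    loh_segments = list(list(chrom = "chr1", frac = 1, copies = c(3, 1)))
  )
  truth <- simulate_genome(cfg)
  counts <- simulate_exome_counts(truth, cfg)
  tumor <- counts[counts$sample == "tumor", ]
  joined <- dplyr::inner_join(
    tumor, truth$loci[, c("chrom", "pos", "cn_alt")],
    by = c("chrom", "pos")
  )
  single <- joined[joined$cn_alt == 1, ]
  vaf <- sum(single$alt_reads) / sum(single$ref_reads + single$alt_reads)
  expect_equal(vaf, 0.25, tolerance = 0.05)
  # normal stays balanced at the same loci
  normal <- counts[counts$sample == "normal", ]
  nvaf <- sum(normal$alt_reads) / sum(normal$ref_reads + normal$alt_reads)
  expect_equal(nvaf, 0.5, tolerance = 0.02)
})

test_that("simulated heterozygotes pass the het_hc band at the analytic rate", {
  sim <- cached_sim(1)
  cfg <- sim$truth$config
  normal <- dplyr::filter(sim$exome, sample == "normal")
  calls <- call_hc_snvs(normal)
  observed <- sum(calls$genotype == "het_hc") / nrow(sim$truth$loci)
  # analytic: P(depth-and-band acceptance) under Poisson depth and
  # Binomial(depth, 0.5) reads, including the 3-read/10% SNV filter
  depths <- 0:80
  p_pass_given_n <- vapply(depths, function(n) {
    if (n == 0) return(0)
    alt <- 0:n
    ok <- alt >= 3 & alt / n >= 0.1 & alt / n >= 0.2 & alt / n <= 0.8
    sum(dbinom(alt[ok], n, 0.5))
  }, 0)
  expected <- sum(dpois(depths, cfg$exome_depth_mean) * p_pass_given_n)
  expect_equal(observed, expected, tolerance = 0.02)
})

test_that("RNA counts express truth drift and silence unexpressed genes", {
  cfg <- sim_config(seed = 21, n_genes = 60, n_het_loci = 600,
                    chrom_lengths = c(chr1 = 3e6), error_rate = 0,
                    ase_fraction = 0.2, ase_drift_range = c(1, 1),
                    loh_segments = list())
  truth <- simulate_genome(cfg)
  rna <- simulate_rna_counts(truth, cfg)
  g <- truth$genes

  # unexpressed genes emit nothing
  silent <- g$gene_id[!g$expressed]
  expect_false(any(rna$pos %in%
    truth$loci$pos[truth$loci$gene_id %in% silent]))

  # drift 1 genes are monoallelic at every locus
  ase_loci <- truth$loci[truth$loci$gene_id %in% g$gene_id[g$is_ase], ]
  at <- dplyr::inner_join(rna, ase_loci[, c("chrom", "pos")],
                          by = c("chrom", "pos"))
  expect_true(all(pmin(at$ref_reads, at$alt_reads) == 0))

  # balanced genes drift to 0.5 in aggregate
  bal_loci <- truth$loci[truth$loci$gene_id %in%
                           g$gene_id[g$expressed & !g$is_ase], ]
  atb <- dplyr::inner_join(rna, bal_loci[, c("chrom", "pos")],
                           by = c("chrom", "pos"))
  drift <- sum(atb$alt_reads) / sum(atb$ref_reads + atb$alt_reads)
  expect_equal(drift, 0.5, tolerance = 0.02)
})

test_that("call scoring reports the documented conventions", {
  truth <- list(genes = tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    is_loh = c(TRUE, TRUE, FALSE, FALSE),
    is_ase = c(FALSE, FALSE, TRUE, FALSE)
  ))
  perfect <- evaluate_calls(truth, c("g1", "g2"), "g3")
  expect_equal(perfect$precision, c(1, 1))
  expect_equal(perfect$recall, c(1, 1))

  empty <- evaluate_calls(truth, character(), character())
  expect_equal(empty$recall, c(0, 0))
  expect_equal(empty$precision, c(1, 1))     # undefined -> 1, flagged
  expect_true(all(empty$no_calls))

  # on a null truth every call is false: FDR = fp / calls
  null_truth <- list(genes = tibble::tibble(
    gene_id = c("g1", "g2"), is_loh = FALSE, is_ase = FALSE
  ))
  fp <- evaluate_calls(null_truth, c("g1", "g2"), character())
  expect_equal(fp$fdr[fp$class == "loh"], 1)
})
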