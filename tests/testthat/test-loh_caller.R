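test_that("the homozygosity test sits exactly at the ten-read boundary", {
  ten <- test_homozygosity(10, 0)
  expect_equal(ten$p_value, 0.5^10)
  expect_true(ten$is_homozygous)          # 9.77e-4 < 0.001

  nine <- test_homozygosity(9, 0)
  expect_equal(nine$p_value, 0.5^9)
  expect_false(nine$is_homozygous)        # 1.95e-3, and depth < 10

  # 20/1: exhaustive sum over y = 0,1 of C(21,y)/2^21
  one_off <- test_homozygosity(20, 1)
  expect_equal(one_off$p_value, 22 / 2^21)
  expect_true(one_off$is_homozygous)

  zero <- test_homozygosity(0, 0)
  expect_equal(zero$p_value, 1)
  expect_false(zero$is_homozygous)
})

test_that("strict mode requires complete absence of the minor allele", {
  expect_true(test_homozygosity(20, 1)$is_homozygous)
  expect_false(test_homozygosity(20, 1, strict = TRUE)$is_homozygous)
  expect_true(test_homozygosity(20, 0, strict = TRUE)$is_homozygous)
})

test_that("the homozygosity P-value increases with the minor count", {
  for (n in c(10, 25, 60)) {
    p <- test_homozygosity(n - 0:5, 0:5)$p_value
    expect_true(all(diff(p) > 0))
  }
  # balanced ties can never pass for any n
  expect_false(any(test_homozygosity(1:50, 1:50)$is_homozygous))
})

test_that("LOH loci require a het_hc normal and a homozygous tumor", {
  normal <- dplyr::bind_rows(
    snv(pos = 1, ref_reads = 10, alt_reads = 10),   # het, tumor 15/0 -> LOH
    snv(pos = 2, ref_reads = 3, alt_reads = 17),    # vaf 0.85, outside band
    snv(pos = 3, ref_reads = 10, alt_reads = 10),   # tumor depth 8 -> no
    snv(pos = 4, ref_reads = 10, alt_reads = 10)    # no tumor coverage
  )
  tumor <- dplyr::bind_rows(
    ac(pos = 1, ref_reads = 15, alt_reads = 0),
    ac(pos = 2, ref_reads = 30, alt_reads = 0),
    ac(pos = 3, ref_reads = 8, alt_reads = 0)
  )
  events <- call_loh_loci(normal, tumor)
  expect_equal(events$pos, 1)
  expect_equal(events$retained_allele, "ref")
  expect_equal(events$tumor_depth, 15)
  expect_equal(attr(events, "n_no_coverage"), 1)
  expect_equal(attr(events, "n_candidates"), 3)  # pos 2 is not het_hc
})

test_that("gene aggregation assigns events to CDS and keeps orphans", {
  genes <- dplyr::bind_rows(
    gm("GA", "chr1", 100, 1000, utr = 50),
    gm("GB", "chr1", 900, 2000)            # overlaps GA at 900-1000
  )
  events <- tibble::tibble(
    chrom = "chr1", pos = c(150, 500, 950, 5000),
    ref = "A", alt = "G", gene_id = NA_character_,
    normal_vaf = 0.5, tumor_depth = 20, tumor_minor_reads = 0,
    p_value = 0.5^20, retained_allele = "ref"
  )
  gs <- aggregate_loh_genes(events, genes)
  ga <- gs[!is.na(gs$gene_id) & gs$gene_id == "GA", ]
  gb <- gs[!is.na(gs$gene_id) & gs$gene_id == "GB", ]
  expect_equal(ga$n_snvs, 3)               # 150, 500, 950
  expect_equal(gb$n_snvs, 1)               # 950 shared with GA
  orphan <- gs[is.na(gs$gene_id), ]
  expect_equal(orphan$n_snvs, 1)
  expect_equal(orphan$loci[[1]]$pos, 5000)
})

test_that("isolated LOH genes face the three plausibility criteria", {
  genes_sum <- function() {
    tibble::tibble(
      gene_id = "LONE", chrom = "chr1", n_snvs = 1, min_p = 1e-4,
      loci = list(tibble::tibble(
        pos = 1e6, ref = "A", alt = "G", major_reads = 30, minor_reads = 0,
        p_value = 1e-4, retained_allele = "alt", normal_vaf = 0.5,
        variant_id = NA_character_
      ))
    )
  }
  catalog <- tibble::tibble(chrom = "chr1", pos = 1e6, allele = "G",
                            id = "rs1")
  rna_good <- ac(pos = 1e6, assay = "RNA", ref_reads = 30, alt_reads = 0)

  ok <- filter_isolated_loh(genes_sum(), tumor_calls = NULL,
                            rna_counts = rna_good, catalog = catalog)
  expect_true(ok$isolated)
  expect_true(ok$accepted)

  # a tumor heterozygote 10 kb away contradicts the deletion
  conflict <- filter_isolated_loh(
    genes_sum(),
    tumor_calls = snv(pos = 1e6 + 1e4, ref_reads = 15, alt_reads = 15),
    rna_counts = rna_good, catalog = catalog
  )
  expect_false(conflict$accepted)
  expect_match(conflict$reject_reason, "conflict-within-window")
  # ... but 30 kb away is outside the window
  far <- filter_isolated_loh(
    genes_sum(),
    tumor_calls = snv(pos = 1e6 + 3e4, ref_reads = 15, alt_reads = 15),
    rna_counts = rna_good, catalog = catalog
  )
  expect_true(far$accepted)

  novel <- filter_isolated_loh(genes_sum(), rna_counts = rna_good,
                               catalog = catalog[0, ])
  expect_match(novel$reject_reason, "not-known-variant")

  no_rna <- filter_isolated_loh(genes_sum(), catalog = catalog,
                                rna_counts = NULL)
  expect_match(no_rna$reject_reason, "no-rna-support")
  shallow <- filter_isolated_loh(
    genes_sum(), catalog = catalog,
    rna_counts = ac(pos = 1e6, assay = "RNA", ref_reads = 5, alt_reads = 0)
  )
  expect_match(shallow$reject_reason, "no-rna-support")
})

test_that("clustered LOH genes bypass the isolated-gene criteria", {
  two <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr1", n_snvs = 1, min_p = 1e-4,
    loci = list(
      tibble::tibble(pos = 1e6, ref = "A", alt = "G", major_reads = 30,
                     minor_reads = 0, p_value = 1e-4,
                     retained_allele = "alt", normal_vaf = 0.5,
                     variant_id = NA_character_),
      tibble::tibble(pos = 1.2e6, ref = "C", alt = "T", major_reads = 25,
                     minor_reads = 0, p_value = 1e-4,
                     retained_allele = "ref", normal_vaf = 0.5,
                     variant_id = NA_character_)
    )
  )
  res <- filter_isolated_loh(two, catalog = NULL, rna_counts = NULL)
  expect_equal(res$isolated, c(FALSE, FALSE))   # 200 kb apart, same chrom
  expect_true(all(res$accepted))
})

test_that("the paired-VAF table keeps only loci covered in both samples", {
  normal <- dplyr::bind_rows(
    ac(pos = 1, ref_reads = 10, alt_reads = 10),
    ac(pos = 2, ref_reads = 12, alt_reads = 8)
  )
  tumor <- ac(pos = 1, ref_reads = 18, alt_reads = 2)
  pv <- paired_vaf_table(normal, tumor)
  expect_equal(nrow(pv), 1)
  expect_equal(pv$normal_vaf, 0.5)
  expect_equal(pv$tumor_vaf, 0.1)
})

test_that("without somatic change, LOH calls stay at the test's alpha level", {
  # tumor drawn from the same balanced distribution as the normal
  sim <- cached_sim(1)
  cfg <- sim$truth$config
  normal <- dplyr::filter(sim$exome, sample == "normal")
  withr::with_seed(2001, {
    n <- nrow(normal)
    null_depth <- rpois(n, cfg$exome_depth_mean)
    null_alt <- rbinom(n, null_depth, 0.5)
  })
  tumor_null <- normal
  tumor_null$sample <- "tumor"
  tumor_null$ref_reads <- null_depth - null_alt
  tumor_null$alt_reads <- null_alt
  calls <- call_hc_snvs(normal)
  events <- call_loh_loci(calls, tumor_null)
  testable <- attr(events, "n_candidates") - attr(events, "n_no_coverage")
  # expected false-call fraction <= alpha; allow binomial sampling slack
  limit <- qbinom(0.999, testable, 0.001)
  expect_lte(nrow(events), limit)
})
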