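#' Filter high-confidence SNVs from DNA allele counts
#'
#' Mirrors the exome SNV filter of a high-confidence variant caller: a
#' locus is retained as an SNV when the variant allele is supported by at
#' least `min_var_reads` reads *and* its variant allele frequency (VAF =
#' alt / (ref + alt)) is at least `min_vaf`.  Defaults are 3 reads and
#' 10%.  Zero-depth loci cannot be called and are skipped (tallied in the
#' `"n_zero_depth"` attribute).
#'
#' Each retained call is genotyped with [classify_genotype()]:
#' high-confidence heterozygous (`het_hc`) inside the 20–80% VAF band,
#' preliminary heterozygous (`het_preliminary`) inside 10–90%, homozygous
#' when the binomial homozygosity test passes, otherwise `ambiguous`.
#'
#' @param counts Allele-count tibble (DNA rows are used).
#' @param min_var_reads Minimum variant-supporting reads (default 3).
#' @param min_vaf Minimum variant allele frequency (default 0.10,
#'   boundary inclusive).
#' @param het_band,prelim_band Inclusive VAF bands for the two
#'   heterozygote classes.
#' @param hom_alpha,hom_min_reads Parameters of the homozygosity test
#'   (see [test_homozygosity()]).
#' @return SNV-call tibble: locus columns, `sample`, `depth`,
#'   `ref_reads`, `alt_reads`, `vaf`, `genotype`, `known` (NA until
#'   [annotate_known()] is applied).
#' @export
call_hc_snvs <- function(counts, min_var_reads = 3, min_vaf = 0.10,
                         het_band = c(0.20, 0.80),
                         prelim_band = c(0.10, 0.90),
                         hom_alpha = 0.001, hom_min_reads = 10) {
  assert_columns(counts, c(LOCUS_COLS, "sample", "assay",
                           "ref_reads", "alt_reads"))
  check_scalar_number(min_var_reads, "min_var_reads", 0)
  check_scalar_number(min_vaf, "min_vaf", 0)
  x <- filter(counts, .data$assay == "DNA")
  depth <- x$ref_reads + x$alt_reads
  n_zero <- sum(depth == 0)
  x <- x[depth > 0, , drop = FALSE]
  depth <- depth[depth > 0]
  vaf <- x$alt_reads / depth
  keep <- x$alt_reads >= min_var_reads & vaf >= min_vaf
  out <- tibble(
    chrom = x$chrom[keep], pos = x$pos[keep],
    ref = x$ref[keep], alt = x$alt[keep],
    sample = x$sample[keep],
    depth = depth[keep],
    ref_reads = x$ref_reads[keep], alt_reads = x$alt_reads[keep],
    vaf = vaf[keep]
  )
  out$genotype <- classify_genotype(
    out$ref_reads, out$alt_reads,
    het_band = het_band, prelim_band = prelim_band,
    hom_alpha = hom_alpha, hom_min_reads = hom_min_reads
  )
  out$known <- rep(NA, nrow(out))
  attr(out, "n_zero_depth") <- n_zero
  out
}

#' Classify a genotype from allele counts
#'
#' Banding rules on the variant allele frequency, applied in order:
#' `het_hc` when VAF lies in the high-confidence heterozygote band
#' (20–80%, inclusive); `het_preliminary` when it lies in the wider
#' preliminary band (10–90%) but not the first; homozygous
#' (`hom_variant` / `hom_reference`, by which allele dominates) when the
#' one-sided binomial homozygosity test passes (minor-allele reads under
#' a fair-coin null, P < `hom_alpha` with at least `hom_min_reads`
#' reads); otherwise `ambiguous`.  Reference-only loci (zero alt reads)
#' are classifiable, so LOH comparison can represent them.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors.
#' @inheritParams call_hc_snvs
#' @return Character vector of genotype labels.
#' @export
classify_genotype <- function(ref_reads, alt_reads,
                              het_band = c(0.20, 0.80),
                              prelim_band = c(0.10, 0.90),
                              hom_alpha = 0.001, hom_min_reads = 10) {
  depth <- ref_reads + alt_reads
  if (any(depth == 0)) abort("classify_genotype needs depth > 0")
  vaf <- alt_reads / depth
  hom <- test_homozygosity(ref_reads, alt_reads,
                           alpha = hom_alpha, min_reads = hom_min_reads)
  dplyr::case_when(
    vaf >= het_band[1] & vaf <= het_band[2] ~ "het_hc",
    vaf >= prelim_band[1] & vaf <= prelim_band[2] ~ "het_preliminary",
    hom$is_homozygous & vaf > 0.5 ~ "hom_variant",
    hom$is_homozygous & vaf <= 0.5 ~ "hom_reference",
    .default = "ambiguous"
  )
}

#' Concordance table between two callsets over shared loci
#'
#' Joins two SNV callsets on (chrom, pos) and cross-tabulates their
#' genotype classes collapsed to heterozygous (`het_hc`,
#' `het_preliminary`) versus homozygous (`hom_variant`,
#' `hom_reference`); ambiguous calls are excluded.  Used to compare a
#' sequencing callset against, e.g., SNP-array genotypes.
#'
#' @param a,b SNV-call tibbles on the same coordinate dialect.
#' @return Tibble with one row per (class_a, class_b) cell: `n`,
#'   `pct_of_a` (per cent of the class_a row total, nearest integer) and
#'   `pct_overall` (per cent of all shared loci, nearest integer).
#'   Disjoint callsets give an empty table.
#' @export
compare_callsets <- function(a, b) {
  assert_columns(a, c("chrom", "pos", "genotype"))
  assert_columns(b, c("chrom", "pos", "genotype"))
  collapse <- function(g) {
    dplyr::case_when(
      g %in% c("het_hc", "het_preliminary") ~ "het",
      g %in% c("hom_variant", "hom_reference") ~ "hom",
      .default = NA_character_
    )
  }
  shared <- inner_join(
    transmute(a, .data$chrom, .data$pos, class_a = collapse(.data$genotype)),
    transmute(b, .data$chrom, .data$pos, class_b = collapse(.data$genotype)),
    by = c("chrom", "pos")
  ) |>
    filter(!is.na(.data$class_a), !is.na(.data$class_b))
  if (nrow(shared) == 0) {
    return(tibble(class_a = character(), class_b = character(),
                  n = integer(), pct_of_a = numeric(),
                  pct_overall = numeric()))
  }
  shared |>
    count(.data$class_a, .data$class_b) |>
    group_by(.data$class_a) |>
    mutate(pct_of_a = round(100 * .data$n / sum(.data$n))) |>
    ungroup() |>
    mutate(pct_overall = round(100 * .data$n / sum(.data$n)))
}
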