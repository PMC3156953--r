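#' Cumulative binomial distribution function
#'
#' `B(x; n, p) = sum_{y=0..x} b(y; n, p)`, the one-sided lower-tail
#' probability of observing at most `x` successes in `n` trials.  This is
#' the shared statistic of both the homozygosity test (minor DNA reads
#' under p = 0.5) and the allelic-imbalance test (rare-allele RNA reads
#' under the copy-number-adjusted null).  Evaluated through the
#' regularized incomplete beta form, so it is numerically stable for
#' `n` well beyond 1e5.
#'
#' @param x Number of successes, `0 <= x <= n` (vectorized).
#' @param n Number of trials.
#' @param p Per-trial success probability, strictly inside (0, 1).
#' @return `P(X <= x)` for `X ~ Binomial(n, p)`.
#' @export
binom_cdf <- function(x, n, p) {
  if (any(!is_count(x)) || any(!is_count(n))) {
    abort("binom_cdf: x and n must be non-negative integers")
  }
  if (any(x > n)) abort("binom_cdf: x must not exceed n")
  if (any(p <= 0 | p >= 1)) abort("binom_cdf: p must be strictly inside (0, 1)")
  pbinom(x, n, p)
}

#' Null success probability for the allelic-imbalance test
#'
#' In a diploid genome the two alleles of a heterozygous locus are read
#' with equal probability, so the binomial null uses p = 0.5.  In a
#' copy-number-altered tumor the expected allele fraction is shifted by
#' the allelic copy numbers, so the null success probability is taken
#' from the exome (DNA) variant allele frequency of the tested allele
#' instead of the static 0.5 — DNA reads sample the same copy-number
#' landscape that the RNA null should reflect.  The value is clamped to
#' `[0.05, 0.95]` against degenerate inputs (unreachable for
#' high-confidence heterozygotes, whose VAF lies in 20–80%).
#'
#' @param exome_vaf Exome VAF of the allele being tested (vectorized).
#' @param mode `"diploid"` (always 0.5) or `"vaf"` (the adjusted null).
#' @return Numeric vector of success probabilities.
#' @export
adjust_ps <- function(exome_vaf, mode = c("vaf", "diploid")) {
  mode <- match.arg(mode)
  if (any(is.na(exome_vaf) | exome_vaf < 0 | exome_vaf > 1)) {
    abort("adjust_ps: exome_vaf must lie in [0, 1]")
  }
  if (mode == "diploid") rep(0.5, length(exome_vaf))
  else clamp(exome_vaf, 0.05, 0.95)
}

#' Allele drift ratio
#'
#' The variant-allele fraction of the RNA reads at a locus,
#' `alt / (ref + alt)`.  A locus is in the biased band when the drift is
#' strictly below `band[1]` or strictly above `band[2]` (defaults 0.2 /
#' 0.8).  Zero-depth loci return NA (no call).
#'
#' @param ref_rna,alt_rna RNA read counts (vectorized).
#' @return Numeric drift values in `[0, 1]`, NA at zero depth.
#' @export
drift_ratio <- function(ref_rna, alt_rna) {
  n <- ref_rna + alt_rna
  ifelse(n > 0, alt_rna / n, NA_real_)
}

in_drift_band <- function(drift, band = c(0.2, 0.8)) {
  !is.na(drift) & (drift < band[1] | drift > band[2])
}

#' Test allelic imbalance at heterozygous loci
#'
#' The core ASE statistic, applied to every exome high-confidence
#' heterozygous locus with RNA coverage:
#'
#' 1. Loci with RNA depth below `min_cov` (default 20 reads) are gated
#'    out as `low_coverage` — below that the binomial test has no power.
#' 2. At tested loci, `x` is the rare-allele RNA read count, `n` the RNA
#'    depth, and the null success probability comes from [adjust_ps()]
#'    applied to the exome VAF of the rare RNA allele (`ps_mode = "vaf"`,
#'    the copy-number-adjusted null) or a fixed 0.5
#'    (`ps_mode = "diploid"`, appropriate for a diploid sample).
#'    `p_raw = B(x; n, p_s)`, one-sided, no doubling.
#' 3. Family-wise correction over the `m` loci passing the coverage gate:
#'    Bonferroni `min(1, m * p_raw)` (default) or Benjamini-Hochberg.
#' 4. A locus is `biased` when its drift ratio falls in the biased band
#'    *and* the corrected P-value is below `alpha` (default 0.05).
#'
#' @param rna RNA allele-count tibble (or the output of
#'   [rna_allele_counts_at()]).
#' @param exome_calls SNV-call tibble for the same sample's exome; only
#'   `het_hc` loci are tested.
#' @param m Size of the correction family; defaults to the number of
#'   loci passing the coverage gate in this call (must be >= 1 when
#'   supplied).
#' @param min_cov RNA coverage gate in reads (default 20).
#' @param band Drift-ratio band, biased strictly outside (default 0.2/0.8).
#' @param alpha Significance cutoff on the corrected P (default 0.05).
#' @param correction `"bonferroni"` or `"bh"`.
#' @param ps_mode `"vaf"` or `"diploid"`, see [adjust_ps()].
#' @return Per-locus tibble: locus columns, `rna_major_reads`,
#'   `rna_minor_reads`, `drift`, `p_s_used`, `p_raw`, `p_corrected`, `m`,
#'   `status` (`tested`/`low_coverage`), `biased`, `preferred_allele`
#'   (`"ref"`/`"alt"`, the majority RNA allele).
#' @export
test_ase_loci <- function(rna, exome_calls, m = NULL, min_cov = 20,
                          band = c(0.2, 0.8), alpha = 0.05,
                          correction = c("bonferroni", "bh"),
                          ps_mode = c("vaf", "diploid")) {
  correction <- match.arg(correction)
  ps_mode <- match.arg(ps_mode)
  if (!is.null(m) && (!is.numeric(m) || m < 1)) {
    abort("m must be >= 1 (the correction family cannot be empty)")
  }
  assert_columns(exome_calls, c(LOCUS_COLS, "vaf", "genotype"))
  het <- filter(exome_calls, .data$genotype == "het_hc") |>
    select(all_of(LOCUS_COLS), exome_vaf = "vaf")
  rna_at <- rna_allele_counts_at(het, rna)
  x <- inner_join(het, rna_at, by = LOCUS_COLS)

  depth <- x$ref_reads + x$alt_reads
  tested <- depth >= min_cov
  m_used <- m %||% sum(tested)

  minor <- pmin(x$ref_reads, x$alt_reads)
  rare_is_alt <- x$alt_reads <= x$ref_reads       # ties: alt by convention
  rare_vaf <- ifelse(rare_is_alt, x$exome_vaf, 1 - x$exome_vaf)
  p_s <- adjust_ps(rare_vaf, mode = ps_mode)
  drift <- drift_ratio(x$ref_reads, x$alt_reads)

  p_raw <- rep(NA_real_, nrow(x))
  if (any(tested)) {
    p_raw[tested] <- binom_cdf(minor[tested], depth[tested], p_s[tested])
  }
  p_corrected <- rep(NA_real_, nrow(x))
  if (any(tested)) {
    p_corrected[tested] <- switch(correction,
      bonferroni = pmin(1, m_used * p_raw[tested]),
      bh = p.adjust(p_raw[tested], method = "BH", n = max(m_used, sum(tested)))
    )
  }
  biased <- tested & in_drift_band(drift, band) &
    !is.na(p_corrected) & p_corrected < alpha

  tibble(
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
    exome_vaf = x$exome_vaf,
    rna_ref_reads = x$ref_reads, rna_alt_reads = x$alt_reads,
    rna_major_reads = depth - minor, rna_minor_reads = minor,
    drift = drift,
    p_s_used = ifelse(tested, p_s, NA_real_),
    p_raw = p_raw, p_corrected = p_corrected,
    m = m_used,
    status = ifelse(tested, "tested", "low_coverage"),
    biased = biased,
    preferred_allele = ifelse(x$alt_reads > x$ref_reads, "alt", "ref")
  )
}

#' Aggregate ASE locus results to genes
#'
#' Loci are assigned to genes whose exon model contains them; each gene
#' is then classified:
#'
#' * `ase` — at least one biased locus, and every tested locus is biased
#'   towards the same allele;
#' * `ambiguous` — biased and well-covered unbiased loci coexist, or
#'   biased loci disagree on the preferred allele (discordant loci along
#'   one transcript suggest local rearrangement or isoform effects);
#' * `not_ase` — tested loci, none biased;
#' * `low_coverage` — loci exist but none passed the RNA coverage gate;
#' * `no_genotype` — no heterozygous locus in the gene at all.
#'
#' The gene P-value is the most significant corrected P among biased
#' loci; the preferred allele is the majority RNA allele of those loci.
#'
#' @param locus_results Tibble from [test_ase_loci()].
#' @param genes Gene-model tibble.
#' @param exons_or_cds Interval set used for assignment (default exons).
#' @return Per-gene tibble: `gene_id`, `chrom`, `status`, `gene_p`,
#'   `preferred_allele`, `n_loci`, `n_tested`, `n_biased`, and a `loci`
#'   list-column (report-shaped, see [write_results()]).
#' @export
aggregate_ase_genes <- function(locus_results, genes,
                                exons_or_cds = c("exons", "cds")) {
  what <- match.arg(exons_or_cds)
  base <- tibble(gene_id = character(), chrom = character(),
                 status = character(), gene_p = numeric(),
                 preferred_allele = character(), n_loci = integer(),
                 n_tested = integer(), n_biased = integer(),
                 loci = list())
  if (nrow(genes) == 0) return(base)
  asn <- assign_loci_to_genes(locus_results, genes, what = what)
  lr <- mutate(locus_results, .row = dplyr::row_number())
  joined <- inner_join(asn, lr, by = c("locus_row" = ".row"),
                       relationship = "many-to-many")
  gene_chrom <- distinct(gene_intervals(genes, what), .data$gene_id,
                         .data$chrom)
  out <- if (nrow(joined) == 0) {
    base[0, setdiff(names(base), "chrom")]
  } else {
    joined |>
      group_by(.data$gene_id) |>
      group_map(function(g, key) {
        summarize_ase_gene(g, key$gene_id)
      }) |>
      bind_rows()
  }
  # genes with no assigned locus at all: no heterozygous genotype to test
  missing <- setdiff(genes$gene_id, out$gene_id)
  if (length(missing) > 0) {
    out <- bind_rows(out, tibble(
      gene_id = missing, status = "no_genotype", gene_p = NA_real_,
      preferred_allele = NA_character_, n_loci = 0L, n_tested = 0L,
      n_biased = 0L, loci = rep(list(empty_gene_loci()), length(missing))
    ))
  }
  out |>
    left_join(gene_chrom, by = "gene_id") |>
    select("gene_id", "chrom", everything()) |>
    arrange(.data$chrom, .data$gene_id)
}

summarize_ase_gene <- function(g, gene_id) {
  tested <- g[g$status == "tested", , drop = FALSE]
  biased <- tested[tested$biased, , drop = FALSE]
  status <- if (nrow(g) == 0) {
    "no_genotype"
  } else if (nrow(tested) == 0) {
    "low_coverage"
  } else if (nrow(biased) == 0) {
    "not_ase"
  } else if (nrow(biased) == nrow(tested)) {
    # every well-covered locus is biased; ref/alt orientation may differ
    # between loci of one gene (phase is unknown), so direction is
    # compared across samples per locus, not here
    "ase"
  } else {
    "ambiguous"
  }
  pref <- if (nrow(biased) > 0) {
    names(sort(table(biased$preferred_allele), decreasing = TRUE))[1]
  } else NA_character_
  tibble(
    gene_id = gene_id,
    status = status,
    gene_p = if (nrow(biased) > 0) min(biased$p_corrected) else NA_real_,
    preferred_allele = pref,
    n_loci = nrow(g),
    n_tested = nrow(tested),
    n_biased = nrow(biased),
    loci = list(tibble(
      pos = g$pos, ref = g$ref, alt = g$alt,
      major_reads = g$rna_major_reads, minor_reads = g$rna_minor_reads,
      drift = g$drift, p_value = g$p_corrected, status = g$status,
      biased = g$biased, preferred_allele = g$preferred_allele,
      variant_id = NA_character_
    ))
  )
}

empty_gene_loci <- function() {
  tibble(pos = numeric(), ref = character(), alt = character(),
         major_reads = numeric(), minor_reads = numeric(),
         drift = numeric(), p_value = numeric(), status = character(),
         biased = logical(), preferred_allele = character(),
         variant_id = character())
}

#' Compare ASE gene calls between two samples
#'
#' Classifies every gene that is ASE in at least one sample:
#' `shared_same_allele` / `shared_opposite_allele` when both samples call
#' ASE, `a_only` / `b_only` when the other sample was tested and
#' balanced, `undetermined_low_expression` when the other sample lacked
#' RNA coverage (or expression), `undetermined_no_genotype` when the
#' other sample has no heterozygous genotype at the gene.
#'
#' For shared ASE genes the preferred alleles are compared *per locus*
#' over the loci biased in both samples (the ref/alt orientation of
#' different SNVs within one gene is not comparable without phasing);
#' they agree when the majority of shared biased loci prefer the same
#' base.  Without any shared biased locus the gene-level majority allele
#' is used as a fallback.
#'
#' @param a,b Per-gene tibbles from [aggregate_ase_genes()] for the two
#'   samples (gene ids comparable).
#' @return Tibble with `gene_id`, `class`, `preferred_allele_a`,
#'   `preferred_allele_b`.
#' @export
compare_ase_across_samples <- function(a, b) {
  assert_columns(a, c("gene_id", "status", "preferred_allele"))
  assert_columns(b, c("gene_id", "status", "preferred_allele"))
  ab <- full_join(
    select(a, "gene_id", status_a = "status", pref_a = "preferred_allele",
           any_of(c(loci_a = "loci"))),
    select(b, "gene_id", status_b = "status", pref_b = "preferred_allele",
           any_of(c(loci_b = "loci"))),
    by = "gene_id"
  ) |>
    filter(.data$status_a == "ase" | .data$status_b == "ase")
  classify_vs <- function(status_other, same, this_only) {
    dplyr::case_when(
      status_other == "ase" & same ~ "shared_same_allele",
      status_other == "ase" & !same ~ "shared_opposite_allele",
      status_other %in% c("not_ase", "ambiguous") ~ this_only,
      status_other == "low_coverage" ~ "undetermined_low_expression",
      is.na(status_other) | status_other == "no_genotype" ~
        "undetermined_no_genotype",
      .default = "undetermined_low_expression"
    )
  }
  same <- map_lgl(seq_len(nrow(ab)), function(i) {
    la <- if ("loci_a" %in% names(ab)) ab$loci_a[[i]] else NULL
    lb <- if ("loci_b" %in% names(ab)) ab$loci_b[[i]] else NULL
    if (!is.null(la) && !is.null(lb)) {
      shared <- inner_join(
        filter(la, .data$biased)[c("pos", "preferred_allele")],
        filter(lb, .data$biased)[c("pos", "preferred_allele")],
        by = "pos", suffix = c("_a", "_b")
      )
      if (nrow(shared) > 0) {
        return(mean(shared$preferred_allele_a ==
                      shared$preferred_allele_b) >= 0.5)
      }
    }
    !is.na(ab$pref_a[i]) && !is.na(ab$pref_b[i]) &&
      ab$pref_a[i] == ab$pref_b[i]
  })
  cls <- ifelse(
    !is.na(ab$status_a) & ab$status_a == "ase",
    classify_vs(ab$status_b, same, "a_only"),
    classify_vs(ab$status_a, same, "b_only")
  )
  tibble(gene_id = ab$gene_id, class = cls,
         preferred_allele_a = ab$pref_a, preferred_allele_b = ab$pref_b) |>
    arrange(.data$gene_id)
}
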