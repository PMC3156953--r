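#' One-sided binomial homozygosity test
#'
#' Tests whether the allele counts at a locus are consistent with
#' homozygosity: under the heterozygous null the reads fall on the two
#' alleles like fair coin flips, so the minor-allele count `x` out of `n`
#' total reads has one-sided cumulative probability `B(x; n, 0.5)`.  The
#' locus is called homozygous when `n >= min_reads` and the P-value is
#' below `alpha`.  With the defaults, ten concordant reads are the
#' minimal passing configuration (`0.5^10 = 9.8e-4 < 0.001`) while nine
#' are not.  In the generalized form a few minor reads are tolerated as
#' long as the tail probability stays under `alpha`; `strict = TRUE`
#' additionally requires zero minor reads.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors (DNA counts).
#' @param alpha Significance level (default 0.001).
#' @param min_reads Minimum total reads to call (default 10).
#' @param strict Require the minor allele to be entirely absent.
#' @return Tibble with `p_value` and `is_homozygous`.  Zero-depth loci
#'   report `p_value = 1` and are never called.
#' @export
test_homozygosity <- function(ref_reads, alt_reads, alpha = 0.001,
                              min_reads = 10, strict = FALSE) {
  n <- ref_reads + alt_reads
  minor <- pmin(ref_reads, alt_reads)  # ties: minor = alt, same count
  p <- ifelse(n == 0, 1, binom_cdf(pmin(minor, n), pmax(n, 1), 0.5))
  hom <- n >= min_reads & p < alpha
  if (strict) hom <- hom & minor == 0
  tibble(p_value = p, is_homozygous = hom)
}

#' Call LOH loci from a normal callset and tumor allele counts
#'
#' A loss-of-heterozygosity event requires a high-confidence heterozygous
#' locus in the normal sample (VAF between 20% and 80%) that is
#' homozygous in the tumor by [test_homozygosity()] (P < `alpha` with at
#' least `min_reads` tumor reads).  Normal het_hc loci without tumor
#' coverage are skipped and tallied in the `"n_no_coverage"` attribute.
#'
#' @param normal SNV-call tibble for the normal sample (from
#'   [call_hc_snvs()]); only `het_hc` rows are candidates.
#' @param tumor Allele-count tibble for the tumor (DNA rows).
#' @inheritParams test_homozygosity
#' @return Tibble of LOH events: locus columns, `gene_id` (NA until
#'   aggregation), `normal_vaf`, `tumor_depth`, `tumor_minor_reads`,
#'   `p_value`, `retained_allele` (the tumor majority allele, `"ref"` or
#'   `"alt"`).  Attributes: `n_candidates`, `n_no_coverage`,
#'   `n_not_homozygous`.
#' @export
call_loh_loci <- function(normal, tumor, alpha = 0.001, min_reads = 10,
                          strict = FALSE) {
  assert_columns(normal, c(LOCUS_COLS, "vaf", "genotype"))
  assert_columns(tumor, c(LOCUS_COLS, "assay", "ref_reads", "alt_reads"))
  check_chrom_dialect(c(normal$chrom, tumor$chrom), "normal+tumor")
  cand <- filter(normal, .data$genotype == "het_hc")
  tum <- tumor |>
    filter(.data$assay == "DNA") |>
    select(all_of(LOCUS_COLS),
           tumor_ref = "ref_reads", tumor_alt = "alt_reads")
  joined <- left_join(cand, tum, by = LOCUS_COLS)
  covered <- !is.na(joined$tumor_ref)
  x <- joined[covered, , drop = FALSE]
  ht <- test_homozygosity(x$tumor_ref, x$tumor_alt,
                          alpha = alpha, min_reads = min_reads,
                          strict = strict)
  out <- tibble(
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
    gene_id = NA_character_,
    normal_vaf = x$vaf,
    tumor_depth = x$tumor_ref + x$tumor_alt,
    tumor_minor_reads = pmin(x$tumor_ref, x$tumor_alt),
    p_value = ht$p_value,
    retained_allele = ifelse(x$tumor_alt > x$tumor_ref, "alt", "ref")
  )[ht$is_homozygous, , drop = FALSE]
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "n_no_coverage") <- sum(!covered)
  attr(out, "n_not_homozygous") <- sum(!ht$is_homozygous)
  out
}

#' Aggregate LOH events to genes
#'
#' Each event is assigned to every gene whose CDS (or exon model, with
#' `cds_only = FALSE`) contains its position; a locus inside two
#' overlapping genes supports both.  Events outside any gene are retained
#' as single-event rows with `gene_id` NA.
#'
#' @param events LOH event tibble from [call_loh_loci()].
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param cds_only Restrict assignment to coding sequence (default TRUE).
#' @return Per-gene tibble: `gene_id`, `chrom`, `n_snvs`, `min_p`, and a
#'   `loci` list-column of the supporting events (with `major_reads` /
#'   `minor_reads` tumor counts for reporting).
#' @export
aggregate_loh_genes <- function(events, genes, cds_only = TRUE) {
  asn <- assign_loci_to_genes(events, genes,
                              what = if (cds_only) "cds" else "exons")
  ev <- mutate(events, .row = dplyr::row_number())
  assigned <- inner_join(ev, asn, by = c(".row" = "locus_row"),
                         relationship = "many-to-many") |>
    mutate(gene_id = .data$gene_id.y) |>
    select(-"gene_id.x", -"gene_id.y")
  unassigned <- filter(ev, !(.data$.row %in% asn$locus_row))
  pack <- function(x) {
    x |>
      group_by(.data$gene_id, .data$chrom) |>
      summarise(
        n_snvs = dplyr::n(),
        min_p = min(.data$p_value),
        loci = list({
          g <- dplyr::pick(dplyr::everything())
          tibble(
            pos = g$pos, ref = g$ref, alt = g$alt,
            major_reads = g$tumor_depth - g$tumor_minor_reads,
            minor_reads = g$tumor_minor_reads,
            p_value = g$p_value,
            retained_allele = g$retained_allele,
            normal_vaf = g$normal_vaf,
            variant_id = NA_character_
          )
        }),
        .groups = "drop"
      )
  }
  out <- pack(assigned)
  if (nrow(unassigned) > 0) {
    # one row per orphan event, gene_id empty
    orphans <- map(seq_len(nrow(unassigned)), function(i) {
      pack(mutate(unassigned[i, , drop = FALSE], gene_id = NA_character_))
    }) |> bind_rows()
    out <- bind_rows(out, orphans)
  }
  arrange(out, is.na(.data$gene_id), .data$chrom, map_dbl(.data$loci, ~ min(.x$pos)))
}

#' Apply the isolated-gene plausibility filters to LOH genes
#'
#' LOH genes usually cluster into large blocks; a lone LOH gene far from
#' any other is more likely a calling artifact, so isolated genes (no
#' other LOH gene within `isolation_bp` on the same chromosome; 1 Mb by
#' default) must additionally satisfy three criteria: (a) every
#' supporting tumor SNV is a known variant in the catalog, (b) no
#' heterozygous high-confidence tumor locus lies within `window_bp`
#' (25 kb) of any supporting SNV — a nearby heterozygote contradicts a
#' real deletion —, and (c) homozygosity is corroborated by RNA at one or
#' more supporting loci (RNA depth at least `min_rna_depth` with zero
#' minor-allele reads).  Clustered genes pass unfiltered.
#'
#' @param gene_summary Per-gene tibble from [aggregate_loh_genes()].
#' @param tumor_calls Tumor SNV-call tibble (for the het-conflict window).
#' @param rna_counts RNA allele-count tibble for the tumor sample.
#' @param catalog Known-variant catalog tibble (or NULL).
#' @param window_bp Het-conflict window, bp on either side (default 25000).
#' @param isolation_bp Clustering distance defining "isolated" (default 1e6).
#' @param min_rna_depth Minimum RNA depth for criterion (c) (default 10).
#' @return `gene_summary` with logical `isolated` and `accepted` columns
#'   and a `reject_reason` string (`""` when accepted): one or more of
#'   `not-known-variant`, `conflict-within-window`, `no-rna-support`.
#' @export
filter_isolated_loh <- function(gene_summary, tumor_calls = NULL,
                                rna_counts = NULL, catalog = NULL,
                                window_bp = 25000, isolation_bp = 1e6,
                                min_rna_depth = 10) {
  gs <- gene_summary
  if (nrow(gs) == 0) {
    return(mutate(gs, isolated = logical(), accepted = logical(),
                  reject_reason = character()))
  }
  pos_list <- map(gs$loci, "pos")
  gs$isolated <- map_lgl(seq_len(nrow(gs)), function(i) {
    others <- which(gs$chrom == gs$chrom[i] & seq_len(nrow(gs)) != i &
                      !is.na(gs$gene_id))
    if (is.na(gs$gene_id[i])) others <- setdiff(others, i)
    if (length(others) == 0) return(TRUE)
    d <- min(vapply(others, function(j) {
      min(abs(outer(pos_list[[i]], pos_list[[j]], "-")))
    }, numeric(1)))
    d > isolation_bp
  })

  cat_key <- if (!is.null(catalog) && nrow(catalog) > 0) {
    paste(catalog$chrom, catalog$pos, catalog$allele)
  } else character()
  het <- if (!is.null(tumor_calls)) {
    filter(tumor_calls, .data$genotype == "het_hc")
  } else tibble(chrom = character(), pos = numeric())
  rna <- if (!is.null(rna_counts)) {
    filter(rna_counts, .data$assay == "RNA")
  } else NULL

  res <- map(seq_len(nrow(gs)), function(i) {
    if (!gs$isolated[i]) return(list(accepted = TRUE, reason = ""))
    loci <- gs$loci[[i]]
    reasons <- character()
    known <- paste(gs$chrom[i], loci$pos, loci$alt) %in% cat_key
    if (!all(known)) reasons <- c(reasons, "not-known-variant")
    near <- het$chrom == gs$chrom[i] &
      vapply(het$pos, function(p) any(abs(p - loci$pos) <= window_bp &
                                        !(p %in% loci$pos)), logical(1))
    if (any(near)) reasons <- c(reasons, "conflict-within-window")
    rna_ok <- FALSE
    if (!is.null(rna)) {
      at <- inner_join(
        tibble(chrom = gs$chrom[i], pos = loci$pos),
        rna, by = c("chrom", "pos")
      )
      if (nrow(at) > 0) {
        depth <- at$ref_reads + at$alt_reads
        minor <- pmin(at$ref_reads, at$alt_reads)
        rna_ok <- any(depth >= min_rna_depth & minor == 0)
      }
    }
    if (!rna_ok) reasons <- c(reasons, "no-rna-support")
    list(accepted = length(reasons) == 0,
         reason = paste(reasons, collapse = ";"))
  })
  gs$accepted <- map_lgl(res, "accepted")
  gs$reject_reason <- map_chr(res, "reason")
  gs
}

#' Paired variant-allele-frequency table for a tumor/normal pair
#'
#' One row per locus with DNA coverage in both samples, giving the normal
#' and tumor VAF — the raw material of the classic per-chromosome LOH
#' scatter (normal VAF near 0.5, tumor VAF collapsing to 0 or 1 inside
#' LOH regions).
#'
#' @param normal,tumor Allele-count tibbles (DNA rows used).
#' @param chrom Optional chromosome to restrict to.
#' @return Tibble with `chrom`, `pos`, `normal_vaf`, `tumor_vaf`.
#' @export
paired_vaf_table <- function(normal, tumor, chrom = NULL) {
  prep <- function(x) {
    x <- filter(x, .data$assay == "DNA",
                .data$ref_reads + .data$alt_reads > 0)
    transmute(x, .data$chrom, .data$pos, .data$ref, .data$alt,
              vaf = .data$alt_reads / (.data$ref_reads + .data$alt_reads))
  }
  out <- inner_join(
    rename(prep(normal), normal_vaf = "vaf"),
    rename(prep(tumor), tumor_vaf = "vaf"),
    by = LOCUS_COLS
  ) |>
    select("chrom", "pos", "normal_vaf", "tumor_vaf") |>
    arrange(.data$chrom, .data$pos)
  if (!is.null(chrom)) out <- out[out$chrom == chrom, , drop = FALSE]
  out
}
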