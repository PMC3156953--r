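#' Reads per kilobase of exon model per million mapped reads
#'
#' `rpkm = gene_reads / (exon_length_bp / 1000) / (total_mapped_reads / 1e6)`.
#' Linear in `gene_reads`, inversely linear in `total_mapped_reads`.
#'
#' @param gene_reads Reads assigned to the gene (vectorized).
#' @param exon_length_bp Total exon-model length in bp (> 0).
#' @param total_mapped_reads Library size in mapped reads (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(gene_reads, exon_length_bp, total_mapped_reads) {
  if (any(exon_length_bp <= 0)) abort("exon_length_bp must be > 0")
  if (any(total_mapped_reads <= 0)) abort("total_mapped_reads must be > 0")
  gene_reads / (exon_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Mean per-base coverage over the exon model and the expressed gate
#'
#' `coverage = gene_reads * read_length_bp / exon_length_bp`; a gene
#' counts as expressed at 1x mean coverage or more (boundary inclusive).
#' The read length is a configuration input, not inferred from the data.
#'
#' @param gene_reads Reads assigned to the gene (vectorized).
#' @param read_length_bp Read length in bp.
#' @param exon_length_bp Total exon-model length in bp (> 0).
#' @return Tibble with `coverage` (x) and logical `expressed`.
#' @export
mean_coverage <- function(gene_reads, read_length_bp, exon_length_bp) {
  if (any(exon_length_bp <= 0)) abort("exon_length_bp must be > 0")
  cov <- gene_reads * read_length_bp / exon_length_bp
  tibble(coverage = cov, expressed = cov >= 1.0)
}

#' Per-gene expression table
#'
#' Combines [rpkm()] and [mean_coverage()] into the per-gene expression
#' report used to gate downstream analyses.
#'
#' @param gene_reads Tibble with `gene_id`, `reads`.
#' @param genes Gene-model tibble (for `exon_length_bp`).
#' @param read_length_bp Read length in bp.
#' @param total_mapped_reads Library size; defaults to `sum(reads)`.
#' @return Tibble: `gene_id`, `reads`, `exon_length_bp`, `coverage`,
#'   `rpkm`, `expressed`.
#' @export
quantify_expression <- function(gene_reads, genes, read_length_bp,
                                total_mapped_reads = sum(gene_reads$reads)) {
  assert_columns(gene_reads, c("gene_id", "reads"))
  x <- inner_join(gene_reads,
                  select(genes, "gene_id", "exon_length_bp"),
                  by = "gene_id")
  mc <- mean_coverage(x$reads, read_length_bp, x$exon_length_bp)
  mutate(x,
         coverage = mc$coverage,
         rpkm = rpkm(x$reads, x$exon_length_bp, total_mapped_reads),
         expressed = mc$expressed)
}

#' Call SNVs from transcriptome allele counts
#'
#' The transcriptome SNV filter: the variant base itself must have mean
#' quality at least `min_central_q` (default 30) and the surrounding
#' bases at least `min_flank_q` (default 15); the minor allele must then
#' be supported by at least `min_minor_reads` reads *or* reach a
#' minor-allele frequency of at least `min_minor_vaf` (defaults 4 reads /
#' 30%).  Loci with missing quality fields are skipped with a warning.
#'
#' @param counts Allele-count tibble (RNA rows with quality fields).
#' @param min_central_q,min_flank_q Quality thresholds.
#' @param min_minor_reads,min_minor_vaf The read-count / frequency
#'   disjunction for the minor allele.
#' @return Tibble of called RNA variant loci with `depth`, `minor_reads`,
#'   `minor_vaf`.
#' @export
call_rna_snvs <- function(counts, min_central_q = 30, min_flank_q = 15,
                          min_minor_reads = 4, min_minor_vaf = 0.30) {
  assert_columns(counts, c(LOCUS_COLS, "assay", "ref_reads", "alt_reads",
                           "central_qual", "flank_qual"))
  x <- filter(counts, .data$assay == "RNA")
  noq <- is.na(x$central_qual) | is.na(x$flank_qual)
  if (any(noq)) {
    warn(paste0(sum(noq), " RNA locus/loci skipped: missing quality fields"))
    x <- x[!noq, , drop = FALSE]
  }
  depth <- x$ref_reads + x$alt_reads
  x <- x[depth > 0, , drop = FALSE]
  depth <- depth[depth > 0]
  minor <- pmin(x$ref_reads, x$alt_reads)
  minor_vaf <- minor / depth
  keep <- x$central_qual >= min_central_q &
    x$flank_qual >= min_flank_q &
    (minor >= min_minor_reads | minor_vaf >= min_minor_vaf)
  tibble(
    chrom = x$chrom[keep], pos = x$pos[keep],
    ref = x$ref[keep], alt = x$alt[keep],
    sample = x$sample[keep],
    depth = depth[keep],
    ref_reads = x$ref_reads[keep], alt_reads = x$alt_reads[keep],
    minor_reads = minor[keep], minor_vaf = minor_vaf[keep]
  )
}

#' RNA allele counts at requested loci
#'
#' Restricts an RNA allele-count table to a set of loci (typically the
#' exome heterozygotes); loci without RNA coverage are reported with zero
#' counts rather than dropped, so the coverage gate downstream sees them.
#' Duplicate RNA rows for one locus violate the input contract and error.
#'
#' @param loci Tibble with the locus columns (`chrom`, `pos`, `ref`, `alt`).
#' @param rna Allele-count tibble (RNA rows used).
#' @return One row per requested locus: locus columns, `ref_reads`,
#'   `alt_reads` (0/0 when uncovered).
#' @export
rna_allele_counts_at <- function(loci, rna) {
  assert_columns(loci, LOCUS_COLS)
  x <- filter(rna, .data$assay == "RNA") |>
    select(all_of(LOCUS_COLS), "ref_reads", "alt_reads")
  dup <- duplicated(x[LOCUS_COLS])
  if (any(dup)) {
    abort(paste0("duplicate locus in RNA counts: ",
                 x$chrom[dup][1], ":", x$pos[dup][1]))
  }
  left_join(distinct(loci[LOCUS_COLS]), x, by = LOCUS_COLS) |>
    mutate(ref_reads = tidyr::replace_na(.data$ref_reads, 0),
           alt_reads = tidyr::replace_na(.data$alt_reads, 0))
}
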