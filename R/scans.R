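#' Scan a tumor/normal pair for loss of heterozygosity
#'
#' End-to-end LOH wrapper: genotypes the normal DNA counts with
#' [call_hc_snvs()], tests tumor homozygosity at every normal
#' high-confidence heterozygote ([call_loh_loci()]), aggregates events to
#' genes when models are supplied ([aggregate_loh_genes()]), applies the
#' isolated-gene plausibility filters when a catalog and RNA counts are
#' available ([filter_isolated_loh()]), and keeps the paired-VAF table
#' for plotting.
#'
#' @param normal,tumor Allele-count tibbles (DNA) for the two samples.
#' @param genes Optional gene-model tibble.
#' @param catalog Optional known-variant catalog.
#' @param rna Optional tumor RNA allele counts (isolated-gene support).
#' @param alpha,min_reads,strict Homozygosity-test parameters.
#' @param window_bp,isolation_bp,min_rna_depth Isolated-gene filter
#'   parameters.
#' @param ... Passed to [call_hc_snvs()] for the normal genotyping.
#' @return An object of class `loh_scan` with elements `events`, `genes`
#'   (NULL without models), `paired_vaf`, `normal_calls`, `tumor_calls`,
#'   `counts`, `params`.  Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
loh_scan <- function(normal, tumor, genes = NULL, catalog = NULL,
                     rna = NULL, alpha = 0.001, min_reads = 10,
                     strict = FALSE, window_bp = 25000,
                     isolation_bp = 1e6, min_rna_depth = 10, ...) {
  normal_calls <- call_hc_snvs(normal, ...)
  tumor_calls <- call_hc_snvs(tumor, ...)
  events <- call_loh_loci(normal_calls, tumor, alpha = alpha,
                          min_reads = min_reads, strict = strict)
  gene_summary <- NULL
  if (!is.null(genes)) {
    gene_summary <- aggregate_loh_genes(events, genes) |>
      filter_isolated_loh(tumor_calls = tumor_calls, rna_counts = rna,
                          catalog = catalog, window_bp = window_bp,
                          isolation_bp = isolation_bp,
                          min_rna_depth = min_rna_depth)
    # propagate gene assignment back onto events (first gene wins for the
    # flat event table; the gene summary keeps every assignment)
    asn <- assign_loci_to_genes(events, genes, what = "cds")
    if (nrow(asn) > 0) {
      first <- asn[!duplicated(asn$locus_row), , drop = FALSE]
      events$gene_id[first$locus_row] <- first$gene_id
    }
  }
  structure(
    list(
      events = events,
      genes = gene_summary,
      paired_vaf = paired_vaf_table(normal, tumor),
      normal_calls = normal_calls,
      tumor_calls = tumor_calls,
      counts = list(
        n_candidates = attr(events, "n_candidates"),
        n_no_coverage = attr(events, "n_no_coverage"),
        n_loh_loci = nrow(events),
        n_loh_genes = if (is.null(gene_summary)) NA_integer_ else
          sum(!is.na(gene_summary$gene_id) & gene_summary$accepted)
      ),
      params = list(alpha = alpha, min_reads = min_reads, strict = strict,
                    window_bp = window_bp, isolation_bp = isolation_bp,
                    min_rna_depth = min_rna_depth)
    ),
    class = "loh_scan"
  )
}

#' @export
print.loh_scan <- function(x, ...) {
  cat("<loh_scan>\n")
  cat("  candidate het loci :", x$counts$n_candidates, "\n")
  cat("  no tumor coverage  :", x$counts$n_no_coverage, "\n")
  cat("  LOH loci           :", x$counts$n_loh_loci, "\n")
  if (!is.na(x$counts$n_loh_genes %||% NA)) {
    cat("  LOH genes (kept)   :", x$counts$n_loh_genes, "\n")
  }
  invisible(x)
}

#' @rdname loh_scan
#' @param x A `loh_scan` object.
#' @param level `"gene"` (default, requires gene models) or `"locus"`.
#' @exportS3Method generics::tidy
tidy.loh_scan <- function(x, level = c("gene", "locus"), ...) {
  level <- match.arg(level)
  if (level == "locus" || is.null(x$genes)) return(as_tibble(x$events))
  as_tibble(x$genes)
}

#' @rdname loh_scan
#' @exportS3Method generics::glance
glance.loh_scan <- function(x, ...) {
  tibble(
    n_candidates = x$counts$n_candidates,
    n_no_coverage = x$counts$n_no_coverage,
    n_loh_loci = x$counts$n_loh_loci,
    n_loh_genes = x$counts$n_loh_genes,
    alpha = x$params$alpha,
    min_reads = x$params$min_reads
  )
}

#' Paired-VAF scatter of a tumor/normal pair
#'
#' One panel per chromosome; each point is a locus with DNA coverage in
#' both samples, LOH loci highlighted.  This is the classic view in
#' which LOH blocks appear as runs of loci with mid-range normal VAF but
#' tumor VAF collapsed towards 0 or 1.
#'
#' @param paired_vaf Tibble from [paired_vaf_table()].
#' @param events Optional LOH event tibble used for highlighting.
#' @return A ggplot object.
#' @export
plot_paired_vaf <- function(paired_vaf, events = NULL) {
  pv <- paired_vaf
  pv$loh <- FALSE
  if (!is.null(events) && nrow(events) > 0) {
    key <- paste(events$chrom, events$pos)
    pv$loh <- paste(pv$chrom, pv$pos) %in% key
  }
  ggplot2::ggplot(pv, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$normal_vaf),
                        colour = "grey55", size = 0.4, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$tumor_vaf,
                                     colour = .data$loh),
                        size = 0.4, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "tumor", `TRUE` = "tumor (LOH)"),
      name = NULL
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "variant allele frequency") +
    ggplot2::theme_minimal()
}

#' @rdname loh_scan
#' @param object A `loh_scan` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.loh_scan <- function(object, ...) {
  plot_paired_vaf(object$paired_vaf, object$events)
}

#' Scan one sample for allele-specific expression
#'
#' End-to-end ASE wrapper: genotypes the DNA counts (unless ready-made
#' calls are supplied), tests every high-confidence heterozygote with
#' RNA coverage ([test_ase_loci()]) and aggregates loci to genes
#' ([aggregate_ase_genes()]).  The correction family `m` defaults to the
#' number of loci passing the RNA coverage gate in this run.
#'
#' @param exome DNA allele-count tibble, or an SNV-call tibble (detected
#'   by the presence of a `genotype` column).
#' @param rna RNA allele-count tibble for the same sample.
#' @param genes Optional gene-model tibble.
#' @inheritParams test_ase_loci
#' @param ... Passed to [call_hc_snvs()] when `exome` is a count table.
#' @return An object of class `ase_scan` with elements `loci`, `genes`
#'   (NULL without models), `m`, `exome_calls`, `counts`, `params`.
#'   Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
ase_scan <- function(exome, rna, genes = NULL, m = NULL, min_cov = 20,
                     band = c(0.2, 0.8), alpha = 0.05,
                     correction = "bonferroni", ps_mode = "vaf", ...) {
  exome_calls <- if ("genotype" %in% names(exome)) exome
                 else call_hc_snvs(exome, ...)
  loci <- test_ase_loci(rna, exome_calls, m = m, min_cov = min_cov,
                        band = band, alpha = alpha,
                        correction = correction, ps_mode = ps_mode)
  gene_summary <- if (!is.null(genes)) aggregate_ase_genes(loci, genes)
  structure(
    list(
      loci = loci,
      genes = gene_summary,
      m = if (nrow(loci) > 0) loci$m[1] else (m %||% 0),
      exome_calls = exome_calls,
      counts = list(
        n_het = sum(exome_calls$genotype == "het_hc"),
        n_tested = sum(loci$status == "tested"),
        n_low_coverage = sum(loci$status == "low_coverage"),
        n_biased_loci = sum(loci$biased),
        n_ase_genes = if (is.null(gene_summary)) NA_integer_ else
          sum(gene_summary$status == "ase")
      ),
      params = list(min_cov = min_cov, band = band, alpha = alpha,
                    correction = correction, ps_mode = ps_mode)
    ),
    class = "ase_scan"
  )
}

#' @export
print.ase_scan <- function(x, ...) {
  cat("<ase_scan>\n")
  cat("  het_hc exome loci  :", x$counts$n_het, "\n")
  cat("  tested (>=", x$params$min_cov, "RNA reads):",
      x$counts$n_tested, " (m =", x$m, ")\n")
  cat("  biased loci        :", x$counts$n_biased_loci, "\n")
  if (!is.na(x$counts$n_ase_genes %||% NA)) {
    cat("  ASE genes          :", x$counts$n_ase_genes, "\n")
  }
  invisible(x)
}

#' @rdname ase_scan
#' @param x An `ase_scan` object.
#' @param level `"gene"` (default, requires gene models) or `"locus"`.
#' @exportS3Method generics::tidy
tidy.ase_scan <- function(x, level = c("gene", "locus"), ...) {
  level <- match.arg(level)
  if (level == "locus" || is.null(x$genes)) return(as_tibble(x$loci))
  as_tibble(x$genes)
}

#' @rdname ase_scan
#' @exportS3Method generics::glance
glance.ase_scan <- function(x, ...) {
  tibble(
    n_het = x$counts$n_het,
    n_tested = x$counts$n_tested,
    n_low_coverage = x$counts$n_low_coverage,
    n_biased_loci = x$counts$n_biased_loci,
    n_ase_genes = x$counts$n_ase_genes,
    m = x$m,
    alpha = x$params$alpha,
    min_cov = x$params$min_cov
  )
}

#' Drift-versus-significance plot for ASE locus results
#'
#' Allele drift ratio against -log10 corrected P for every tested locus,
#' with the biased band marked; biased loci stand out in the two outer
#' strips.
#'
#' @param locus_results Tibble from [test_ase_loci()].
#' @param band The drift band to mark.
#' @return A ggplot object.
#' @export
plot_ase_drift <- function(locus_results, band = c(0.2, 0.8)) {
  x <- filter(locus_results, .data$status == "tested")
  x$mlogp <- -log10(pmax(x$p_corrected, 1e-300))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$drift, y = .data$mlogp,
                                  colour = .data$biased)) +
    ggplot2::geom_vline(xintercept = band, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"), name = "biased"
    ) +
    ggplot2::labs(x = "allele drift ratio (alt RNA fraction)",
                  y = expression(-log[10] ~ "corrected P")) +
    ggplot2::theme_minimal()
}

#' @rdname ase_scan
#' @param object An `ase_scan` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ase_scan <- function(object, ...) {
  plot_ase_drift(object$loci, object$params$band)
}
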