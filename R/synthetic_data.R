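#' Configuration for the paired tumor/normal simulator
#'
#' The generator emulates the downstream products of a paired
#' tumor/normal exome + transcriptome experiment on a copy-number-altered
#' tumor: DNA allele counts at germline heterozygous loci under a
#' pseudo-tetraploid landscape with LOH blocks, and RNA allele counts
#' with per-gene expression levels and allele drift.  Defaults describe a
#' desk-scale genome — two 10-Mb chromosomes, 200 genes, 3,000
#' heterozygous loci, one LOH block spanning 15% of chromosome 1 — rich
#' enough to exercise every filter while running in seconds.
#'
#' @param seed Integer seed; all three simulators derive from it.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_genes Number of genes, split across chromosomes by length.
#' @param n_het_loci Total germline heterozygous loci (genic + intergenic).
#' @param mean_loci_per_gene Mean CDS heterozygous loci per gene
#'   (1 + Poisson).
#' @param baseline_copies Allelic copies outside altered segments
#'   (default `c(2, 2)`, the pseudo-tetraploid baseline).
#' @param loh_segments List of LOH/copy-number segments, each a list with
#'   `chrom`, `frac` (fraction of the chromosome) and `copies`
#'   (length-2, retained/lost allelic copies).  The default is one full
#'   LOH block `c(2, 0)` over 15% of chromosome 1.
#' @param ase_fraction Fraction of expressed non-LOH genes under ASE.
#' @param ase_drift_range Range of the preferred-allele RNA fraction for
#'   ASE genes (default `c(0.85, 1)`).
#' @param exome_depth_mean Mean DNA depth per locus (Poisson); default
#'   19.4x, a typical mean target coverage for captured exomes.
#' @param rna_coverage_mean Mean RNA coverage of expressed genes
#'   (log-normal across genes); default 120x.
#' @param rna_coverage_sdlog Log-scale SD of the expression distribution.
#' @param expressed_fraction Fraction of genes expressed at all.
#' @param read_length_bp RNA read length used for coverage bookkeeping.
#' @param error_rate Per-read allele-flip error rate (default 0.005).
#' @param known_fraction Fraction of loci present in the known-variant
#'   catalog (with synthetic ids).
#' @param dirty_quality If TRUE, a subset of RNA loci gets sub-threshold
#'   quality values to exercise the RNA SNV filters.
#' @param x_chrom Optional chromosome name to treat as an X-like
#'   chromosome: all its expressed genes receive whole-chromosome drift.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       n_genes = 200,
                       n_het_loci = 3000,
                       mean_loci_per_gene = 2,
                       baseline_copies = c(2, 2),
                       loh_segments = list(
                         list(chrom = "chr1", frac = 0.15, copies = c(2, 0))
                       ),
                       ase_fraction = 0.05,
                       ase_drift_range = c(0.85, 1.0),
                       exome_depth_mean = 19.4,
                       rna_coverage_mean = 120,
                       rna_coverage_sdlog = 1.0,
                       expressed_fraction = 0.85,
                       read_length_bp = 75,
                       error_rate = 0.005,
                       known_fraction = 0.9,
                       dirty_quality = FALSE,
                       x_chrom = NULL) {
  cfg <- list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    n_genes = n_genes, n_het_loci = n_het_loci,
    mean_loci_per_gene = mean_loci_per_gene,
    baseline_copies = baseline_copies, loh_segments = loh_segments,
    ase_fraction = ase_fraction, ase_drift_range = ase_drift_range,
    exome_depth_mean = exome_depth_mean,
    rna_coverage_mean = rna_coverage_mean,
    rna_coverage_sdlog = rna_coverage_sdlog,
    expressed_fraction = expressed_fraction,
    read_length_bp = read_length_bp, error_rate = error_rate,
    known_fraction = known_fraction, dirty_quality = dirty_quality,
    x_chrom = x_chrom
  )
  stopifnot(
    all(cfg$chrom_lengths > 0), cfg$n_genes > 0, cfg$n_het_loci > 0,
    cfg$ase_fraction >= 0, cfg$ase_fraction <= 1,
    cfg$exome_depth_mean > 0, cfg$error_rate >= 0, cfg$error_rate < 0.5,
    cfg$expressed_fraction >= 0, cfg$expressed_fraction <= 1,
    length(cfg$baseline_copies) == 2
  )
  for (seg in cfg$loh_segments) {
    if (!seg$chrom %in% names(cfg$chrom_lengths)) {
      abort(paste0("loh segment on unknown chromosome ", seg$chrom))
    }
    stopifnot(seg$frac > 0, seg$frac <= 1, length(seg$copies) == 2)
  }
  structure(cfg, class = "sim_config")
}

# deterministic child seeds (kept below 2^31)
child_seed <- function(cfg, k) (cfg$seed * 7L + k) %% .Machine$integer.max

#' Simulate the ground-truth genome, copy-number landscape and expression
#'
#' Lays out genes, places germline heterozygous loci (a per-gene CDS
#' quota plus an intergenic remainder), assigns tumor allelic copy
#' numbers from the segment list, draws expression levels and marks ASE
#' genes with their drift.  A gene is in LOH truth iff one of its
#' germline alleles has copy number zero across its whole CDS.
#' Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `genes` (gene-model tibble plus truth
#'   columns `expressed`, `rna_coverage`, `is_loh`, `is_ase`, `drift`),
#'   `loci` (per-locus truth: copies, phase, known flag, RNA allele
#'   fraction), `segments`, `catalog`, and the `config`.
#' @export
simulate_genome <- function(config) {
  cfg <- config
  set.seed(child_seed(cfg, 1L))
  genes <- sim_genes(cfg)
  segments <- sim_segments(cfg)
  loci <- sim_loci(cfg, genes)
  loci <- sim_assign_copies(loci, segments, cfg)

  # gene-level LOH truth: every CDS locus has one allele at copy 0
  loh_by_gene <- loci |>
    filter(!is.na(.data$gene_id)) |>
    group_by(.data$gene_id) |>
    summarise(is_loh = dplyr::n() > 0 &&
                all(pmin(.data$cn_ref, .data$cn_alt) == 0),
              .groups = "drop")
  genes <- genes |>
    left_join(loh_by_gene, by = "gene_id") |>
    mutate(is_loh = tidyr::replace_na(.data$is_loh, FALSE))

  genes$expressed <- runif(nrow(genes)) < cfg$expressed_fraction
  genes$rna_coverage <- ifelse(
    genes$expressed,
    rlnorm(nrow(genes),
           meanlog = log(cfg$rna_coverage_mean) - cfg$rna_coverage_sdlog^2 / 2,
           sdlog = cfg$rna_coverage_sdlog),
    0
  )

  eligible <- genes$expressed & !genes$is_loh
  if (!is.null(cfg$x_chrom)) {
    x_like <- eligible & genes$chrom == cfg$x_chrom
  } else {
    x_like <- rep(FALSE, nrow(genes))
  }
  pool <- which(eligible & !x_like)
  n_ase <- round(cfg$ase_fraction * length(pool))
  ase_idx <- pool[sample.int(length(pool), n_ase)]
  genes$is_ase <- seq_len(nrow(genes)) %in% ase_idx | x_like
  genes$drift <- ifelse(
    genes$is_ase,
    runif(nrow(genes), cfg$ase_drift_range[1], cfg$ase_drift_range[2]),
    NA_real_
  )
  # which haplotype is preferred (per gene)
  genes$preferred_hap <- ifelse(genes$is_ase,
                                sample(c("A", "B"), nrow(genes), TRUE),
                                NA_character_)

  loci <- sim_rna_fraction(loci, genes)
  loci$known <- runif(nrow(loci)) < cfg$known_fraction
  catalog <- tibble(
    chrom = loci$chrom[loci$known], pos = loci$pos[loci$known],
    allele = loci$alt[loci$known],
    id = paste0("sv", which(loci$known))
  )
  structure(
    list(genes = genes, loci = loci, segments = segments,
         catalog = catalog, config = cfg),
    class = "sim_truth"
  )
}

sim_genes <- function(cfg) {
  n_by_chrom <- round(cfg$n_genes * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  n_by_chrom[1] <- cfg$n_genes - sum(n_by_chrom[-1])
  out <- map(seq_along(cfg$chrom_lengths), function(ci) {
    chrom <- names(cfg$chrom_lengths)[ci]
    n <- n_by_chrom[ci]
    L <- cfg$chrom_lengths[ci]
    slot <- floor(L / n)
    cds_len <- round(runif(n, 1000, 3000))
    # place each gene inside its own slot; 500-bp UTR padding on each side
    start <- (seq_len(n) - 1) * slot +
      floor(runif(n, 501, pmax(502, slot - cds_len - 501)))
    tibble(
      gene_id = sprintf("%s_g%03d", chrom, seq_len(n)),
      tx_id = sprintf("%s_g%03d.t1", chrom, seq_len(n)),
      chrom = chrom,
      strand = sample(c("+", "-"), n, TRUE),
      cds = map2(start, cds_len, ~ tibble(start = .x, end = .x + .y - 1)),
      exons = map2(start, cds_len,
                   ~ tibble(start = .x - 500, end = .x + .y - 1 + 500))
    )
  }) |> bind_rows()
  mutate(out, exon_length_bp = map_dbl(.data$exons, interval_length))
}

sim_segments <- function(cfg) {
  segs <- map(cfg$loh_segments, function(s) {
    L <- cfg$chrom_lengths[[s$chrom]]
    w <- round(s$frac * L)
    start <- if (w >= L) 1 else floor(runif(1, 1, L - w + 1))
    tibble(chrom = s$chrom, start = start, end = start + w - 1,
           cn_retained = s$copies[1], cn_lost = s$copies[2])
  })
  bind_rows(segs)
}

random_alleles <- function(n) {
  ref <- sample(VALID_BASES, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(VALID_BASES, r), 1), "")
  list(ref = ref, alt = unname(alt))
}

sim_loci <- function(cfg, genes) {
  # per-gene CDS quota
  k <- 1L + rpois(nrow(genes), cfg$mean_loci_per_gene - 1)
  genic <- map(seq_len(nrow(genes)), function(i) {
    cds <- genes$cds[[i]]
    pos <- sort(sample(seq(cds$start[1], cds$end[1]), k[i]))
    tibble(chrom = genes$chrom[i], pos = pos, gene_id = genes$gene_id[i])
  }) |> bind_rows()
  n_inter <- max(0L, cfg$n_het_loci - nrow(genic))
  inter <- map(seq_along(cfg$chrom_lengths), function(ci) {
    n <- round(n_inter * cfg$chrom_lengths[ci] / sum(cfg$chrom_lengths))
    tibble(chrom = names(cfg$chrom_lengths)[ci],
           pos = sort(sample.int(cfg$chrom_lengths[ci], n)),
           gene_id = NA_character_)
  }) |> bind_rows()
  loci <- bind_rows(genic, inter) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  al <- random_alleles(nrow(loci))
  loci$ref <- al$ref
  loci$alt <- al$alt
  # phase: which haplotype carries the alt allele
  loci$alt_hap <- sample(c("A", "B"), nrow(loci), TRUE)
  loci
}

sim_assign_copies <- function(loci, segments, cfg) {
  cn_A <- rep(cfg$baseline_copies[1], nrow(loci))
  cn_B <- rep(cfg$baseline_copies[2], nrow(loci))
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      inside <- loci$chrom == segments$chrom[i] &
        loci$pos >= segments$start[i] & loci$pos <= segments$end[i]
      # haplotype A is the retained allele throughout a segment
      cn_A[inside] <- segments$cn_retained[i]
      cn_B[inside] <- segments$cn_lost[i]
    }
  }
  loci$cn_alt <- ifelse(loci$alt_hap == "A", cn_A, cn_B)
  loci$cn_ref <- ifelse(loci$alt_hap == "A", cn_B, cn_A)
  loci
}

# expected RNA alt-allele fraction per locus:
# 0.5 for ordinary expressed genes, the gene drift (phased) for ASE genes,
# the allelic copy fraction for loci inside copy-altered segments
sim_rna_fraction <- function(loci, genes) {
  g <- select(genes, "gene_id", "is_ase", "drift", "preferred_hap",
              "is_loh")
  x <- left_join(loci, g, by = "gene_id")
  cn_total <- x$cn_ref + x$cn_alt
  copy_frac <- ifelse(cn_total > 0, x$cn_alt / cn_total, 0.5)
  ase_frac <- ifelse(x$alt_hap == x$preferred_hap, x$drift, 1 - x$drift)
  loci$rna_alt_frac <- dplyr::case_when(
    !is.na(x$is_ase) & x$is_ase ~ ase_frac,
    cn_total > 0 & (x$cn_ref == 0 | x$cn_alt == 0) ~ copy_frac,
    abs(copy_frac - 0.5) > 1e-9 ~ copy_frac,
    .default = 0.5
  )
  loci
}

#' Simulate DNA (exome) allele counts for the pair
#'
#' Per locus and sample, depth is Poisson with the configured mean; the
#' alternate-read count is binomial with success probability 0.5 in the
#' normal (both alleles present once per haplotype) and the allelic copy
#' fraction in the tumor, in both cases perturbed by the symmetric
#' allele-flip error rate `e`: `p' = p (1 - e) + (1 - p) e`.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return Allele-count tibble (TSV dialect columns) for samples
#'   `"normal"` and `"tumor"`, assay `DNA`.
#' @export
simulate_exome_counts <- function(truth, config) {
  cfg <- config
  set.seed(child_seed(cfg, 2L))
  loci <- truth$loci
  e <- cfg$error_rate
  flip <- function(p) p * (1 - e) + (1 - p) * e
  one_sample <- function(sample, p_alt) {
    n_depth <- rpois(nrow(loci), cfg$exome_depth_mean)
    n_alt <- rbinom(nrow(loci), n_depth, flip(p_alt))
    tibble(
      chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
      sample = sample, assay = "DNA",
      ref_reads = n_depth - n_alt, alt_reads = n_alt,
      central_qual = 35, flank_qual = 20
    )
  }
  cn_total <- loci$cn_ref + loci$cn_alt
  tumor_frac <- ifelse(cn_total > 0, loci$cn_alt / cn_total, 0)
  bind_rows(
    one_sample("normal", rep(0.5, nrow(loci))),
    one_sample("tumor", tumor_frac)
  )
}

#' Simulate RNA allele counts
#'
#' For every expressed gene, each CDS heterozygous locus receives a
#' Poisson depth at the gene's expression level (mean per-base coverage)
#' and an alternate-read count binomial at the locus's true RNA allele
#' fraction — 0.5 for balanced genes, the gene drift for ASE genes, the
#' copy fraction for loci in copy-altered segments — perturbed by the
#' error rate.  For `sample = "normal"` the diploid genome makes every
#' non-ASE locus balanced.  Unexpressed genes emit no rows.
#'
#' @param truth A `sim_truth`.
#' @param config The same [sim_config()].
#' @param sample `"tumor"` (default) or `"normal"`.
#' @return Allele-count tibble, assay `RNA`.
#' @export
simulate_rna_counts <- function(truth, config, sample = "tumor") {
  cfg <- config
  set.seed(child_seed(cfg, if (sample == "tumor") 3L else 4L))
  e <- cfg$error_rate
  loci <- truth$loci |>
    filter(!is.na(.data$gene_id)) |>
    inner_join(select(truth$genes, "gene_id", "expressed", "rna_coverage",
                      "is_ase", "drift", "preferred_hap"),
               by = "gene_id") |>
    filter(.data$expressed)
  if (nrow(loci) == 0) {
    return(tibble(chrom = character(), pos = numeric(), ref = character(),
                  alt = character(), sample = character(),
                  assay = character(), ref_reads = numeric(),
                  alt_reads = numeric(), central_qual = numeric(),
                  flank_qual = numeric()))
  }
  p_alt <- if (sample == "tumor") {
    loci$rna_alt_frac
  } else {
    # normal: diploid and balanced unless the gene drifts in both lines
    ifelse(loci$is_ase & !is.na(loci$drift),
           ifelse(loci$alt_hap == loci$preferred_hap,
                  loci$drift, 1 - loci$drift),
           0.5)
  }
  p_alt <- p_alt * (1 - e) + (1 - p_alt) * e
  n_depth <- rpois(nrow(loci), loci$rna_coverage)
  n_alt <- rbinom(nrow(loci), n_depth, p_alt)
  central <- rep(35, nrow(loci))
  flank <- rep(20, nrow(loci))
  if (isTRUE(cfg$dirty_quality)) {
    dirty <- runif(nrow(loci)) < 0.1
    central[dirty] <- 20
    flank[dirty] <- 10
  }
  tibble(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    sample = sample, assay = "RNA",
    ref_reads = n_depth - n_alt, alt_reads = n_alt,
    central_qual = central, flank_qual = flank
  )
}

#' Simulate a complete paired dataset
#'
#' Convenience wrapper running [simulate_genome()],
#' [simulate_exome_counts()] and [simulate_rna_counts()] (tumor RNA; add
#' the normal with `normal_rna = TRUE`).
#'
#' @param config A [sim_config()].
#' @param normal_rna Also simulate normal-sample RNA counts.
#' @return List with `truth`, `exome` (both samples), `rna`, and the
#'   gene models / catalog pulled out of the truth for convenience.
#' @export
simulate_dataset <- function(config = sim_config(), normal_rna = FALSE) {
  truth <- simulate_genome(config)
  exome <- simulate_exome_counts(truth, config)
  rna <- simulate_rna_counts(truth, config, sample = "tumor")
  if (normal_rna) {
    rna <- bind_rows(rna, simulate_rna_counts(truth, config, "normal"))
  }
  list(truth = truth,
       exome = exome,
       rna = rna,
       genes = select(truth$genes, "gene_id", "tx_id", "chrom", "strand",
                      "exons", "cds", "exon_length_bp"),
       catalog = truth$catalog)
}

#' Score calls against simulation truth
#'
#' Gene-level confusion counts, precision, recall and false discovery
#' rate for the LOH and ASE callers.  With no calls at all, precision is
#' undefined; it is reported as 1 by convention with `no_calls = TRUE`.
#'
#' @param truth A `sim_truth`.
#' @param loh_genes Character vector of called LOH gene ids.
#' @param ase_genes Character vector of called ASE gene ids.
#' @return Tibble with one row per event class (`loh`, `ase`): `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `fdr`, `no_calls`.
#' @export
evaluate_calls <- function(truth, loh_genes, ase_genes) {
  score <- function(called, true_set, class) {
    called <- unique(called[!is.na(called)])
    tp <- sum(called %in% true_set)
    fp <- length(called) - tp
    fn <- length(setdiff(true_set, called))
    no_calls <- length(called) == 0
    tibble(
      class = class, tp = tp, fp = fp, fn = fn,
      precision = if (no_calls) 1 else tp / (tp + fp),
      recall = if (length(true_set) == 0) 1 else tp / (tp + fn),
      fdr = if (no_calls) 0 else fp / (tp + fp),
      no_calls = no_calls
    )
  }
  bind_rows(
    score(loh_genes, truth$genes$gene_id[truth$genes$is_loh], "loh"),
    score(ase_genes, truth$genes$gene_id[truth$genes$is_ase], "ase")
  )
}
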