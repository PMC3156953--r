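#' Read a per-locus allele-count table
#'
#' Allele counts are the input contract of the whole pipeline: one row per
#' (locus, sample, assay) giving the number of reads supporting the
#' reference and the alternate base.  Two dialects are accepted:
#'
#' * `"tsv"` — tab-separated with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `sample`, `assay` (`DNA`/`RNA`), `ref_reads`,
#'   `alt_reads`, `central_qual`, `flank_qual`; `"."` marks a missing
#'   quality.  `central_qual` is the mean base quality at the variant base
#'   itself, `flank_qual` the mean quality of the surrounding bases (used
#'   by the transcriptome SNV filter).
#' * `"vcf"` — loci and alleles from `POS`/`REF`/`ALT`, counts from the
#'   per-sample `AD` field.  Multi-allelic records are split into one row
#'   per alternate allele; indel alleles are dropped with a message (only
#'   biallelic single-base substitutions are modeled).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param assay For VCF input, the assay label to attach (`"DNA"` default);
#'   the TSV dialect carries its own `assay` column.
#' @return A tibble with the TSV-dialect columns, positions 1-based.
#' @export
read_allele_counts <- function(path, dialect = c("tsv", "vcf"),
                               assay = "DNA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- switch(dialect,
    tsv = read_allele_counts_tsv(path),
    vcf = read_allele_counts_vcf(path, assay = assay)
  )
  check_chrom_dialect(x$chrom, what = path)
  x
}

allele_count_cols <- c(
  "chrom", "pos", "ref", "alt", "sample", "assay",
  "ref_reads", "alt_reads", "central_qual", "flank_qual"
)

read_allele_counts_tsv <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      sample = readr::col_character(),
      assay = readr::col_character(),
      ref_reads = readr::col_double(),
      alt_reads = readr::col_double(),
      central_qual = readr::col_character(),
      flank_qual = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  assert_columns(x, allele_count_cols, path)
  x <- mutate(
    x,
    central_qual = parse_dot_number(.data$central_qual),
    flank_qual = parse_dot_number(.data$flank_qual)
  )
  validate_allele_counts(x, path)
  as_tibble(x)
}

# "." encodes a missing quality value in the TSV dialect
parse_dot_number <- function(x) {
  x[x == "." | x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

validate_allele_counts <- function(x, path) {
  bad_row <- function(ok, why) {
    if (all(ok)) return(invisible())
    line <- which(!ok)[1] + 1L  # +1 for the header line
    abort(paste0(path, ": line ", line, ": ", why))
  }
  bad_row(is_count(x$pos) & x$pos >= 1, "pos must be a positive integer")
  bad_row(x$ref %in% VALID_BASES & x$alt %in% VALID_BASES,
          "ref/alt must be single bases in {A,C,G,T} (indels are rejected)")
  bad_row(x$ref != x$alt, "ref and alt must differ")
  bad_row(x$assay %in% c("DNA", "RNA"), "assay must be DNA or RNA")
  bad_row(is_count(x$ref_reads), "ref_reads must be a non-negative integer")
  bad_row(is_count(x$alt_reads), "alt_reads must be a non-negative integer")
  bad_row(is.na(x$central_qual) | x$central_qual >= 0,
          "central_qual must be '.' or a non-negative number")
  bad_row(is.na(x$flank_qual) | x$flank_qual >= 0,
          "flank_qual must be '.' or a non-negative number")
  invisible(x)
}

read_allele_counts_vcf <- function(path, assay = "DNA") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) abort(paste0(path, ": VCF has no per-sample AD field"))
  samples <- colnames(ad)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      counts <- suppressWarnings(
        as.numeric(strsplit(ad[i, s], ",", fixed = TRUE)[[1]])
      )
      for (k in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = fix$CHROM[i],
          pos = as.numeric(fix$POS[i]),
          ref = fix$REF[i],
          alt = alts[k],
          sample = s,
          assay = assay,
          ref_reads = counts[1] %||% NA_real_,
          alt_reads = if (length(counts) > k) counts[k + 1] else NA_real_,
          central_qual = NA_real_,
          flank_qual = NA_real_
        )
      }
    }
  }
  x <- bind_rows(rows)
  snv <- x$ref %in% VALID_BASES & x$alt %in% VALID_BASES
  if (any(!snv)) {
    inform(paste0(path, ": dropped ", sum(!snv),
                  " non-SNV allele record(s) (indels are not modeled)"))
    x <- x[snv, , drop = FALSE]
  }
  x <- filter(x, !is.na(.data$ref_reads), !is.na(.data$alt_reads))
  x
}

#' Write a per-locus allele-count table (TSV dialect)
#'
#' Inverse of [read_allele_counts()] for the TSV dialect; missing quality
#' values are written as `"."` so that `read(write(x))` round-trips.
#'
#' @param x Allele-count tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_allele_counts <- function(x, path) {
  assert_columns(x, allele_count_cols)
  out <- mutate(
    x,
    central_qual = ifelse(is.na(.data$central_qual), ".",
                          format(.data$central_qual, trim = TRUE)),
    flank_qual = ifelse(is.na(.data$flank_qual), ".",
                        format(.data$flank_qual, trim = TRUE))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a known-variant catalog
#'
#' A dbSNP-style lookup of previously reported variants, used to flag
#' novel SNVs and to require catalog membership for isolated LOH genes.
#' Accepted formats: a TSV with columns `chrom`, `pos`, `allele` (and an
#' optional `id`), or a VCF whose `ID` column carries the variant name.
#' Duplicate entries collapse to one; lookup is by (chrom, pos, allele).
#'
#' @param path Path to the catalog.
#' @param format `"tsv"` or `"vcf"`.
#' @return A tibble with columns `chrom`, `pos`, `allele`, `id`.
#' @export
read_known_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    assert_columns(x, c("chrom", "pos", "allele"), path)
    if (!"id" %in% names(x)) x$id <- NA_character_
    x <- select(x, "chrom", "pos", "allele", "id")
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    x <- tibble(
      chrom = fix$CHROM, pos = as.numeric(fix$POS),
      allele = fix$ALT, id = fix$ID
    )
    x <- tidyr::separate_rows(x, "allele", sep = ",")
  }
  x <- distinct(x, .data$chrom, .data$pos, .data$allele, .keep_all = TRUE)
  check_chrom_dialect(x$chrom, what = path)
  as_tibble(x)
}

#' Flag SNV calls as known or novel against a variant catalog
#'
#' A call is *known* when its (chrom, pos, alt) triple is present in the
#' catalog — the allele must match, a catalog entry for the other allele
#' at the same position does not count.
#'
#' @param snvs SNV-call tibble (needs `chrom`, `pos`, `alt`).
#' @param catalog Catalog tibble from [read_known_variants()] (may be
#'   empty, in which case everything is novel).
#' @return `snvs` with a logical `known` column and, as attribute
#'   `"fraction_novel"`, the share of novel calls (see [fraction_novel()]).
#' @export
annotate_known <- function(snvs, catalog) {
  assert_columns(snvs, c("chrom", "pos", "alt"))
  if (is.null(catalog) || nrow(catalog) == 0) {
    snvs$known <- rep(FALSE, nrow(snvs))
  } else {
    assert_columns(catalog, c("chrom", "pos", "allele"))
    key <- paste(catalog$chrom, catalog$pos, catalog$allele)
    snvs$known <- paste(snvs$chrom, snvs$pos, snvs$alt) %in% key
  }
  attr(snvs, "fraction_novel") <- fraction_novel(snvs)
  snvs
}

#' Fraction of novel SNVs in an annotated callset
#'
#' Novel calls over total calls; an empty callset reports 0 (with zero
#' counts) rather than NaN.
#'
#' @param snvs Tibble with a logical `known` column.
#' @return A single number in `[0, 1]`.
#' @export
fraction_novel <- function(snvs) {
  assert_columns(snvs, "known")
  if (nrow(snvs) == 0) return(0)
  sum(!snvs$known) / nrow(snvs)
}

#' Write LOH and ASE results to an output directory
#'
#' Emits plain-text result files:
#' * `loh_loci.bed` — LOH loci as BED6 (0-based half-open), `name` the
#'   gene id (`.` when unassigned), `score` the Phred-scaled test P-value
#'   `-10 log10(P)` capped at 1000.
#' * `loh_genes.tsv`, `ase_genes.tsv` — per-gene tables in the shape of a
#'   published ASE gene listing: gene, major/minor read counts per locus,
#'   chromosome, P-value (three decimals at this report layer), variant id.
#' * `paired_vaf.tsv` — per-locus normal/tumor variant allele frequencies
#'   for scatter plotting, when supplied.
#'
#' @param loh LOH event tibble (may be empty or NULL).
#' @param ase ASE locus-result tibble (may be empty or NULL).
#' @param out_dir Output directory, created if needed.
#' @param loh_genes,ase_genes Optional per-gene summaries.
#' @param paired_vaf Optional paired-VAF table from [paired_vaf_table()].
#' @return Invisibly, a character vector of the files written.
#' @export
write_results <- function(loh, ase, out_dir, loh_genes = NULL,
                          ase_genes = NULL, paired_vaf = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(x, file) {
    p <- file.path(out_dir, file)
    readr::write_tsv(x, p, progress = FALSE)
    written <<- c(written, p)
  }

  loh <- loh %||% empty_loh_events()
  bed <- tibble(
    chrom = loh$chrom,
    start = loh$pos - 1,          # BED is 0-based half-open
    end = loh$pos,
    name = if ("gene_id" %in% names(loh)) {
      ifelse(is.na(loh$gene_id), ".", loh$gene_id)
    } else rep(".", nrow(loh)),
    score = bed_score(loh$p_value),
    strand = rep(".", nrow(loh))
  )
  p <- file.path(out_dir, "loh_loci.bed")
  readr::write_tsv(bed, p, col_names = FALSE, progress = FALSE)
  written <- c(written, p)

  emit(loh, "loh_events.tsv")
  if (!is.null(loh_genes)) emit(report_gene_table(loh_genes), "loh_genes.tsv")
  ase <- ase %||% empty_ase_loci()
  emit(mutate(ase, p_raw = signif(.data$p_raw, 4),
              p_corrected = round(.data$p_corrected, 3)),
       "ase_loci.tsv")
  if (!is.null(ase_genes)) emit(report_gene_table(ase_genes), "ase_genes.tsv")
  if (!is.null(paired_vaf)) emit(paired_vaf, "paired_vaf.tsv")
  invisible(written)
}

# Phred-scaled BED score, capped at 1000 (P = 0 maps to the cap)
bed_score <- function(p) {
  if (length(p) == 0) return(numeric())
  s <- ifelse(is.na(p) | p <= 0, 1000, -10 * log10(p))
  round(pmin(s, 1000))
}

# flatten a per-gene summary (list-column of supporting loci) to a report
# table: one row per locus, P rounded to three decimals
report_gene_table <- function(genes) {
  if (nrow(genes) == 0 || !"loci" %in% names(genes)) {
    return(tibble(gene = character(), major_reads = numeric(),
                  minor_reads = numeric(), chrom = character(),
                  p_value = numeric(), variant_id = character()))
  }
  x <- tidyr::unnest(select(genes, "gene_id", "chrom", "loci"),
                     "loci", names_sep = ".")
  tibble(
    gene = ifelse(is.na(x$gene_id), ".", x$gene_id),
    major_reads = x$loci.major_reads,
    minor_reads = x$loci.minor_reads,
    chrom = x$chrom,
    p_value = round(x$loci.p_value, 3),
    variant_id = ifelse(is.na(x$loci.variant_id), "novel", x$loci.variant_id)
  )
}

empty_loh_events <- function() {
  tibble(chrom = character(), pos = numeric(), ref = character(),
         alt = character(), gene_id = character(), normal_vaf = numeric(),
         tumor_depth = numeric(), tumor_minor_reads = numeric(),
         p_value = numeric(), retained_allele = character())
}

empty_ase_loci <- function() {
  tibble(chrom = character(), pos = numeric(), ref = character(),
         alt = character(), rna_major_reads = numeric(),
         rna_minor_reads = numeric(), drift = numeric(),
         p_s_used = numeric(), p_raw = numeric(), p_corrected = numeric(),
         m = numeric(), status = character(), biased = logical(),
         preferred_allele = character())
}
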