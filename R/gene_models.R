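#' Read gene models from BED12 or GFF3
#'
#' Builds one exon/CDS model per gene.  When a gene has several annotated
#' transcripts only the longest alternative form (by total exon length) is
#' retained as the reference model; ties are broken lexicographically by
#' transcript id.
#'
#' For BED12 the `name` field identifies the transcript; a `gene|transcript`
#' name is split on `|`, otherwise the name serves as both gene and
#' transcript id.  Exons come from the block structure and the CDS from the
#' thick range.  For GFF3 the usual gene/mRNA/exon/CDS hierarchy is walked
#' through `ID`/`Parent` attributes.
#'
#' Internally all intervals are 1-based closed (BED's 0-based half-open
#' starts are converted at this boundary).
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"gff3"`.
#' @return A tibble with one row per gene: `gene_id`, `tx_id`, `chrom`,
#'   `strand`, `exon_length_bp`, and list-columns `exons` and `cds`
#'   holding `start`/`end` interval tibbles.
#' @export
read_gene_models <- function(path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  models <- switch(format,
    bed12 = read_gene_models_bed12(path),
    gff3 = read_gene_models_gff3(path)
  )
  check_chrom_dialect(models$chrom, what = path)
  # CDS must lie inside the exon model
  ok <- map2(models$cds, models$exons, cds_within_exons)
  bad <- which(!unlist(ok))
  if (length(bad) > 0) {
    abort(paste0(path, ": CDS outside exons for transcript ",
                 models$tx_id[bad[1]]))
  }
  keep_longest_transcript(models)
}

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)  # absolute, 1-based closed GRangesList
  name <- gr$name
  gene_id <- ifelse(grepl("|", name, fixed = TRUE),
                    sub("\\|.*$", "", name), name)
  tx_id <- ifelse(grepl("|", name, fixed = TRUE),
                  sub("^[^|]*\\|", "", name), name)
  thick <- gr$thick
  tibble(
    gene_id = gene_id,
    tx_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exons = map(seq_along(gr), function(i) {
      b <- blocks[[i]]
      merge_intervals(tibble(start = GenomicRanges::start(b),
                             end = GenomicRanges::end(b)))
    }),
    cds = map(seq_along(gr), function(i) {
      b <- blocks[[i]]
      th <- IRanges::IRanges(IRanges::start(thick)[i], IRanges::end(thick)[i])
      if (IRanges::width(th) == 0) return(tibble(start = numeric(), end = numeric()))
      ov <- IRanges::intersect(IRanges::ranges(b), th)
      merge_intervals(tibble(start = IRanges::start(ov), end = IRanges::end(ov)))
    })
  ) |>
    mutate(exon_length_bp = map_dbl(.data$exons, interval_length))
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  first_parent <- function(p) {
    if (is.null(p)) return(NA_character_)
    vapply(p, function(v) if (length(v) > 0) v[1] else NA_character_, "")
  }
  df$parent1 <- first_parent(df$Parent)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0) abort(paste0(path, ": no mRNA/transcript features"))
  models <- map(seq_len(nrow(mrna)), function(i) {
    tx <- mrna$ID[i]
    kids <- df[!is.na(df$parent1) & df$parent1 == tx, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0) ex <- mrna[i, , drop = FALSE]  # single-span fallback
    tibble(
      gene_id = mrna$parent1[i] %||% tx,
      tx_id = tx,
      chrom = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exons = list(merge_intervals(tibble(start = ex$start, end = ex$end))),
      cds = list(merge_intervals(tibble(start = cd$start, end = cd$end)))
    )
  })
  bind_rows(models) |>
    mutate(gene_id = ifelse(is.na(.data$gene_id), .data$tx_id, .data$gene_id),
           exon_length_bp = map_dbl(.data$exons, interval_length))
}

# merge overlapping/adjacent 1-based closed intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(tibble(start = numeric(), end = numeric()))
  r <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
  tibble(start = IRanges::start(r), end = IRanges::end(r))
}

interval_length <- function(iv) {
  if (nrow(iv) == 0) return(0)
  sum(iv$end - iv$start + 1)
}

cds_within_exons <- function(cds, exons) {
  if (nrow(cds) == 0) return(TRUE)
  ci <- IRanges::IRanges(cds$start, cds$end)
  ei <- IRanges::IRanges(exons$start, exons$end)
  sum(IRanges::width(IRanges::intersect(ci, ei))) == sum(IRanges::width(ci))
}

keep_longest_transcript <- function(models) {
  models |>
    arrange(.data$gene_id, desc(.data$exon_length_bp), .data$tx_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$chrom, map_dbl(.data$exons, ~ min(.x$start, Inf)))
}

#' Flatten gene models to a long interval table
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param what `"cds"` or `"exons"`.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_intervals <- function(genes, what = c("cds", "exons")) {
  what <- match.arg(what)
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric()))
  }
  genes |>
    select("gene_id", "chrom", "strand", iv = all_of(what)) |>
    tidyr::unnest("iv")
}

# GRanges helpers used by the aggregation and window operations ----------

loci_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
}

intervals_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
}

# map loci (rows of `x`) to genes whose `what` intervals contain them;
# returns tibble(locus_row, gene_id) with one row per assignment
assign_loci_to_genes <- function(x, genes, what = "cds") {
  iv <- gene_intervals(genes, what)
  if (nrow(x) == 0 || nrow(iv) == 0) {
    return(tibble(locus_row = integer(), gene_id = character()))
  }
  hits <- GenomicRanges::findOverlaps(loci_granges(x), intervals_granges(iv))
  tibble(
    locus_row = S4Vectors::queryHits(hits),
    gene_id = iv$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
}
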