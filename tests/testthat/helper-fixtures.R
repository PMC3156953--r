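# fixtures are built in code at test time; nothing is stored on disk

# quick allele-count rows with sensible defaults
ac <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
               sample = "s1", assay = "DNA", ref_reads = 10,
               alt_reads = 10, central_qual = 35, flank_qual = 20) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 sample = sample, assay = assay, ref_reads = ref_reads,
                 alt_reads = alt_reads, central_qual = central_qual,
                 flank_qual = flank_qual)
}

# an SNV-call row as produced by call_hc_snvs()
snv <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                sample = "s1", ref_reads = 10, alt_reads = 10,
                genotype = NULL, known = NA) {
  depth <- ref_reads + alt_reads
  vaf <- alt_reads / depth
  if (is.null(genotype)) genotype <- classify_genotype(ref_reads, alt_reads)
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 sample = sample, depth = depth, ref_reads = ref_reads,
                 alt_reads = alt_reads, vaf = vaf, genotype = genotype,
                 known = known)
}

write_tsv_fixture <- function(x, path = tempfile(fileext = ".tsv")) {
  write_allele_counts(x, path)
  path
}

# minimal VCF 4.2 with per-sample AD
write_vcf_fixture <- function(rows, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  )
  writeLines(c(header, rows), path)
  path
}

# BED12 line builder: starts are 0-based half-open
bed12_line <- function(chrom, start, end, name, block_sizes, block_starts,
                       thick_start = start, thick_end = end) {
  paste(chrom, start, end, name, 0, "+", thick_start, thick_end, "0",
        length(block_sizes), paste0(paste(block_sizes, collapse = ","), ","),
        paste0(paste(block_starts, collapse = ","), ","), sep = "\t")
}

write_bed12_fixture <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

write_gff3_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# one-interval gene model tibble in the internal shape
gm <- function(gene_id, chrom, cds_start, cds_end, utr = 0,
               strand = "+") {
  tibble::tibble(
    gene_id = gene_id, tx_id = paste0(gene_id, ".t1"), chrom = chrom,
    strand = strand,
    exons = list(tibble::tibble(start = cds_start - utr,
                                end = cds_end + utr)),
    cds = list(tibble::tibble(start = cds_start, end = cds_end)),
    exon_length_bp = (cds_end + utr) - (cds_start - utr) + 1
  )
}

# default-scenario simulations are reused across files; cache per seed
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed) {
  key <- as.character(seed)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_dataset(sim_config(seed = seed))
  }
  sim_cache[[key]]
}
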