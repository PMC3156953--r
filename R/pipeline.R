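run_config_fields <- c(
  "normal_dna", "tumor_dna", "tumor_rna", "normal_rna", "genes",
  "gene_format", "catalog", "catalog_format", "out_dir", "seed",
  "min_var_reads", "min_vaf", "het_band", "prelim_band",
  "hom_alpha", "hom_min_reads", "strict_homozygosity",
  "window_bp", "isolation_bp", "min_rna_depth",
  "ase_min_cov", "ase_band", "ase_alpha", "correction", "ps_mode"
)

#' Build a validated pipeline run configuration
#'
#' Collects input paths (or in-memory tibbles) and every stage threshold,
#' at the same defaults as the stage functions.  Unknown keys are
#' rejected up front so a typo cannot silently fall back to a default.
#'
#' @param normal_dna,tumor_dna DNA allele counts: paths (TSV dialect) or
#'   tibbles.
#' @param tumor_rna RNA allele counts for the tumor sample (path or
#'   tibble); optional but required for the ASE stage.
#' @param normal_rna Optional RNA counts for the normal sample.
#' @param genes Optional gene models: path (BED12/GFF3 per
#'   `gene_format`) or tibble.
#' @param gene_format `"bed12"` or `"gff3"` when `genes` is a path.
#' @param catalog Optional known-variant catalog (path or tibble).
#' @param catalog_format `"tsv"` or `"vcf"` when `catalog` is a path.
#' @param out_dir Output directory for result files and the manifest.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the inputs are simulated).
#' @param min_var_reads,min_vaf,het_band,prelim_band,hom_alpha,hom_min_reads
#'   Genotyping thresholds (see [call_hc_snvs()]).
#' @param strict_homozygosity Strict (zero minor reads) homozygosity.
#' @param window_bp,isolation_bp,min_rna_depth Isolated-LOH filters.
#' @param ase_min_cov,ase_band,ase_alpha,correction,ps_mode ASE
#'   thresholds (see [test_ase_loci()]).
#' @param ... Unknown keys: rejected with an error.
#' @return A `run_config` list.
#' @export
run_config <- function(normal_dna, tumor_dna, tumor_rna = NULL,
                       normal_rna = NULL, genes = NULL,
                       gene_format = "bed12", catalog = NULL,
                       catalog_format = "tsv",
                       out_dir = tempfile("alleledrift_run_"), seed = 1L,
                       min_var_reads = 3, min_vaf = 0.10,
                       het_band = c(0.20, 0.80),
                       prelim_band = c(0.10, 0.90),
                       hom_alpha = 0.001, hom_min_reads = 10,
                       strict_homozygosity = FALSE,
                       window_bp = 25000, isolation_bp = 1e6,
                       min_rna_depth = 10,
                       ase_min_cov = 20, ase_band = c(0.2, 0.8),
                       ase_alpha = 0.05, correction = "bonferroni",
                       ps_mode = "vaf", ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(paste0("unknown run_config key(s): ",
                 paste(names(extra), collapse = ", ")))
  }
  cfg <- mget(run_config_fields, envir = environment())
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_fields)
  if (length(unknown) > 0) {
    abort(paste0(path, ": unknown run_config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

load_counts <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", x)) "vcf" else "tsv"
    return(read_allele_counts(x, dialect = dialect))
  }
  assert_columns(x, c(LOCUS_COLS, "sample", "assay",
                      "ref_reads", "alt_reads"), what)
  x
}

#' Run the full LOH + ASE pipeline
#'
#' Executes genotype -> LOH -> expression gating -> ASE -> report as one
#' reproducible run.  The ASE correction family `m` is set to the number
#' of heterozygous loci passing the RNA coverage gate *in this run* — it
#' is a property of the dataset, never a constant.  All stage outputs are
#' written to `config$out_dir` together with `manifest.json` recording
#' the package version, seed, every threshold and per-stage counts.  A
#' stage failure aborts with the stage name and cause.
#'
#' @param config A [run_config()] (or a path to a YAML file for
#'   [read_run_config()]).
#' @return Invisibly, a list with `manifest`, `loh` (the [loh_scan()]
#'   object), `ase` (the [ase_scan()] object or NULL), and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    abort("config must be a run_config or a path to a YAML config")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  inform("alleledrift: reading inputs")
  normal <- stage("read", load_counts(config$normal_dna, "normal_dna"))
  tumor <- stage("read", load_counts(config$tumor_dna, "tumor_dna"))
  rna <- stage("read", load_counts(config$tumor_rna, "tumor_rna"))
  genes <- stage("read", {
    g <- config$genes
    if (is.character(g)) read_gene_models(g, format = config$gene_format)
    else g
  })
  catalog <- stage("read", {
    k <- config$catalog
    if (is.character(k)) read_known_variants(k, format = config$catalog_format)
    else k
  })

  inform("alleledrift: genotype + LOH stage")
  loh <- stage("loh", loh_scan(
    normal, tumor, genes = genes, catalog = catalog, rna = rna,
    alpha = config$hom_alpha, min_reads = config$hom_min_reads,
    strict = config$strict_homozygosity, window_bp = config$window_bp,
    isolation_bp = config$isolation_bp,
    min_rna_depth = config$min_rna_depth,
    min_var_reads = config$min_var_reads, min_vaf = config$min_vaf,
    het_band = config$het_band, prelim_band = config$prelim_band
  ))

  ase <- NULL
  if (!is.null(rna)) {
    inform("alleledrift: ASE stage")
    tumor_calls <- loh$tumor_calls
    if (!is.null(catalog)) tumor_calls <- annotate_known(tumor_calls, catalog)
    ase <- stage("ase", ase_scan(
      tumor_calls, rna, genes = genes,
      min_cov = config$ase_min_cov, band = config$ase_band,
      alpha = config$ase_alpha, correction = config$correction,
      ps_mode = config$ps_mode
    ))
  } else {
    inform("alleledrift: no RNA input; ASE stage reports 0 tested loci")
  }

  inform("alleledrift: writing results")
  files <- stage("report", write_results(
    loh = {
      ev <- loh$events
      ev |> arrange(.data$chrom, .data$pos)
    },
    ase = if (!is.null(ase)) arrange(ase$loci, .data$chrom, .data$pos),
    out_dir = config$out_dir,
    loh_genes = loh$genes,
    ase_genes = if (!is.null(ase)) ase$genes,
    paired_vaf = loh$paired_vaf
  ))

  manifest <- list(
    package = "alleledrift",
    version = as.character(packageVersion("alleledrift")),
    seed = config$seed,
    thresholds = config[setdiff(run_config_fields,
                                c("normal_dna", "tumor_dna", "tumor_rna",
                                  "normal_rna", "genes", "catalog",
                                  "out_dir"))],
    counts = list(
      snvs_normal = nrow(loh$normal_calls),
      snvs_tumor = nrow(loh$tumor_calls),
      het_hc_normal = sum(loh$normal_calls$genotype == "het_hc"),
      loh_loci = loh$counts$n_loh_loci,
      loh_no_coverage = loh$counts$n_no_coverage,
      loh_genes = loh$counts$n_loh_genes,
      ase_loci_tested = if (is.null(ase)) 0L else ase$counts$n_tested,
      ase_m = if (is.null(ase)) 0L else ase$m,
      ase_biased_loci = if (is.null(ase)) 0L else ase$counts$n_biased_loci,
      ase_genes = if (is.null(ase)) NA_integer_ else ase$counts$n_ase_genes
    )
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, loh = loh, ase = ase,
                 files = c(files, manifest_path)))
}
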