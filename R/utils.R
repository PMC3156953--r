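VALID_BASES <- c("A", "C", "G", "T")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Check that chromosome names use one dialect
#'
#' Inputs may name chromosomes either with or without the `"chr"` prefix,
#' but all tables in one analysis must agree; a mixture is almost always a
#' sign that two inputs come from different coordinate dialects and would
#' silently fail to join.
#'
#' @param chrom Character vector of chromosome names.
#' @param what Label used in the error message.
#' @return Invisibly, `chrom`.  Errors on a mixed dialect.
#' @export
check_chrom_dialect <- function(chrom, what = "input") {
  chrom <- unique(as.character(chrom))
  pref <- grepl("^chr", chrom)
  if (any(pref) && !all(pref)) {
    abort(paste0(
      "mixed chromosome-name dialects in ", what, ": found both ",
      "'chr'-prefixed and bare names (e.g. ",
      chrom[pref][1], " and ", chrom[!pref][1], ")"
    ))
  }
  invisible(chrom)
}

#' Normalize chromosome names to one dialect
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"asis"` (default; only checks consistency), `"chr"`
#'   (add the prefix) or `"plain"` (strip it).
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, style = c("asis", "chr", "plain")) {
  style <- match.arg(style)
  chrom <- as.character(chrom)
  switch(style,
    asis = {
      check_chrom_dialect(chrom)
      chrom
    },
    chr = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    plain = sub("^chr", "", chrom)
  )
}

# locus key columns shared by every per-locus table
LOCUS_COLS <- c("chrom", "pos", "ref", "alt")

assert_columns <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

is_count <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x == floor(x)

# scalar integer-ish check for thresholds
check_scalar_number <- function(x, name, lo = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo) {
    abort(paste0("`", name, "` must be a single number >= ", lo))
  }
  invisible(x)
}
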