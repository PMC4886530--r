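# Shared helpers: metadata column handling, Phred conversion, seeded RNG.

# Columns of a sample table that are metadata rather than taxon abundances.
META_COLS <- c("sample_id", "batch", "day", "fraction", "quality")

#' Names of the abundance (feature) columns of a sample table
#'
#' Abundance tables in fermeta are wide tibbles: one row per sample, a
#' `sample_id` column plus optional `batch`, `day`, `fraction` and `quality`
#' metadata, and one numeric column per taxon, OTU or gene.
#'
#' @param tbl A wide abundance tibble.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(tbl) {
  setdiff(names(tbl), META_COLS)
}

#' Extract the numeric abundance matrix of a wide sample table
#'
#' @inheritParams feature_columns
#' @return Numeric matrix, rows named by `sample_id` when present.
#' @export
abundance_matrix <- function(tbl) {
  feats <- feature_columns(tbl)
  m <- as.matrix(tbl[, feats, drop = FALSE])
  if (!is.numeric(m)) abort("feature columns must all be numeric")
  if ("sample_id" %in% names(tbl)) rownames(m) <- tbl$sample_id
  m
}

#' Drop samples taken before community divergence
#'
#' Quality-association analyses (ordination group tests, the day-7 quality
#' tree) only consider samples fermented for at least `min_day` days; earlier
#' samples have not yet diverged between good and poor batches.
#'
#' @param tbl A tibble with a `day` column.
#' @param min_day Minimum fermentation day retained (default 7).
#' @return The filtered tibble.
#' @export
exclude_early_samples <- function(tbl, min_day = 7) {
  if (!"day" %in% names(tbl)) abort("`tbl` must have a `day` column")
  dplyr::filter(tbl, .data$day >= min_day)
}

# Phred+33 string -> integer quality scores
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# integer scores -> Phred+33 string
phred_string <- function(scores) {
  intToUtf8(scores + 33L)
}

# Run `code` under a fixed seed when `seed` is non-NULL, leaving the global
# RNG state untouched; otherwise run as-is.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n random DNA strings of common length len (vectorised: one matrix draw)
random_dna_set <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# n random Phred+33 quality strings of length len with per-base scores
# drawn uniformly from score_range
random_quality_set <- function(n, len, score_range) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(score_range, n * len, replace = TRUE) + 33L, nrow = n)
  apply(m, 1L, intToUtf8, multiple = FALSE)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1) {
    abort(sprintf("`%s` must be a probability in [0, 1)", name))
  }
  invisible(x)
}

check_range01 <- function(r, name) {
  if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) ||
      r[1] > r[2] || r[1] < 0 || r[2] > 1) {
    abort(sprintf("`%s` must be an ordered interval within [0, 1]", name))
  }
  invisible(r)
}

# Total length of the union of 1-based inclusive intervals.
interval_union_length <- function(starts, ends) {
  lo <- pmin(starts, ends)
  hi <- pmax(starts, ends)
  o <- order(lo, hi)
  lo <- lo[o]
  hi <- hi[o]
  total <- 0
  cur_lo <- lo[1]
  cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi + 1) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo + 1)
      cur_lo <- lo[i]
      cur_hi <- hi[i]
    }
  }
  total + (cur_hi - cur_lo + 1)
}
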