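# Diversity and association statistics: Shannon-Wiener evenness, Bray-Curtis
# PCoA ordination, and Spearman antagonism among the most abundant genera.

#' Shannon-Wiener diversity index
#'
#' H = -sum(p_i * ln(p_i)) over nonzero abundances after normalisation;
#' natural logarithm. 0 for a single taxon, ln(k) for k equally abundant
#' taxa.
#'
#' @param p Nonnegative abundance vector with positive sum (one profile row).
#' @return Nonnegative scalar.
#' @export
shannon_wiener <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || all(is.na(p))) abort("abundances must be nonnegative")
  s <- sum(p, na.rm = TRUE)
  if (s <= 0) abort("all-zero profile: diversity undefined")
  p <- p[!is.na(p) & p > 0] / s
  -sum(p * log(p))
}

#' Principal coordinate analysis on Bray-Curtis dissimilarities
#'
#' Computes the Bray-Curtis dissimilarity matrix on relative abundances,
#' then classical PCoA (double centering and eigendecomposition). Axes are
#' ordered by descending eigenvalue; axes with negative eigenvalues are
#' reported in `eigenvalues` but carry no coordinates.
#'
#' @param profiles Wide genus table (>= 3 samples) with optional metadata
#'   columns, which are carried through to the scores.
#' @return A `pcoa_ordination` object: list with `scores` (tibble:
#'   `sample_id`, metadata, `Axis1`, `Axis2`, ...), `eigenvalues`, and
#'   `distances` (the `dist` object).
#' @export
bray_curtis_pcoa <- function(profiles) {
  m <- abundance_matrix(profiles)
  if (nrow(m) < 3L) abort("PCoA requires at least 3 samples")
  d <- vegan::vegdist(m, method = "bray")
  fit <- suppressWarnings(cmdscale(d, k = nrow(m) - 1L, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) == 0L) {
    # all samples identical: zero dissimilarity everywhere
    pts <- matrix(0, nrow = nrow(m), ncol = 1L)
    rownames(pts) <- rownames(m)
  }
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  meta <- profiles[, intersect(META_COLS, names(profiles)), drop = FALSE]
  structure(
    list(
      scores = dplyr::bind_cols(meta, as_tibble(pts)),
      eigenvalues = fit$eig,
      distances = d
    ),
    class = "pcoa_ordination"
  )
}

#' @method tidy pcoa_ordination
#' @export
tidy.pcoa_ordination <- function(x, ...) x$scores

#' @method glance pcoa_ordination
#' @export
glance.pcoa_ordination <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble(
    n_samples = nrow(x$scores),
    n_positive_axes = length(pos),
    var_explained_axis1 = pos[1] / sum(pos),
    var_explained_axis2 = if (length(pos) >= 2L) pos[2] / sum(pos) else NA_real_
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Bray-Curtis PCoA: %d samples, %d positive axes (Axis1 %.1f%%, Axis2 %s)\n",
    g$n_samples, g$n_positive_axes, 100 * g$var_explained_axis1,
    if (is.na(g$var_explained_axis2)) "-"
    else sprintf("%.1f%%", 100 * g$var_explained_axis2)
  ))
  invisible(x)
}

#' Spearman correlation among the most abundant genera
#'
#' Restricts the table to the `top_n` genera by mean relative abundance and
#' returns their Spearman rank-correlation matrix (average ranks for ties).
#' Strongly negative coefficients indicate candidate antagonistic genus
#' pairs. Constant genera have undefined correlation, reported as `NA`.
#'
#' @param profiles Wide genus table with >= 3 samples.
#' @param top_n Number of most abundant genera to keep (default 30).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
spearman_antagonism <- function(profiles, top_n = 30) {
  m <- abundance_matrix(profiles)
  if (nrow(m) < 3L) abort("requires at least 3 samples")
  keep <- names(sort(colMeans(m), decreasing = TRUE))
  keep <- utils::head(keep, top_n)
  m <- m[, keep, drop = FALSE]
  rho <- suppressWarnings(cor(m, method = "spearman"))
  diag(rho) <- 1
  rho
}
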