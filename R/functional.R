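# Functional profiling: quorum-sensing and antibiotic-resistance annotation
# rules, the tenfold KEGG marker-gene rule, and per-sample summaries.

#' Annotate genes against the quorum-sensing reference
#'
#' A hit is effective iff its bit score is at least `min_score` (default 60)
#' and its E-value is below `max_evalue` (default 1e-5). Each gene takes the
#' group of its best surviving hit (highest score; ties broken by lower
#' E-value, then lexicographic label). Genes with no surviving hit are left
#' unannotated (absent from the result).
#'
#' @param hits Tibble with `gene_id`, `label` (one of the eight
#'   [qs_groups()]), `score`, `evalue`.
#' @param min_score,max_evalue Effective-hit thresholds.
#' @return Tibble `gene_id`, `qs_group`, `score`, `evalue`.
#' @export
annotate_qs <- function(hits, min_score = 60, max_evalue = 1e-5) {
  hits |>
    filter(.data$score >= min_score, .data$evalue < max_evalue) |>
    arrange(.data$gene_id, desc(.data$score), .data$evalue, .data$label) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", qs_group = "label", "score", "evalue")
}

#' Annotate genes with antibiotic-resistance types
#'
#' A hit is valid iff its identity is at least `min_identity` (default 0.80).
#' The best valid hit (highest identity; ties by lower E-value when present,
#' then lexicographic label) assigns its resistance type.
#'
#' @param hits Tibble with `gene_id`, `label` (resistance type, e.g.
#'   `"baca"`), `identity` (fraction) and optionally `evalue`.
#' @param min_identity Validity threshold (default 0.80).
#' @return Tibble `gene_id`, `ar_type`, `identity`.
#' @export
annotate_ar <- function(hits, min_identity = 0.80) {
  if (!"evalue" %in% names(hits)) hits$evalue <- NA_real_
  hits |>
    filter(.data$identity >= min_identity) |>
    arrange(.data$gene_id, desc(.data$identity), .data$evalue, .data$label) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", ar_type = "label", "identity")
}

#' Tenfold between-sample marker genes
#'
#' A gene is significantly more abundant in one sample than in another iff
#' its abundance there is at least `fold` (default 10) times the other
#' sample's. A gene absent from one sample counts as enriched in the other
#' when its abundance reaches `zero_floor` (default: `fold` times the
#' smallest nonzero abundance in the table).
#'
#' @param abundance Wide gene table: `gene_id` plus one abundance column per
#'   sample.
#' @param sample_a,sample_b Column names of the two samples to compare.
#' @param fold Fold threshold, > 1.
#' @param zero_floor Absent-vs-present enrichment floor; see above.
#' @return Tibble `gene_id`, `enriched_in` (sample name), `abundance_a`,
#'   `abundance_b`, `ratio` (`Inf` against a zero denominator).
#' @export
kegg_marker_genes <- function(abundance, sample_a, sample_b, fold = 10,
                              zero_floor = NULL) {
  if (fold <= 1) abort("`fold` must be > 1")
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(abundance)) abort(sprintf("sample `%s` not in table", s))
  }
  a <- abundance[[sample_a]]
  b <- abundance[[sample_b]]
  if (is.null(zero_floor)) {
    nz <- c(a[a > 0], b[b > 0])
    zero_floor <- if (length(nz) > 0L) fold * min(nz) else Inf
  }
  in_a <- (b > 0 & a >= fold * b) | (b == 0 & a >= zero_floor)
  in_b <- (a > 0 & b >= fold * a) | (a == 0 & b >= zero_floor)
  tibble(
    gene_id = abundance$gene_id[in_a | in_b],
    enriched_in = ifelse(in_a[in_a | in_b], sample_a, sample_b),
    abundance_a = a[in_a | in_b],
    abundance_b = b[in_a | in_b],
    ratio = ifelse(in_a[in_a | in_b],
                   ifelse(b[in_a | in_b] > 0, a[in_a | in_b] / b[in_a | in_b], Inf),
                   ifelse(a[in_a | in_b] > 0, b[in_a | in_b] / a[in_a | in_b], Inf))
  ) |>
    arrange(.data$gene_id)
}

#' Per-sample functional summary of annotated genes
#'
#' For every sample and functional label: the number of annotated genes
#' present (abundance > 0) and their summed relative abundance. Sample
#' metadata (batch, day) can be joined in for trend plots across the
#' fermentation course.
#'
#' @param annotations Tibble with `gene_id` and a label column (its second
#'   column is used, e.g. `qs_group` or `ar_type`).
#' @param abundance Wide gene table: `gene_id` + one column per sample.
#' @param metadata Optional tibble with `sample_id` (+ `batch`, `day`, ...)
#'   joined onto the result.
#' @return Tibble `sample_id`, `label`, `n_genes`, `total_abundance`
#'   (plus metadata columns).
#' @export
functional_summary <- function(annotations, abundance, metadata = NULL) {
  label_col <- names(annotations)[2]
  ann <- select(annotations, "gene_id", label = all_of(label_col))
  long <- abundance |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "abundance") |>
    inner_join(ann, by = "gene_id")
  out <- long |>
    group_by(.data$sample_id, .data$label) |>
    summarise(n_genes = sum(.data$abundance > 0),
              total_abundance = sum(.data$abundance), .groups = "drop")
  if (!is.null(metadata)) {
    out <- left_join(out, metadata, by = "sample_id")
  }
  out
}

#' Packaged miniature quorum-sensing reference
#'
#' A small synthetic stand-in for a curated QS protein reference: protein
#' ids with one of the eight functional groups. Real analyses should supply
#' their own labelled reference; this one exists so the annotation rules can
#' be exercised and tested.
#'
#' @return Tibble `protein_id`, `qs_group`.
#' @export
qs_reference <- function() {
  readr::read_tsv(
    system.file("extdata", "qs_reference_synthetic.tsv", package = "fermeta"),
    show_col_types = FALSE
  )
}
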