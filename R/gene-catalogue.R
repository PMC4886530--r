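# Non-redundant gene catalogues and length-normalised gene abundance.

#' Dereplicate a CDS set into a non-redundant gene catalogue
#'
#' Greedy longest-first dereplication: genes are processed by descending
#' length (ties by lexicographic sequence, then id); a gene is redundant and
#' dropped iff it aligns to an already retained gene with identity >= 95%
#' and coverage of the shorter sequence >= 90% (ends-free alignment,
#' CD-HIT-style shorter-sequence coverage). When a `domain` column is
#' present, bacterial and fungal sets are dereplicated separately and then
#' merged, mirroring how the bacterial and fungal CDS catalogues are built
#' before merging into one.
#'
#' @param genes Tibble with `gene_id`, `sequence` and optionally `domain`.
#' @param identity_threshold Redundancy identity (default 0.95).
#' @param coverage_threshold Coverage of the shorter sequence (default 0.90).
#' @return The retained rows, with a `length` column added.
#' @export
dereplicate_genes <- function(genes, identity_threshold = 0.95,
                              coverage_threshold = 0.90) {
  derep_one <- function(tbl) {
    tbl <- tbl |>
      mutate(length = nchar(.data$sequence)) |>
      arrange(desc(.data$length), .data$sequence, .data$gene_id)
    keep <- logical(nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      redundant <- FALSE
      for (j in which(keep)) {
        st <- overlap_identity_coverage(tbl$sequence[i], tbl$sequence[j])
        if (st["identity"] >= identity_threshold &&
            st["coverage"] >= coverage_threshold) {
          redundant <- TRUE
          break
        }
      }
      keep[i] <- !redundant
    }
    tbl[keep, , drop = FALSE]
  }
  if ("domain" %in% names(genes)) {
    genes |>
      group_by(.data$domain) |>
      dplyr::group_split() |>
      purrr::map_dfr(derep_one)
  } else {
    derep_one(genes)
  }
}

#' Length-normalised gene abundance from paired-read alignments
#'
#' Mirrors the species valid-hit rule at gene level: a pair counts for gene
#' g iff both mates hit g; pairs hitting several genes are ambiguous and
#' discarded (or fractionally split). Abundance of g is
#' (count / length) renormalised to sum to 1 per sample.
#'
#' @param alignments m8 tibble of read hits against the transcript catalogue
#'   (`query` = `<pair_id>/1` or `/2`, `subject` = gene id).
#' @param gene_lengths Tibble `gene_id`, `length` covering every hit gene.
#' @param pairs Optional tibble `pair_id`, `sample_id`; without it all pairs
#'   are attributed to sample `"S1"`.
#' @param ambiguous `"discard"` or `"fractional"`.
#' @return Tibble `sample_id`, `gene_id`, `count`, `length`, `abundance`;
#'   a sample with no valid pair at all is an error.
#' @export
gene_abundance <- function(alignments, gene_lengths, pairs = NULL,
                           ambiguous = c("discard", "fractional")) {
  ambiguous <- match.arg(ambiguous)
  q <- split_read_query(alignments$query)
  hits <- tibble(pair_id = q$pair_id, mate = q$mate,
                 gene_id = alignments$subject) |> distinct()
  both <- inner_join(
    filter(hits, .data$mate == "1"),
    filter(hits, .data$mate == "2"),
    by = c("pair_id", "gene_id")
  ) |>
    distinct(.data$pair_id, .data$gene_id) |>
    group_by(.data$pair_id) |>
    mutate(n_genes = dplyr::n()) |>
    ungroup()
  if (ambiguous == "discard") {
    both <- filter(both, .data$n_genes == 1L) |> mutate(weight = 1)
  } else {
    both <- mutate(both, weight = 1 / .data$n_genes)
  }
  if (nrow(both) == 0L) abort("no valid gene pairs: abundance undefined")
  if (is.null(pairs)) {
    both$sample_id <- "S1"
  } else {
    both <- left_join(both, select(pairs, "pair_id", "sample_id"),
                      by = "pair_id")
  }
  missing <- setdiff(unique(both$gene_id), gene_lengths$gene_id)
  if (length(missing) > 0L) {
    abort(paste0("no length for gene(s): ", paste(missing, collapse = ", ")))
  }
  both |>
    group_by(.data$sample_id, .data$gene_id) |>
    summarise(count = sum(.data$weight), .groups = "drop") |>
    left_join(gene_lengths, by = "gene_id") |>
    group_by(.data$sample_id) |>
    mutate(abundance = (.data$count / .data$length) /
             sum(.data$count / .data$length)) |>
    ungroup()
}
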