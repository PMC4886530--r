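# Amplicon tag quality control and exact dereplication.

#' Quality-filter amplicon tags
#'
#' A tag is kept iff its length falls in the marker window (350-500 bp for
#' 16S, 300-420 bp for ITS), its mean Phred score is at least 20, and it
#' carries at most 3 ambiguous N bases. Input order is preserved.
#'
#' @param tags Tibble with `sequence` and `quality` (Phred+33) columns, as
#'   from [simulate_tags()] or [read_tags_fastq()].
#' @param marker `"16S"` or `"ITS"`.
#' @param min_mean_phred Mean base-quality floor (default 20).
#' @param max_n Maximum ambiguous N count (default 3).
#' @return The retained rows of `tags`.
#' @export
qc_filter_tags <- function(tags, marker = "16S", min_mean_phred = 20,
                           max_n = 3) {
  check_marker(marker)
  if (nrow(tags) == 0L) return(tags)
  win <- MARKER_WINDOWS[[marker]]
  len <- nchar(tags$sequence)
  n_count <- nchar(tags$sequence) - nchar(gsub("N", "", tags$sequence,
                                               fixed = TRUE))
  mean_q <- vapply(phred_scores(tags$quality), mean, numeric(1))
  keep <- len >= win[1] & len <= win[2] & mean_q >= min_mean_phred &
    n_count <= max_n
  tags[keep, , drop = FALSE]
}

#' Dereplicate tags into unique sequences with counts
#'
#' Exact-sequence dereplication over all samples. Sequences seen only once
#' are flagged as singletons: they are excluded from OTU clustering (only
#' tags with frequency above 1 are considered reliable enough to seed OTUs)
#' but remain available for the later tag-mapping step.
#'
#' @param tags Tibble with a `sequence` column.
#' @return Tibble with `sequence`, `count`, `singleton` (logical), sorted by
#'   descending count then sequence.
#' @export
dereplicate_tags <- function(tags) {
  tags |>
    count(.data$sequence, name = "count") |>
    mutate(singleton = .data$count == 1L) |>
    arrange(desc(.data$count), .data$sequence)
}
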