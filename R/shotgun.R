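# Shotgun read QC, cereal decontamination, paired valid-hit species
# assignment and gap-adjusted abundance estimation.

# per-mate QC statistics from a quality string
mate_qc <- function(qual, seq, quality_floor) {
  q <- utf8ToInt(qual) - 33L
  n_count <- sum(strsplit(seq, "", fixed = TRUE)[[1]] == "N")
  highq <- q >= quality_floor
  trim_to <- if (any(highq)) max(which(highq)) else 0L
  c(n_count = n_count, highq_frac = mean(highq), trim_to = trim_to)
}

#' Quality-filter and 3'-trim shotgun read pairs
#'
#' Per mate, in order: (1) drop if it has more than `max_n` ambiguous N
#' bases; (2) drop if fewer than `min_highq_frac` of its bases reach Phred
#' `quality_floor` (default Q20); (3) trim the 3' end back to the last base
#' with quality at or above the floor. The whole pair is discarded if either
#' mate was dropped or either trimmed mate is shorter than `min_length`.
#'
#' @param pairs Tibble with `pair_id`, `seq1`, `qual1`, `seq2`, `qual2` (and
#'   any metadata columns, carried through).
#' @param max_n Maximum N count per mate (default 3).
#' @param min_highq_frac Minimum fraction of high-quality bases (default 0.6).
#' @param quality_floor Phred score defining a high-quality base (default 20).
#' @param min_length Minimum post-trim mate length (default 30 bp).
#' @return List with `pairs` (retained rows, sequences/qualities trimmed)
#'   and `removed` (tibble of per-rule discarded-pair counts; a pair is
#'   attributed to the first rule that hit it).
#' @export
qc_filter_pairs <- function(pairs, max_n = 3, min_highq_frac = 0.6,
                            quality_floor = 20, min_length = 30) {
  if (nrow(pairs) == 0L) {
    return(list(pairs = pairs,
                removed = tibble(rule = character(0), pairs_removed = integer(0))))
  }
  s1 <- t(mapply(mate_qc, pairs$qual1, pairs$seq1,
                 MoreArgs = list(quality_floor = quality_floor)))
  s2 <- t(mapply(mate_qc, pairs$qual2, pairs$seq2,
                 MoreArgs = list(quality_floor = quality_floor)))
  fail_n <- s1[, "n_count"] > max_n | s2[, "n_count"] > max_n
  fail_q <- s1[, "highq_frac"] < min_highq_frac |
    s2[, "highq_frac"] < min_highq_frac
  fail_trim <- s1[, "trim_to"] < min_length | s2[, "trim_to"] < min_length
  drop <- fail_n | fail_q | fail_trim
  removed <- tibble(
    rule = c("too_many_n", "low_quality_fraction", "short_after_trim"),
    pairs_removed = c(sum(fail_n),
                      sum(fail_q & !fail_n),
                      sum(fail_trim & !fail_n & !fail_q))
  )
  kept <- pairs[!drop, , drop = FALSE]
  t1 <- s1[!drop, "trim_to"]
  t2 <- s2[!drop, "trim_to"]
  kept$seq1 <- substr(kept$seq1, 1L, t1)
  kept$qual1 <- substr(kept$qual1, 1L, t1)
  kept$seq2 <- substr(kept$seq2, 1L, t2)
  kept$qual2 <- substr(kept$qual2, 1L, t2)
  list(pairs = kept, removed = removed)
}

# query names follow the <pair_id>/1, <pair_id>/2 convention
split_read_query <- function(query) {
  tibble(pair_id = sub("/[12]$", "", query),
         mate = sub("^.*/", "", query))
}

split_subject <- function(subject) {
  ok <- grepl("|", subject, fixed = TRUE)
  if (!all(ok)) {
    abort(paste0("malformed contig name (expected <genome>|<contig>): ",
                 paste(utils::head(unique(subject[!ok])), collapse = ", ")))
  }
  tibble(genome = sub("\\|.*$", "", subject),
         contig = subject)
}

#' Remove read pairs with any hit to a cereal genome
#'
#' Cereal DNA co-extracts with fungal DNA, so any pair in which either mate
#' hits any cereal genome is removed wholesale (the mate drags its partner
#' out with it).
#'
#' @param pairs Tibble with `pair_id`.
#' @param alignments m8 tibble of read hits against cereal genomes (`query`
#'   is `<pair_id>/1` or `/2`). A query naming an unknown pair is an error.
#' @return The retained rows of `pairs`.
#' @export
remove_cereal_pairs <- function(pairs, alignments) {
  if (nrow(alignments) == 0L) return(pairs)
  q <- split_read_query(alignments$query)
  unknown <- setdiff(unique(q$pair_id), pairs$pair_id)
  if (length(unknown) > 0L) {
    abort(paste0("alignment references unknown read pair(s): ",
                 paste(utils::head(unknown), collapse = ", ")))
  }
  pairs[!pairs$pair_id %in% q$pair_id, , drop = FALSE]
}

#' Count valid same-contig paired hits per genome
#'
#' A pair contributes one valid hit to genome G iff some contig of G is hit
#' by both mates. Pairs valid for more than one genome are ambiguous and are
#' discarded by default (`ambiguous = "discard"`); `"fractional"` instead
#' splits the pair equally across its candidate genomes.
#'
#' @param pairs Tibble with `pair_id` and `sample_id`.
#' @param alignments m8 tibble of read hits against microbial genome contigs
#'   named `<genome>|<contig>`.
#' @param ambiguous `"discard"` or `"fractional"`.
#' @return Tibble `sample_id`, `genome`, `valid_hits`.
#' @export
assign_species <- function(pairs, alignments,
                           ambiguous = c("discard", "fractional")) {
  ambiguous <- match.arg(ambiguous)
  q <- split_read_query(alignments$query)
  s <- split_subject(alignments$subject)
  hits <- tibble(pair_id = q$pair_id, mate = q$mate,
                 genome = s$genome, contig = s$contig) |> distinct()
  both <- inner_join(
    filter(hits, .data$mate == "1"),
    filter(hits, .data$mate == "2"),
    by = c("pair_id", "genome", "contig")
  ) |>
    distinct(.data$pair_id, .data$genome)
  per_pair <- both |>
    group_by(.data$pair_id) |>
    mutate(n_genomes = n_distinct(.data$genome)) |>
    ungroup()
  if (ambiguous == "discard") {
    per_pair <- filter(per_pair, .data$n_genomes == 1L) |>
      mutate(weight = 1)
  } else {
    per_pair <- mutate(per_pair, weight = 1 / .data$n_genomes)
  }
  per_pair |>
    left_join(select(pairs, "pair_id", "sample_id"), by = "pair_id") |>
    group_by(.data$sample_id, .data$genome) |>
    summarise(valid_hits = sum(.data$weight), .groups = "drop")
}

#' Gap-adjusted genome length
#'
#' Assembled reference genomes contain scaffold gaps whose true span is
#' unknown; for abundance normalisation each genome length is the sum of its
#' contig lengths minus gap count times the mean library insert size
#' (default 350 bp).
#'
#' @param genome A [genome_spec()].
#' @param average_insert Mean insert size in bp (default 350).
#' @return Adjusted length in bp; an adjusted length <= 0 is an error
#'   (degenerate genome model).
#' @export
adjusted_genome_length <- function(genome, average_insert = 350) {
  stopifnot(inherits(genome, "genome_spec"))
  l <- sum(genome$contig_lengths) - genome$gap_count * average_insert
  if (l <= 0) {
    abort(sprintf("adjusted length of %s is %d (<= 0): degenerate genome model",
                  genome$name, as.integer(l)))
  }
  l
}

#' Adjusted lengths for a list of genomes
#'
#' @param genomes List of [genome_spec()] objects.
#' @inheritParams adjusted_genome_length
#' @return Tibble `genome`, `adjusted_length`.
#' @export
adjusted_genome_lengths <- function(genomes, average_insert = 350) {
  tibble(
    genome = vapply(genomes, `[[`, character(1), "name"),
    adjusted_length = vapply(genomes, adjusted_genome_length, numeric(1),
                             average_insert = average_insert)
  )
}

#' Length-normalised species relative abundance
#'
#' For each sample, abundance of genome G is (valid hits / adjusted length)
#' renormalised to sum to 1 over all genomes; genomes with zero hits get 0.
#'
#' @param counts Tibble `sample_id`, `genome`, `valid_hits`, as from
#'   [assign_species()].
#' @param lengths Tibble `genome`, `adjusted_length` covering every counted
#'   genome (extra genomes are reported with abundance 0).
#' @return Tibble `sample_id`, `genome`, `valid_hits`, `adjusted_length`,
#'   `abundance`.
#' @export
species_abundance <- function(counts, lengths) {
  missing <- setdiff(counts$genome, lengths$genome)
  if (length(missing) > 0L) {
    abort(paste0("no adjusted length for genome(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(counts) == 0L || all(counts$valid_hits == 0)) {
    abort("all valid-hit counts are zero")
  }
  tidyr::crossing(sample_id = unique(counts$sample_id),
                  genome = lengths$genome) |>
    left_join(counts, by = c("sample_id", "genome")) |>
    mutate(valid_hits = dplyr::coalesce(.data$valid_hits, 0)) |>
    left_join(lengths, by = "genome") |>
    group_by(.data$sample_id) |>
    mutate(abundance = (.data$valid_hits / .data$adjusted_length) /
             sum(.data$valid_hits / .data$adjusted_length)) |>
    ungroup()
}
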