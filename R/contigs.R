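# Post-assembly contig handling: scaffold splitting at Ns, length filtering,
# N50-based assembly selection, cereal-contig removal and the three-step
# bacteria/fungi domain classifier.

#' Cut scaffolds at ambiguous bases and length-filter the pieces
#'
#' Scaffolds are split on maximal runs of one or more `N`; only pieces
#' strictly longer than `min_length` (default 500 bp) are kept. Piece ids
#' are the scaffold id suffixed with the piece index (counted over all
#' pieces of the scaffold, kept or not).
#'
#' @param scaffolds Tibble with `id` and `sequence`, or a named character
#'   vector.
#' @param min_length Strict length cutoff in bp (default 500).
#' @return Tibble `contig_id`, `scaffold_id`, `sequence`, `length`.
#' @export
split_and_filter <- function(scaffolds, min_length = 500) {
  if (!is.data.frame(scaffolds)) {
    scaffolds <- tibble(id = names(scaffolds), sequence = unname(scaffolds))
  }
  purrr::map2_dfr(scaffolds$id, scaffolds$sequence, function(id, s) {
    pieces <- strsplit(s, "N+")[[1]]
    pieces <- pieces[pieces != ""]
    if (length(pieces) == 0L) return(NULL)
    tibble(
      contig_id = sprintf("%s_%d", id, seq_along(pieces)),
      scaffold_id = id, sequence = pieces, length = nchar(pieces)
    )
  }) |>
    filter(.data$length > min_length)
}

#' N50 of a contig set
#'
#' The smallest contig length L such that contigs of length >= L cover at
#' least half the total assembly length.
#'
#' @param contigs Numeric vector of contig lengths, or a tibble with a
#'   `length` column. Must be non-empty.
#' @return N50 in bp.
#' @export
n50 <- function(contigs) {
  lens <- if (is.data.frame(contigs)) contigs$length else as.numeric(contigs)
  if (length(lens) == 0L) abort("N50 of an empty contig set is undefined")
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Pick the assembly with the largest N50
#'
#' Several k-mer sizes are tried per sample (39 to 59 by 4 in the assembly
#' protocol this mirrors) and only the contigs of the largest-N50 assembly
#' are attributed to the sample. Ties go to the larger total assembly
#' length, then to the smaller k-mer.
#'
#' @param candidates List of assembly candidates, each a list with `kmer`
#'   and either `contigs` (tibble with `length`) or `contig_lengths`.
#' @return The winning candidate, with `n50` and `total_length` added.
#' @export
select_best_assembly <- function(candidates) {
  if (length(candidates) == 0L) abort("no assembly candidates")
  stats <- purrr::map_dfr(candidates, function(cand) {
    lens <- cand$contig_lengths %||% cand$contigs$length
    tibble(kmer = cand$kmer, n50 = n50(lens), total_length = sum(lens))
  })
  best <- stats |>
    mutate(idx = row_number()) |>
    arrange(desc(.data$n50), desc(.data$total_length), .data$kmer) |>
    slice(1)
  out <- candidates[[best$idx]]
  out$n50 <- best$n50
  out$total_length <- best$total_length
  out
}

#' Remove contigs belonging to cereal genomes
#'
#' A contig is removed iff some cereal genome aligns it with coverage >= 90%
#' and identity >= 95%. Coverage is the merged-interval union of aligned
#' query bases divided by contig length; identity is the alignment-length
#' weighted mean over that genome's hits.
#'
#' @param contigs Tibble with `contig_id` and `length` (and optionally
#'   `sequence`).
#' @param alignments m8 tibble of contig hits vs cereal genomes (`query` =
#'   contig id, `subject` = `<genome>|<contig>` or a bare genome name;
#'   identities as fractions).
#' @param min_coverage,min_identity Removal thresholds (defaults 0.90, 0.95).
#' @return List with `contigs` (retained) and `removed` (tibble `contig_id`,
#'   `genome`, `coverage`, `identity`).
#' @export
remove_cereal_contigs <- function(contigs, alignments,
                                  min_coverage = 0.90, min_identity = 0.95) {
  if (nrow(alignments) == 0L) {
    return(list(contigs = contigs,
                removed = tibble(contig_id = character(0),
                                 genome = character(0),
                                 coverage = numeric(0),
                                 identity = numeric(0))))
  }
  genome_of <- sub("\\|.*$", "", alignments$subject)
  per <- alignments |>
    mutate(genome = genome_of) |>
    inner_join(select(contigs, "contig_id", contig_length = "length"),
               by = c(query = "contig_id")) |>
    group_by(contig_id = .data$query, .data$genome) |>
    summarise(
      coverage = interval_union_length(.data$qstart, .data$qend) /
        first(.data$contig_length),
      identity = sum(.data$identity * .data$length) / sum(.data$length),
      .groups = "drop"
    )
  removed <- filter(per, .data$coverage >= min_coverage,
                    .data$identity >= min_identity)
  list(
    contigs = contigs[!contigs$contig_id %in% removed$contig_id, , drop = FALSE],
    removed = removed
  )
}

#' Classify a contig as bacterial or fungal
#'
#' Three-step procedure over precomputed gene and alignment evidence:
#' \enumerate{
#'   \item If the contig's genes are predictable by exactly one of the two
#'     gene predictors (fungal vs bacterial), it takes that predictor's
#'     domain.
#'   \item Otherwise genome alignments decide: among hits with
#'     (coverage >= 90% and identity >= 95%) or (overlap > 100 bp and
#'     identity >= 95%), the highest bit score wins and assigns its domain.
#'   \item Otherwise protein (NR) annotations vote: among genes with a
#'     domain label at E-value < 1e-10, if one domain reaches at least 40%
#'     of the vote base and is the unique maximum, it wins; a tie at the
#'     maximum (or no domain reaching 40%) falls back to the higher mean
#'     m8 bit score per domain. No usable evidence gives `"unclassified"`.
#' }
#'
#' @param genes Tibble of the contig's genes: `gene_id`, `predictable_by`
#'   (comma-separated subset of `bacterial_predictor`, `fungal_predictor`),
#'   `nr_domain` (`"bacteria"`, `"fungi"` or `NA`), `nr_evalue`, `m8_score`.
#' @param genome_hits Optional tibble of contig-vs-genome hits: `domain`,
#'   `identity`, `coverage`, `overlap`, `bitscore`.
#' @param vote_threshold Step-3 voting floor (default 0.4).
#' @param vote_base `"labeled"` (default): the 40% is taken over genes with a
#'   valid NR label; `"all"`: over all genes of the contig.
#' @param nr_evalue_max Validity cutoff for NR labels (default 1e-10).
#' @return `"bacteria"`, `"fungi"` or `"unclassified"`.
#' @export
classify_contig_domain <- function(genes, genome_hits = NULL,
                                   vote_threshold = 0.4,
                                   vote_base = c("labeled", "all"),
                                   nr_evalue_max = 1e-10) {
  vote_base <- match.arg(vote_base)
  predictor_domain <- c(bacterial_predictor = "bacteria",
                        fungal_predictor = "fungi")

  # step 1: predictability by exactly one gene predictor
  if (!is.null(genes) && nrow(genes) > 0L) {
    preds <- unique(unlist(strsplit(
      genes$predictable_by[!is.na(genes$predictable_by)], ",", fixed = TRUE
    )))
    preds <- trimws(preds)
    preds <- preds[preds != ""]
    if (length(preds) == 1L && preds %in% names(predictor_domain)) {
      return(unname(predictor_domain[preds]))
    }
  }

  # step 2: qualifying genome alignment with the best bit score
  if (!is.null(genome_hits) && nrow(genome_hits) > 0L) {
    ok <- genome_hits |>
      filter(.data$identity >= 0.95,
             (.data$coverage >= 0.90) | (.data$overlap > 100))
    if (nrow(ok) > 0L) {
      return(ok$domain[which.max(ok$bitscore)])
    }
  }

  # step 3: NR domain voting with mean-score tie-break
  if (is.null(genes) || nrow(genes) == 0L) return("unclassified")
  labeled <- filter(genes, !is.na(.data$nr_domain),
                    .data$nr_domain %in% c("bacteria", "fungi"),
                    !is.na(.data$nr_evalue), .data$nr_evalue < nr_evalue_max)
  if (nrow(labeled) == 0L) return("unclassified")
  denom <- if (vote_base == "labeled") nrow(labeled) else nrow(genes)
  frac <- table(labeled$nr_domain) / denom
  top <- names(frac)[frac == max(frac)]
  if (length(top) == 1L && max(frac) >= vote_threshold) return(top)
  # ambiguous: better average m8 score decides
  means <- labeled |>
    filter(!is.na(.data$m8_score)) |>
    group_by(.data$nr_domain) |>
    summarise(mean_score = mean(.data$m8_score), .groups = "drop")
  if (nrow(means) == 0L) return("unclassified")
  means$nr_domain[which.max(means$mean_score)]
}

#' Classify many contigs at once
#'
#' @param gene_evidence Tibble with a `contig_id` column plus the per-gene
#'   columns of [classify_contig_domain()].
#' @param genome_hits Optional tibble with a `contig_id` column plus the hit
#'   columns of [classify_contig_domain()].
#' @param ... Passed on to [classify_contig_domain()].
#' @return Tibble `contig_id`, `domain`.
#' @export
classify_contigs <- function(gene_evidence, genome_hits = NULL, ...) {
  ids <- unique(c(gene_evidence$contig_id, genome_hits$contig_id))
  purrr::map_dfr(ids, function(id) {
    g <- filter(gene_evidence, .data$contig_id == id)
    h <- if (is.null(genome_hits)) NULL else
      filter(genome_hits, .data$contig_id == id)
    tibble(contig_id = id,
           domain = classify_contig_domain(g, h, ...))
  })
}
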