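# Synthetic shotgun sequencing: reference genome models, paired reads with
# ~350 bp inserts, truth labels, and emitted m8-style alignment records.

#' Describe a reference genome model
#'
#' A genome is an ordered set of contigs with a scaffold gap count and a
#' domain label. Gap counts matter because abundance normalisation uses the
#' gap-adjusted genome length (see [adjusted_genome_length()]).
#'
#' @param name Genome identifier (no `|` characters; contig records are named
#'   `<genome>|<contig>`).
#' @param domain One of `"bacteria"`, `"fungi"`, `"cereal"`.
#' @param contig_lengths Positive integer vector of contig lengths (bp).
#' @param gap_count Number of scaffold gaps, >= 0.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(name, domain, contig_lengths, gap_count = 0L) {
  domain <- match.arg(domain, c("bacteria", "fungi", "cereal"))
  if (grepl("|", name, fixed = TRUE)) abort("genome `name` must not contain '|'")
  if (length(contig_lengths) == 0L || any(contig_lengths <= 0)) {
    abort("`contig_lengths` must all be positive")
  }
  if (gap_count < 0) abort("`gap_count` must be >= 0")
  structure(
    list(name = name, domain = domain,
         contig_lengths = as.integer(contig_lengths),
         gap_count = as.integer(gap_count)),
    class = "genome_spec"
  )
}

#' Simulate paired-end shotgun reads over a genome mixture
#'
#' Pairs are assigned to genomes with probability proportional to
#' `mixture x total genome length` (read yield scales with both how abundant
#' a genome is and how much sequence it has), then to contigs proportional to
#' contig length. Insert sizes are normal around `insert_mean` (default
#' 350 bp), floored at the read length and capped at the contig length.
#' Alignment records place both mates on the true source contig; an optional
#' `decoy_rate` fraction of pairs additionally gets a spurious single-mate
#' hit on a random other contig, exercising the valid-hit filter.
#'
#' @param genomes List of [genome_spec()] objects.
#' @param mixture Relative genome abundances, same length as `genomes`,
#'   summing to 1.
#' @param n_pairs Number of read pairs.
#' @param insert_mean,insert_sd Insert-size distribution (bp).
#' @param read_length Read length (bp), default 125 (paired-end 125).
#' @param decoy_rate Fraction of pairs receiving a decoy hit.
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return List with tibbles `pairs` (`pair_id`, `sample_id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`), `truth` (`pair_id`, `source_genome`,
#'   `source_contig`, `insert_size`) and `alignments` (m8 columns; mate reads
#'   named `<pair_id>/1` and `<pair_id>/2`, subjects `<genome>|<contig>`).
#' @export
simulate_shotgun <- function(genomes, mixture, n_pairs,
                             insert_mean = 350, insert_sd = 35,
                             read_length = 125L, decoy_rate = 0,
                             sample_id = "S1", seed = 1L) {
  if (!all(vapply(genomes, inherits, logical(1), "genome_spec"))) {
    abort("`genomes` must be a list of genome_spec objects")
  }
  if (length(mixture) != length(genomes)) {
    abort("`mixture` must have one entry per genome")
  }
  if (abs(sum(mixture) - 1) > 1e-8) abort("`mixture` must sum to 1")
  if (n_pairs <= 0) abort("`n_pairs` must be positive")
  check_probability(decoy_rate, "decoy_rate")

  gnames <- vapply(genomes, `[[`, character(1), "name")
  glens <- vapply(genomes, function(g) sum(g$contig_lengths), numeric(1))
  contig_tbl <- purrr::map_dfr(genomes, function(g) {
    tibble(genome = g$name,
           contig = sprintf("c%02d", seq_along(g$contig_lengths)),
           length = g$contig_lengths)
  })

  with_seed_maybe(seed, {
    gi <- sample.int(length(genomes), n_pairs, replace = TRUE,
                     prob = mixture * glens)
    # contig within genome, proportional to contig length (vectorised per genome)
    ci <- integer(n_pairs)
    for (k in seq_along(genomes)) {
      idx <- which(gi == k)
      if (length(idx) == 0L) next
      lens <- genomes[[k]]$contig_lengths
      ci[idx] <- if (length(lens) == 1L) 1L else
        sample.int(length(lens), length(idx), replace = TRUE, prob = lens)
    }
    lens_flat <- unlist(lapply(genomes, `[[`, "contig_lengths"))
    offsets <- cumsum(c(0L, vapply(genomes, function(g)
      length(g$contig_lengths), integer(1))))
    src <- tibble(
      genome = gnames[gi],
      contig = sprintf("c%02d", ci),
      contig_length = lens_flat[offsets[gi] + ci]
    )
    insert <- pmax(read_length,
                   round(rnorm(n_pairs, insert_mean, insert_sd)))
    insert <- pmin(insert, src$contig_length)
    start <- floor(runif(n_pairs) * (src$contig_length - insert + 1)) + 1
    end <- start + insert - 1

    pair_id <- sprintf("%s_p%06d", sample_id, seq_len(n_pairs))
    pairs <- tibble(
      pair_id = pair_id, sample_id = sample_id,
      seq1 = random_dna_set(n_pairs, read_length),
      qual1 = random_quality_set(n_pairs, read_length, 30:40),
      seq2 = random_dna_set(n_pairs, read_length),
      qual2 = random_quality_set(n_pairs, read_length, 30:40)
    )
    truth <- tibble(pair_id = pair_id, source_genome = src$genome,
                    source_contig = src$contig, insert_size = insert)

    subj <- paste0(src$genome, "|", src$contig)
    aln <- bind_rows(
      tibble(query = paste0(pair_id, "/1"), subject = subj,
             identity = 1, length = read_length, mismatches = 0L,
             gap_openings = 0L, qstart = 1L, qend = read_length,
             sstart = start, send = pmin(start + read_length - 1, end),
             evalue = 1e-30, bitscore = 2 * read_length),
      tibble(query = paste0(pair_id, "/2"), subject = subj,
             identity = 1, length = read_length, mismatches = 0L,
             gap_openings = 0L, qstart = 1L, qend = read_length,
             # mate 2 is reverse strand: subject coordinates descend
             sstart = end, send = pmax(end - read_length + 1, start),
             evalue = 1e-30, bitscore = 2 * read_length)
    )
    if (decoy_rate > 0 && nrow(contig_tbl) > 1L) {
      hit <- which(runif(n_pairs) < decoy_rate)
      if (length(hit) > 0L) {
        decoys <- purrr::map_dfr(hit, function(i) {
          own <- paste0(src$genome[i], "|", src$contig[i])
          pool <- contig_tbl[paste0(contig_tbl$genome, "|",
                                    contig_tbl$contig) != own, ]
          d <- pool[sample.int(nrow(pool), 1L), ]
          dstart <- floor(runif(1) * max(1, d$length - read_length + 1)) + 1
          tibble(query = paste0(pair_id[i], "/1"),
                 subject = paste0(d$genome, "|", d$contig),
                 identity = 0.9, length = read_length, mismatches = 12L,
                 gap_openings = 0L, qstart = 1L, qend = read_length,
                 sstart = dstart,
                 send = min(dstart + read_length - 1, d$length),
                 evalue = 1e-10, bitscore = 100)
        })
        aln <- bind_rows(aln, decoys)
      }
    }
    list(pairs = pairs, truth = truth,
         alignments = arrange(aln, .data$query))
  })
}

#' Generate contig sequences for a genome model
#'
#' Random nucleotide sequences of the specified contig lengths, reproducible
#' per seed; records are named `<genome>|<contig>`.
#'
#' @param genome A [genome_spec()].
#' @param seed Integer seed.
#' @return Tibble with `contig_id` and `sequence`.
#' @export
simulate_genome_contigs <- function(genome, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"))
  with_seed_maybe(seed, {
    tibble(
      contig_id = paste0(genome$name, "|",
                         sprintf("c%02d", seq_along(genome$contig_lengths))),
      sequence = vapply(genome$contig_lengths, random_dna, character(1))
    )
  })
}
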