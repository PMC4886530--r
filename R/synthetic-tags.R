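# Synthetic amplicon tag sets with known genus-of-origin, substitution
# noise, planted chimeras and a controllable QC-failing fraction.

MARKER_WINDOWS <- list(`16S` = c(350L, 500L), ITS = c(300L, 420L))
# typical merged-tag lengths: ~420 bp V3-V4 16S amplicons, ~350 bp ITS2
MARKER_TEMPLATE_LEN <- c(`16S` = 420L, ITS = 350L)

check_marker <- function(marker) {
  if (!is.character(marker) || length(marker) != 1L ||
      !marker %in% names(MARKER_WINDOWS)) {
    abort('`marker` must be "16S" or "ITS"')
  }
  marker
}

#' Reference template sequences for a genus vocabulary
#'
#' One random fixed-length template per genus, reproducible per seed. The
#' templates stand in for marker-gene reference sequences: taxonomy travels
#' with the simulated tags as truth labels, so no real rRNA/ITS sequence is
#' needed.
#'
#' @param genus_names Character vector of genera.
#' @param marker `"16S"` or `"ITS"` (sets template length: 420 / 350 bp).
#' @param seed Integer seed.
#' @return Named character vector of templates.
#' @export
genus_templates <- function(genus_names, marker = "16S", seed = 1L) {
  check_marker(marker)
  len <- MARKER_TEMPLATE_LEN[[marker]]
  with_seed_maybe(seed, {
    setNames(random_dna_set(length(genus_names), len), genus_names)
  })
}

#' Simulate amplicon tags from a genus profile
#'
#' Draws `depth` tags whose genus of origin follows the profile, copies the
#' genus template, applies per-base substitution errors, splices a
#' `chimera_rate` fraction from two distinct parent templates (left half of
#' one, right half of the other), and attaches Phred+33 qualities such that
#' a `qc_fail_rate` fraction of tags fails the mean-Q20 criterion.
#'
#' @param profile One row of a genus table (or a named numeric vector of
#'   relative abundances).
#' @param depth Number of tags to draw.
#' @param marker `"16S"` or `"ITS"`.
#' @param error_rate Per-base substitution probability, in `[0, 1)`.
#' @param chimera_rate Fraction of tags that are two-parent splices.
#' @param qc_fail_rate Fraction of tags given low-quality strings.
#' @param sample_id Sample label carried on each tag.
#' @param templates Optional template vector from [genus_templates()]; built
#'   from `seed` when absent.
#' @param seed Integer seed.
#' @return Tibble with `tag_id`, `sample_id`, `sequence`, `quality` and truth
#'   columns `true_genus`, `is_chimera`, `parent_a`, `parent_b`.
#' @export
simulate_tags <- function(profile, depth, marker = "16S", error_rate = 0,
                          chimera_rate = 0, qc_fail_rate = 0,
                          sample_id = "S1", templates = NULL, seed = 1L) {
  check_marker(marker)
  if (depth <= 0) abort("`depth` must be positive")
  check_probability(error_rate, "error_rate")
  check_probability(chimera_rate, "chimera_rate")
  check_probability(qc_fail_rate, "qc_fail_rate")
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1L) abort("`profile` must be a single row")
    p <- unlist(profile[, feature_columns(profile)])
  } else {
    p <- profile
  }
  p <- p[p > 0]
  if (length(p) == 0L) abort("profile has no positive abundances")

  with_seed_maybe(seed, {
    if (is.null(templates)) {
      templates <- genus_templates(names(p), marker,
                                   seed = NULL)
    }
    missing <- setdiff(names(p), names(templates))
    if (length(missing) > 0L) {
      abort(paste0("no template for genus: ", paste(missing, collapse = ", ")))
    }
    len <- nchar(templates[[1]])
    genus <- sample(names(p), depth, replace = TRUE, prob = p)
    seqs <- unname(templates[genus])

    # substitution noise
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        b <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- runif(length(b)) < error_rate
        if (any(hit)) {
          b[hit] <- vapply(b[hit], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1L)
          }, character(1))
        }
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }

    # two-parent midpoint splices
    is_chimera <- runif(depth) < chimera_rate & length(templates) >= 2L
    parent_a <- parent_b <- rep(NA_character_, depth)
    if (any(is_chimera)) {
      half <- len %/% 2L
      for (i in which(is_chimera)) {
        pr <- sample(names(templates), 2L)
        parent_a[i] <- pr[1]
        parent_b[i] <- pr[2]
        seqs[i] <- paste0(substr(templates[[pr[1]]], 1L, half),
                         substr(templates[[pr[2]]], half + 1L, len))
      }
      genus[is_chimera] <- NA_character_
    }

    fails <- runif(depth) < qc_fail_rate
    qual <- character(depth)
    qual[!fails] <- random_quality_set(sum(!fails), len, 30:40)
    qual[fails] <- random_quality_set(sum(fails), len, 5:15)

    tibble(
      tag_id = sprintf("%s_t%06d", sample_id, seq_len(depth)),
      sample_id = sample_id,
      sequence = seqs,
      quality = qual,
      true_genus = genus,
      is_chimera = is_chimera,
      parent_a = parent_a,
      parent_b = parent_b
    )
  })
}
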