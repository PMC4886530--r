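# Synthetic gene-abundance tables with planted tenfold between-sample
# markers and QS / antibiotic-resistance / KEGG label maps.

QS_GROUPS <- c("Autoinducer", "Autoinducer_producer", "Autoinducer_receptor",
               "Decomposer", "Effector", "Regulator", "Transporter", "unclear")

AR_TYPES <- c("baca", "nora", "acrb", "tetm", "ermb", "blaz", "vana")

#' The eight quorum-sensing functional groups
#'
#' Closed vocabulary used by [annotate_qs()] and the synthetic label maps.
#'
#' @return Character vector of length 8.
#' @export
qs_groups <- function() QS_GROUPS

#' Simulate a gene-abundance table with planted tenfold markers
#'
#' Builds an `n_genes x n_samples` relative-abundance table. Between the
#' first two samples, a `marker_fraction` of genes is planted to differ by at
#' least `fold` (half enriched in each sample, boosted 5 x `fold` before
#' column normalisation); all other genes differ by less than `fold`. Each
#' gene also receives a quorum-sensing group, an antibiotic-resistance type
#' and a KEGG ortholog/pathway label so functional profiling can be
#' exercised on known truth.
#'
#' @param n_genes,n_samples Table dimensions (`n_samples >= 2`).
#' @param marker_fraction Fraction of genes planted as markers, in `[0, 1]`.
#' @param fold Marker fold-change threshold, > 1 (default 10).
#' @param seed Integer seed.
#' @return List with `abundance` (wide tibble `gene_id` + one column per
#'   sample, columns summing to 1), `markers` (tibble `gene_id`,
#'   `enriched_in`), and `labels` (tibble `gene_id`, `qs_group`, `ar_type`,
#'   `ko`, `pathway`).
#' @export
simulate_gene_table <- function(n_genes, n_samples = 2, marker_fraction = 0.05,
                                fold = 10, seed = 1L) {
  if (fold <= 1) abort("`fold` must be > 1")
  if (marker_fraction < 0 || marker_fraction > 1) {
    abort("`marker_fraction` must be in [0, 1]")
  }
  if (n_samples < 2) abort("`n_samples` must be >= 2")
  sample_ids <- sprintf("S%d", seq_len(n_samples))
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))

  with_seed_maybe(seed, {
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    # mild per-sample noise, far below the marker fold threshold
    m <- vapply(seq_len(n_samples), function(j) {
      base * exp(rnorm(n_genes, 0, 0.15))
    }, numeric(n_genes))
    n_markers <- round(marker_fraction * n_genes)
    markers <- tibble(gene_id = character(0), enriched_in = character(0))
    if (n_markers > 0L) {
      idx <- sample.int(n_genes, n_markers)
      in_a <- idx[seq_len(ceiling(n_markers / 2))]
      in_b <- setdiff(idx, in_a)
      m[in_a, 1] <- m[in_a, 1] * 5 * fold
      m[in_b, 2] <- m[in_b, 2] * 5 * fold
      markers <- tibble(
        gene_id = gene_ids[c(in_a, in_b)],
        enriched_in = rep(sample_ids[1:2], c(length(in_a), length(in_b)))
      ) |> arrange(.data$gene_id)
    }
    m <- sweep(m, 2, colSums(m), "/")
    colnames(m) <- sample_ids
    labels <- tibble(
      gene_id = gene_ids,
      qs_group = sample(QS_GROUPS, n_genes, replace = TRUE),
      ar_type = sample(AR_TYPES, n_genes, replace = TRUE),
      ko = sprintf("K%05d", sample.int(20000L, n_genes, replace = TRUE)),
      pathway = sample(sprintf("map%05d", c(10, 20, 30, 40, 51, 52)),
                       n_genes, replace = TRUE)
    )
    list(
      abundance = dplyr::bind_cols(tibble(gene_id = gene_ids), as_tibble(m)),
      markers = markers,
      labels = labels
    )
  })
}
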