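# Rarefaction to a common depth and genus-level relative-abundance profiling.

#' Rarefy an OTU count table to a common depth
#'
#' Each sample is randomly subsampled without replacement to exactly `depth`
#' counts, removing sequencing-depth differences between samples. Samples
#' with fewer total counts than `depth` are dropped with a warning rather
#' than failing the whole table.
#'
#' @param counts Wide count tibble (`sample_id` + one integer column per
#'   OTU), as from [map_tags_to_otus()].
#' @param depth Target depth per sample, > 0.
#' @param seed Integer seed; subsampling is reproducible per seed.
#' @return Rarefied wide count tibble.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (depth <= 0) abort("`depth` must be positive")
  m <- abundance_matrix(counts)
  totals <- rowSums(m)
  drop <- totals < depth
  if (any(drop)) {
    warn(sprintf("dropping %d sample(s) with fewer than %d counts: %s",
                 sum(drop), depth,
                 paste(counts$sample_id[drop], collapse = ", ")))
  }
  m <- m[!drop, , drop = FALSE]
  with_seed_maybe(seed, {
    out <- t(apply(m, 1L, function(cnt) {
      total <- sum(cnt)
      if (total == depth) return(cnt)
      pool <- rep.int(seq_along(cnt), cnt)
      picked <- sample(pool, depth, replace = FALSE)
      tabulate(picked, nbins = length(cnt))
    }))
  })
  colnames(out) <- colnames(m)
  dplyr::bind_cols(tibble(sample_id = rownames(m)),
                   as_tibble(out))
}

#' Collapse an OTU count table to genus-level relative abundances
#'
#' Counts are summed per lowest assigned taxonomic label and each sample row
#' is normalised to relative abundance. Taxonomy strings follow the
#' `k__...;p__...;...;g__Genus` convention; the lowest non-empty rank is
#' used, with genus labels stripped of their `g__` prefix and above-genus
#' labels kept prefixed (e.g. `f__Lactobacillaceae`) to mark OTUs annotated
#' only to that level.
#'
#' @param counts Wide OTU count tibble (`sample_id` + OTU columns).
#' @param taxonomy Tibble with `otu_id` and `taxonomy` columns covering every
#'   OTU in `counts`; a missing OTU is an error naming it.
#' @return Wide genus table: `sample_id` plus one relative-abundance column
#'   per label; rows sum to 1 (0 for empty samples).
#' @export
genus_profile <- function(counts, taxonomy) {
  otus <- feature_columns(counts)
  missing <- setdiff(otus, taxonomy$otu_id)
  if (length(missing) > 0L) {
    abort(paste0("no taxonomy for OTU(s): ", paste(missing, collapse = ", ")))
  }
  label <- setNames(vapply(taxonomy$taxonomy, lowest_rank_label, character(1)),
                    taxonomy$otu_id)
  m <- abundance_matrix(counts)
  agg <- t(rowsum(t(m), group = label[colnames(m)]))
  totals <- rowSums(agg)
  rel <- sweep(agg, 1L, ifelse(totals > 0, totals, 1), "/")
  dplyr::bind_cols(tibble(sample_id = counts$sample_id),
                   as_tibble(rel))
}

lowest_rank_label <- function(tax) {
  parts <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
  assigned <- parts[!grepl("^[a-z]__$", parts) & parts != ""]
  if (length(assigned) == 0L) return("unassigned")
  last <- assigned[length(assigned)]
  if (startsWith(last, "g__")) sub("^g__", "", last) else last
}
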