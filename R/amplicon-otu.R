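# Greedy centroid OTU clustering at 97% identity, chimera screening of
# representatives, and mapping of all QC tags back onto OTU centroids.

#' Cluster dereplicated tags into OTUs
#'
#' Greedy centroid clustering in descending abundance order (ties broken by
#' lexicographic sequence, making the partition deterministic and
#' input-order invariant): each sequence joins the first existing centroid
#' whose global pairwise identity (see [global_identity()]) reaches the
#' threshold, otherwise it founds a new OTU whose representative it becomes.
#' Only non-singleton sequences should be supplied.
#'
#' @param unique_tags Tibble from [dereplicate_tags()]; rows with
#'   `singleton == TRUE` are dropped with a warning if present.
#' @param identity_threshold Clustering identity, in `(0, 1]` (default 0.97).
#' @return Tibble with `otu_id`, `representative`, `count` (total member
#'   count) and `n_members`, in founding order.
#' @export
cluster_otus <- function(unique_tags, identity_threshold = 0.97) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("`identity_threshold` must be in (0, 1]")
  }
  if ("singleton" %in% names(unique_tags) && any(unique_tags$singleton)) {
    warn("dropping singleton sequences from clustering")
    unique_tags <- unique_tags[!unique_tags$singleton, , drop = FALSE]
  }
  tags <- arrange(unique_tags, desc(.data$count), .data$sequence)
  reps <- character(0)
  counts <- integer(0)
  members <- integer(0)
  for (i in seq_len(nrow(tags))) {
    s <- tags$sequence[i]
    assigned <- FALSE
    if (length(reps) > 0L) {
      ident <- global_identity(reps, s)
      j <- which(ident >= identity_threshold)
      if (length(j) > 0L) {
        j <- j[1]  # first (earliest-founded) qualifying centroid
        counts[j] <- counts[j] + tags$count[i]
        members[j] <- members[j] + 1L
        assigned <- TRUE
      }
    }
    if (!assigned) {
      reps <- c(reps, s)
      counts <- c(counts, tags$count[i])
      members <- c(members, 1L)
    }
  }
  tibble(
    otu_id = sprintf("OTU_%04d", seq_along(reps)),
    representative = reps, count = counts, n_members = members
  )
}

#' Flag and drop chimeric OTUs
#'
#' Simplified two-parent splice test on each representative: split it at its
#' midpoint; find each half's best-matching parent among more abundant OTUs
#' (comparing against the parent representative's corresponding half). The
#' representative is chimeric iff the two best parents are distinct, each
#' half-identity is at least `half_identity`, and the full-length identity
#' to both parents stays below `identity_threshold`. Flagged OTUs are
#' removed entirely.
#'
#' @param otus Tibble from [cluster_otus()].
#' @param identity_threshold Full-length identity ceiling (default 0.97).
#' @param half_identity Half-match floor (default 0.99).
#' @return List with `otus` (retained, unchanged columns plus `chimeric =
#'   FALSE`) and `chimeras` (the dropped rows).
#' @export
flag_chimeras <- function(otus, identity_threshold = 0.97,
                          half_identity = 0.99) {
  otus <- arrange(otus, desc(.data$count), .data$representative)
  chimeric <- logical(nrow(otus))
  if (nrow(otus) >= 2L) {
    for (i in 2:nrow(otus)) {
      rep_i <- otus$representative[i]
      len <- nchar(rep_i)
      half <- len %/% 2L
      left <- substr(rep_i, 1L, half)
      right <- substr(rep_i, half + 1L, len)
      parents <- otus$representative[seq_len(i - 1L)]
      left_id <- global_identity(substr(parents, 1L, half), left)
      right_id <- global_identity(substr(parents, half + 1L,
                                         nchar(parents)), right)
      bl <- which.max(left_id)
      br <- which.max(right_id)
      if (bl != br && left_id[bl] >= half_identity &&
          right_id[br] >= half_identity) {
        full <- global_identity(parents[c(bl, br)], rep_i)
        if (all(full < identity_threshold)) chimeric[i] <- TRUE
      }
    }
  }
  list(
    otus = mutate(otus[!chimeric, , drop = FALSE], chimeric = FALSE),
    chimeras = otus[chimeric, , drop = FALSE]
  )
}

#' Map all QC-passed tags onto OTU representatives
#'
#' Every tag (singletons included) is assigned to the best-identity
#' non-chimeric representative with identity at or above the threshold; ties
#' go to the more abundant OTU. Tags matching no representative are dropped.
#'
#' @param tags QC-passed tag tibble with `sequence` and `sample_id`.
#' @param otus Non-chimeric OTU tibble (`otu_id`, `representative`, `count`).
#' @param identity_threshold Mapping identity (default 0.97).
#' @return Wide count tibble: one row per `sample_id`, one column per
#'   `otu_id`.
#' @export
map_tags_to_otus <- function(tags, otus, identity_threshold = 0.97) {
  if (nrow(otus) == 0L) abort("no OTUs to map against")
  otus <- arrange(otus, desc(.data$count), .data$representative)
  # identity of every tag against every representative
  ident <- vapply(otus$representative, function(r) {
    global_identity(tags$sequence, r)
  }, numeric(nrow(tags)))
  ident <- matrix(ident, nrow = nrow(tags))
  best <- apply(ident, 1L, which.max)         # ties -> more abundant OTU
  best_id <- ident[cbind(seq_len(nrow(tags)), best)]
  assigned <- best_id >= identity_threshold
  long <- tibble(
    sample_id = tags$sample_id[assigned],
    otu_id = otus$otu_id[best[assigned]]
  ) |>
    count(.data$sample_id, .data$otu_id, name = "n")
  tidyr::pivot_wider(long, names_from = "otu_id", values_from = "n",
                     values_fill = 0L) |>
    select("sample_id", all_of(sort(unique(long$otu_id))))
}
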