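# File-format boundaries: FASTQ/FASTA via Biostrings, m8 and TSV tables via
# readr. In-memory identities are fractions; m8 files use the blast percent
# convention.

M8_COLS <- c("query", "subject", "identity", "length", "mismatches",
             "gap_openings", "qstart", "qend", "sstart", "send",
             "evalue", "bitscore")

#' Read amplicon tags from a FASTQ file
#'
#' @param path FASTQ path (Phred+33).
#' @param sample_id Sample label attached to every tag.
#' @return Tag tibble: `tag_id`, `sample_id`, `sequence`, `quality`.
#' @export
read_tags_fastq <- function(path, sample_id = "S1") {
  # Biostrings warns about dropping per-record metadata columns we never use
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    tag_id = names(x),
    sample_id = sample_id,
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write amplicon tags to a FASTQ file
#'
#' @param tags Tag tibble with `tag_id`, `sequence`, `quality`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_tags_fastq <- function(tags, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(tags$sequence, tags$tag_id)),
    Biostrings::PhredQuality(tags$quality)
  )
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::quality(x))
  invisible(path)
}

#' Write read pairs to a pair of FASTQ files
#'
#' Mates go to `<prefix>_1.fastq` and `<prefix>_2.fastq`, reads named
#' `<pair_id>/1` and `<pair_id>/2`.
#'
#' @param pairs Pair tibble (`pair_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_pairs_fastq <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(pairs[[paste0("seq", m)]],
                                        paste0(pairs$pair_id, "/", m))),
      Biostrings::PhredQuality(pairs[[paste0("qual", m)]])
    )
    Biostrings::writeXStringSet(x, paths[m], format = "fastq",
                                qualities = Biostrings::quality(x))
  }
  invisible(paths)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Tibble `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), sequence = unname(as.character(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble whose first column is the id and second the sequence
#'   (e.g. contig or catalogue tables), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    v <- setNames(seqs[[2]], seqs[[1]])
  } else {
    v <- seqs
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(v), path)
  invisible(path)
}

#' Read a 12-column m8 alignment table
#'
#' Identities are converted from blast percent to fractions on read.
#'
#' @param path Tab-separated m8 path (no header).
#' @return m8 tibble with the 12 canonical columns (query, subject,
#'   identity, length, mismatches, gap_openings, qstart, qend, sstart,
#'   send, evalue, bitscore).
#' @export
read_m8 <- function(path) {
  x <- readr::read_tsv(path, col_names = M8_COLS, show_col_types = FALSE,
                       col_types = "ccdiiiiiiidd")
  x$identity <- x$identity / 100
  x
}

#' Write an m8 alignment table
#'
#' Fraction identities are written as blast percentages.
#'
#' @param alignments m8 tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_m8 <- function(alignments, path) {
  out <- alignments[, M8_COLS]
  out$identity <- round(out$identity * 100, 2)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with header `sample_id batch day fraction quality` (missing
#' optional columns are tolerated).
#'
#' @param path TSV path.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a wide abundance or metadata table as TSV
#'
#' @param tbl Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a wide abundance table written by [write_table_tsv()]
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a taxonomy map
#'
#' Two tab-separated columns: OTU id and a `k__...;p__...;...` lineage
#' string.
#'
#' @param path TSV path (no header).
#' @return Tibble `otu_id`, `taxonomy`.
#' @export
read_taxonomy_map <- function(path) {
  readr::read_tsv(path, col_names = c("otu_id", "taxonomy"),
                  show_col_types = FALSE, col_types = "cc")
}
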