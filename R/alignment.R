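# Pairwise identity primitives shared by OTU clustering, tag mapping,
# chimera screening and gene dereplication.

unit_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Global pairwise identity of sequences against one reference
#'
#' Identity is the number of matching columns divided by the full alignment
#' length (gap columns included) of a global Needleman-Wunsch alignment under
#' unit scoring: match +1, mismatch -1, gap -1 per gapped position.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param ref Single reference sequence.
#' @return Numeric vector of identities in `[0, 1]`, one per input sequence.
#' @export
global_identity <- function(seqs, ref) {
  if (length(seqs) == 0L) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = unit_submat(),
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

# Overlap (ends-free) alignment statistics used by gene dereplication:
# identity over the aligned region and coverage of the shorter sequence.
overlap_identity_coverage <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    type = "overlap", substitutionMatrix = unit_submat(),
    gapOpening = 0, gapExtension = 1
  )
  aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (aln_len == 0L) return(c(identity = 0, coverage = 0))
  span_a <- Biostrings::end(Biostrings::pattern(aln)) -
    Biostrings::start(Biostrings::pattern(aln)) + 1L
  span_b <- Biostrings::end(Biostrings::subject(aln)) -
    Biostrings::start(Biostrings::subject(aln)) + 1L
  shorter <- min(nchar(a), nchar(b))
  span_shorter <- if (nchar(a) <= nchar(b)) span_a else span_b
  c(identity = Biostrings::nmatch(aln) / aln_len,
    coverage = span_shorter / shorter)
}
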