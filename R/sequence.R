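## Pairwise alignment and position mapping between a reference sequence
## (e.g. the UniProt entry carrying the catalytic-lysine annotation) and a
## structure-derived sequence.

align_pair <- function(query_seq, target_seq) {
  if (nchar(query_seq) == 0 || nchar(target_seq) == 0)
    stop_plp("plpscreen_value_error", "empty sequence")
  ## substitution matrix: match 1, mismatch -1 over the residue alphabet
  alpha <- unique(c(aa3to1(names(AA321)), "X"))
  mat <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_seq), Biostrings::AAString(target_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1)
  list(query = as.character(Biostrings::alignedPattern(aln)),
       target = as.character(Biostrings::alignedSubject(aln)))
}

#' Map a sequence position through a pairwise alignment
#'
#' Globally aligns `query_seq` to `target_seq` (match 1, mismatch -1, gap
#' opening 5, gap extension 1) and carries a 1-based query position through
#' the alignment.
#'
#' @param query_seq,target_seq plain amino-acid strings.
#' @param query_pos 1-based position in `query_seq`.
#' @return the corresponding 1-based position in `target_seq`, or `NA` if
#'   the position aligns to a gap.
#' @examples
#' map_sequence_position("MAKKLG", "AKKLG", 4)  # 3
#' @export
map_sequence_position <- function(query_seq, target_seq, query_pos) {
  n <- nchar(query_seq)
  if (query_pos < 1 || query_pos > n)
    stop_plp("plpscreen_value_error",
             "query_pos %d outside 1..%d", query_pos, n)
  aln <- align_pair(query_seq, target_seq)
  qa <- strsplit(aln$query, "")[[1]]
  ta <- strsplit(aln$target, "")[[1]]
  qi <- cumsum(qa != "-")
  col <- match(query_pos, qi)   # first alignment column holding query_pos
  if (is.na(col) || ta[col] == "-") return(NA_integer_)
  sum(ta[seq_len(col)] != "-")
}
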