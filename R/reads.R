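#' Construct a read table
#'
#' The package-wide container for sequencing reads is a tibble with one row
#' per read and columns:
#' \describe{
#'   \item{read_id}{character, unique within the table}
#'   \item{sequence}{character over `{A,C,G,T,N}` (normalised to upper case)}
#'   \item{qualities}{list of integer phred scores (one per base) or `NULL`
#'     entries for reads without qualities (FASTA provenance)}
#'   \item{mate_of}{character, `NA` or the id of the paired mate}
#'   \item{origin}{character provenance tag, set by [simulate_reads()]}
#' }
#'
#' @param read_id Character vector of unique ids.
#' @param sequence Character vector of sequences.
#' @param qualities Optional list of integer vectors (or `NULL` for none).
#' @param mate_of Optional character vector of mate ids (`NA` = unpaired).
#' @param origin Optional character vector of provenance tags.
#' @return A `tbl_df` of class `c("overbin_reads", ...)`.
#' @export
#' @examples
#' reads_tbl(c("r1", "r2"), c("ACGT", "GGTT"))
reads_tbl <- function(read_id, sequence, qualities = NULL,
                      mate_of = NA_character_, origin = NA_character_) {
  read_id <- as.character(read_id)
  if (anyDuplicated(read_id)) {
    contract_error(sprintf(
      "duplicate read_id: %s", read_id[duplicated(read_id)][1]
    ))
  }
  sequence <- normalize_dna(as.character(sequence), "read")
  n <- length(read_id)
  if (length(sequence) != n) contract_error("read_id and sequence lengths differ")
  if (is.null(qualities)) {
    qualities <- rep(list(NULL), n)
  }
  stopifnot(is.list(qualities), length(qualities) == n)
  for (i in seq_len(n)) {
    q <- qualities[[i]]
    if (is.null(q)) next
    q <- as.integer(q)
    if (length(q) != nchar(sequence[i]) || any(q < 0L)) {
      contract_error(sprintf(
        "read '%s': qualities must be %d non-negative scores",
        read_id[i], nchar(sequence[i])
      ))
    }
    qualities[[i]] <- q
  }
  out <- tibble::tibble(
    read_id = read_id,
    sequence = sequence,
    qualities = qualities,
    mate_of = rep_len(as.character(mate_of), n),
    origin = rep_len(as.character(origin), n)
  )
  class(out) <- c("overbin_reads", class(out))
  out
}

has_qualities <- function(reads) {
  !vapply(reads$qualities, is.null, logical(1))
}

empty_reads <- function() {
  reads_tbl(character(0), character(0), list())
}
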