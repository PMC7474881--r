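#' 16S screening parameters
#'
#' Thresholds for the built-in seed-and-extend ungapped mapper used to
#' flag ribosomal reads before binning.
#'
#' @param seed_k Seed k-mer length. Default 21.
#' @param min_identity Minimum identity of a qualifying alignment.
#'   Default 0.9.
#' @param min_aligned Minimum aligned length in bases. Default 50.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(seed_k = 21L, min_identity = 0.9, min_aligned = 50L) {
  seed_k <- as.integer(seed_k)
  min_aligned <- as.integer(min_aligned)
  if (is.na(seed_k) || seed_k < 1L || seed_k > min_aligned) {
    config_error("seed_k must satisfy 1 <= seed_k <= min_aligned")
  }
  if (min_identity <= 0 || min_identity > 1) {
    config_error("min_identity must be in (0, 1]")
  }
  structure(list(seed_k = seed_k, min_identity = min_identity,
                 min_aligned = min_aligned),
            class = "screen_params")
}

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  seq_len(n - k + 1L)
}

kmers_of <- function(seq, k) {
  p <- kmer_starts(seq, k)
  if (length(p) == 0L) return(character(0))
  substring(seq, p, p + k - 1L)
}

#' Build a k-mer index over a 16S reference set
#'
#' Indexes every length-`seed_k` substring free of `N` of every reference
#' sequence and of its reverse complement, keyed to subject and position;
#' both orientations of each reference are stored as subjects so that
#' reads from either strand seed alignments directly.
#'
#' @param ref Path to a reference FASTA, or a named character vector of
#'   sequences.
#' @param seed_k Seed k-mer length (default 21).
#' @return A list of class `rrna_index` with elements `k`, `subjects`
#'   (oriented sequences) and `table` (k-mer -> hits data frame).
#' @export
build_reference_index <- function(ref, seed_k = 21L) {
  seed_k <- as.integer(seed_k)
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    rr <- read_sequences(ref, "fasta")
    ref <- stats::setNames(rr$sequence, rr$read_id)
  }
  if (length(ref) == 0L) config_error("empty 16S reference")
  ref <- normalize_dna(ref, "reference")
  if (is.null(names(ref))) names(ref) <- paste0("ref", seq_along(ref))
  subjects <- c(
    stats::setNames(ref, paste0(names(ref), "|+")),
    stats::setNames(revcomp(ref), paste0(names(ref), "|-"))
  )
  km <- list()
  pos <- list()
  subj <- list()
  for (s in names(subjects)) {
    k <- kmers_of(subjects[[s]], seed_k)
    keep <- !grepl("N", k, fixed = TRUE)
    km[[s]] <- k[keep]
    pos[[s]] <- which(keep)
    subj[[s]] <- rep(s, sum(keep))
  }
  hits <- data.frame(
    kmer = unlist(km, use.names = FALSE),
    subject = unlist(subj, use.names = FALSE),
    pos = unlist(pos, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  table <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(hits) == 0L) {
    warning("all reference sequences are shorter than seed_k; index is empty")
  } else {
    list2env(split(hits[c("subject", "pos")], hits$kmer), envir = table)
  }
  structure(list(k = seed_k, subjects = subjects, table = table),
            class = "rrna_index")
}

# Does any window of length >= min_aligned along this diagonal reach
# min_identity? match is a logical vector over the diagonal span.
diagonal_qualifies <- function(match, min_aligned, min_identity) {
  L <- length(match)
  if (L < min_aligned) return(FALSE)
  cs <- c(0L, cumsum(match))
  for (s in seq_len(L - min_aligned + 1L)) {
    lens <- min_aligned:(L - s + 1L)
    matches <- cs[s + lens] - cs[s]
    if (any(matches >= min_identity * lens)) return(TRUE)
  }
  FALSE
}

read_is_ribosomal <- function(seq, index, params) {
  k <- index$k
  starts <- kmer_starts(seq, k)
  if (length(starts) == 0L) return(FALSE)
  kms <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", kms, fixed = TRUE)
  rchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nr <- length(rchars)
  seen_diag <- character(0)
  for (ii in which(keep)) {
    hit <- get0(kms[ii], envir = index$table, inherits = FALSE)
    if (is.null(hit)) next
    for (h in seq_len(nrow(hit))) {
      subj_name <- hit$subject[h]
      d <- hit$pos[h] - starts[ii] # diagonal: subject pos - read pos
      dkey <- paste0(subj_name, "@", d)
      if (dkey %in% seen_diag) next
      seen_diag <- c(seen_diag, dkey)
      subj <- index$subjects[[subj_name]]
      ns <- nchar(subj)
      r_from <- max(1L, 1L - d)
      r_to <- min(nr, ns - d)
      if (r_to - r_from + 1L < params$min_aligned) next
      schars <- strsplit(substr(subj, r_from + d, r_to + d), "",
                         fixed = TRUE)[[1]]
      span_r <- rchars[r_from:r_to]
      m <- span_r == schars & span_r != "N" & schars != "N"
      if (diagonal_qualifies(m, params$min_aligned, params$min_identity)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Partition reads into ribosomal and passthrough
#'
#' A read is flagged ribosomal when some seed k-mer hit extends (ungapped,
#' along its diagonal) to an alignment of at least `min_aligned` bases at
#' identity at least `min_identity` against a reference sequence on either
#' strand. The two returned id sets are disjoint and together cover the
#' input. Classification is strand-symmetric and deterministic.
#'
#' @param reads A read or merged-read table (columns including an id
#'   column and `sequence`).
#' @param index An [build_reference_index()] result.
#' @param params A [screen_params()]; its `seed_k` must equal `index$k`.
#' @return A list of class `rrna_partition` with `ribosomal_ids` and
#'   `passthrough_ids`.
#' @export
partition_rrna <- function(reads, index, params = screen_params()) {
  stopifnot(inherits(index, "rrna_index"))
  if (params$seed_k != index$k) {
    config_error("params$seed_k does not match the index k")
  }
  ids <- reads[[if ("merged_id" %in% names(reads)) "merged_id" else "read_id"]]
  ribo <- vapply(
    reads$sequence, read_is_ribosomal, logical(1),
    index = index, params = params, USE.NAMES = FALSE
  )
  structure(
    list(ribosomal_ids = ids[ribo], passthrough_ids = ids[!ribo]),
    class = "rrna_partition"
  )
}
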