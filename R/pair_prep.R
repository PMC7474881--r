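#' Paired-end merge parameters
#'
#' @param min_overlap Minimum suffix/prefix overlap in bases for a true
#'   merge. Default 10.
#' @param max_mismatch_rate Maximum fraction of mismatching positions
#'   tolerated inside the overlap. Default 0.1.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 10L, max_mismatch_rate = 0.1) {
  min_overlap <- as.integer(min_overlap)
  if (is.na(min_overlap) || min_overlap < 1L) {
    config_error("min_overlap must be >= 1")
  }
  if (max_mismatch_rate < 0 || max_mismatch_rate > 1) {
    config_error("max_mismatch_rate must be in [0, 1]")
  }
  structure(list(min_overlap = min_overlap,
                 max_mismatch_rate = max_mismatch_rate),
            class = "merge_params")
}

merged_tbl <- function(merged_id, sequence, qualities, source_ids, forced) {
  out <- tibble::tibble(
    merged_id = as.character(merged_id),
    sequence = sequence,
    qualities = qualities,
    source_ids = source_ids,
    forced = forced
  )
  class(out) <- c("overbin_merged", class(out))
  out
}

as_read_row <- function(r) {
  if (is.data.frame(r)) {
    stopifnot(nrow(r) == 1L)
    list(read_id = r$read_id, sequence = r$sequence,
         qualities = r$qualities[[1]])
  } else {
    list(read_id = r$read_id, sequence = r$sequence,
         qualities = r$qualities %||% NULL)
  }
}

#' Merge a read pair by suffix/prefix overlap
#'
#' Searches for the longest suffix of `r1` matching a prefix of the
#' reverse complement of `r2` (its mate, given in sequencing orientation)
#' with at most `max_mismatch_rate` mismatching positions and length at
#' least `min_overlap`. On success returns the merged consensus: inside
#' the overlap, mismatches resolve toward the base with the higher
#' quality (ties, or absent qualities, toward `r1`); overlap qualities
#' take the pairwise maximum. Returns `NULL` when no qualifying overlap
#' exists.
#'
#' @param r1,r2 One-row read tables (or lists with `read_id`, `sequence`,
#'   `qualities`).
#' @param params A [merge_params()].
#' @return A one-row merged-read table, or `NULL` (no-merge signal).
#' @export
merge_pair <- function(r1, r2, params = merge_params()) {
  a <- as_read_row(r1)
  b <- as_read_row(r2)
  if (nchar(a$sequence) == 0L || nchar(b$sequence) == 0L) {
    contract_error("merge_pair: reads must be non-empty")
  }
  s1 <- a$sequence
  s2 <- revcomp(b$sequence)
  q1 <- a$qualities
  q2 <- if (is.null(b$qualities)) NULL else rev(b$qualities)
  n1 <- nchar(s1)
  n2 <- nchar(s2)
  if (min(n1, n2) < params$min_overlap) return(NULL)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  for (ov in seq(min(n1, n2), params$min_overlap, by = -1L)) {
    i1 <- (n1 - ov + 1L):n1
    i2 <- 1L:ov
    mm <- which(c1[i1] != c2[i2])
    if (length(mm) > floor(params$max_mismatch_rate * ov)) next
    # consensus over the overlap
    cons <- c1[i1]
    consq <- NULL
    if (!is.null(q1) && !is.null(q2)) {
      take2 <- mm[q2[i2][mm] > q1[i1][mm]]
      cons[take2] <- c2[i2][take2]
      consq <- pmax(q1[i1], q2[i2])
    } else if (length(mm) > 0L) {
      cons <- c1[i1] # r1 wins without qualities
    }
    merged_seq <- paste0(
      substr(s1, 1L, n1 - ov),
      paste(cons, collapse = ""),
      substr(s2, ov + 1L, n2)
    )
    merged_q <- if (!is.null(q1) && !is.null(q2)) {
      list(c(q1[seq_len(n1 - ov)], consq, q2[seq(ov + 1L, length.out = n2 - ov)]))
    } else {
      list(NULL)
    }
    return(merged_tbl(
      merged_id = paste0(a$read_id, "+", b$read_id),
      sequence = merged_seq,
      qualities = merged_q,
      source_ids = list(c(a$read_id, b$read_id)),
      forced = FALSE
    ))
  }
  NULL
}

#' Force-merge a read pair with an NNN spacer
#'
#' Concatenates `r1`, three `N` characters, and the reverse complement of
#' `r2`. Used when the true overlap merge fails (fragment too long to
#' combine); the spacer bases get quality 0.
#'
#' @inheritParams merge_pair
#' @return A one-row merged-read table with `forced = TRUE`.
#' @export
#' @examples
#' r1 <- reads_tbl("p/1", "ATCGT")
#' r2 <- reads_tbl("p/2", revcomp("TTATC"))
#' force_merge(r1, r2)$sequence  # "ATCGTNNNTTATC"
force_merge <- function(r1, r2) {
  a <- as_read_row(r1)
  b <- as_read_row(r2)
  if (nchar(a$sequence) == 0L || nchar(b$sequence) == 0L) {
    contract_error("force_merge: reads must be non-empty")
  }
  merged_q <- if (!is.null(a$qualities) && !is.null(b$qualities)) {
    list(c(a$qualities, rep(0L, 3L), rev(b$qualities)))
  } else {
    list(NULL)
  }
  merged_tbl(
    merged_id = paste0(a$read_id, "+", b$read_id),
    sequence = paste0(a$sequence, "NNN", revcomp(b$sequence)),
    qualities = merged_q,
    source_ids = list(c(a$read_id, b$read_id)),
    forced = TRUE
  )
}

#' Prepare the binning input from pairs and singles
#'
#' Every mate pair contributes exactly one merged read: the overlap merge
#' when [merge_pair()] succeeds, otherwise the forced NNN merge. Unpaired
#' reads pass through as their own merged record. The returned provenance
#' maps every merged id back to its source read ids so that original
#' reads can be recovered per bin after binning.
#'
#' @param pairs An [reads_tbl()] whose `mate_of` links are symmetric.
#' @param singles An [reads_tbl()] of unpaired reads.
#' @param params A [merge_params()].
#' @return `list(merged = merged-read table, provenance = named list)`.
#' @export
prepare_binning_input <- function(pairs = empty_reads(),
                                  singles = empty_reads(),
                                  params = merge_params()) {
  rows <- list()
  if (nrow(pairs) > 0L) {
    ids <- pairs$read_id
    mates <- pairs$mate_of
    idx <- match(mates, ids)
    bad <- which(is.na(mates) | is.na(idx) | mates[idx] != ids |
                   idx == seq_along(ids))
    if (length(bad) > 0L) {
      contract_error(sprintf(
        "dangling or asymmetric mate link for read '%s'", ids[bad[1]]
      ))
    }
    done <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (done[i]) next
      j <- idx[i]
      done[i] <- done[j] <- TRUE
      r1 <- pairs[i, ]
      r2 <- pairs[j, ]
      m <- merge_pair(r1, r2, params)
      if (is.null(m)) m <- force_merge(r1, r2)
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (nrow(singles) > 0L) {
    rows[[length(rows) + 1L]] <- merged_tbl(
      merged_id = singles$read_id,
      sequence = singles$sequence,
      qualities = singles$qualities,
      source_ids = lapply(singles$read_id, identity),
      forced = rep(FALSE, nrow(singles))
    )
  }
  merged <- if (length(rows) == 0L) {
    merged_tbl(character(0), character(0), list(), list(), logical(0))
  } else {
    do.call(rbind, rows)
  }
  provenance <- merged$source_ids
  names(provenance) <- merged$merged_id
  list(merged = merged, provenance = provenance)
}

#' Map binned merged ids back to original read ids
#'
#' @param bin_read_ids Merged-read ids of one bin.
#' @param provenance Named list from [prepare_binning_input()].
#' @return Sorted unique character vector of original read ids.
#' @export
restore_original <- function(bin_read_ids, provenance) {
  if (length(bin_read_ids) == 0L) return(character(0))
  unknown <- setdiff(bin_read_ids, names(provenance))
  if (length(unknown) > 0L) {
    contract_error(sprintf("unknown merged id: %s", unknown[1]))
  }
  sort(unique(unlist(provenance[bin_read_ids], use.names = FALSE)))
}
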