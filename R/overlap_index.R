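#' Binning parameters
#'
#' `b` is the minimum alignment length in bases two reads must share for
#' an edge to connect them in the overlap graph. Binning starts at the
#' first value of `b_schedule` (default 70 bp) and iterates over the
#' remaining, smaller values to explore the metagenome in more detail;
#' lowering `b` increases the chance that reads from different molecules
#' land in the same bin.
#'
#' @param b_schedule Strictly descending integer vector of minimum
#'   alignment lengths. Default `c(70, 50, 30)`.
#' @param max_mismatches Mismatches tolerated inside an alignment
#'   (default 0 = exact common substring).
#' @param min_bin_size Minimum number of reads for a bin to be reported.
#'   Default 2000.
#' @param mad_cutoff Multiplier of the MAD-based spread estimate beyond
#'   which a read's degree marks it as an outlier. Default 3.
#' @param block_size Reads per processing block. Default 2e7.
#' @return A list of class `binning_params`; element `b` is
#'   `b_schedule[1]`.
#' @export
binning_params <- function(b_schedule = c(70L, 50L, 30L),
                           max_mismatches = 0L,
                           min_bin_size = 2000L,
                           mad_cutoff = 3,
                           block_size = 2e7) {
  b_schedule <- as.integer(b_schedule)
  if (length(b_schedule) > 0L) {
    if (any(b_schedule < 1L) || any(diff(b_schedule) >= 0L)) {
      config_error("b_schedule must be strictly descending, all values >= 1")
    }
  }
  if (min_bin_size < 1L) config_error("min_bin_size must be >= 1")
  if (mad_cutoff <= 0) config_error("mad_cutoff must be > 0")
  if (block_size < 1) config_error("block_size must be >= 1")
  structure(list(
    b = if (length(b_schedule)) b_schedule[1] else NA_integer_,
    b_schedule = b_schedule,
    max_mismatches = as.integer(max_mismatches),
    min_bin_size = as.integer(min_bin_size),
    mad_cutoff = mad_cutoff,
    block_size = block_size
  ), class = "binning_params")
}

overlap_tbl <- function(id_a, id_b, length, strand) {
  tibble::tibble(
    id_a = as.character(id_a),
    id_b = as.character(id_b),
    length = as.integer(length),
    strand = as.character(strand)
  )
}

ordered_reads <- function(reads) {
  id_col <- if ("merged_id" %in% names(reads)) "merged_id" else "read_id"
  ids <- reads[[id_col]]
  o <- order(ids)
  list(ids = ids[o], seqs = reads$sequence[o])
}

#' All-vs-all overlap detection, brute force
#'
#' The reference detector: for every unordered read pair, an edge is
#' reported iff the longest common substring between the two reads, or
#' between one read and the reverse complement of the other, reaches `b`
#' bases (computed by dynamic programming for `max_mismatches = 0`;
#' substrings containing `N` never match). With `max_mismatches > 0` the
#' alignment is the longest ungapped diagonal window with at most that
#' many mismatches. Quadratic in the number of reads; intended as the
#' oracle for [find_overlaps_indexed()] at small scale.
#'
#' @param reads A read or merged-read table.
#' @param b Minimum alignment length in bases.
#' @param max_mismatches Tolerated mismatches (default 0).
#' @return A tibble `(id_a, id_b, length, strand)` with `id_a < id_b`,
#'   one row per connected pair, sorted by `(id_a, id_b)`.
#' @export
find_overlaps_bruteforce <- function(reads, b, max_mismatches = 0L) {
  or <- ordered_reads(reads)
  n <- length(or$ids)
  if (n < 2L) return(overlap_tbl(character(0), character(0), integer(0), character(0)))
  rc <- revcomp(or$seqs)
  ia <- integer(0); ib <- integer(0); ln <- integer(0); st <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (max_mismatches == 0L) {
        ls <- .lcs_dp_cpp(or$seqs[i], or$seqs[j])
        lo <- .lcs_dp_cpp(or$seqs[i], rc[j])
      } else {
        ls <- .overlap_scan_cpp(or$seqs[i], or$seqs[j], max_mismatches)
        lo <- .overlap_scan_cpp(or$seqs[i], rc[j], max_mismatches)
      }
      best <- max(ls, lo)
      if (best >= b) {
        ia <- c(ia, i); ib <- c(ib, j); ln <- c(ln, best)
        st <- c(st, if (ls >= lo) "same" else "opposite")
      }
    }
  }
  overlap_tbl(or$ids[ia], or$ids[ib], ln, st)
}

#' All-vs-all overlap detection, seed-indexed
#'
#' Produces the identical overlap set to [find_overlaps_bruteforce()] on
#' the same input: a shared alignment of length `>= b` implies a shared
#' seed k-mer, so a canonical b-mer index (seeds shortened by pigeonhole
#' in the mismatch-tolerant mode) followed by per-pair verification is
#' complete. Near-linear in total sequence length for typical coverage.
#'
#' @inheritParams find_overlaps_bruteforce
#' @return A tibble `(id_a, id_b, length, strand)` with `id_a < id_b`,
#'   sorted by `(id_a, id_b)`.
#' @export
find_overlaps_indexed <- function(reads, b, max_mismatches = 0L) {
  or <- ordered_reads(reads)
  if (length(or$ids) < 2L) {
    return(overlap_tbl(character(0), character(0), integer(0), character(0)))
  }
  df <- .find_overlaps_indexed_cpp(or$seqs, as.integer(b),
                                   as.integer(max_mismatches))
  out <- overlap_tbl(
    or$ids[df$i + 1L], or$ids[df$j + 1L], df$length,
    ifelse(df$same_strand == 1L, "same", "opposite")
  )
  out[order(out$id_a, out$id_b), ]
}

#' Build the read-overlap graph
#'
#' Reads are nodes, qualifying pairwise alignments are undirected edges
#' (one edge per read pair, carrying the maximal shared length). Isolated
#' reads are retained as degree-0 nodes.
#'
#' @param overlaps Overlap tibble from [find_overlaps_indexed()] or
#'   [find_overlaps_bruteforce()].
#' @param node_ids Character vector of all read ids (a superset of the
#'   overlap endpoints).
#' @return An undirected [igraph::graph] with vertex name = read id and
#'   edge attributes `length` and `strand`.
#' @export
build_graph <- function(overlaps, node_ids) {
  node_ids <- as.character(node_ids)
  ends <- unique(c(overlaps$id_a, overlaps$id_b))
  missing <- setdiff(ends, node_ids)
  if (length(missing) > 0L) {
    contract_error(sprintf("overlap endpoint not in node_ids: %s", missing[1]))
  }
  if (any(overlaps$id_a == overlaps$id_b)) {
    contract_error("self-loop overlap is not allowed")
  }
  igraph::graph_from_data_frame(
    d = as.data.frame(overlaps),
    directed = FALSE,
    vertices = data.frame(name = sort(node_ids))
  )
}
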