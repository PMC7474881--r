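# Consistency factor relating the MAD to the standard deviation of a
# normal distribution: sigma_hat = 1.4826 * MAD (= 1 / qnorm(0.75) to the
# printed precision).
MAD_SIGMA_FACTOR <- 1.4826

#' MAD-to-sigma consistency factor
#'
#' The constant `1.4826` by which the median absolute deviation is
#' multiplied to obtain a consistent estimator of a normal population
#' standard deviation (`1 / qnorm(0.75)` to four decimal places).
#'
#' @return A numeric scalar.
#' @export
mad_sigma_factor <- function() MAD_SIGMA_FACTOR

#' Robust spread of a numeric vector
#'
#' Median (midpoint convention for even n), MAD (median of absolute
#' deviations from the median) and the derived normal-consistent spread
#' estimate `sigma_hat = 1.4826 * MAD`.
#'
#' @param values Non-empty numeric vector.
#' @return A list of class `robust_spread` with `median`, `mad`,
#'   `sigma_hat`.
#' @export
#' @examples
#' mad_spread(c(1, 2, 3, 4, 5)) # median 3, mad 1, sigma_hat 1.4826
mad_spread <- function(values) {
  if (length(values) == 0L) contract_error("mad_spread: empty input")
  med <- stats::median(values)
  m <- stats::median(abs(values - med))
  structure(list(median = med, mad = m, sigma_hat = MAD_SIGMA_FACTOR * m),
            class = "robust_spread")
}

#' MAD-based degree outlier filter
#'
#' Marks reads whose edge degree lies more than `cutoff * sigma_hat` from
#' the median degree as outliers (`sigma_hat = 1.4826 * MAD`). When
#' `MAD = 0` — a perfectly uniform degree histogram, the signature of a
#' clean single-molecule bin — nothing is removed and the degenerate flag
#' is raised, because any removal rule would then delete arbitrary reads.
#'
#' @param degrees Named numeric vector, read id -> degree.
#' @param cutoff Spread multiplier (default 3).
#' @param raw_mad If `TRUE`, compare distances against `cutoff * MAD`
#'   instead of `cutoff * sigma_hat`.
#' @return A list with `kept_ids`, `removed_ids`, `spread`
#'   (a [mad_spread()] result) and `mad_degenerate`.
#' @export
mad_outlier_filter <- function(degrees, cutoff = 3, raw_mad = FALSE) {
  if (length(degrees) == 0L) contract_error("mad_outlier_filter: empty input")
  ids <- names(degrees)
  stopifnot(!is.null(ids))
  spread <- mad_spread(as.numeric(degrees))
  if (spread$mad == 0) {
    return(list(kept_ids = ids, removed_ids = character(0),
                spread = spread, mad_degenerate = TRUE))
  }
  scale <- if (raw_mad) spread$mad else spread$sigma_hat
  out <- abs(as.numeric(degrees) - spread$median) > cutoff * scale
  list(kept_ids = ids[!out], removed_ids = ids[out],
       spread = spread, mad_degenerate = FALSE)
}

new_bin <- function(bin_id, read_ids, b_used, degree_histogram, spread,
                    removed_outliers, mad_degenerate) {
  structure(list(
    bin_id = bin_id,
    read_ids = read_ids,
    b_used = b_used,
    degree_histogram = degree_histogram,
    spread = spread,
    removed_outliers = removed_outliers,
    mad_degenerate = mad_degenerate
  ), class = "overbin_bin")
}

new_bin_set <- function(bins, leftover_ids) {
  structure(list(bins = bins, leftover_ids = leftover_ids),
            class = "overbin_binset")
}

#' @export
print.overbin_binset <- function(x, ...) {
  cat(sprintf("<overbin_binset> %d bin(s), %d leftover read(s)\n",
              length(x$bins), length(x$leftover_ids)))
  for (bn in x$bins) {
    cat(sprintf(
      "  bin %d: %d reads (b=%s, %d outliers removed, median degree %.1f)\n",
      bn$bin_id, length(bn$read_ids),
      ifelse(is.na(bn$b_used), "?", bn$b_used),
      length(bn$removed_outliers), bn$spread$median
    ))
  }
  invisible(x)
}

degree_hist_tbl <- function(degrees) {
  t <- table(factor(as.integer(degrees)))
  tibble::tibble(degree = as.integer(names(t)), count = as.integer(t))
}

# Renumber bins by their smallest member read id, deterministically.
renumber_bins <- function(bins) {
  if (length(bins) == 0L) return(bins)
  key <- vapply(bins, function(b) min(b$read_ids), character(1))
  bins <- bins[order(key)]
  for (i in seq_along(bins)) bins[[i]]$bin_id <- i
  bins
}

#' Extract bins from an overlap graph
#'
#' Candidate bins are the connected components of the graph. Within each
#' component, degrees are computed, the degree histogram recorded, and the
#' MAD outlier filter applied; after removing outliers, connectivity is
#' recomputed and every resulting sub-component with at least
#' `min_bin_size` reads is reported as a bin. Outliers, members of
#' sub-threshold components and degree-0 nodes all go to the leftover
#' pool. A reported bin's histogram covers its members plus its parent
#' component's removed outliers (pre-filter degrees), so histogram counts
#' sum to `|read_ids| + |removed_outliers|`.
#'
#' @param graph An [build_graph()] result.
#' @param params A [binning_params()].
#' @return A bin set: `list(bins, leftover_ids)` of class
#'   `overbin_binset`, bins ordered by smallest member read id.
#' @export
extract_bins <- function(graph, params = binning_params()) {
  all_ids <- igraph::V(graph)$name
  comps <- igraph::components(graph)
  bins <- list()
  leftover <- character(0)
  for (cid in seq_len(comps$no)) {
    members <- all_ids[comps$membership == cid]
    if (length(members) < 2L) { # isolated node
      leftover <- c(leftover, members)
      next
    }
    sub <- igraph::induced_subgraph(graph, members)
    deg <- igraph::degree(sub)
    filt <- mad_outlier_filter(deg, cutoff = params$mad_cutoff)
    kept <- filt$kept_ids
    removed <- filt$removed_ids
    leftover <- c(leftover, removed)
    if (length(kept) == 0L) next
    sub2 <- igraph::induced_subgraph(sub, kept)
    c2 <- igraph::components(sub2)
    kept_ids2 <- igraph::V(sub2)$name
    for (sc in seq_len(c2$no)) {
      sc_members <- kept_ids2[c2$membership == sc]
      if (length(sc_members) >= params$min_bin_size) {
        hist_ids <- c(sc_members, removed)
        bins[[length(bins) + 1L]] <- new_bin(
          bin_id = NA_integer_,
          read_ids = sort(sc_members),
          b_used = NA_integer_,
          degree_histogram = degree_hist_tbl(deg[hist_ids]),
          spread = filt$spread,
          removed_outliers = sort(removed),
          mad_degenerate = filt$mad_degenerate
        )
      } else {
        leftover <- c(leftover, sc_members)
      }
    }
  }
  new_bin_set(renumber_bins(bins), sort(leftover))
}

#' Iterative binning over a descending b schedule
#'
#' Binning starts at the first (largest) `b`; reads captured in reported
#' bins are withdrawn from the pool, and each subsequent, smaller `b`
#' re-examines only the remaining pool (including reads removed as degree
#' outliers at earlier iterations). Each bin records the `b` of the
#' iteration that produced it.
#'
#' @param reads A read or merged-read table.
#' @param params A [binning_params()].
#' @return An `overbin_binset`; `leftover_ids` is the pool after the last
#'   iteration.
#' @export
iterative_binning <- function(reads, params = binning_params()) {
  id_col <- if ("merged_id" %in% names(reads)) "merged_id" else "read_id"
  pool <- reads
  bins <- list()
  for (b in params$b_schedule) {
    if (nrow(pool) < 2L) break
    ov <- find_overlaps_indexed(pool, b, params$max_mismatches)
    g <- build_graph(ov, pool[[id_col]])
    bs <- extract_bins(g, params)
    for (bn in bs$bins) {
      bn$b_used <- b
      bins[[length(bins) + 1L]] <- bn
    }
    binned <- unlist(lapply(bs$bins, `[[`, "read_ids"), use.names = FALSE)
    pool <- pool[!(pool[[id_col]] %in% binned), ]
  }
  new_bin_set(renumber_bins(bins), sort(pool[[id_col]]))
}

#' Block-wise binning with cross-block bin merging
#'
#' Reads are split into consecutive blocks of at most `block_size`; each
#' block is binned independently with [iterative_binning()]. A merge pass
#' then builds a bin-level graph with an edge between bins from different
#' blocks whenever some cross-bin read pair overlaps by at least the
#' stricter of the two bins' `b_used`; connected bins are unioned (the
#' merged bin keeps the stricter `b_used`). With `block_size >= n` the
#' result is identical to the non-blocked path.
#'
#' @inheritParams iterative_binning
#' @return An `overbin_binset`.
#' @export
block_binning <- function(reads, params = binning_params()) {
  id_col <- if ("merged_id" %in% names(reads)) "merged_id" else "read_id"
  n <- nrow(reads)
  n_blocks <- max(1L, ceiling(n / params$block_size))
  if (n_blocks == 1L) return(iterative_binning(reads, params))
  block_of <- ceiling(seq_len(n) / params$block_size)
  all_bins <- list()
  leftover <- character(0)
  bin_block <- integer(0)
  for (blk in seq_len(n_blocks)) {
    bs <- iterative_binning(reads[block_of == blk, ], params)
    for (bn in bs$bins) {
      all_bins[[length(all_bins) + 1L]] <- bn
      bin_block <- c(bin_block, blk)
    }
    leftover <- c(leftover, bs$leftover_ids)
  }
  k <- length(all_bins)
  if (k > 1L) {
    # cross-block merge: overlap all binned reads at the smallest b in
    # play, then test each bin pair at its own threshold
    binned_ids <- unlist(lapply(all_bins, `[[`, "read_ids"), use.names = FALSE)
    sub <- reads[reads[[id_col]] %in% binned_ids, ]
    b_min <- min(vapply(all_bins, `[[`, integer(1), "b_used"))
    ov <- find_overlaps_indexed(sub, b_min, params$max_mismatches)
    bin_of <- rep(seq_len(k), vapply(all_bins, function(b) length(b$read_ids),
                                     integer(1)))
    names(bin_of) <- binned_ids
    ba <- bin_of[ov$id_a]
    bb <- bin_of[ov$id_b]
    cross <- which(ba != bb & bin_block[ba] != bin_block[bb])
    bg_edges <- unique(data.frame(
      a = pmin(ba[cross], bb[cross]),
      b = pmax(ba[cross], bb[cross]),
      len = ov$length[cross]
    ))
    thr <- pmax(
      vapply(all_bins, `[[`, integer(1), "b_used")[bg_edges$a],
      vapply(all_bins, `[[`, integer(1), "b_used")[bg_edges$b]
    )
    bg_edges <- bg_edges[bg_edges$len >= thr, , drop = FALSE]
    if (nrow(bg_edges) > 0L) {
      bg <- igraph::graph_from_data_frame(
        bg_edges[c("a", "b")], directed = FALSE,
        vertices = data.frame(name = as.character(seq_len(k)))
      )
      comp <- igraph::components(bg)$membership[as.character(seq_len(k))]
      merged <- list()
      for (grp in sort(unique(comp))) {
        idx <- which(comp == grp)
        if (length(idx) == 1L) {
          merged[[length(merged) + 1L]] <- all_bins[[idx]]
          next
        }
        parts <- all_bins[idx]
        ids <- sort(unique(unlist(lapply(parts, `[[`, "read_ids"))))
        outl <- sort(unique(unlist(lapply(parts, `[[`, "removed_outliers"))))
        hist <- do.call(rbind, lapply(parts, `[[`, "degree_histogram"))
        hist <- stats::aggregate(count ~ degree, data = hist, FUN = sum)
        hist <- tibble::as_tibble(hist[order(hist$degree), ])
        merged[[length(merged) + 1L]] <- new_bin(
          bin_id = NA_integer_,
          read_ids = ids,
          b_used = max(vapply(parts, `[[`, integer(1), "b_used")),
          degree_histogram = hist,
          spread = parts[[1]]$spread,
          removed_outliers = outl,
          mad_degenerate = any(vapply(parts, `[[`, logical(1),
                                      "mad_degenerate"))
        )
      }
      all_bins <- merged
    }
  }
  new_bin_set(renumber_bins(all_bins), sort(leftover))
}
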