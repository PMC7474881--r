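#' Score bins against a ground-truth table
#'
#' Per bin: the dominant genome is the plurality label of its member
#' reads (ties broken toward the lexicographically smallest label),
#' purity is the fraction of member reads from the dominant genome, and
#' contamination is its complement. Per genome: completeness is the
#' fraction of the genome's truth reads captured by its best bin (ties
#' toward the smaller bin id). Read-level scoring replaces marker-gene
#' methods, which is exact when the truth is known.
#'
#' @param bins An `overbin_binset` (or a list of bins).
#' @param truth A data frame `(read_id, genome)` covering every binned
#'   read id.
#' @return `list(bin_scores, genome_scores)`, both tibbles.
#' @export
evaluate_bins <- function(bins, truth) {
  bin_list <- if (inherits(bins, "overbin_binset")) bins$bins else bins
  lab <- stats::setNames(as.character(truth$genome), truth$read_id)
  genomes <- sort(unique(as.character(truth$genome)))
  bin_rows <- vector("list", length(bin_list))
  per_genome_in_bin <- list()
  for (i in seq_along(bin_list)) {
    bn <- bin_list[[i]]
    unknown <- setdiff(bn$read_ids, names(lab))
    if (length(unknown) > 0L) {
      contract_error(sprintf("read id missing from truth: %s", unknown[1]))
    }
    counts <- table(lab[bn$read_ids])
    top <- max(counts)
    dominant <- sort(names(counts)[counts == top])[1]
    purity <- top / length(bn$read_ids)
    bin_rows[[i]] <- tibble::tibble(
      bin_id = bn$bin_id,
      dominant_genome = dominant,
      purity = as.numeric(purity),
      contamination = 1 - as.numeric(purity),
      n_reads = length(bn$read_ids)
    )
    per_genome_in_bin[[i]] <- counts
  }
  bin_scores <- if (length(bin_rows)) do.call(rbind, bin_rows) else
    tibble::tibble(bin_id = integer(0), dominant_genome = character(0),
                   purity = numeric(0), contamination = numeric(0),
                   n_reads = integer(0))
  genome_rows <- lapply(genomes, function(g) {
    total <- sum(lab == g)
    captured <- vapply(per_genome_in_bin, function(ct) {
      if (g %in% names(ct)) as.integer(ct[[g]]) else 0L
    }, integer(1))
    if (length(captured) == 0L || max(captured) == 0L || total == 0L) {
      return(tibble::tibble(genome = g, completeness = 0,
                            best_bin_id = NA_integer_))
    }
    best <- which.max(captured) # first max = smallest bin index
    tibble::tibble(
      genome = g,
      completeness = captured[best] / total,
      best_bin_id = bin_list[[best]]$bin_id
    )
  })
  list(bin_scores = bin_scores,
       genome_scores = do.call(rbind, genome_rows))
}

#' Degree histogram report for one bin
#'
#' The number-of-edges-per-node histogram recorded for the bin before
#' outlier filtering, sorted ascending by degree, plus the robust spread
#' summary used by the MAD filter. Counts sum to the bin size plus the
#' number of removed outliers.
#'
#' @param bin An `overbin_bin`.
#' @return `list(histogram = tibble(degree, count), median, mad,
#'   sigma_hat, mad_degenerate)`.
#' @export
degree_histogram_report <- function(bin) {
  stopifnot(inherits(bin, "overbin_bin"))
  h <- bin$degree_histogram
  h <- h[order(h$degree), ]
  list(
    histogram = h,
    median = bin$spread$median,
    mad = bin$spread$mad,
    sigma_hat = bin$spread$sigma_hat,
    mad_degenerate = bin$mad_degenerate
  )
}
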