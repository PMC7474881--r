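split_pairs_singles <- function(reads) {
  ids <- reads$read_id
  m <- reads$mate_of
  paired <- !is.na(m) & m %in% ids
  # a pair is valid only if the link is symmetric
  idx <- match(m, ids)
  sym <- paired & !is.na(idx) & reads$mate_of[idx] == ids
  list(pairs = reads[sym, ], singles = reads[!sym, ])
}

merged_subset <- function(merged, ids) {
  merged[merged$merged_id %in% ids, ]
}

#' Run the full binning pipeline
#'
#' Executes the workflow described by the configuration as a dependency
#' -driven task graph: quality trimming, paired-read merging (overlap
#' merge with forced NNN fallback), optional 16S screening, iterative
#' overlap-graph binning with the MAD degree filter, per-bin export of
#' the original reads (fan-out, parallelisable), optional evaluation
#' against a truth table, and the final report. Serial and parallel
#' backends produce bit-identical outputs.
#'
#' @param config An `overbin_config` from [pipeline_config()] or
#'   [load_config()].
#' @param quiet Suppress progress messages.
#' @return The run manifest: a list with `counts` (reads per stage
#'   boundary), `task_status`, `binset`, `bin_table`, `scores` (or
#'   `NULL`), `provenance` and `artifacts` (file paths).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "overbin_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$config <- config
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  chain <- list()
  chain[[length(chain) + 1L]] <- list(
    id = "trim", deps = character(0),
    fun = function(st) {
      reads <- read_sequences(st$config$input_path, st$config$input_format)
      st$counts <- list(reads_in = nrow(reads))
      if (st$config$trim && st$config$input_format == "fastq") {
        tr <- trim_reads(reads, st$config$trim_params)
        reads <- tr$kept
        st$counts$trimmed_dropped <- tr$stats$dropped
      } else {
        st$counts$trimmed_dropped <- 0L
      }
      st$counts$kept_after_trim <- nrow(reads)
      st$orig_reads <- reads
      NULL
    }
  )
  chain[[length(chain) + 1L]] <- list(
    id = "merge", deps = "trim",
    fun = function(st) {
      if (st$config$merge_pairs) {
        ps <- split_pairs_singles(st$orig_reads)
        prep <- prepare_binning_input(ps$pairs, ps$singles,
                                      st$config$merge_params)
      } else {
        prep <- prepare_binning_input(singles = st$orig_reads,
                                      params = st$config$merge_params)
      }
      st$merged <- prep$merged
      st$provenance <- prep$provenance
      st$counts$n_merged <- nrow(prep$merged)
      write_sequences(
        reads_tbl(prep$merged$merged_id, prep$merged$sequence),
        file.path(st$config$output_dir, "merged.fasta"), "fasta"
      )
      prov <- tibble::tibble(
        merged_id = names(prep$provenance),
        source_ids = vapply(prep$provenance, paste, character(1),
                            collapse = ",")
      )
      write_tsv_plain(prov, file.path(st$config$output_dir, "provenance.tsv"))
      NULL
    }
  )
  if (config$rrna_screen) {
    chain[[length(chain) + 1L]] <- list(
      id = "screen", deps = "merge",
      fun = function(st) {
        idx <- build_reference_index(st$config$reference_path,
                                     st$config$screen_params$seed_k)
        part <- partition_rrna(st$merged, idx, st$config$screen_params)
        st$counts$n_ribosomal <- length(part$ribosomal_ids)
        ribo <- merged_subset(st$merged, part$ribosomal_ids)
        pass <- merged_subset(st$merged, part$passthrough_ids)
        od <- st$config$output_dir
        write_sequences(reads_tbl(ribo$merged_id, ribo$sequence),
                        file.path(od, "ribosomal.fasta"), "fasta")
        write_sequences(reads_tbl(pass$merged_id, pass$sequence),
                        file.path(od, "passthrough.fasta"), "fasta")
        cls <- tibble::tibble(
          read_id = c(part$ribosomal_ids, part$passthrough_ids),
          class = c(rep("ribosomal", length(part$ribosomal_ids)),
                    rep("passthrough", length(part$passthrough_ids)))
        )
        cls <- cls[order(cls$read_id), ]
        write_tsv_plain(cls, file.path(od, "rrna_classes.tsv"))
        st$pool <- pass
        NULL
      }
    )
  }
  chain[[length(chain) + 1L]] <- list(
    id = "binning", deps = if (config$rrna_screen) "screen" else "merge",
    fun = function(st) {
      if (is.null(st$pool)) {
        st$pool <- st$merged
        st$counts$n_ribosomal <- 0L
      }
      st$binset <- block_binning(st$pool, st$config$binning_params)
      st$counts$n_binned <- sum(vapply(st$binset$bins,
                                       function(b) length(b$read_ids),
                                       integer(1)))
      st$counts$n_leftover <- length(st$binset$leftover_ids)
      st$bin_table <- bin_table_tbl(st$binset)
      write_tsv_plain(st$bin_table,
                      file.path(st$config$output_dir, "bins.tsv"))
      NULL
    }
  )
  res1 <- execute(chain, backend = "serial", state = state)
  failed <- res1$status$status %in% c("failed", "not-run")
  if (any(failed)) {
    for (i in seq_len(nrow(res1$status))) {
      note("task %s: %s", res1$status$task_id[i], res1$status$status[i])
    }
    manifest <- list(
      counts = state$counts %||% list(),
      task_status = res1$status,
      binset = NULL, bin_table = NULL, scores = NULL,
      provenance = NULL, artifacts = character(0),
      ok = FALSE
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(manifest)
  }

  # fan-out: one task per reported bin, parallel-safe and cacheable
  bins <- state$binset$bins
  orig <- state$orig_reads
  prov <- state$provenance
  fan <- lapply(seq_along(bins), function(i) {
    bn <- bins[[i]]
    fa <- file.path(out_dir, sprintf("bin_%03d.fasta", bn$bin_id))
    ht <- file.path(out_dir, sprintf("bin_%03d_hist.tsv", bn$bin_id))
    list(
      id = sprintf("bin_%03d", bn$bin_id),
      deps = character(0),
      parallel_safe = TRUE, cacheable = TRUE,
      inputs = config$input_path, outputs = c(fa, ht),
      fun = function(st) {
        orig_ids <- restore_original(bn$read_ids, prov)
        sel <- orig[orig$read_id %in% orig_ids, ]
        write_sequences(reads_tbl(sel$read_id, sel$sequence), fa, "fasta")
        write_tsv_plain(degree_histogram_report(bn)$histogram, ht)
        list(bin_id = bn$bin_id, original_ids = orig_ids)
      }
    )
  })
  res2 <- if (length(fan) > 0L) {
    execute(fan, backend = config$backend, workers = config$workers,
            state = state)
  } else {
    list(status = tibble::tibble(task_id = character(0),
                                 status = character(0),
                                 message = character(0)),
         results = list())
  }

  # evaluation on the original reads restored per bin
  scores <- NULL
  if (config$evaluate && !is.null(config$truth_path)) {
    truth <- read.delim(config$truth_path, stringsAsFactors = FALSE)
    orig_bins <- lapply(bins, function(bn) {
      list(bin_id = bn$bin_id,
           read_ids = restore_original(bn$read_ids, prov))
    })
    scores <- evaluate_bins(orig_bins, truth)
  }

  task_status <- rbind(res1$status, res2$status,
                       tibble::tibble(task_id = "report", status = "done",
                                      message = NA_character_))
  for (i in seq_len(nrow(task_status))) {
    note("task %s: %s", task_status$task_id[i], task_status$status[i])
  }
  for (nm in names(state$counts)) {
    note("count %s: %d", nm, state$counts[[nm]])
  }
  manifest <- list(
    counts = state$counts,
    task_status = task_status,
    binset = state$binset,
    bin_table = state$bin_table,
    scores = scores,
    provenance = prov,
    ok = TRUE
  )
  paths <- write_report(manifest, scores, out_dir)
  manifest$artifacts <- paths
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest
}
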