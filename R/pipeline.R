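CONFIG_KEYS <- c(
  "input_path", "input_format", "output_dir", "reference_path", "truth_path",
  "trim", "merge_pairs", "rrna_screen", "evaluate", "workers", "seed",
  "backend",
  "min_quality", "min_length",
  "min_overlap", "max_mismatch_rate",
  "seed_k", "min_identity", "min_aligned",
  "b_schedule", "max_mismatches", "min_bin_size", "mad_cutoff", "block_size"
)

parse_bool <- function(x, key) {
  v <- tolower(trimws(x))
  if (v %in% c("true", "yes", "1")) return(TRUE)
  if (v %in% c("false", "no", "0")) return(FALSE)
  config_error(sprintf("key '%s': expected true/false, got '%s'", key, x))
}

#' Assemble a pipeline configuration
#'
#' Programmatic equivalent of [load_config()]. The minimum viable
#' configuration is `input_path`, `input_format` and `output_dir`;
#' everything else is defaulted (binning starts at b = 70 with the
#' `c(70, 50, 30)` schedule). The rRNA screen runs only when a reference
#' is given; evaluation only when a truth table is given.
#'
#' @param input_path Input FASTA/FASTQ file.
#' @param input_format `"fasta"` or `"fastq"`.
#' @param output_dir Output directory (created if needed).
#' @param reference_path Optional 16S reference FASTA.
#' @param truth_path Optional truth TSV (`read_id`, `genome`).
#' @param trim,merge_pairs Stage toggles.
#' @param rrna_screen,evaluate Stage toggles; `NULL` = automatic
#'   (enabled when the corresponding input is present).
#' @param workers Parallel task slots for the fan-out stage.
#' @param seed Run seed.
#' @param backend `"serial"` or `"parallel"`.
#' @param trim_params,merge_params,screen_params,binning_params Stage
#'   parameter objects.
#' @return A list of class `overbin_config`.
#' @export
pipeline_config <- function(input_path, input_format, output_dir,
                            reference_path = NULL, truth_path = NULL,
                            trim = TRUE, merge_pairs = TRUE,
                            rrna_screen = NULL, evaluate = NULL,
                            workers = 1L, seed = 1L, backend = "serial",
                            trim_params = overbin::trim_params(),
                            merge_params = overbin::merge_params(),
                            screen_params = overbin::screen_params(),
                            binning_params = overbin::binning_params()) {
  if (missing(input_path)) config_error("missing mandatory key: input_path")
  if (missing(input_format)) config_error("missing mandatory key: input_format")
  if (missing(output_dir)) config_error("missing mandatory key: output_dir")
  if (!input_format %in% c("fasta", "fastq")) {
    config_error("input_format must be 'fasta' or 'fastq'")
  }
  if (!backend %in% c("serial", "parallel")) {
    config_error("backend must be 'serial' or 'parallel'")
  }
  structure(list(
    input_path = input_path,
    input_format = input_format,
    output_dir = output_dir,
    reference_path = reference_path,
    truth_path = truth_path,
    trim = isTRUE(trim),
    merge_pairs = isTRUE(merge_pairs),
    rrna_screen = if (is.null(rrna_screen)) !is.null(reference_path)
                  else isTRUE(rrna_screen),
    evaluate = if (is.null(evaluate)) !is.null(truth_path)
               else isTRUE(evaluate),
    workers = as.integer(workers),
    seed = as.integer(seed),
    backend = backend,
    trim_params = trim_params,
    merge_params = merge_params,
    screen_params = screen_params,
    binning_params = binning_params
  ), class = "overbin_config")
}

#' Load a pipeline configuration file
#'
#' The configuration is a flat `key = value` text file; `#` starts a
#' comment. Unknown keys are rejected with the list of valid keys;
#' missing mandatory keys are reported by name. `b_schedule` is a
#' comma-separated descending list (default `70,50,30`).
#'
#' @param path Configuration file.
#' @return An `overbin_config` (see [pipeline_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      config_error(sprintf("config line is not 'key = value': '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% CONFIG_KEYS) {
      config_error(sprintf("unknown config key '%s'; valid keys: %s",
                           key, paste(CONFIG_KEYS, collapse = ", ")))
    }
    kv[[key]] <- val
  }
  for (mand in c("input_path", "input_format", "output_dir")) {
    if (is.null(kv[[mand]])) {
      config_error(sprintf("missing mandatory key: %s", mand))
    }
  }
  num <- function(key, default) if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  tp <- trim_params(
    min_quality = num("min_quality", 30),
    min_length = num("min_length", 60)
  )
  mp <- merge_params(
    min_overlap = num("min_overlap", 10),
    max_mismatch_rate = num("max_mismatch_rate", 0.1)
  )
  sp <- screen_params(
    seed_k = num("seed_k", 21),
    min_identity = num("min_identity", 0.9),
    min_aligned = num("min_aligned", 50)
  )
  bs <- if (is.null(kv$b_schedule)) c(70L, 50L, 30L) else
    as.integer(trimws(strsplit(kv$b_schedule, ",", fixed = TRUE)[[1]]))
  bp <- binning_params(
    b_schedule = bs,
    max_mismatches = num("max_mismatches", 0),
    min_bin_size = num("min_bin_size", 2000),
    mad_cutoff = num("mad_cutoff", 3),
    block_size = num("block_size", 2e7)
  )
  pipeline_config(
    input_path = kv$input_path,
    input_format = kv$input_format,
    output_dir = kv$output_dir,
    reference_path = kv$reference_path,
    truth_path = kv$truth_path,
    trim = if (is.null(kv$trim)) TRUE else parse_bool(kv$trim, "trim"),
    merge_pairs = if (is.null(kv$merge_pairs)) TRUE else
      parse_bool(kv$merge_pairs, "merge_pairs"),
    rrna_screen = if (is.null(kv$rrna_screen)) NULL else
      parse_bool(kv$rrna_screen, "rrna_screen"),
    evaluate = if (is.null(kv$evaluate)) NULL else
      parse_bool(kv$evaluate, "evaluate"),
    workers = num("workers", 1),
    seed = num("seed", 1),
    backend = if (is.null(kv$backend)) "serial" else kv$backend,
    trim_params = tp, merge_params = mp, screen_params = sp,
    binning_params = bp
  )
}

#' Build the pipeline task graph
#'
#' Upstream stages (trim, merge, screen, binning) form a chain; after
#' binning, one downstream task per reported bin (per-bin export and
#' scoring) fans out, followed by a single report task that depends on
#' all of them. Disabled stages are absent and the chain reconnects
#' around them. The graph is acyclic by construction.
#'
#' @param config An `overbin_config`.
#' @param n_bins Number of reported bins (known after binning; default 0).
#' @return A tibble `(task_id, stage, deps)` of class `overbin_taskgraph`;
#'   `deps` is a list column of prerequisite task ids.
#' @export
build_task_graph <- function(config, n_bins = 0L) {
  chain <- c(
    if (config$trim) "trim",
    if (config$merge_pairs) "merge",
    if (config$rrna_screen) "screen",
    "binning"
  )
  ids <- chain
  deps <- c(list(character(0)),
            lapply(seq_along(chain)[-1], function(i) chain[i - 1L]))
  if (n_bins > 0L) {
    fan <- sprintf("bin_%03d", seq_len(n_bins))
    ids <- c(ids, fan)
    deps <- c(deps, rep(list("binning"), n_bins))
    ids <- c(ids, "report")
    deps <- c(deps, list(fan))
  } else {
    ids <- c(ids, "report")
    deps <- c(deps, list("binning"))
  }
  out <- tibble::tibble(task_id = ids, stage = ids, deps = deps)
  class(out) <- c("overbin_taskgraph", class(out))
  out
}

# topological order of a task list; errors on cycles
topo_order <- function(ids, deps) {
  remaining <- stats::setNames(deps, ids)
  order <- character(0)
  while (length(remaining) > 0L) {
    ready <- names(remaining)[vapply(remaining, function(d) {
      all(d %in% order)
    }, logical(1))]
    if (length(ready) == 0L) contract_error("task graph has a cycle")
    ready <- sort(ready)
    order <- c(order, ready)
    remaining <- remaining[!(names(remaining) %in% ready)]
  }
  order
}

# all declared outputs exist and are newer than every declared input
outputs_fresh <- function(task) {
  if (length(task$outputs) == 0L) return(FALSE)
  if (!all(file.exists(task$outputs))) return(FALSE)
  if (length(task$inputs) == 0L) return(TRUE)
  if (!all(file.exists(task$inputs))) return(FALSE)
  min(file.mtime(task$outputs)) >= max(file.mtime(task$inputs))
}

#' Execute a list of tasks respecting dependencies
#'
#' Tasks run in dependency order. Under the parallel backend, ready
#' tasks marked `parallel_safe` run together through
#' [parallel::mclapply()]; results are collected in task-id order, so
#' serial and parallel execution produce identical outputs. A task whose
#' declared outputs all exist and are newer than its declared inputs is
#' skipped (`"cached"`). A failing task is recorded and all its
#' dependents are marked `"not-run"`.
#'
#' @param tasks List of tasks; each a list with `id`, `deps`, `fun`
#'   (a function of the shared state environment), and optionally
#'   `parallel_safe`, `inputs`, `outputs`, `cacheable`.
#' @param backend `"serial"` or `"parallel"`.
#' @param workers Worker count for the parallel backend.
#' @param state Shared state environment passed to every task.
#' @return `list(status = tibble(task_id, status, message),
#'   results = named list)`.
#' @export
execute <- function(tasks, backend = c("serial", "parallel"), workers = 2L,
                    state = new.env(parent = emptyenv())) {
  backend <- match.arg(backend)
  ids <- vapply(tasks, `[[`, character(1), "id")
  names(tasks) <- ids
  deps <- lapply(tasks, function(t) t$deps %||% character(0))
  topo_order(ids, deps) # cycle check
  status <- stats::setNames(rep("pending", length(ids)), ids)
  msg <- stats::setNames(rep(NA_character_, length(ids)), ids)
  results <- list()
  run_one <- function(task) {
    tryCatch(list(ok = TRUE, value = task$fun(state)),
             error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  }
  while (any(status == "pending")) {
    ready <- names(status)[status == "pending" & vapply(ids, function(i) {
      d <- deps[[i]]
      all(status[d] %in% c("done", "cached"))
    }, logical(1))]
    blocked <- names(status)[status == "pending" & vapply(ids, function(i) {
      any(status[deps[[i]]] %in% c("failed", "not-run"))
    }, logical(1))]
    if (length(blocked) > 0L) {
      status[blocked] <- "not-run"
      next
    }
    if (length(ready) == 0L) break
    ready <- sort(ready)
    cached <- ready[vapply(ready, function(i) {
      isTRUE(tasks[[i]]$cacheable) && outputs_fresh(tasks[[i]])
    }, logical(1))]
    status[cached] <- "cached"
    ready <- setdiff(ready, cached)
    if (length(ready) == 0L) next
    par_ok <- vapply(ready, function(i) isTRUE(tasks[[i]]$parallel_safe),
                     logical(1))
    if (backend == "parallel" && length(ready) > 1L && all(par_ok)) {
      out <- parallel::mclapply(tasks[ready], run_one,
                                mc.cores = max(1L, workers))
    } else {
      out <- lapply(tasks[ready], run_one)
    }
    for (i in seq_along(ready)) {
      id <- ready[i]
      if (isTRUE(out[[i]]$ok)) {
        status[id] <- "done"
        results[[id]] <- out[[i]]$value
      } else {
        status[id] <- "failed"
        msg[id] <- as.character(out[[i]]$value)
      }
    }
  }
  list(
    status = tibble::tibble(task_id = ids, status = unname(status[ids]),
                            message = unname(msg[ids])),
    results = results
  )
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

bin_table_tbl <- function(binset) {
  bins <- binset$bins
  tibble::tibble(
    bin_id = vapply(bins, `[[`, integer(1), "bin_id"),
    b_used = vapply(bins, `[[`, integer(1), "b_used"),
    n_reads = vapply(bins, function(b) length(b$read_ids), integer(1)),
    n_outliers = vapply(bins, function(b) length(b$removed_outliers),
                        integer(1)),
    median_degree = vapply(bins, function(b) b$spread$median, numeric(1)),
    mad = vapply(bins, function(b) b$spread$mad, numeric(1)),
    mad_degenerate = vapply(bins, `[[`, logical(1), "mad_degenerate")
  )
}

html_table <- function(df) {
  if (nrow(df) == 0L) return("<p>(empty)</p>")
  head <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                 "</tr>")
  rows <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table border='1'>", head, paste(rows, collapse = ""), "</table>")
}

#' Write the final pipeline report
#'
#' Emits one HTML summary plus machine-readable TSVs (stage counts, bin
#' table, and — when evaluation ran — bin and genome scores) into
#' `output_dir`. The output contains no timestamps, so re-running on the
#' same manifest is byte-identical.
#'
#' @param manifest A [run_pipeline()] manifest.
#' @param scores `NULL` or an [evaluate_bins()] result.
#' @param output_dir Output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(manifest, scores, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output_dir: %s", output_dir))
  }
  counts <- tibble::tibble(
    stage = names(manifest$counts),
    reads = as.integer(unlist(manifest$counts))
  )
  paths <- c(
    stage_counts = file.path(output_dir, "stage_counts.tsv"),
    bin_table = file.path(output_dir, "bins.tsv"),
    report = file.path(output_dir, "report.html")
  )
  write_tsv_plain(counts, paths[["stage_counts"]])
  write_tsv_plain(manifest$bin_table, paths[["bin_table"]])
  score_html <- ""
  if (!is.null(scores)) {
    paths <- c(paths,
               bin_scores = file.path(output_dir, "bin_scores.tsv"),
               genome_scores = file.path(output_dir, "genome_scores.tsv"))
    write_tsv_plain(scores$bin_scores, paths[["bin_scores"]])
    write_tsv_plain(scores$genome_scores, paths[["genome_scores"]])
    score_html <- paste0(
      "<h2>Bin scores</h2>", html_table(as.data.frame(scores$bin_scores)),
      "<h2>Genome scores</h2>", html_table(as.data.frame(scores$genome_scores))
    )
  }
  html <- paste0(
    "<!DOCTYPE html><html><head><title>overbin report</title></head><body>",
    "<h1>overbin run report</h1>",
    "<h2>Stage read counts</h2>", html_table(as.data.frame(counts)),
    "<h2>Bins (", nrow(manifest$bin_table), ")</h2>",
    html_table(as.data.frame(manifest$bin_table)),
    score_html,
    "<h2>Tasks</h2>", html_table(as.data.frame(manifest$task_status)),
    "</body></html>"
  )
  writeLines(html, paths[["report"]])
  invisible(paths)
}
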