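#' Quality-trimming parameters
#'
#' Defaults follow the usual run settings for short-read quality control:
#' bases below phred 30 are trimmed from both ends and reads shorter than
#' 60 bp after trimming are discarded.
#'
#' @param min_quality Phred threshold; bases strictly below it are trimmed
#'   from the read ends. Default 30.
#' @param min_length Minimum kept read length in bases. Default 60.
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(min_quality = 30L, min_length = 60L) {
  min_quality <- as.integer(min_quality)
  min_length <- as.integer(min_length)
  if (is.na(min_quality) || min_quality < 0L) {
    config_error("min_quality must be >= 0")
  }
  if (is.na(min_length) || min_length < 1L) {
    config_error("min_length must be >= 1")
  }
  structure(list(min_quality = min_quality, min_length = min_length),
            class = "trim_params")
}

read_id_from_header <- function(x) sub("\\s.*$", "", x)

# Structural FASTQ check so malformed records are reported by index.
validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L) {
    parse_error(sprintf(
      "malformed FASTQ: record %d is truncated", length(lines) %/% 4L + 1L
    ))
  }
  n <- length(lines) %/% 4L
  for (r in seq_len(n)) {
    i <- (r - 1L) * 4L
    if (!startsWith(lines[i + 1L], "@")) {
      parse_error(sprintf("malformed FASTQ: record %d missing '@' header", r))
    }
    if (!startsWith(lines[i + 3L], "+")) {
      parse_error(sprintf("malformed FASTQ: record %d missing '+' separator", r))
    }
    if (nchar(lines[i + 2L]) != nchar(lines[i + 4L])) {
      parse_error(sprintf(
        "malformed FASTQ: record %d sequence/quality length mismatch", r
      ))
    }
  }
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA records (2-line or wrapped) yield reads without qualities; FASTQ
#' qualities are decoded with the phred+33 convention. Sequences are
#' normalised to upper case; characters outside `{A,C,G,T,N}` are rejected.
#' SFF is not supported.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return An [reads_tbl()] in file order.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- tolower(format[1])
  if (identical(format, "sff")) {
    config_error("SFF input is not supported; convert to FASTA or FASTQ")
  }
  if (!format %in% c("fasta", "fastq")) {
    config_error(sprintf("unknown sequence format '%s' (use fasta or fastq)",
                         format))
  }
  if (!file.exists(path)) config_error(sprintf("input file not found: %s", path))
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    return(reads_tbl(
      read_id = read_id_from_header(names(ss)),
      sequence = as.character(ss)
    ))
  }
  validate_fastq_lines(path)
  qs <- quiet_mcols(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(qs) == 0L) return(empty_reads())
  quals <- as(Biostrings::quality(qs), "IntegerList")
  reads_tbl(
    read_id = read_id_from_header(names(qs)),
    sequence = as.character(qs),
    qualities = as.list(quals)
  )
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA is emitted as 2-line records; FASTQ uses phred+33. Writing FASTQ
#' requires every read to carry qualities. Round-trips through
#' [read_sequences()] reproduce ids, sequences and qualities.
#'
#' @param reads An [reads_tbl()].
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return The number of records written, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  n <- nrow(reads)
  if (n == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  if (format == "fasta") {
    Biostrings::writeXStringSet(ss, path, width = max(nchar(reads$sequence)))
    return(invisible(n))
  }
  if (!all(has_qualities(reads))) {
    contract_error("fastq output requested but some reads lack qualities")
  }
  qual <- Biostrings::PhredQuality(vapply(
    reads$qualities,
    function(q) rawToChar(as.raw(q + 33L)),
    character(1)
  ))
  quiet_mcols({
    qs <- Biostrings::QualityScaledDNAStringSet(ss, qual)
    Biostrings::writeQualityScaledXStringSet(qs, path)
  })
  invisible(n)
}

#' Trim low-quality read ends and drop short reads
#'
#' Removes the maximal run of bases with quality strictly below
#' `min_quality` from each end of every read (interior bases are never
#' touched), then discards reads whose trimmed length is below
#' `min_length`. Reads without qualities (FASTA provenance) skip trimming
#' and are only length-filtered. The operation is idempotent.
#'
#' @param reads An [reads_tbl()].
#' @param params A [trim_params()].
#' @return `list(kept = reads_tbl, stats = list(trimmed_bases, dropped, kept))`.
#' @export
trim_reads <- function(reads, params = trim_params()) {
  stopifnot(inherits(params, "trim_params"))
  n <- nrow(reads)
  if (n == 0L) {
    return(list(kept = reads,
                stats = list(trimmed_bases = 0L, dropped = 0L, kept = 0L)))
  }
  keep <- logical(n)
  trimmed_bases <- 0L
  seqs <- reads$sequence
  quals <- reads$qualities
  for (i in seq_len(n)) {
    q <- quals[[i]]
    len <- nchar(seqs[i])
    if (is.null(q)) {
      keep[i] <- len >= params$min_length
      next
    }
    good <- which(q >= params$min_quality)
    if (length(good) == 0L) {
      trimmed_bases <- trimmed_bases + len
      next
    }
    from <- good[1]
    to <- good[length(good)]
    trimmed_bases <- trimmed_bases + (from - 1L) + (len - to)
    new_len <- to - from + 1L
    if (new_len < params$min_length) next
    keep[i] <- TRUE
    if (from > 1L || to < len) {
      seqs[i] <- substr(seqs[i], from, to)
      quals[[i]] <- q[from:to]
    }
  }
  kept <- reads_tbl(
    read_id = reads$read_id[keep],
    sequence = seqs[keep],
    qualities = quals[keep],
    mate_of = reads$mate_of[keep],
    origin = reads$origin[keep]
  )
  list(kept = kept,
       stats = list(trimmed_bases = trimmed_bases,
                    dropped = n - sum(keep),
                    kept = sum(keep)))
}
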