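# Shared fixture builders. Everything is generated in code at test time.

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tile a genome with fixed-step reads (forward strand, error free).
tiling_reads <- function(genome, read_length, step, prefix = "r") {
  starts <- seq(1L, nchar(genome) - read_length + 1L, by = step)
  reads_tbl(
    read_id = sprintf("%s%04d", prefix, seq_along(starts)),
    sequence = substring(genome, starts, starts + read_length - 1L)
  )
}

# Pure-R longest-common-substring oracle, independent of the compiled
# kernels: classic DP over the full matrix. 'N' never matches.
lcs_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av); nb <- length(bv)
  if (na == 0 || nb == 0) return(0L)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (av[i] == bv[j] && av[i] != "N") {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# Overlap set computed entirely with the pure-R oracle (both strands).
overlaps_oracle <- function(reads, b) {
  ids <- sort(reads$read_id)
  seqs <- reads$sequence[match(ids, reads$read_id)]
  out <- list()
  n <- length(ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ls <- lcs_oracle(seqs[i], seqs[j])
        lo <- lcs_oracle(seqs[i], revcomp(seqs[j]))
        if (max(ls, lo) >= b) {
          out[[length(out) + 1]] <- data.frame(
            id_a = ids[i], id_b = ids[j], length = max(ls, lo),
            strand = if (ls >= lo) "same" else "opposite",
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      length = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

# A random overlap-detection instance: reads sampled from a few small
# genomes (natural overlaps of varying length) plus unrelated reads.
random_overlap_instance <- function(n_reads, seed) {
  set.seed(seed)
  n_genomes <- sample(1:3, 1)
  genomes <- replicate(n_genomes, random_genome(sample(500:1200, 1)))
  rl <- sample(90:150, 1)
  ids <- sprintf("q%04d", seq_len(n_reads))
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    g <- genomes[[sample.int(n_genomes, 1)]]
    s <- sample.int(nchar(g) - rl + 1L, 1)
    x <- substr(g, s, s + rl - 1L)
    if (runif(1) < 0.5) x <- revcomp(x)
    seqs[i] <- x
  }
  reads_tbl(ids, seqs)
}

overlap_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$id_a, df$id_b, df$length, df$strand, sep = "|"))
}

edge_pairs <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$id_a, df$id_b, sep = "|"))
}
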