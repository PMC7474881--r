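#' Specification of a synthetic community
#'
#' Describes a mixed-species community to simulate: genomes of equal
#' stated length with relative abundances, optionally sharing one
#' conserved segment (a stand-in for ribosomal genes) copied into every
#' genome.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Bases per genome.
#' @param abundances Positive relative weights, normalised to sum 1
#'   (default equal).
#' @param conserved_segment_length Bases of the shared segment copied
#'   into every genome (0 = none).
#' @param seed Random seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_genomes, genome_length,
                           abundances = rep(1, n_genomes),
                           conserved_segment_length = 0L,
                           seed = 1L) {
  if (n_genomes < 1L) config_error("n_genomes must be >= 1")
  if (length(abundances) != n_genomes || any(abundances <= 0)) {
    config_error("abundances must be n_genomes positive weights")
  }
  if (conserved_segment_length >= genome_length) {
    config_error("conserved_segment_length must be < genome_length")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    genome_length = as.integer(genome_length),
    abundances = abundances / sum(abundances),
    conserved_segment_length = as.integer(conserved_segment_length),
    seed = as.integer(seed)
  ), class = "community_spec")
}

#' Specification of read simulation
#'
#' @param coverage Mean per-genome fold coverage.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability.
#' @param paired Emit mate pairs from opposite strands?
#' @param insert_mean,insert_sd Insert-size distribution (paired mode).
#' @param seed Random seed.
#' @return A list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(coverage, read_length, error_rate = 0,
                          paired = FALSE, insert_mean = 300L,
                          insert_sd = 30L, seed = 1L) {
  if (error_rate < 0 || error_rate >= 1) {
    config_error("error_rate must be in [0, 1)")
  }
  if (coverage < 0) config_error("coverage must be >= 0")
  structure(list(
    coverage = coverage,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    paired = isTRUE(paired),
    insert_mean = as.integer(insert_mean),
    insert_sd = as.numeric(insert_sd),
    seed = as.integer(seed)
  ), class = "read_sim_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a community of genomes
#'
#' Genomes are i.i.d. uniform random over `{A,C,G,T}`; when
#' `conserved_segment_length > 0` a single shared segment is written over
#' a random position of every genome, emulating a near-identical
#' ribosomal region capable of falsely connecting reads across species.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @return `list(genomes = named character vector, conserved_segment =
#'   character or NULL)`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    genomes <- vapply(seq_len(spec$n_genomes),
                      function(i) random_dna(spec$genome_length),
                      character(1))
    names(genomes) <- sprintf("g%02d", seq_len(spec$n_genomes))
    segment <- NULL
    if (spec$conserved_segment_length > 0L) {
      segment <- random_dna(spec$conserved_segment_length)
      for (i in seq_along(genomes)) {
        at <- sample.int(spec$genome_length - spec$conserved_segment_length + 1L, 1L)
        substr(genomes[i], at, at + spec$conserved_segment_length - 1L) <- segment
      }
    }
    list(genomes = genomes, conserved_segment = segment)
  })
}

apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < error_rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate reads from a community with ground truth
#'
#' The total read count is `coverage * sum(genome lengths) / read_length`,
#' allocated across genomes proportionally to `abundance * length` (so
#' under equal abundances each genome receives `coverage`-fold coverage).
#' Start positions are uniform; each fragment samples a strand with
#' probability 1/2; paired mode emits mates from opposite fragment ends
#' at a normally distributed insert size. Substitution errors are applied
#' per base. All reads carry constant quality 40 and are labeled in the
#' truth table. Deterministic given `sim$seed`.
#'
#' @param genomes Named character vector from [simulate_community()].
#' @param abundances Relative weights (normalised internally).
#' @param sim A [read_sim_spec()].
#' @return `list(reads = reads_tbl, truth = tibble(read_id, genome),
#'   genomes = the input genomes)`.
#' @export
simulate_reads <- function(genomes, abundances, sim) {
  stopifnot(inherits(sim, "read_sim_spec"))
  glens <- nchar(genomes)
  if (any(sim$read_length > glens)) {
    config_error("read_length must not exceed genome_length")
  }
  abundances <- abundances / sum(abundances)
  w <- abundances * glens
  n_total <- round(sim$coverage * sum(glens) / sim$read_length)
  n_per <- round(n_total * w / sum(w))
  withr::with_seed(sim$seed, {
    ids <- character(0); seqs <- character(0)
    mates <- character(0); origin <- character(0)
    for (gi in seq_along(genomes)) {
      g <- genomes[[gi]]
      gname <- names(genomes)[gi]
      L <- glens[gi]
      rl <- sim$read_length
      n <- n_per[gi]
      if (n == 0L) next
      if (!sim$paired) {
        starts <- sample.int(L - rl + 1L, n, replace = TRUE)
        fwd <- runif(n) < 0.5
        s <- substring(g, starts, starts + rl - 1L)
        s[!fwd] <- revcomp(s[!fwd])
        if (sim$error_rate > 0) {
          s <- vapply(s, apply_errors, character(1), sim$error_rate,
                      USE.NAMES = FALSE)
        }
        id <- sprintf("%s_r%06d", gname, seq_len(n))
        ids <- c(ids, id); seqs <- c(seqs, s)
        mates <- c(mates, rep(NA_character_, n))
        origin <- c(origin, rep(gname, n))
      } else {
        n_frag <- ceiling(n / 2)
        ins <- pmin(pmax(round(rnorm(n_frag, sim$insert_mean, sim$insert_sd)),
                         rl), L)
        starts <- vapply(ins, function(l) sample.int(L - l + 1L, 1L),
                         integer(1))
        flip <- runif(n_frag) < 0.5
        for (fi in seq_len(n_frag)) {
          frag <- substr(g, starts[fi], starts[fi] + ins[fi] - 1L)
          if (flip[fi]) frag <- revcomp(frag)
          r1 <- substr(frag, 1L, rl)
          r2 <- revcomp(substr(frag, ins[fi] - rl + 1L, ins[fi]))
          if (sim$error_rate > 0) {
            r1 <- apply_errors(r1, sim$error_rate)
            r2 <- apply_errors(r2, sim$error_rate)
          }
          stem <- sprintf("%s_p%06d", gname, fi)
          ids <- c(ids, paste0(stem, "/1"), paste0(stem, "/2"))
          seqs <- c(seqs, r1, r2)
          mates <- c(mates, paste0(stem, "/2"), paste0(stem, "/1"))
          origin <- c(origin, gname, gname)
        }
      }
    }
    reads <- reads_tbl(
      read_id = ids,
      sequence = seqs,
      qualities = lapply(nchar(seqs), function(l) rep(40L, l)),
      mate_of = mates,
      origin = origin
    )
    list(
      reads = reads,
      truth = tibble::tibble(read_id = ids, genome = origin),
      genomes = genomes
    )
  })
}
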