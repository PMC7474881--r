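test_that("revcomp is an involution mapping N to N", {
  set.seed(5)
  seqs <- c("N", "ACGTN", replicate(20, random_genome(sample(1:60, 1))))
  expect_identical(revcomp(revcomp(seqs)), seqs)
  expect_identical(revcomp("ANNT"), "ANNT")
  expect_identical(revcomp("ACGT"), "ACGT") # palindrome
})

test_that("merge_pair joins mates through a suffix/prefix overlap", {
  p <- merge_params(min_overlap = 4)
  r1 <- reads_tbl("a/1", "AAAACCCC")
  r2 <- reads_tbl("a/2", revcomp("CCCCGGGG")) # sequencing orientation
  m <- merge_pair(r1, r2, p)
  expect_equal(m$sequence, "AAAACCCCGGGG")
  expect_false(m$forced)
  expect_equal(m$source_ids[[1]], c("a/1", "a/2"))
  # exhaustive offset-scan oracle: the only overlap >= 4 has length 4
  s2 <- "CCCCGGGG"
  lens <- vapply(1:8, function(ov) {
    all(substring("AAAACCCC", 8 - ov + 1, 8) == substring(s2, 1, ov))
  }, logical(1))
  expect_equal(max(which(lens)), 4L)
})

test_that("merge_pair returns the no-merge signal without a real overlap", {
  p <- merge_params(min_overlap = 10)
  r1 <- reads_tbl("b/1", random_genome(40, seed = 31))
  r2 <- reads_tbl("b/2", random_genome(40, seed = 32))
  # premise: no 10-base suffix/prefix agreement (checked by scan)
  s2 <- revcomp(r2$sequence)
  agree <- vapply(10:40, function(ov) {
    mism <- sum(strsplit(substr(r1$sequence, 41 - ov, 40), "")[[1]] !=
                  strsplit(substr(s2, 1, ov), "")[[1]])
    mism <= floor(0.1 * ov)
  }, logical(1))
  expect_false(any(agree))
  expect_null(merge_pair(r1, r2, p))
})

test_that("full containment merges to r1 and empty reads are rejected", {
  s <- random_genome(50, seed = 33)
  r1 <- reads_tbl("c/1", s)
  r2 <- reads_tbl("c/2", revcomp(s))
  m <- merge_pair(r1, r2, merge_params(min_overlap = 10))
  expect_equal(m$sequence, s)
  expect_error(merge_pair(list(read_id = "x", sequence = "", qualities = NULL),
                          r2), class = "overbin_contract_error")
})

test_that("mismatches in the overlap resolve toward the higher quality base", {
  # overlap of 10 with one mismatch at overlap position 5
  left <- "TTTTT"
  ov1 <- "ACGTACGTAC"
  ov2 <- "ACGTTCGTAC"
  right <- "GGGGG"
  r1 <- reads_tbl("d/1", paste0(left, ov1),
                  qualities = list(rep(20L, 15)))
  r2 <- reads_tbl("d/2", revcomp(paste0(ov2, right)),
                  qualities = list(rep(30L, 15)))
  m <- merge_pair(r1, r2, merge_params(min_overlap = 8, max_mismatch_rate = 0.2))
  expect_equal(m$sequence, paste0(left, ov2, right)) # r2 base wins (q30 > q20)
  expect_equal(m$qualities[[1]], c(rep(20L, 5), rep(30L, 10), rep(30L, 5)))
})

test_that("force_merge inserts exactly three N characters at the junction", {
  r1 <- reads_tbl("p/1", "ATCGT")
  r2 <- reads_tbl("p/2", revcomp("TTATC"))
  m <- force_merge(r1, r2)
  expect_equal(m$sequence, "ATCGTNNNTTATC")
  expect_true(m$forced)
  expect_equal(substr(m$sequence, 6, 8), "NNN")
  # minimal mates
  mm <- force_merge(reads_tbl("q/1", "A"), reads_tbl("q/2", "A"))
  expect_equal(mm$sequence, "ANNNT")
  # length law on random mates
  set.seed(41)
  for (i in 1:5) {
    a <- reads_tbl("x/1", random_genome(sample(1:50, 1)))
    b <- reads_tbl("x/2", random_genome(sample(1:50, 1)))
    out <- force_merge(a, b)
    expect_equal(nchar(out$sequence),
                 nchar(a$sequence) + nchar(b$sequence) + 3L)
  }
})

test_that("prepare_binning_input merges pairs, passes singles, keeps provenance", {
  empty <- prepare_binning_input()
  expect_equal(nrow(empty$merged), 0L)
  expect_length(empty$provenance, 0L)

  g <- random_genome(400, seed = 51)
  # two overlapping pairs (fragments shorter than 2 reads)
  frag1 <- substr(g, 1, 150)
  frag2 <- substr(g, 200, 360)
  mk_pair <- function(stem, frag, rl = 100) {
    r1 <- substr(frag, 1, rl)
    r2 <- revcomp(substr(frag, nchar(frag) - rl + 1, nchar(frag)))
    reads_tbl(paste0(stem, c("/1", "/2")), c(r1, r2),
              mate_of = paste0(stem, c("/2", "/1")))
  }
  pairs <- rbind(mk_pair("p1", frag1), mk_pair("p2", frag2))
  single <- reads_tbl("s1", random_genome(80))
  prep <- prepare_binning_input(pairs, single, merge_params())
  expect_equal(nrow(prep$merged), 3L)
  expect_false(any(prep$merged$forced))
  expect_setequal(restore_original(prep$merged$merged_id, prep$provenance),
                  c(pairs$read_id, "s1"))

  # non-overlapping mates fall back to the forced merge
  far <- rbind(
    reads_tbl("f/1", random_genome(60, seed = 61), mate_of = "f/2"),
    reads_tbl("f/2", random_genome(60, seed = 62), mate_of = "f/1")
  )
  prep2 <- prepare_binning_input(far, params = merge_params())
  expect_equal(nrow(prep2$merged), 1L)
  expect_true(prep2$merged$forced)
  expect_equal(restore_original(prep2$merged$merged_id, prep2$provenance),
               c("f/1", "f/2"))
})

test_that("dangling mate links and unknown merged ids are contract errors", {
  bad <- reads_tbl(c("a/1", "a/2"), c("ACGTACGTACGT", "ACGTACGTACGT"),
                   mate_of = c("a/2", "zzz"))
  expect_error(prepare_binning_input(bad), "a/1|a/2",
               class = "overbin_contract_error")
  expect_error(restore_original("nope", list(x = "y")),
               class = "overbin_contract_error")
})

test_that("merged-read conservation holds on a simulated paired set", {
  cs <- community_spec(2, 2000, seed = 71)
  com <- simulate_community(cs)
  sim <- simulate_reads(com$genomes, cs$abundances,
                        read_sim_spec(coverage = 3, read_length = 80,
                                      paired = TRUE, insert_mean = 180,
                                      insert_sd = 15, seed = 72))
  ps <- sim$reads
  n_pairs <- sum(!is.na(ps$mate_of)) / 2
  prep <- prepare_binning_input(ps[!is.na(ps$mate_of), ],
                                ps[is.na(ps$mate_of), ])
  expect_equal(nrow(prep$merged), n_pairs + sum(is.na(ps$mate_of)))
  expect_setequal(restore_original(prep$merged$merged_id, prep$provenance),
                  ps$read_id)
  # forced merges carry the NNN junction at the stated position
  forced <- prep$merged[prep$merged$forced, ]
  if (nrow(forced) > 0) {
    for (i in seq_len(nrow(forced))) {
      first_len <- nchar(forced$sequence[i]) -
        3L - sum(nchar(ps$sequence[ps$read_id == forced$source_ids[[i]][2]]))
      expect_equal(substr(forced$sequence[i], first_len + 1, first_len + 3),
                   "NNN")
    }
  }
})
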