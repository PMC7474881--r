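test_that("single reads and sub-threshold sharing give no edges", {
  one <- reads_tbl("a", random_genome(100, seed = 1))
  expect_equal(nrow(find_overlaps_bruteforce(one, 30)), 0L)
  expect_equal(nrow(find_overlaps_indexed(one, 30)), 0L)
})

test_that("an exact shared block is an edge exactly at its length", {
  set.seed(2)
  block <- random_genome(70)
  r <- reads_tbl(c("x", "y"),
                 c(paste0(random_genome(40), block),
                   paste0(block, random_genome(40))))
  e70 <- find_overlaps_bruteforce(r, 70)
  expect_equal(nrow(e70), 1L)
  expect_equal(e70$length, 70L)
  expect_equal(nrow(find_overlaps_bruteforce(r, 71)), 0L)
  expect_equal(nrow(find_overlaps_indexed(r, 71)), 0L)
})

test_that("reverse-complement slices are found with strand = opposite", {
  set.seed(3)
  x <- random_genome(150)
  slice <- revcomp(substr(x, 41, 100)) # 60-base opposite-strand slice
  r <- reads_tbl(c("x", "y"), c(x, paste0(random_genome(30), slice)))
  e <- find_overlaps_bruteforce(r, 50)
  expect_equal(nrow(e), 1L)
  expect_equal(e$strand, "opposite")
  # pure-R longest-common-substring oracle confirms the length
  expect_equal(e$length, lcs_oracle(x, revcomp(r$sequence[2])))
})

test_that("duplicate reads give one identity edge", {
  s <- random_genome(90, seed = 4)
  r <- reads_tbl(c("a", "b"), c(s, s))
  e <- find_overlaps_indexed(r, 70)
  expect_equal(nrow(e), 1L)
  expect_equal(e$length, 90L)
})

test_that("indexed detection equals brute force on random instances", {
  cases <- expand.grid(seed = 1:4, b = c(30L, 50L, 70L))
  for (i in seq_len(nrow(cases))) {
    reads <- random_overlap_instance(n_reads = 40, seed = 1000 + cases$seed[i])
    bf <- find_overlaps_bruteforce(reads, cases$b[i])
    ix <- find_overlaps_indexed(reads, cases$b[i])
    expect_identical(overlap_key(bf), overlap_key(ix),
                     label = sprintf("instance seed=%d b=%d",
                                     cases$seed[i], cases$b[i]))
  }
})

test_that("both detectors agree with the pure-R oracle on tiny instances", {
  for (seed in 1:3) {
    reads <- random_overlap_instance(n_reads = 10, seed = 2000 + seed)
    oracle <- overlaps_oracle(reads, 30)
    expect_identical(overlap_key(find_overlaps_bruteforce(reads, 30)),
                     overlap_key(oracle))
    expect_identical(overlap_key(find_overlaps_indexed(reads, 30)),
                     overlap_key(oracle))
  }
})

test_that("reads with no shared b-mer across genomes give no cross edges", {
  set.seed(6)
  gA <- random_genome(2000)
  gB <- random_genome(2000)
  # premise verified by brute force: no shared 30-mer on either strand
  kmers <- function(s) substring(s, 1:(nchar(s) - 29), 30:nchar(s))
  expect_length(intersect(kmers(gA), c(kmers(gB), kmers(revcomp(gB)))), 0L)
  rA <- tiling_reads(gA, 100, 200, prefix = "A")
  rB <- tiling_reads(gB, 100, 200, prefix = "B")
  e <- find_overlaps_indexed(rbind(rA, rB), 30)
  cross <- xor(startsWith(e$id_a, "A"), startsWith(e$id_b, "A"))
  expect_false(any(cross))
})

test_that("edge sets shrink monotonically as b grows", {
  reads <- random_overlap_instance(n_reads = 60, seed = 3001)
  e70 <- edge_pairs(find_overlaps_indexed(reads, 70))
  e50 <- edge_pairs(find_overlaps_indexed(reads, 50))
  e30 <- edge_pairs(find_overlaps_indexed(reads, 30))
  expect_true(all(e70 %in% e50))
  expect_true(all(e50 %in% e30))
})

test_that("reverse-complementing a read flips strands but not connectivity", {
  reads <- random_overlap_instance(n_reads = 30, seed = 3002)
  before <- find_overlaps_indexed(reads, 30)
  flipped <- reads
  flipped$sequence[5] <- revcomp(flipped$sequence[5])
  after <- find_overlaps_indexed(flipped, 30)
  expect_identical(edge_pairs(before), edge_pairs(after))
  id5 <- reads$read_id[5]
  touched <- before$id_a == id5 | before$id_b == id5
  expect_identical(before$strand[!touched], after$strand[!touched])
  expect_true(all(before$strand[touched] != after$strand[touched]))
})

test_that("the mismatch-tolerant mode finds alignments the exact mode misses", {
  set.seed(7)
  core <- random_genome(80)
  ch <- strsplit(core, "")[[1]]
  ch[40] <- setdiff(c("A", "C", "G", "T"), ch[40])[1]
  mut <- paste(ch, collapse = "")
  r <- reads_tbl(c("a", "b"),
                 c(paste0(random_genome(20), core),
                   paste0(mut, random_genome(20))))
  expect_equal(nrow(find_overlaps_indexed(r, 70, max_mismatches = 0)), 0L)
  e <- find_overlaps_indexed(r, 70, max_mismatches = 1)
  expect_equal(nrow(e), 1L)
  expect_gte(e$length, 80L)
  expect_identical(overlap_key(e),
                   overlap_key(find_overlaps_bruteforce(r, 70,
                                                        max_mismatches = 1)))
})

test_that("build_graph keeps isolated nodes and obeys the handshake lemma", {
  empty <- overbin::find_overlaps_indexed(
    reads_tbl(c("a", "b"), c(random_genome(50, seed = 8),
                             random_genome(50, seed = 9))), 40)
  g0 <- build_graph(empty, c("n1", "n2", "n3", "n4", "n5"))
  expect_equal(unname(igraph::degree(g0)), rep(0, 5))

  tri <- tibble::tibble(id_a = c("1", "1", "2"), id_b = c("2", "3", "3"),
                        length = 70L, strand = "same")
  gt <- build_graph(tri, c("1", "2", "3"))
  expect_equal(unname(igraph::degree(gt)), rep(2, 3))

  set.seed(10)
  nodes <- sprintf("v%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  take <- sample(nrow(pairs), 20)
  rnd <- tibble::tibble(id_a = pairs[take, 1], id_b = pairs[take, 2],
                        length = 30L, strand = "same")
  gr <- build_graph(rnd, nodes)
  expect_equal(sum(igraph::degree(gr)), 2L * nrow(rnd))

  expect_error(build_graph(tri, c("1", "2")), class = "overbin_contract_error")
})
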