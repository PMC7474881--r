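test_that("mad_spread follows the median / MAD / 1.4826 definitions", {
  s <- mad_spread(c(7, 7, 7, 7))
  expect_equal(s$median, 7)
  expect_equal(s$mad, 0)
  expect_equal(s$sigma_hat, 0)

  s <- mad_spread(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$mad, 1) # deviations 2,1,0,1,2
  expect_equal(s$sigma_hat, 1.4826)

  expect_equal(mad_sigma_factor(), 1.4826)
  expect_error(mad_spread(numeric(0)), class = "overbin_contract_error")
})

test_that("the MAD filter removes exactly the far-out degrees", {
  deg <- stats::setNames(c(5, 5, 6, 6, 7, 7, 8, 100), paste0("r", 1:8))
  f <- mad_outlier_filter(deg, cutoff = 3)
  # median 6.5, mad 1, sigma_hat 1.4826, threshold 4.4478: only 100 is out
  expect_equal(f$spread$median, 6.5)
  expect_equal(f$spread$mad, 1)
  expect_equal(f$removed_ids, "r8")
  expect_setequal(c(f$kept_ids, f$removed_ids), names(deg))
  expect_false(f$mad_degenerate)

  uniform <- stats::setNames(rep(4, 10), paste0("u", 1:10))
  fu <- mad_outlier_filter(uniform)
  expect_length(fu$removed_ids, 0L)
  expect_true(fu$mad_degenerate)

  # raw-MAD variant uses cutoff * MAD: degree 8 sits outside 6.5 +/- 3
  fr <- mad_outlier_filter(deg, cutoff = 3, raw_mad = TRUE)
  expect_setequal(fr$removed_ids, c("r5", "r6", "r7", "r8")[4]) # |8-6.5|<=3
  expect_equal(fr$removed_ids, "r8")
})

test_that("on normal degrees the filter removes roughly the 3-sigma tail", {
  set.seed(123)
  deg <- stats::setNames(rnorm(10000, mean = 50, sd = 8), sprintf("n%05d", 1:10000))
  f <- mad_outlier_filter(deg, cutoff = 3)
  frac <- length(f$removed_ids) / 10000
  expect_lte(frac, 0.01) # expected about 0.0027
  expect_gt(frac, 0)
})

test_that("extract_bins reports components and keeps the partition exact", {
  params <- binning_params(min_bin_size = 2)
  empty <- build_graph(
    tibble::tibble(id_a = character(0), id_b = character(0),
                   length = integer(0), strand = character(0)),
    c("a", "b", "c"))
  bs <- extract_bins(empty, params)
  expect_length(bs$bins, 0L)
  expect_setequal(bs$leftover_ids, c("a", "b", "c"))

  ed <- tibble::tibble(id_a = c("1", "2", "4"), id_b = c("2", "3", "5"),
                       length = 70L, strand = "same")
  g <- build_graph(ed, as.character(1:5))
  bs <- extract_bins(g, params)
  expect_length(bs$bins, 2L)
  expect_equal(bs$bins[[1]]$read_ids, c("1", "2", "3"))
  expect_equal(bs$bins[[2]]$read_ids, c("4", "5"))
  expect_length(bs$leftover_ids, 0L)
  # histogram counts sum to bin size + removed outliers
  for (bn in bs$bins) {
    expect_equal(sum(bn$degree_histogram$count),
                 length(bn$read_ids) + length(bn$removed_outliers))
  }
})

test_that("a high-degree bridge read is filtered and the component splits", {
  # two noisy near-cliques joined by one bridge connected to most nodes
  set.seed(31)
  side <- function(prefix) {
    nodes <- sprintf("%s%02d", prefix, 1:30)
    pr <- t(combn(nodes, 2))
    keep <- runif(nrow(pr)) < 0.75
    list(nodes = nodes, edges = pr[keep, , drop = FALSE])
  }
  A <- side("a"); B <- side("b")
  bridge_to <- c(A$nodes[1:25], B$nodes[1:25])
  ed <- rbind(A$edges, B$edges, cbind("zz", bridge_to))
  ov <- tibble::tibble(id_a = pmin(ed[, 1], ed[, 2]),
                       id_b = pmax(ed[, 1], ed[, 2]),
                       length = 70L, strand = "same")
  nodes <- c(A$nodes, B$nodes, "zz")
  g <- build_graph(ov, nodes)
  # oracle: apply the rule by hand to the component degrees
  deg <- igraph::degree(g)
  f <- mad_outlier_filter(deg[nodes], cutoff = 3)
  expect_true("zz" %in% f$removed_ids)

  bs <- extract_bins(g, binning_params(min_bin_size = 10))
  expect_length(bs$bins, 2L)
  expect_true("zz" %in% bs$leftover_ids)
  sides <- vapply(bs$bins, function(b) {
    paste(sort(unique(substr(b$read_ids, 1, 1))), collapse = "")
  }, character(1))
  expect_setequal(sides, c("a", "b"))
  # the pre-filter histogram isolates the bridge degree
  rep1 <- degree_histogram_report(bs$bins[[1]])
  expect_true(max(rep1$histogram$degree) >= length(bridge_to))
})

test_that("iterative binning withdraws reads and records b_used", {
  params0 <- binning_params(b_schedule = integer(0), min_bin_size = 3)
  reads <- tiling_reads(random_genome(400, seed = 41), 100, 25, prefix = "A")
  bs0 <- iterative_binning(reads, params0)
  expect_length(bs0$bins, 0L)
  expect_setequal(bs0$leftover_ids, reads$read_id)

  gA <- random_genome(400, seed = 42)
  gB <- random_genome(400, seed = 43)
  # premise: the genomes share no 50-base substring (oracle-checked)
  expect_lt(lcs_oracle(gA, gB), 50)
  expect_lt(lcs_oracle(gA, revcomp(gB)), 50)
  rA <- tiling_reads(gA, 100, 25, prefix = "A") # adjacent overlaps 75
  rB <- tiling_reads(gB, 100, 40, prefix = "B") # adjacent overlaps 60
  both <- rbind(rA, rB)
  bs <- iterative_binning(both, binning_params(b_schedule = c(70L, 50L),
                                               min_bin_size = 3))
  expect_length(bs$bins, 2L)
  b_used <- stats::setNames(
    vapply(bs$bins, `[[`, integer(1), "b_used"),
    vapply(bs$bins, function(b) substr(b$read_ids[1], 1, 1), character(1))
  )
  expect_equal(b_used[["A"]], 70L)
  expect_equal(b_used[["B"]], 50L)
  ids_of <- function(p) sort(both$read_id[startsWith(both$read_id, p)])
  expect_equal(bs$bins[[which(names(b_used) == "A")]]$read_ids, ids_of("A"))
  expect_equal(bs$bins[[which(names(b_used) == "B")]]$read_ids, ids_of("B"))
})

test_that("an exhausted pool leaves later iterations empty", {
  reads <- tiling_reads(random_genome(500, seed = 44), 100, 20, prefix = "A")
  bs <- iterative_binning(reads, binning_params(b_schedule = c(70L, 50L, 30L),
                                                min_bin_size = 3))
  expect_length(bs$bins, 1L)
  expect_equal(bs$bins[[1]]$b_used, 70L)
  expect_length(bs$leftover_ids, 0L)
})

test_that("block binning is identical to the plain path for one block", {
  reads <- random_overlap_instance(60, seed = 45)
  p <- binning_params(b_schedule = c(70L, 50L), min_bin_size = 5,
                      block_size = 1e6)
  expect_identical(block_binning(reads, p), iterative_binning(reads, p))
})

test_that("cross-block overlaps merge a genome split over two blocks", {
  g <- random_genome(700, seed = 46)
  reads <- tiling_reads(g, 100, 20, prefix = "A") # 31 reads
  p <- binning_params(b_schedule = 70L, min_bin_size = 3,
                      block_size = 16)
  bs <- block_binning(reads, p)
  expect_length(bs$bins, 1L)
  expect_setequal(bs$bins[[1]]$read_ids, reads$read_id)
})

test_that("unrelated genomes stay in separate pure bins across blocks", {
  gA <- random_genome(700, seed = 47)
  gB <- random_genome(700, seed = 48)
  expect_lt(lcs_oracle(gA, gB), 70)
  reads <- rbind(tiling_reads(gA, 100, 20, prefix = "A"),
                 tiling_reads(gB, 100, 20, prefix = "B"))
  p <- binning_params(b_schedule = 70L, min_bin_size = 3, block_size = 21)
  bs <- block_binning(reads, p)
  expect_length(bs$bins, 2L)
  purity <- vapply(bs$bins, function(b) {
    max(table(substr(b$read_ids, 1, 1))) / length(b$read_ids)
  }, numeric(1))
  expect_equal(unname(purity), c(1, 1))
})

test_that("binning conserves and never duplicates reads, deterministically", {
  reads <- random_overlap_instance(80, seed = 49)
  p <- binning_params(b_schedule = c(50L, 30L), min_bin_size = 4)
  bs1 <- iterative_binning(reads, p)
  bs2 <- iterative_binning(reads, p)
  expect_identical(bs1, bs2)
  all_ids <- c(unlist(lapply(bs1$bins, `[[`, "read_ids")), bs1$leftover_ids)
  expect_setequal(all_ids, reads$read_id)
  expect_false(anyDuplicated(all_ids) > 0)
})
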