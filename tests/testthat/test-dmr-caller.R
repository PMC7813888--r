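test_that("site differences match a direct per-site recomputation", {
  g <- random_genome(500, seed = 21)
  A <- random_sample(g, seed = 22)
  B <- random_sample(g, seed = 23)
  for (ctx in c("CG", "CHH")) {
    got <- site_differences(A, B, ctx, min_coverage = 4L)
    exp <- oracle_site_diffs(A, B, ctx, 4L)
    exp <- exp[order(exp$chrom, exp$pos, exp$strand), ]
    rownames(exp) <- NULL
    expect_equal(got[c("chrom", "pos", "strand")],
                 exp[c("chrom", "pos", "strand")])
    expect_equal(got$diff, exp$diff, tolerance = 1e-12)
  }
})

test_that("identical samples give all-zero differences and no DMRs", {
  g <- random_genome(2000, seed = 31)
  A <- random_sample(g, seed = 32)
  expect_true(all(site_differences(A, A, "CG", 4L)$diff == 0))
  dm <- call_dmrs(A, A)
  expect_true(all(vapply(dm, nrow, 0L) == 0L))
})

test_that("extreme single-site difference is +/- 1", {
  A <- sample_from_counts("chr1", 10L, "+", 10L, 0L, "CG")
  B <- sample_from_counts("chr1", 10L, "+", 0L, 10L, "CG")
  expect_equal(site_differences(A, B, "CG", 4L)$diff, 1)
  expect_equal(site_differences(B, A, "CG", 4L)$diff, -1)
})

test_that("candidate bins honour the per-context thresholds", {
  p <- dmr_params()
  base <- data.frame(chrom = "chr1", pos = c(10L, 30L), strand = "+",
                     context = "CG", level_A = 0, level_B = 0,
                     stringsAsFactors = FALSE)
  # two CG sites at diff -0.45: one hypo bin
  d <- base; d$diff <- c(-0.45, -0.45)
  b <- call_candidate_bins(d, p, "CG")
  expect_equal(nrow(b), 1L)
  expect_equal(b$direction, "hypo")
  expect_equal(c(b$start, b$end), c(0L, 50L))
  expect_equal(b$n_sites, 2L)
  # just below the 0.40 threshold: nothing
  d$diff <- c(-0.39, -0.39)
  expect_equal(nrow(call_candidate_bins(d, p, "CG")), 0L)
  # exactly at the threshold qualifies (absolute difference "of 0.40")
  d$diff <- c(-0.40, -0.40)
  expect_equal(nrow(call_candidate_bins(d, p, "CG")), 1L)
  # one site is not enough for CG
  d <- d[1, ]; d$diff <- -0.9
  expect_equal(nrow(call_candidate_bins(d, p, "CG")), 0L)
})

test_that("a bin can qualify in both directions", {
  p <- dmr_params()
  d <- data.frame(chrom = "chr1", pos = c(5L, 15L, 25L, 35L), strand = "+",
                  context = "CG", level_A = 0, level_B = 0,
                  diff = c(-0.8, -0.8, 0.8, 0.8), stringsAsFactors = FALSE)
  b <- call_candidate_bins(d, p, "CG")
  expect_equal(sort(b$direction), c("hyper", "hypo"))
  expect_equal(b$start, c(0L, 0L))
})

test_that("bins within the merge gap fuse transitively, beyond it stay apart", {
  mk <- function(starts) data.frame(
    chrom = "chr1", start = starts, end = starts + 50L, context = "CG",
    direction = "hypo", n_sites = 2L, sum_abs_diff = 1.0,
    stringsAsFactors = FALSE)
  # gap 350 <= 400: merge into [0, 450)
  m <- merge_bins(mk(c(0L, 400L)), 400L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 450L))
  expect_equal(m$n_sites, 4L)
  expect_equal(m$n_bins_merged, 2L)
  # gap 401 > 400: two DMRs
  m2 <- merge_bins(mk(c(0L, 451L)), 400L)
  expect_equal(nrow(m2), 2L)
  # transitive chain: each neighbour within gap
  m3 <- merge_bins(mk(c(0L, 400L, 800L)), 400L)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start, m3$end), c(0L, 850L))
  # single bin passes through unchanged
  m4 <- merge_bins(mk(0L), 400L)
  expect_equal(c(m4$start, m4$end, m4$n_bins_merged), c(0L, 50L, 1L))
})

test_that("merging respects direction and chromosome boundaries", {
  bins <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(0L, 100L, 0L), end = c(50L, 150L, 50L),
                     context = "CG", direction = c("hypo", "hyper", "hypo"),
                     n_sites = 2L, sum_abs_diff = 1.0,
                     stringsAsFactors = FALSE)
  m <- merge_bins(bins, 400L)
  expect_equal(nrow(m), 3L)
  expect_error(merge_bins(transform(bins, context = c("CG", "CHG", "CG")),
                          400L), "single context")
})

test_that("weighted methylation equals direct summation", {
  g <- random_genome(300, seed = 41)
  s <- random_sample(g, seed = 42)
  df <- as.data.frame(s)
  for (win in list(c(0L, 100L), c(50L, 300L))) {
    sel <- df$context == "CG" & df$pos - 1L >= win[1] & df$pos - 1L < win[2]
    tot <- sum(df$count_meth[sel] + df$count_unmeth[sel])
    expect_equal(weighted_methylation(s, "chrT", win[1], win[2], "CG"),
                 sum(df$count_meth[sel]) / tot)
  }
  # fully methylated region
  s2 <- sample_from_counts("chr1", c(2L, 10L), "+", c(5L, 8L), c(0L, 0L), "CG")
  expect_equal(weighted_methylation(s2, "chr1", 0L, 20L, "CG"), 1)
  # zero coverage is undefined, not zero
  expect_true(is.na(weighted_methylation(s2, "chr1", 100L, 200L, "CG")))
  expect_error(weighted_methylation(s2, "chr1", 10L, 10L, "CG"), "start")
})

test_that("call_dmrs matches the brute-force tile-and-closure oracle", {
  p <- dmr_params()
  for (rep in 1:12) {
    g <- random_genome(600, seed = 5000 + rep)
    A <- random_sample(g, seed = 6000 + rep)
    B <- random_sample(g, seed = 7000 + rep)
    got <- dmr_table(call_dmrs(A, B, p))
    exp <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx)
      oracle_call_dmrs(A, B, p, ctx)))
    exp <- exp[order(exp$chrom, exp$start, exp$context, exp$direction), ]
    rownames(exp) <- NULL
    expect_equal(got[c("chrom", "start", "end", "context", "direction",
                       "n_sites")],
                 exp[c("chrom", "start", "end", "context", "direction",
                       "n_sites")])
    expect_equal(got$meth_A, exp$meth_A, tolerance = 1e-12)
    expect_equal(got$meth_B, exp$meth_B, tolerance = 1e-12)
    expect_equal(got$mean_abs_diff, exp$mean_abs_diff, tolerance = 1e-12)
  }
})

test_that("swapping samples flips hypo and hyper but keeps intervals", {
  g <- random_genome(800, seed = 51)
  A <- random_sample(g, seed = 52)
  B <- random_sample(g, seed = 53)
  ab <- dmr_table(call_dmrs(A, B))
  ba <- dmr_table(call_dmrs(B, A))
  flip <- c(hypo = "hyper", hyper = "hypo")
  ba$direction <- unname(flip[ba$direction])
  ba <- ba[order(ba$chrom, ba$start, ba$context, ba$direction), ]
  rownames(ba) <- NULL
  expect_equal(ab[c("chrom", "start", "end", "context", "direction",
                    "n_sites")],
               ba[c("chrom", "start", "end", "context", "direction",
                    "n_sites")])
  expect_equal(ab$meth_A, ba$meth_B, tolerance = 1e-12)
})

test_that("stricter thresholds never add bins; larger gaps never add DMRs", {
  g <- random_genome(1500, seed = 61)
  A <- random_sample(g, seed = 62)
  B <- random_sample(g, seed = 63)
  d <- site_differences(A, B, "CG", 4L)
  p1 <- dmr_params()
  n1 <- nrow(call_candidate_bins(d, p1, "CG"))
  for (diff_thr in c(0.5, 0.7, 0.9)) {
    p2 <- dmr_params(min_abs_diff = c(CG = diff_thr, CHG = 0.25, CHH = 0.10))
    expect_lte(nrow(call_candidate_bins(d, p2, "CG")), n1)
  }
  for (ms in c(3L, 4L)) {
    p3 <- dmr_params(min_sites = c(CG = ms, CHG = 3L, CHH = 4L))
    expect_lte(nrow(call_candidate_bins(d, p3, "CG")), n1)
  }
  bins <- call_candidate_bins(d, p1, "CG")
  prev_n <- Inf; prev_bp <- 0
  for (gap in c(0L, 100L, 400L, 1000L)) {
    m <- merge_bins(bins, gap)
    expect_lte(nrow(m), prev_n)
    expect_gte(sum(m$end - m$start), prev_bp)
    prev_n <- nrow(m); prev_bp <- sum(m$end - m$start)
  }
})

test_that("DMR tables are deterministic for identical inputs", {
  g <- random_genome(800, seed = 71)
  A <- random_sample(g, seed = 72)
  B <- random_sample(g, seed = 73)
  t1 <- dmr_table(call_dmrs(A, B))
  t2 <- dmr_table(call_dmrs(A, B))
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_dmr_table(t1, f1); write_dmr_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cluster_order reproduces complete-linkage structure", {
  # identical columns merge at height 0 and sit adjacent
  m <- cbind(a = c(0, 1), b = c(1, 0), a2 = c(0, 1))
  ord <- cluster_order(m)
  pos <- match(c(1, 3), ord)
  expect_equal(abs(diff(pos)), 1)
  h <- attr(ord, "heights")
  expect_equal(min(h), 0)
  # 3 columns with pairwise distances 1, 2, 3: closest pair merges first
  # at height 1 and the final merge is at the max distance 3
  m3 <- cbind(x = 0, y = 1, z = 3)
  h3 <- attr(cluster_order(m3), "heights")
  expect_equal(h3, c(1, 3))
  expect_error(cluster_order(m3[, 1, drop = FALSE]), "2 columns")
  m3[1, 1] <- NA
  expect_error(cluster_order(m3), "missing")
})

test_that("cluster_order merge heights equal the naive reimplementation", {
  for (rep in 1:10) {
    set.seed(8000 + rep)
    m <- matrix(runif(5 * 10), nrow = 5)
    got <- sort(attr(cluster_order(m), "heights"))
    exp <- sort(oracle_complete_linkage_heights(m))
    expect_equal(got, exp, tolerance = 1e-10)
  }
})

test_that("methylation matrix holds weighted levels with NA for no coverage", {
  g <- random_genome(400, seed = 81)
  s1 <- random_sample(g, seed = 82)
  s2 <- random_sample(g, seed = 83)
  regions <- data.frame(chrom = "chrT", start = c(0L, 100L),
                        end = c(100L, 200L))
  m <- methylation_matrix(list(a = s1, b = s2), regions, "CG")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["a", 1], weighted_methylation(s1, "chrT", 0L, 100L, "CG"))
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
})

test_that("dmr_params validates thresholds", {
  expect_error(dmr_params(bin_size = 0L), "bin_size")
  expect_error(dmr_params(min_sites = c(CG = 0L, CHG = 3L, CHH = 4L)),
               "min_sites")
  expect_error(dmr_params(min_abs_diff = c(CG = 1.2, CHG = 0.25, CHH = 0.1)),
               "min_abs_diff")
  expect_error(dmr_params(merge_gap = -1L), "merge_gap")
  expect_error(site_differences(NULL, NULL, "CNN"), "context")
})
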