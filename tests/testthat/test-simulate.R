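small_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 60000L, n_genes = 12L, n_truth_regions = 6L,
         n_hyper_regions = 2L),
    list(...))
  do.call(simulation_config, args)
}

test_that("genome generation is deterministic and respects te_density", {
  cfg <- small_config(seed = 401L)
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$tes, b$tes)
  expect_identical(a$genes, b$genes)
  # zero density: no TEs, genes still placed
  cfg0 <- small_config(seed = 402L, te_density = 0, n_truth_regions = 0L,
                       n_hyper_regions = 0L)
  g0 <- make_genome(cfg0)
  expect_equal(nrow(g0$tes), 0L)
  expect_equal(nrow(g0$genes), 12L)
  # TE coverage within 10% of the requested density on a larger genome
  cfgL <- simulation_config(genome_length = 150000L, n_genes = 10L,
                            seed = 403L)
  gl <- make_genome(cfgL)
  covered <- sum(gl$tes$end - gl$tes$start) / cfgL$genome_length
  expect_lt(abs(covered - cfgL$te_density) / cfgL$te_density, 0.10)
  # features stay inside the genome and TEs do not overlap
  expect_true(all(gl$tes$start >= 0 & gl$tes$end <= cfgL$genome_length))
  expect_true(all(diff(gl$tes$start) > 0))
  expect_true(all(gl$tes$start[-1] >= gl$tes$end[-nrow(gl$tes)]))
})

test_that("planted truth regions sit over TEs and never collide", {
  cfg <- small_config(seed = 411L)
  lay <- make_genome(cfg)
  tr <- plant_truth(cfg, lay)
  expect_equal(sum(tr$kind == "TE-hypo"), 6L)
  expect_equal(sum(tr$kind == "promoter-hyper"), 2L)
  # no overlap between truth regions
  tr_sorted <- tr[order(tr$start), ]
  expect_true(all(tr_sorted$start[-1] >= tr_sorted$end[-nrow(tr_sorted)]))
  # every TE-hypo region overlaps a TE (placement is TE-nested)
  hypo <- tr[tr$kind == "TE-hypo", ]
  frac_on_te <- mean(vapply(seq_len(nrow(hypo)), function(i)
    any(hypo$start[i] < lay$tes$end & hypo$end[i] > lay$tes$start), TRUE))
  expect_gte(frac_on_te, 0.8)
  # empty request
  cfg0 <- small_config(seed = 412L, n_truth_regions = 0L,
                       n_hyper_regions = 0L)
  expect_equal(nrow(plant_truth(cfg0, make_genome(cfg0))), 0L)
  # infeasible: more regions than TEs
  cfg_bad <- small_config(seed = 413L, n_truth_regions = 500L)
  expect_error(plant_truth(cfg_bad, make_genome(cfg_bad)), "infeasible")
})

test_that("simulated levels follow truth in the high-coverage noiseless limit", {
  cfg <- small_config(seed = 421L, coverage_mean = 400,
                      nonconversion_error = 0)
  lay <- make_genome(cfg)
  tr <- plant_truth(cfg, lay)
  vc <- simulate_sample(tr, lay, "VC", "functional", cfg)
  df <- as.data.frame(vc)
  lev <- df$count_meth / (df$count_meth + df$count_unmeth)
  hypo <- tr[tr$kind == "TE-hypo", ][1, ]
  sel <- df$context == "CG" & df$pos - 1 >= hypo$start & df$pos - 1 < hypo$end
  expect_lt(abs(mean(lev[sel]) - cfg$demethylated_level), 0.02)
  # SC keeps the baseline there
  sc <- simulate_sample(tr, lay, "SC", "functional", cfg)
  dfs <- as.data.frame(sc)
  levs <- dfs$count_meth / (dfs$count_meth + dfs$count_unmeth)
  expect_lt(abs(mean(levs[sel]) - cfg$baseline_level), 0.02)
  # a null-genotype VC is not demethylated
  vc0 <- simulate_sample(tr, lay, "VC", "null", cfg)
  df0 <- as.data.frame(vc0)
  lev0 <- df0$count_meth / (df0$count_meth + df0$count_unmeth)
  expect_lt(abs(mean(lev0[sel]) - cfg$baseline_level), 0.02)
})

test_that("pool mixing is linear in the mixing fraction", {
  cfg1 <- small_config(seed = 431L, coverage_mean = 50,
                       nonconversion_error = 0)
  cfg5 <- small_config(seed = 431L, coverage_mean = 50,
                       nonconversion_error = 0, mixing_fraction = 0.5)
  lay <- make_genome(cfg1)
  tr <- plant_truth(cfg1, lay)
  sc <- simulate_sample(tr, lay, "SC", "functional", cfg1)
  vc1 <- simulate_sample(tr, lay, "VC", "functional", cfg1)
  vc5 <- simulate_sample(tr, lay, "VC", "functional", cfg5)
  lev <- function(s) {
    d <- as.data.frame(s)
    d$level <- d$count_meth / (d$count_meth + d$count_unmeth)
    d
  }
  hypo <- tr[tr$kind == "TE-hypo", ]
  in_truth <- function(d) {
    sel <- rep(FALSE, nrow(d))
    for (i in seq_len(nrow(hypo)))
      sel <- sel | (d$context == "CG" & d$pos - 1 >= hypo$start[i] &
                      d$pos - 1 < hypo$end[i])
    sel
  }
  d1 <- lev(vc1); d5 <- lev(vc5); ds <- lev(sc)
  full_diff <- mean(d1$level[in_truth(d1)]) - mean(ds$level[in_truth(ds)])
  half_diff <- mean(d5$level[in_truth(d5)]) - mean(ds$level[in_truth(ds)])
  n_sites <- sum(in_truth(d1))
  se <- sqrt(2 * 0.25 / (50 * n_sites))  # conservative binomial SE
  expect_lt(abs(half_diff - 0.5 * full_diff), 3 * se + 0.01)
})

test_that("simulation is deterministic per seed and role", {
  cfg <- small_config(seed = 441L)
  lay <- make_genome(cfg)
  tr <- plant_truth(cfg, lay)
  v1 <- simulate_sample(tr, lay, "VC", "functional", cfg)
  v2 <- simulate_sample(tr, lay, "VC", "functional", cfg)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  s1 <- simulate_sample(tr, lay, "SC", "functional", cfg)
  expect_false(identical(v1$count_meth, s1$count_meth))
  # zero coverage everywhere when coverage_mean is 0
  cfg0 <- small_config(seed = 442L, coverage_mean = 0)
  z <- simulate_sample(tr, lay, "VC", "functional", cfg0)
  expect_true(all(z$count_meth + z$count_unmeth == 0L))
})

test_that("recovery scoring matches brute-force reciprocal overlap", {
  truth <- data.frame(chrom = "chr1", start = c(100L, 1000L),
                      end = c(400L, 1600L), context = "CG",
                      direction = "hypo", stringsAsFactors = FALSE)
  exact <- data.frame(chrom = "chr1", start = truth$start,
                      end = truth$end, context = "CG", direction = "hypo",
                      stringsAsFactors = FALSE)
  r <- score_recovery(exact, truth)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  # empty call set: recall 0, precision reported 0 with flag
  r0 <- score_recovery(exact[0, ], truth)
  expect_equal(c(r0$precision, r0$recall), c(0, 0))
  expect_true(attr(r0, "precision_undefined"))
  # direction mismatch never matches
  flipped <- transform(exact, direction = "hyper")
  expect_equal(score_recovery(flipped, truth)$recall, 0)
  # random perturbations against brute force
  set.seed(451)
  for (rep in 1:50) {
    shift <- sample(-400:400, 1)
    called <- transform(exact[2, ], start = start + shift,
                        end = end + shift)
    ov <- max(0, min(called$end, truth$end[2]) -
                max(called$start, truth$start[2]))
    manual <- ov >= 0.5 * 600 && ov >= 0.5 * (called$end - called$start)
    expect_equal(score_recovery(called, truth)$recall,
                 mean(c(FALSE, manual)))
  }
})

test_that("simulated crosses recover the true transmission rate", {
  rec <- simulate_cross(0, 20, c(20L, 30L), seed = 461)
  expect_true(all(rec$n_carrier == 0L))
  rec2 <- simulate_cross(0.175, 50, c(20L, 30L), seed = 462)
  expect_identical(simulate_cross(0.175, 50, c(20L, 30L), seed = 462), rec2)
  pooled <- sum(rec2$n_carrier) /
    sum(rec2$n_carrier + rec2$n_noncarrier)
  n <- sum(rec2$n_carrier + rec2$n_noncarrier)
  se <- sqrt(0.175 * 0.825 / n)
  expect_lt(abs(pooled - 0.175), 3 * se)
  expect_true(all(rec2$n_carrier + rec2$n_noncarrier >= 20))
  expect_true(all(rec2$n_carrier + rec2$n_noncarrier <= 30))
})

test_that("mixture attenuates per-site qualification and DMR footprint", {
  # the detection-loss mechanism for heterozygous pools: at mixing 0.5
  # the fraction of truth-region CG sites crossing the 0.40 per-site
  # threshold and the total called CG-hypo footprint both drop strictly
  cfg1 <- simulation_config(seed = 471L)
  cfg5 <- simulation_config(seed = 471L, mixing_fraction = 0.5)
  lay <- make_genome(cfg1)
  tr <- plant_truth(cfg1, lay)
  sc <- simulate_sample(tr, lay, "SC", "functional", cfg1)
  hypo <- tr[tr$direction == "hypo", ]
  stats_for <- function(cfg) {
    vc <- simulate_sample(tr, lay, "VC", "functional", cfg)
    d <- site_differences(vc, sc, "CG", 4L)
    sel <- rep(FALSE, nrow(d))
    for (i in seq_len(nrow(hypo)))
      sel <- sel | (d$pos - 1 >= hypo$start[i] & d$pos - 1 < hypo$end[i])
    dm <- call_dmrs(vc, sc, contexts = "CG")$CG
    hy <- dm[dm$direction == "hypo", ]
    c(qualify = mean(d$diff[sel] <= -0.40),
      footprint = sum(hy$end - hy$start))
  }
  full <- stats_for(cfg1)
  half <- stats_for(cfg5)
  expect_lt(half["qualify"], full["qualify"])
  expect_lt(half["footprint"], full["footprint"])
})

test_that("simulation_config validates fractions", {
  expect_error(simulation_config(te_density = 1.2), "fractions")
  expect_error(simulation_config(mixing_fraction = -0.1), "fractions")
  expect_error(simulate_cross(1.5, 10), "true_transmission")
})
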