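#' Configuration for the synthetic bisulfite methylome
#'
#' Defines the statistical structure the simulator emulates: a random
#' genome with planted TE and gene annotations, paired vegetative-cell
#' (VC) and sperm-cell (SC) methylomes in which the VC is
#' CG-demethylated over TE regions, binomially sampled read counts at
#' Poisson coverage with a symmetric non-conversion mis-call floor, and
#' heterozygote pollen pools modelled as a mixture of
#' demethylation-competent and -incompetent cells.
#'
#' Defaults describe a compact but realistic chromosome arm: 200 kb,
#' 20% TE coverage in 0.5-1.5 kb elements, 40 genes (half placed within
#' 500 bp of a TE), 30 TE-hypo CG regions of 300-800 bp dropping from
#' 0.8 to 0.1 methylation, 5 promoter-hyper CG regions rising from 0.05
#' to 0.5, mean coverage 20 and a 0.5% non-conversion floor.
#' `mixing_fraction = 1` is a wild-type pool; 0.5 emulates a
#' heterozygous father whose pollen is an equal mix of demethylating and
#' non-demethylating VCs.
#'
#' @param genome_length Chromosome length in bp.
#' @param te_density Fraction of the genome covered by TEs.
#' @param te_length_range TE length range in bp.
#' @param n_genes Number of genes to place.
#' @param gene_length_range Gene length range in bp.
#' @param n_truth_regions Number of planted TE-hypo regions.
#' @param n_hyper_regions Number of planted promoter-hyper regions.
#' @param region_size_range Planted region size range in bp.
#' @param baseline_level True methylation inside TE-hypo regions in the
#'   non-demethylated state (SC level).
#' @param demethylated_level True methylation there in a demethylating
#'   VC.
#' @param hyper_baseline_level,hyper_vc_level Promoter-hyper region
#'   levels outside / inside the VC.
#' @param background_levels Named list (`TE`, `gene`) of per-context
#'   background methylation outside planted regions.
#' @param coverage_mean Mean per-site read depth (Poisson).
#' @param nonconversion_error Symmetric per-read mis-call floor.
#' @param mixing_fraction Fraction of demethylation-competent cells in
#'   the VC pool.
#' @param min_separation Minimum bp between planted elements/regions.
#' @param chrom Chromosome name.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 200000L,
                              te_density = 0.2,
                              te_length_range = c(500L, 1500L),
                              n_genes = 40L,
                              gene_length_range = c(800L, 1600L),
                              n_truth_regions = 30L,
                              n_hyper_regions = 5L,
                              region_size_range = c(300L, 800L),
                              baseline_level = 0.8,
                              demethylated_level = 0.1,
                              hyper_baseline_level = 0.05,
                              hyper_vc_level = 0.5,
                              background_levels = list(
                                TE = c(CG = 0.8, CHG = 0.4, CHH = 0.1),
                                gene = c(CG = 0.05, CHG = 0.02, CHH = 0.02)),
                              coverage_mean = 20,
                              nonconversion_error = 0.005,
                              mixing_fraction = 1,
                              min_separation = 1000L,
                              chrom = "chr1",
                              seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              te_density = te_density,
              te_length_range = as.integer(te_length_range),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_truth_regions = as.integer(n_truth_regions),
              n_hyper_regions = as.integer(n_hyper_regions),
              region_size_range = as.integer(region_size_range),
              baseline_level = baseline_level,
              demethylated_level = demethylated_level,
              hyper_baseline_level = hyper_baseline_level,
              hyper_vc_level = hyper_vc_level,
              background_levels = background_levels,
              coverage_mean = coverage_mean,
              nonconversion_error = nonconversion_error,
              mixing_fraction = mixing_fraction,
              min_separation = as.integer(min_separation),
              chrom = chrom,
              seed = as.integer(seed))
  fracs <- c(cfg$te_density, cfg$baseline_level, cfg$demethylated_level,
             cfg$hyper_baseline_level, cfg$hyper_vc_level,
             cfg$nonconversion_error, cfg$mixing_fraction,
             unlist(cfg$background_levels))
  if (any(fracs < 0) || any(fracs > 1))
    stop("all fractions must lie in [0, 1]")
  if (cfg$genome_length <= 0L) stop("genome_length must be > 0")
  if (cfg$coverage_mean < 0) stop("coverage_mean must be >= 0")
  structure(cfg, class = "simulation_config")
}

# place n non-overlapping intervals with at least `pad` bp between
# members of the same class; rejection sampling against `occupied`
# (2-column matrix of 0-based half-open intervals)
.place_intervals <- function(n_target_bp, len_range, genome_length, pad,
                             max_tries = 20000L) {
  placed <- matrix(integer(0), ncol = 2L)
  covered <- 0L
  tries <- 0L
  while (covered < n_target_bp && tries < max_tries) {
    tries <- tries + 1L
    len <- if (len_range[1L] == len_range[2L]) len_range[1L] else
      sample(len_range[1L]:len_range[2L], 1L)
    if (len > genome_length) next
    start <- sample(0:(genome_length - len), 1L)
    if (nrow(placed) &&
        any(start - pad < placed[, 2L] & start + len + pad > placed[, 1L]))
      next
    placed <- rbind(placed, c(start, start + len))
    covered <- covered + len
  }
  if (covered < n_target_bp)
    stop("could not reach requested density: genome too short or too crowded")
  placed[order(placed[, 1L]), , drop = FALSE]
}

#' Generate a synthetic genome with TE and gene annotations
#'
#' Draws a uniform-random nucleotide sequence and plants non-overlapping
#' TE intervals to the requested density and genes in the remaining
#' space, half of them deliberately within 500 bp of a TE so that
#' TE-proximity statistics are non-trivial. Deterministic per seed.
#'
#' @param config A [simulation_config].
#' @return List with `genome` (a [genome_sequence]), `genes` and `tes`
#'   ([genomic_features] tables).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$genome_length
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  genome <- genome_sequence(config$chrom, seq)
  target <- as.integer(round(config$te_density * L))
  tes <- if (target > 0L)
    .place_intervals(target, config$te_length_range, L,
                     pad = config$min_separation)
  else matrix(integer(0), ncol = 2L)
  te_feats <- genomic_features(
    if (nrow(tes)) sprintf("TE%04d", seq_len(nrow(tes))) else character(0),
    rep(config$chrom, nrow(tes)), tes[, 1L], tes[, 2L], "*", "TE")

  occupied <- tes
  genes <- matrix(integer(0), ncol = 2L)
  gene_strand <- character(0)
  n_prox <- if (nrow(tes)) config$n_genes %/% 2L else 0L
  overlaps_any <- function(s, e, occ, pad = 0L)
    nrow(occ) && any(s - pad < occ[, 2L] & e + pad > occ[, 1L])
  for (i in seq_len(config$n_genes)) {
    placed <- FALSE
    for (try in 1:2000) {
      len <- sample(config$gene_length_range[1L]:config$gene_length_range[2L], 1L)
      if (i <= n_prox) {
        te <- tes[sample(nrow(tes), 1L), ]
        gap <- sample(0:400, 1L)
        start <- if (stats::runif(1) < 0.5) te[2L] + gap else
          te[1L] - gap - len
      } else {
        start <- sample(0:(max(L - len, 1L)), 1L)
      }
      if (start < 0L || start + len > L) next
      if (overlaps_any(start, start + len, occupied)) next
      if (i > n_prox && nrow(tes) &&
          overlaps_any(start, start + len, tes, pad = 600L)) next
      genes <- rbind(genes, c(start, start + len))
      gene_strand <- c(gene_strand, sample(c("+", "-"), 1L))
      occupied <- rbind(occupied, c(start, start + len))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place all genes: genome too short or too crowded")
  }
  gene_feats <- genomic_features(
    if (nrow(genes)) sprintf("GENE%04d", seq_len(nrow(genes))) else character(0),
    rep(config$chrom, nrow(genes)), genes[, 1L], genes[, 2L],
    gene_strand, "gene")
  list(genome = genome, genes = gene_feats, tes = te_feats)
}

#' Plant ground-truth differentially methylated regions
#'
#' Places `n_truth_regions` TE-hypo regions, each nested inside its own
#' TE (clamped to the TE when the drawn size exceeds it), and
#' `n_hyper_regions` promoter-hyper regions in the strand-aware upstream
#' windows of genes. Regions never overlap each other and keep at least
#' `min_separation` bp apart so that merged calls remain distinct.
#' Deterministic per seed.
#'
#' @param config A [simulation_config].
#' @param layout Output of [make_genome()].
#' @return Data frame of truth regions: `chrom`, `start`, `end`,
#'   `context`, `kind` (`TE-hypo`/`promoter-hyper`), `direction`
#'   (VC relative to SC), `baseline_level`, `vc_level`.
#' @export
plant_truth <- function(config, layout) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  tes <- layout$tes
  genes <- layout$genes
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      kind = character(0), direction = character(0),
                      baseline_level = numeric(0), vc_level = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$n_truth_regions > nrow(tes))
    stop("infeasible placement: fewer TEs than requested TE-hypo regions")
  rows <- list()
  placed <- matrix(integer(0), ncol = 2L)
  sep <- config$min_separation
  clash <- function(s, e)
    nrow(placed) && any(s - sep < placed[, 2L] & e + sep > placed[, 1L])
  if (config$n_truth_regions > 0L) {
    pick <- sample(nrow(tes), config$n_truth_regions)
    for (i in pick) {
      te_len <- tes$end[i] - tes$start[i]
      size <- min(te_len,
                  sample(config$region_size_range[1L]:config$region_size_range[2L], 1L))
      start <- tes$start[i] +
        if (te_len > size) sample(0:(te_len - size), 1L) else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = config$chrom, start = start, end = start + size,
        context = "CG", kind = "TE-hypo", direction = "hypo",
        baseline_level = config$baseline_level,
        vc_level = config$demethylated_level, stringsAsFactors = FALSE)
      placed <- rbind(placed, c(start, start + size))
    }
  }
  if (config$n_hyper_regions > 0L) {
    if (nrow(genes) == 0L)
      stop("infeasible placement: promoter-hyper regions need genes")
    done <- 0L
    for (gi in sample(nrow(genes))) {
      if (done >= config$n_hyper_regions) break
      size <- sample(config$region_size_range[1L]:config$region_size_range[2L], 1L)
      size <- min(size, 500L)
      g <- genes[gi, ]
      if (g$strand == "-") {
        start <- g$end
      } else {
        start <- g$start - size
      }
      if (start < 0L || start + size > config$genome_length) next
      if (clash(start, start + size)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = config$chrom, start = start, end = start + size,
        context = "CG", kind = "promoter-hyper", direction = "hyper",
        baseline_level = config$hyper_baseline_level,
        vc_level = config$hyper_vc_level, stringsAsFactors = FALSE)
      placed <- rbind(placed, c(start, start + size))
      done <- done + 1L
    }
    if (done < config$n_hyper_regions)
      stop("infeasible placement: could not place all promoter-hyper regions")
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# deterministic per-role seed offsets
.role_offset <- function(role, genotype_effect) {
  10L + match(role, c("VC", "SC")) * 2L +
    match(genotype_effect, c("functional", "null"))
}

#' Simulate one bisulfite methylome sample
#'
#' For every classifiable cytosine, the true methylation probability is
#' the background profile of its annotation (TE-like high, gene-body
#' low), overridden inside a planted region of matching context. A
#' demethylation-competent VC uses the region's VC level; an
#' incompetent VC or any SC uses the baseline. A heterozygous pool is a
#' linear mixture: `p = f * p_vc + (1 - f) * p_baseline` with
#' `f = mixing_fraction`. Observed methylated counts are drawn as
#' `Binomial(coverage, p*(1-e) + (1-p)*e)` with coverage
#' `Poisson(coverage_mean)` and `e` the symmetric non-conversion
#' mis-call floor. Deterministic per seed, role and genotype.
#'
#' @param truth Truth regions from [plant_truth()].
#' @param layout Output of [make_genome()].
#' @param role `"VC"` or `"SC"`.
#' @param genotype_effect `"functional"` (demethylation-competent pool,
#'   weighted by `mixing_fraction`) or `"null"` (no demethylation).
#' @param config A [simulation_config].
#' @return A [methylome_sample] with `cell_type = role` and
#'   `genotype = genotype_effect`.
#' @export
simulate_sample <- function(truth, layout, role = c("VC", "SC"),
                            genotype_effect = c("functional", "null"),
                            config) {
  role <- match.arg(role)
  genotype_effect <- match.arg(genotype_effect)
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + .role_offset(role, genotype_effect))
  sites <- all_cytosines(layout$genome)
  n <- nrow(sites)
  pos0 <- sites$pos - 1L
  in_te <- rep(FALSE, n)
  if (nrow(layout$tes))
    for (i in seq_len(nrow(layout$tes)))
      in_te <- in_te | (pos0 >= layout$tes$start[i] &
                          pos0 < layout$tes$end[i])
  p_base <- ifelse(in_te,
                   config$background_levels$TE[sites$context],
                   config$background_levels$gene[sites$context])
  p_vc <- p_base
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      sel <- sites$context == truth$context[i] &
        pos0 >= truth$start[i] & pos0 < truth$end[i]
      p_base[sel] <- truth$baseline_level[i]
      p_vc[sel] <- truth$vc_level[i]
    }
  }
  f <- if (role == "VC" && genotype_effect == "functional")
    config$mixing_fraction else 0
  p <- f * p_vc + (1 - f) * p_base
  e <- config$nonconversion_error
  p_obs <- p * (1 - e) + (1 - p) * e
  coverage <- stats::rpois(n, config$coverage_mean)
  cm <- stats::rbinom(n, coverage, p_obs)
  methylome_sample(
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               count_meth = cm, count_unmeth = coverage - cm,
               context = sites$context, stringsAsFactors = FALSE),
    genotype = genotype_effect, cell_type = role)
}

#' Score called DMRs against planted truth
#'
#' A truth region is recovered when some called DMR of matching context
#' and direction achieves the required reciprocal overlap (intersection
#' at least `min_reciprocal_overlap` of both interval lengths).
#' Precision is the fraction of called DMRs matching at least one truth
#' region; recall the fraction of truth regions recovered; F1 their
#' harmonic mean. With no called DMRs, precision is reported as 0 with
#' attribute `precision_undefined = TRUE`.
#'
#' @param called_dmrs DMR data frame (e.g. one element of
#'   [call_dmrs()]'s output, or [dmr_table()]).
#' @param truth Truth regions from [plant_truth()].
#' @param min_reciprocal_overlap Required reciprocal overlap fraction.
#' @return List with `precision`, `recall`, `f1`, `n_called`, `n_truth`.
#' @export
score_recovery <- function(called_dmrs, truth,
                           min_reciprocal_overlap = 0.5) {
  n_called <- nrow(called_dmrs)
  n_truth <- nrow(truth)
  if (n_truth == 0L) stop("no truth regions to score against")
  match_mat <- matrix(FALSE, n_truth, max(n_called, 1L))
  for (i in seq_len(n_truth)) {
    for (j in seq_len(n_called)) {
      if (truth$context[i] != called_dmrs$context[j] ||
          truth$direction[i] != called_dmrs$direction[j] ||
          truth$chrom[i] != called_dmrs$chrom[j]) next
      ov <- min(truth$end[i], called_dmrs$end[j]) -
        max(truth$start[i], called_dmrs$start[j])
      if (ov <= 0) next
      lt <- truth$end[i] - truth$start[i]
      lc <- called_dmrs$end[j] - called_dmrs$start[j]
      match_mat[i, j] <- ov >= min_reciprocal_overlap * lt &&
        ov >= min_reciprocal_overlap * lc
    }
  }
  recall <- mean(apply(match_mat, 1L, any))
  if (n_called == 0L) {
    precision <- 0
    out <- list(precision = precision, recall = recall, f1 = 0,
                n_called = 0L, n_truth = n_truth)
    attr(out, "precision_undefined") <- TRUE
    return(out)
  }
  precision <- mean(apply(match_mat, 2L, any))
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_called = n_called, n_truth = n_truth)
}

#' Simulate silique-level progeny counts for a cross
#'
#' Per silique, the total seed count is uniform over
#' `seeds_per_silique_range` and the carrier count is
#' `Binomial(total, true_transmission)`. Deterministic per seed.
#'
#' @param true_transmission True transmission frequency of the tracked
#'   allele through pollen.
#' @param n_siliques Number of siliques (replicates).
#' @param seeds_per_silique_range Inclusive range of seeds per silique.
#' @param seed Integer seed.
#' @param cross_id,father_genotype Labels for the output table.
#' @return A [cross_progeny] data frame.
#' @export
simulate_cross <- function(true_transmission, n_siliques,
                           seeds_per_silique_range = c(20L, 30L),
                           seed = 1L, cross_id = "cross1",
                           father_genotype = "het") {
  if (true_transmission < 0 || true_transmission > 1)
    stop("true_transmission must be in [0, 1]")
  set.seed(seed)
  lo <- seeds_per_silique_range[1L]
  hi <- seeds_per_silique_range[2L]
  totals <- if (lo == hi) rep(lo, n_siliques) else
    sample(lo:hi, n_siliques, replace = TRUE)
  carriers <- stats::rbinom(n_siliques, totals, true_transmission)
  cross_progeny(cross_id, father_genotype,
                sprintf("silique%03d", seq_len(n_siliques)),
                carriers, totals - carriers)
}
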