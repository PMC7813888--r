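#' DMR-calling parameters
#'
#' Thresholds for the binned DMR definition: the genome is tiled into
#' fixed `bin_size` windows; a bin is a candidate when it holds at least
#' `min_sites[context]` sites whose per-site methylation difference
#' exceeds `min_abs_diff[context]` in the same direction; candidate bins
#' within `merge_gap` of each other are merged. Defaults are the
#' standard plant WGBS thresholds: 50-bp bins with at least 2, 3 or 4
#' differential mCG, mCHG or mCHH sites at absolute differences 0.40,
#' 0.25 and 0.10, merged within 400 bp.
#'
#' `min_coverage` is the per-site read depth required in *each* sample
#' before a site enters the comparison; small absolute differences are
#' meaningless at depth 1-3 reads.
#'
#' @param bin_size Bin width in bp.
#' @param min_sites Named integer vector (CG, CHG, CHH): minimum
#'   qualifying sites per bin.
#' @param min_abs_diff Named numeric vector (CG, CHG, CHH): per-site
#'   absolute methylation-difference threshold, as a fraction.
#' @param merge_gap Maximum edge-to-edge distance in bp for merging
#'   candidate bins.
#' @param min_coverage Minimum reads per site per sample.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(bin_size = 50L,
                       min_sites = c(CG = 2L, CHG = 3L, CHH = 4L),
                       min_abs_diff = c(CG = 0.40, CHG = 0.25, CHH = 0.10),
                       merge_gap = 400L,
                       min_coverage = 4L) {
  bin_size <- as.integer(bin_size)
  merge_gap <- as.integer(merge_gap)
  min_coverage <- as.integer(min_coverage)
  ctxs <- c("CG", "CHG", "CHH")
  if (!all(ctxs %in% names(min_sites)) || !all(ctxs %in% names(min_abs_diff)))
    stop("min_sites and min_abs_diff must be named for CG, CHG, CHH")
  min_sites <- vapply(min_sites[ctxs], as.integer, 0L)
  min_abs_diff <- min_abs_diff[ctxs]
  if (bin_size <= 0L) stop("bin_size must be > 0")
  if (any(min_sites < 1L)) stop("min_sites must be >= 1")
  if (any(min_abs_diff <= 0) || any(min_abs_diff > 1))
    stop("min_abs_diff must be in (0, 1]")
  if (merge_gap < 0L) stop("merge_gap must be >= 0")
  if (min_coverage < 0L) stop("min_coverage must be >= 0")
  structure(list(bin_size = bin_size, min_sites = min_sites,
                 min_abs_diff = min_abs_diff, merge_gap = merge_gap,
                 min_coverage = min_coverage),
            class = "dmr_params")
}

.check_context <- function(context) {
  if (length(context) != 1L || !context %in% c("CG", "CHG", "CHH"))
    stop("context must be one of CG, CHG, CHH")
  context
}

#' Per-site methylation differences between two samples
#'
#' Joins two samples on (chrom, pos, strand), restricted to one context
#' and to sites covered by at least `min_coverage` reads in each sample,
#' and computes per-site levels `count_meth / (count_meth + count_unmeth)`
#' and their difference A minus B. Sites present (or sufficiently
#' covered) in only one sample are skipped; the number skipped is
#' attached as attribute `n_skipped`.
#'
#' @param sample_A,sample_B [methylome_sample] objects on the same genome.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_coverage Minimum reads per site per sample.
#' @return Data frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `level_A`, `level_B`, `diff`, sorted by (chrom, pos, strand).
#' @export
site_differences <- function(sample_A, sample_B, context, min_coverage = 4L) {
  .check_context(context)
  pick <- function(s) {
    s <- as.data.frame(s)
    s[s$context == context &
        (s$count_meth + s$count_unmeth) >= min_coverage, , drop = FALSE]
  }
  a <- pick(sample_A)
  b <- pick(sample_B)
  m <- merge(a, b, by = c("chrom", "pos", "strand"),
             suffixes = c("_A", "_B"))
  out <- data.frame(
    chrom = m$chrom, pos = m$pos, strand = m$strand, context = context,
    level_A = m$count_meth_A / (m$count_meth_A + m$count_unmeth_A),
    level_B = m$count_meth_B / (m$count_meth_B + m$count_unmeth_B),
    stringsAsFactors = FALSE)
  out$diff <- out$level_A - out$level_B
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- nrow(a) + nrow(b) - 2L * nrow(out)
  out
}

#' Call candidate bins from per-site differences
#'
#' Tiles each chromosome into consecutive non-overlapping `bin_size`
#' windows anchored at coordinate 0 and counts, per bin and per
#' direction, the sites whose difference passes the context threshold:
#' `diff <= -min_abs_diff` for hypo (sample A lower), `diff >=
#' +min_abs_diff` for hyper. A bin qualifies for a direction when the
#' count reaches `min_sites[context]`; the two directions are counted
#' separately and a bin may qualify in both.
#'
#' @param diffs Output of [site_differences()] for `context`.
#' @param params A [dmr_params] object.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return Data frame of candidate bins: `chrom`, `start`, `end` (0-based
#'   half-open), `context`, `direction` (`hypo`/`hyper`), `n_sites`,
#'   `sum_abs_diff` (summed |diff| of the qualifying sites), sorted by
#'   (chrom, start, direction).
#' @export
call_candidate_bins <- function(diffs, params, context) {
  .check_context(context)
  stopifnot(inherits(params, "dmr_params"))
  thr <- params$min_abs_diff[[context]]
  need <- params$min_sites[[context]]
  bs <- params$bin_size
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      direction = character(0), n_sites = integer(0),
                      sum_abs_diff = numeric(0), stringsAsFactors = FALSE)
  if (nrow(diffs) == 0L) return(empty)
  one_direction <- function(sel, direction) {
    d <- diffs[sel, , drop = FALSE]
    if (nrow(d) == 0L) return(empty)
    bin <- (d$pos - 1L) %/% bs
    key <- paste(d$chrom, bin, sep = "\r")
    n <- as.vector(tapply(rep(1L, nrow(d)), key, sum))
    s <- as.vector(tapply(abs(d$diff), key, sum))
    keys <- names(tapply(rep(1L, nrow(d)), key, sum))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1L)
    b <- as.integer(vapply(parts, `[`, "", 2L))
    keep <- which(n >= need)
    data.frame(chrom = chrom[keep], start = b[keep] * bs,
               end = (b[keep] + 1L) * bs,
               context = rep(context, length(keep)),
               direction = rep(direction, length(keep)),
               n_sites = as.integer(n[keep]),
               sum_abs_diff = s[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(one_direction(diffs$diff <= -thr, "hypo"),
               one_direction(diffs$diff >= thr, "hyper"))
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge candidate bins into DMRs
#'
#' Bins of the same chromosome, context and direction whose edge-to-edge
#' gap is at most `merge_gap` are merged transitively into one region
#' spanning from the first bin's start to the last bin's end. Merged
#' regions are not re-tested against the bin thresholds. Site counts and
#' summed |diff| are accumulated over the merged bins.
#'
#' @param bins Candidate bins from [call_candidate_bins()], sorted by
#'   (chrom, start); all rows must share one context.
#' @param merge_gap Maximum separation in bp.
#' @return Data frame of DMRs: `chrom`, `start`, `end`, `context`,
#'   `direction`, `n_sites`, `n_bins_merged`, `mean_abs_diff`.
#' @export
merge_bins <- function(bins, merge_gap = 400L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      direction = character(0), n_sites = integer(0),
                      n_bins_merged = integer(0), mean_abs_diff = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(bins) == 0L) return(empty)
  if (length(unique(bins$context)) != 1L)
    stop("merge_bins expects bins of a single context")
  o <- order(bins$chrom, bins$start)
  if (is.unsorted(o)) stop("internal error: candidate bins are unsorted")
  res <- lapply(split(bins, paste(bins$chrom, bins$direction, sep = "\r")),
                function(g) {
    g <- g[order(g$start), , drop = FALSE]
    new_run <- c(TRUE, g$start[-1L] - g$end[-nrow(g)] > merge_gap)
    run <- cumsum(new_run)
    data.frame(
      chrom = g$chrom[!duplicated(run)],
      start = as.vector(tapply(g$start, run, min)),
      end = as.vector(tapply(g$end, run, max)),
      context = g$context[1L],
      direction = g$direction[1L],
      n_sites = as.integer(tapply(g$n_sites, run, sum)),
      n_bins_merged = as.integer(tapply(rep(1L, nrow(g)), run, sum)),
      mean_abs_diff = as.vector(tapply(g$sum_abs_diff, run, sum) /
                                  tapply(g$n_sites, run, sum)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted methylation level of a region
#'
#' The coverage-weighted level: summed methylated reads over summed total
#' reads across the context sites falling in the 0-based half-open
#' interval `[start, end)`. Returns `NA` (undefined), not 0, when total
#' coverage is zero.
#'
#' @param sample A [methylome_sample].
#' @param chrom Chromosome identifier.
#' @param start,end 0-based half-open interval bounds.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return A fraction in `[0, 1]`, or `NA` if the region has no covered
#'   context site.
#' @export
weighted_methylation <- function(sample, chrom, start, end, context) {
  .check_context(context)
  if (start >= end) stop("start must be < end")
  s <- as.data.frame(sample)
  sel <- s$chrom == chrom & s$context == context &
    s$pos - 1L >= start & s$pos - 1L < end
  tot <- sum(s$count_meth[sel]) + sum(s$count_unmeth[sel])
  if (tot == 0L) return(NA_real_)
  sum(s$count_meth[sel]) / tot
}

#' Call differentially methylated regions between two samples
#'
#' Composes [site_differences()], [call_candidate_bins()] and
#' [merge_bins()] per context, then annotates each DMR with the weighted
#' methylation level of both samples over the region. Direction is that
#' of sample A relative to sample B: `hypo` means A is less methylated.
#'
#' @param sample_A,sample_B [methylome_sample] objects on the same genome
#'   (conventionally A = vegetative cell, B = sperm cell).
#' @param params A [dmr_params] object.
#' @param contexts Contexts to call; default all three.
#' @return Named list (one element per context) of DMR data frames with
#'   columns `chrom`, `start`, `end`, `context`, `direction`, `n_sites`,
#'   `n_bins_merged`, `meth_A`, `meth_B`, `mean_abs_diff`.
#' @export
call_dmrs <- function(sample_A, sample_B, params = dmr_params(),
                      contexts = c("CG", "CHG", "CHH")) {
  stopifnot(inherits(params, "dmr_params"))
  out <- lapply(contexts, function(ctx) {
    diffs <- site_differences(sample_A, sample_B, ctx, params$min_coverage)
    bins <- call_candidate_bins(diffs, params, ctx)
    dmrs <- merge_bins(bins, params$merge_gap)
    if (nrow(dmrs)) {
      dmrs$meth_A <- vapply(seq_len(nrow(dmrs)), function(i)
        weighted_methylation(sample_A, dmrs$chrom[i], dmrs$start[i],
                             dmrs$end[i], ctx), 0)
      dmrs$meth_B <- vapply(seq_len(nrow(dmrs)), function(i)
        weighted_methylation(sample_B, dmrs$chrom[i], dmrs$start[i],
                             dmrs$end[i], ctx), 0)
    } else {
      dmrs$meth_A <- numeric(0)
      dmrs$meth_B <- numeric(0)
    }
    dmrs[c("chrom", "start", "end", "context", "direction", "n_sites",
           "n_bins_merged", "meth_A", "meth_B", "mean_abs_diff")]
  })
  names(out) <- contexts
  out
}

#' Flatten per-context DMR sets into one table
#'
#' @param dmr_sets Output of [call_dmrs()].
#' @return One data frame, sorted by (chrom, start, context, direction).
#' @export
dmr_table <- function(dmr_sets) {
  out <- do.call(rbind, unname(dmr_sets))
  out <- out[order(out$chrom, out$start, out$context, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write DMRs as a TSV table
#'
#' Columns: chrom, start, end, context, direction, n_sites, meth_A,
#' meth_B, mean_abs_diff (coordinates 0-based half-open).
#'
#' @param dmrs A DMR data frame (e.g. from [dmr_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmrs, path) {
  cols <- c("chrom", "start", "end", "context", "direction", "n_sites",
            "meth_A", "meth_B", "mean_abs_diff")
  utils::write.table(dmrs[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DMR TSV table written by [write_dmr_table()]
#' @param path Input path.
#' @return A DMR data frame.
#' @export
read_dmr_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write DMRs in BED6 format
#'
#' Coordinates are 0-based half-open (native BED). The name field encodes
#' context and direction (`CG_hypo`), the score field the mean absolute
#' per-site difference scaled to 0-1000, and the strand field is `.`.
#'
#' @param dmrs A DMR data frame; same-(context, direction) regions must
#'   not overlap.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs)) {
    for (g in split(dmrs, paste(dmrs$context, dmrs$direction))) {
      g <- g[order(g$chrom, g$start), , drop = FALSE]
      same <- g$chrom[-1L] == g$chrom[-nrow(g)]
      if (nrow(g) > 1L && any(same & g$start[-1L] < g$end[-nrow(g)]))
        stop("overlapping DMRs of the same context and direction")
    }
  }
  bed <- data.frame(
    dmrs$chrom, dmrs$start, dmrs$end,
    paste(dmrs$context, dmrs$direction, sep = "_"),
    as.integer(round(pmin(1, dmrs$mean_abs_diff) * 1000)),
    rep(".", nrow(dmrs)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (nrow(dmrs) == 0L) writeLines(character(0), path)
  invisible(path)
}

#' Region-by-sample methylation matrix
#'
#' Builds the matrix behind a methylation heatmap: rows are samples,
#' columns are regions, values are weighted methylation levels.
#'
#' @param samples Named list of [methylome_sample] objects.
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return Numeric matrix, samples x regions; zero-coverage cells are
#'   `NA`.
#' @export
methylation_matrix <- function(samples, regions, context = "CG") {
  .check_context(context)
  m <- vapply(seq_len(nrow(regions)), function(j) {
    vapply(samples, function(s)
      weighted_methylation(s, regions$chrom[j], regions$start[j],
                           regions$end[j], context), 0)
  }, numeric(length(samples)))
  m <- matrix(m, nrow = length(samples),
              dimnames = list(names(samples),
                              paste0(regions$chrom, ":", regions$start,
                                     "-", regions$end)))
  m
}

#' Column ordering by complete-linkage hierarchical clustering
#'
#' Orders the columns of a methylation matrix by agglomerative
#' complete-linkage clustering with Euclidean distance, the standard
#' ordering for region heatmaps. The merge heights of the dendrogram are
#' attached as attribute `heights`.
#'
#' @param mat Numeric matrix (samples x regions) without missing values.
#' @return Integer vector of column indices (the dendrogram leaf order)
#'   with attributes `heights` and `hclust`.
#' @export
cluster_order <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2L)
    stop("cluster_order needs a matrix with at least 2 columns")
  if (anyNA(mat))
    stop("missing values must be imputed or dropped before clustering")
  hc <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                      method = "complete")
  structure(hc$order, heights = hc$height, hclust = hc)
}
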