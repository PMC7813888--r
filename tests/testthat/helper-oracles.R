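# Independent reference implementations used as oracles. These are
# deliberately naive (string rules, exhaustive enumeration, O(n^2)
# closures) and share no code with the package internals they check.

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# forward-strand trinucleotide rule applied to the sequence itself (+) or
# to its reverse complement (-)
oracle_context <- function(seq, pos, strand) {
  rule <- function(s, p) {
    n <- nchar(s)
    if (substr(s, p, p) != "C") return("notC")
    tri <- substr(s, p, min(p + 2L, n))
    if (grepl("^CG", tri)) return("CG")
    if (grepl("^C[ACT]G", tri)) return("CHG")
    if (grepl("^C[ACT][ACT]", tri)) return("CHH")
    NA_character_
  }
  if (strand == "+") rule(seq, pos)
  else rule(revcomp(seq), nchar(seq) - pos + 1L)
}

# site-by-site difference table computed with explicit per-row lookup
oracle_site_diffs <- function(A, B, context, min_coverage) {
  A <- as.data.frame(A); B <- as.data.frame(B)
  rows <- list()
  for (i in seq_len(nrow(A))) {
    if (A$context[i] != context) next
    if (A$count_meth[i] + A$count_unmeth[i] < min_coverage) next
    j <- which(B$chrom == A$chrom[i] & B$pos == A$pos[i] &
                 B$strand == A$strand[i])
    if (length(j) != 1L) next
    if (B$context[j] != context) next
    if (B$count_meth[j] + B$count_unmeth[j] < min_coverage) next
    la <- A$count_meth[i] / (A$count_meth[i] + A$count_unmeth[i])
    lb <- B$count_meth[j] / (B$count_meth[j] + B$count_unmeth[j])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = A$chrom[i], pos = A$pos[i], strand = A$strand[i],
      level_A = la, level_B = lb, diff = la - lb,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), level_A = numeric(0),
                      level_B = numeric(0), diff = numeric(0)))
  do.call(rbind, rows)
}

# full brute-force DMR caller: enumerate every bin tile over the observed
# range, count qualifying sites explicitly, merge by repeated pairwise
# transitive closure, then recompute region summaries by direct summation
oracle_call_dmrs <- function(A, B, params, context) {
  d <- oracle_site_diffs(A, B, context, params$min_coverage)
  thr <- params$min_abs_diff[[context]]
  need <- params$min_sites[[context]]
  bs <- params$bin_size
  out <- list()
  for (ch in unique(d$chrom)) {
    dc <- d[d$chrom == ch, , drop = FALSE]
    max_bin <- max((dc$pos - 1L) %/% bs)
    for (dir in c("hypo", "hyper")) {
      bins <- list()
      for (t in 0:max_bin) {
        lo <- t * bs; hi <- (t + 1L) * bs
        insel <- dc$pos - 1L >= lo & dc$pos - 1L < hi
        q <- if (dir == "hypo") insel & dc$diff <= -thr else
          insel & dc$diff >= thr
        if (sum(q) >= need)
          bins[[length(bins) + 1L]] <- list(start = lo, end = hi,
                                            n = sum(q),
                                            s = sum(abs(dc$diff[q])))
      }
      # transitive closure by repeated pairwise merging
      repeat {
        merged <- FALSE
        for (i in seq_along(bins)) {
          for (j in seq_along(bins)) {
            if (i >= j) next
            gap <- max(bins[[i]]$start, bins[[j]]$start) -
              min(bins[[i]]$end, bins[[j]]$end)
            if (gap <= params$merge_gap) {
              bins[[i]] <- list(start = min(bins[[i]]$start, bins[[j]]$start),
                                end = max(bins[[i]]$end, bins[[j]]$end),
                                n = bins[[i]]$n + bins[[j]]$n,
                                s = bins[[i]]$s + bins[[j]]$s)
              bins[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) break
      }
      for (bn in bins) {
        wm <- function(S) {
          S <- as.data.frame(S)
          sel <- S$chrom == ch & S$context == context &
            S$pos - 1L >= bn$start & S$pos - 1L < bn$end
          tot <- sum(S$count_meth[sel] + S$count_unmeth[sel])
          if (tot == 0) NA_real_ else sum(S$count_meth[sel]) / tot
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = bn$start, end = bn$end, context = context,
          direction = dir, n_sites = bn$n,
          meth_A = wm(A), meth_B = wm(B),
          mean_abs_diff = bn$s / bn$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      direction = character(0), n_sites = integer(0),
                      meth_A = numeric(0), meth_B = numeric(0),
                      mean_abs_diff = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# naive complete-linkage agglomeration over columns: cluster distance is
# the max pairwise Euclidean distance between members
oracle_complete_linkage_heights <- function(mat) {
  d <- as.matrix(stats::dist(t(mat), method = "euclidean"))
  groups <- as.list(seq_len(ncol(mat)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best[1L]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1L])
    groups[[best[2L]]] <- c(groups[[best[2L]]], groups[[best[3L]]])
    groups[[best[3L]]] <- NULL
  }
  heights
}

# exact hypergeometric Fisher p by direct enumeration with choose()
oracle_fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0L, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  po <- pr[match(a, xs)]
  switch(alternative,
         two.sided = sum(pr[pr <= po * (1 + 1e-7)]),
         greater = sum(pr[xs >= a]),
         less = sum(pr[xs <= a]))
}

# exact two-sided binomial p by full enumeration
oracle_binom_two_sided <- function(k, n, p) {
  ks <- 0:n
  pr <- choose(n, ks) * p^ks * (1 - p)^(n - ks)
  po <- pr[k + 1L]
  sum(pr[pr <= po * (1 + 1e-7)])
}

# one-sided (greater) hypergeometric enrichment p by summation
oracle_enrichment_p <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js) / choose(N, n))
}

# textbook Welch two-sided p
oracle_welch_p <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 /
    (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * stats::pt(-abs(tt), df)
}

# all-pairs interval overlap (0-based half-open)
oracle_overlaps <- function(s1, e1, s2, e2) {
  max(s1, s2) < min(e1, e2)
}

# --- fixture builders -------------------------------------------------

random_genome <- function(len, seed, name = "chrT") {
  set.seed(seed)
  genome_sequence(name, paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = ""))
}

# random methylome on a genome with per-site true levels drawn from
# {0, 0.5, 1} so that large differences are common
random_sample <- function(genome, seed, coverage = 10) {
  set.seed(seed)
  sites <- all_cytosines(genome)
  p <- sample(c(0, 0.5, 1), nrow(sites), replace = TRUE)
  cov <- stats::rpois(nrow(sites), coverage)
  cm <- stats::rbinom(nrow(sites), cov, p)
  methylome_sample(data.frame(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    count_meth = cm, count_unmeth = cov - cm, context = sites$context,
    stringsAsFactors = FALSE))
}

# deterministic sample with given per-site meth/unmeth counts
sample_from_counts <- function(chrom, pos, strand, cm, cu, context) {
  methylome_sample(data.frame(chrom = chrom, pos = pos, strand = strand,
                              count_meth = cm, count_unmeth = cu,
                              context = context, stringsAsFactors = FALSE))
}
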