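#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test on the table `rbind(c(a, b), c(c, d))`
#' (rows = group, columns = outcome). The two-sided p-value is the
#' minimum-likelihood definition: the sum of probabilities, over all
#' tables with the observed margins, of tables whose point probability
#' is at most that of the observed table (within a relative tolerance of
#' 1e-7). The odds ratio reported is the sample odds ratio
#' `(a*d)/(b*c)`, `Inf` when `b*c == 0` with `a*d > 0`, and `NaN` when
#' both products are zero.
#'
#' @param a,b,c,d Non-negative integer cell counts; alternatively `a`
#'   may be a 2x2 matrix.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`
#'   (`"two-sided"` is accepted).
#' @return List with `p_value`, `odds_ratio` and `alternative`.
#' @examples
#' # selection vs genotyping validation: 84/480 vs 33/185 carriers
#' fisher_exact(84, 396, 33, 152)$p_value
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  alternative <- sub("-", ".", alternative[1L], fixed = TRUE)
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("table entries must be non-negative")
  if (sum(cells) == 0)
    stop(errorCondition("all-zero contingency table: test undefined",
                        class = "undefined_table"))
  tab <- rbind(c(a, b), c(c, d))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  list(p_value = min(p, 1), odds_ratio = or, alternative = alternative)
}

#' Gene-set enrichment by one-sided Fisher's exact test
#'
#' For each term with `k` list genes, list size `n`, term size `K` and
#' background size `N`, computes the one-sided (greater) Fisher p-value
#' on the table `(k, n-k; K-k, N-n-K+k)`, the fold enrichment
#' `(k/n) / (K/N)` and the percentage `100*k/n`. Terms with no list gene
#' are omitted; results are sorted by p ascending. Raw p-values are
#' reported by default; set `p_adjust = TRUE` to add a
#' Benjamini-Hochberg column.
#'
#' @param gene_list Character vector of gene ids (subset of
#'   `background`).
#' @param term_sets Named list of character vectors (each a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param p_adjust Add a `p_adjusted` (BH) column.
#' @return Data frame with columns `term`, `count`, `percent`,
#'   `p_value`, `fold_enrichment` (plus `p_adjusted` if requested).
#' @export
term_enrichment <- function(gene_list, term_sets, background,
                            p_adjust = FALSE) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  off <- setdiff(gene_list, background)
  if (length(off))
    stop("gene_list members not in background: ",
         paste(utils::head(off, 10L), collapse = ", "))
  bad_terms <- names(term_sets)[vapply(term_sets, function(g)
    length(setdiff(g, background)) > 0L, TRUE)]
  if (length(bad_terms))
    stop("term sets with genes outside background: ",
         paste(utils::head(bad_terms, 10L), collapse = ", "))
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(term_sets), function(tm) {
    term <- unique(term_sets[[tm]])
    K <- length(term)
    k <- length(intersect(gene_list, term))
    if (k == 0L) return(NULL)
    p <- fisher_exact(k, n - k, K - k, N - n - K + k,
                      alternative = "greater")$p_value
    data.frame(term = tm, count = k, percent = 100 * k / n, p_value = p,
               fold_enrichment = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(0), count = integer(0),
                      percent = numeric(0), p_value = numeric(0),
                      fold_enrichment = numeric(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  if (p_adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Filter enrichment results by p-value
#'
#' Keeps results with `p_value` strictly below `p_max`, preserving
#' order. Strict, matching the reporting convention of showing only
#' values below the cutoff.
#'
#' @param results Data frame from [term_enrichment()].
#' @param p_max Exclusive p-value cutoff.
#' @return Filtered data frame.
#' @export
filter_enrichment <- function(results, p_max = 0.02) {
  out <- results[results$p_value < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' Each line: term id, description, then one gene id per tab-separated
#' field.
#'
#' @param path GMT file.
#' @return Named list of character vectors; descriptions are attached as
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT lines need at least 3 fields; offending line(s): ",
         paste(utils::head(short, 10L), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "descriptions") <- vapply(fields, `[`, "", 2L)
  sets
}

#' Write enrichment results as TSV
#'
#' @param results Data frame from [term_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
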