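#' Construct a methylome sample
#'
#' A methylome sample is a per-cytosine count table: one row per
#' (chrom, pos, strand) with methylated and unmethylated read counts and
#' the sequence context. This is the unit all DMR-calling functions
#' operate on, and it mirrors one sample of a Bismark-style cytosine
#' report.
#'
#' @param records Data frame with columns `chrom`, `pos` (1-based
#'   integer), `strand` (`+`/`-`), `count_meth`, `count_unmeth`
#'   (non-negative integers), `context` (`CG`/`CHG`/`CHH`).
#' @param genotype,cell_type Free-text metadata labels (e.g. `"Col"` and
#'   `"VC"`), stored as attributes.
#' @return A data frame of class `methylome_sample`, sorted by
#'   (chrom, pos, strand), with attributes `genotype` and `cell_type`.
#' @export
methylome_sample <- function(records, genotype = NA_character_,
                             cell_type = NA_character_) {
  required <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                "context")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[required]
  records$pos <- as.integer(records$pos)
  records$count_meth <- as.integer(records$count_meth)
  records$count_unmeth <- as.integer(records$count_unmeth)
  if (nrow(records)) {
    if (any(records$count_meth < 0L) || any(records$count_unmeth < 0L))
      stop("read counts must be non-negative")
    if (!all(records$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!all(records$context %in% c("CG", "CHG", "CHH")))
      stop("context must be one of CG, CHG, CHH")
    key <- paste(records$chrom, records$pos, records$strand)
    if (anyDuplicated(key))
      stop("duplicate (chrom, pos, strand) records in sample")
    records <- records[order(records$chrom, records$pos, records$strand), ,
                       drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records, genotype = genotype, cell_type = cell_type,
            class = c("methylome_sample", "data.frame"))
}

#' Parse a Bismark-style cytosine report
#'
#' Expects a tab-separated, header-less file with seven columns: chrom,
#' 1-based position, strand, methylated count, unmethylated count,
#' context, trinucleotide. Malformed lines are rejected with their line
#' numbers. If a genome is supplied, the context column is re-validated
#' against [classify_context()].
#'
#' @param path Input file.
#' @param genotype,cell_type Metadata labels for the returned sample.
#' @param genome Optional [genome_sequence] for context re-validation.
#' @return A [methylome_sample].
#' @export
parse_cytosine_report <- function(path, genotype = NA_character_,
                                  cell_type = NA_character_,
                                  genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) {
    warning("empty cytosine report: ", path)
    return(methylome_sample(
      data.frame(chrom = character(0), pos = integer(0),
                 strand = character(0), count_meth = integer(0),
                 count_unmeth = integer(0), context = character(0)),
      genotype, cell_type))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("malformed cytosine report (expected 7 tab-separated fields) at line(s): ",
         paste(utils::head(which(nf != 7L), 10L), collapse = ", "))
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  cm <- suppressWarnings(as.integer(m[, 4L]))
  cu <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(pos) | is.na(cm) | is.na(cu) | cm < 0L | cu < 0L |
    !(m[, 3L] %in% c("+", "-")) | !(m[, 6L] %in% c("CG", "CHG", "CHH"))
  if (any(bad))
    stop("invalid field values in cytosine report at line(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  rec <- data.frame(chrom = m[, 1L], pos = pos, strand = m[, 3L],
                    count_meth = cm, count_unmeth = cu, context = m[, 6L],
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    sel <- rec$chrom == genome$name
    recomputed <- classify_context(genome, rec$pos[sel], rec$strand[sel])
    mism <- which(!is.na(recomputed) & recomputed != rec$context[sel])
    if (length(mism))
      stop("context column disagrees with genome at line(s): ",
           paste(utils::head(which(sel)[mism], 10L), collapse = ", "))
  }
  methylome_sample(rec, genotype, cell_type)
}

#' Write a methylome sample as a cytosine report
#'
#' Emits the 7-column tab-separated dialect read by
#' [parse_cytosine_report()]; the trinucleotide column is filled from
#' `genome` when given, otherwise written as `"."`. Writing then
#' re-parsing is the identity on the sample's records.
#'
#' @param sample A [methylome_sample].
#' @param path Output path.
#' @param genome Optional [genome_sequence] used to spell out the
#'   strand-relative trinucleotide.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sample, path, genome = NULL) {
  stopifnot(inherits(sample, "methylome_sample"))
  if (nrow(sample) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  tri <- rep(".", nrow(sample))
  if (!is.null(genome)) {
    chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    sel <- sample$chrom == genome$name
    step <- ifelse(sample$strand[sel] == "+", 1L, -1L)
    idx <- cbind(sample$pos[sel], sample$pos[sel] + step,
                 sample$pos[sel] + 2L * step)
    b <- matrix(NA_character_, nrow(idx), 3L)
    ok <- idx >= 1L & idx <= n
    b[ok] <- chars[idx[ok]]
    rev_rows <- step == -1L
    b[rev_rows, ] <- .COMPLEMENT[b[rev_rows, ]]
    b[is.na(b)] <- "N"
    tri[sel] <- paste0(b[, 1L], b[, 2L], b[, 3L])
  }
  out <- data.frame(sample$chrom, sample$pos, sample$strand,
                    sample$count_meth, sample$count_unmeth,
                    sample$context, tri)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
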