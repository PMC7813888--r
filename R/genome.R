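#' A named genome sequence
#'
#' Lightweight carrier for a single chromosome: a name and an uppercase
#' nucleotide string over `A`, `C`, `G`, `T`, `N`. All context
#' classification and simulation functions take this object.
#'
#' @param name Chromosome identifier (length-1 character).
#' @param seq Nucleotide sequence (length-1 character); lower case is
#'   accepted and upper-cased.
#' @return An object of class `genome_sequence` with fields `name` and
#'   `seq`.
#' @examples
#' g <- genome_sequence("chr1", "ACGTACGT")
#' classify_context(g, 2, "+")
#' @export
genome_sequence <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name),
            is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome sequence must have length > 0")
  if (grepl("[^ACGTN]", seq))
    stop("genome sequence may only contain A, C, G, T, N")
  structure(list(name = name, seq = seq), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp\n", x$name, nchar(x$seq)))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named list of [genome_sequence] objects, one per record.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    genome_sequence(names(ss)[i], as.character(ss[[i]])))
  names(out) <- names(ss)
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes A [genome_sequence] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(ss) <- vapply(genomes, `[[`, "", "name")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify the sequence context of a cytosine
#'
#' Plant cytosine methylation is tracked in three contexts: CG, CHG and
#' CHH, where H is A, C or T. The context is read strand-relatively: a
#' `-`-strand cytosine appears as `G` on the forward sequence and its
#' downstream bases are the complemented bases at decreasing positions.
#'
#' A CG call needs one downstream base; CHG/CHH need two. Sites whose
#' downstream window runs off the chromosome, or contains `N`, are
#' unclassifiable and returned as `NA`.
#'
#' @param genome A [genome_sequence].
#' @param pos 1-based position(s) on the forward sequence.
#' @param strand `"+"` or `"-"`, recycled against `pos`.
#' @return Character vector over `"CG"`, `"CHG"`, `"CHH"` with `NA` for
#'   unclassifiable sites.
#' @section Errors: positions outside the sequence raise an error; a base
#'   that is not a strand-relative cytosine raises a condition of class
#'   `not_a_cytosine`.
#' @export
classify_context <- function(genome, pos, strand) {
  stopifnot(inherits(genome, "genome_sequence"))
  n <- nchar(genome$seq)
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L | pos > n))
    stop(sprintf("position out of bounds for %s (length %d)", genome$name, n))
  strand <- rep_len(as.character(strand), length(pos))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  fwd <- strand == "+"
  base <- chars[pos]
  bad <- ifelse(fwd, base != "C", base != "G")
  if (any(bad)) {
    stop(errorCondition(
      sprintf("base at position %d (%s strand) is not a cytosine",
              pos[which(bad)[1]], strand[which(bad)[1]]),
      class = "not_a_cytosine"))
  }
  step <- ifelse(fwd, 1L, -1L)
  d1 <- pos + step
  d2 <- pos + 2L * step
  get_rel <- function(idx) {
    b <- rep(NA_character_, length(idx))
    ok <- idx >= 1L & idx <= n
    b[ok] <- chars[idx[ok]]
    b[!fwd & !is.na(b)] <- .COMPLEMENT[b[!fwd & !is.na(b)]]
    b[!is.na(b) & b == "N"] <- NA_character_
    b
  }
  b1 <- get_rel(d1)
  b2 <- get_rel(d2)
  ctx <- rep(NA_character_, length(pos))
  isH1 <- !is.na(b1) & b1 %in% c("A", "C", "T")
  ctx[!is.na(b1) & b1 == "G"] <- "CG"
  ctx[isH1 & !is.na(b2) & b2 == "G"] <- "CHG"
  ctx[isH1 & !is.na(b2) & b2 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

#' Enumerate all classifiable cytosines of a genome
#'
#' Scans both strands and classifies every strand-relative cytosine.
#' Unclassifiable sites (chromosome edge, `N` in the window) are dropped.
#' Symmetric CG positions on opposite strands are kept as separate
#' records; no strand pooling is done anywhere in the package.
#'
#' @param genome A [genome_sequence].
#' @return A data frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, sorted by position then strand.
#' @export
all_cytosines <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  pos_p <- which(chars == "C")
  pos_m <- which(chars == "G")
  df <- data.frame(
    chrom = genome$name,
    pos = c(pos_p, pos_m),
    strand = rep(c("+", "-"), c(length(pos_p), length(pos_m))),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df$context <- character(0)
    return(df)
  }
  df$context <- classify_context(genome, df$pos, df$strand)
  df <- df[!is.na(df$context), , drop = FALSE]
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
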