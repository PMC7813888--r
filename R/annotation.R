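#' Construct a genomic feature table
#'
#' Genes and transposable elements (TEs) are carried as a plain interval
#' table in 0-based half-open coordinates.
#'
#' @param id Feature identifiers.
#' @param chrom Chromosome identifiers.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param strand `+`, `-` or `*`.
#' @param kind `"gene"` or `"TE"`.
#' @return Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `kind`.
#' @export
genomic_features <- function(id, chrom, start, end, strand = "*",
                             kind = "gene") {
  n <- length(id)
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   kind = rep_len(as.character(kind), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("features must satisfy start < end")
    if (!all(df$strand %in% c("+", "-", "*")))
      stop("strand must be '+', '-' or '*'")
    if (!all(df$kind %in% c("gene", "TE")))
      stop("kind must be 'gene' or 'TE'")
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

.features_as_iranges <- function(f) {
  IRanges::IRanges(start = f$start + 1L, end = f$end)
}

#' Parse gene and TE features from a GFF3 file
#'
#' Reads a GFF3 file and returns gene and TE feature tables, converting
#' GFF's 1-based closed coordinates to the package's 0-based half-open
#' convention. Feature identity comes from the `ID` (or `Name`)
#' attribute, with a positional fallback.
#'
#' @param path GFF3 file.
#' @param gene_types GFF `type` values treated as genes.
#' @param te_types GFF `type` values treated as TEs.
#' @return List with elements `genes` and `tes`, each a
#'   [genomic_features] table.
#' @export
parse_gff <- function(path,
                      gene_types = "gene",
                      te_types = c("transposable_element",
                                   "transposable_element_gene",
                                   "transposon")) {
  gr <- rtracklayer::import(path, format = "gff3")
  take <- function(types, kind) {
    g <- gr[as.character(gr$type) %in% types]
    if (length(g) == 0L)
      return(genomic_features(character(0), character(0), integer(0),
                              integer(0), character(0), character(0)))
    ids <- if (!is.null(g$ID)) as.character(g$ID) else rep(NA_character_, length(g))
    if (!is.null(g$Name)) ids[is.na(ids)] <- as.character(g$Name)[is.na(ids)]
    ids[is.na(ids)] <- paste0(kind, "_", seq_len(length(g)))[is.na(ids)]
    genomic_features(ids, as.character(GenomicRanges::seqnames(g)),
                     GenomicRanges::start(g) - 1L, GenomicRanges::end(g),
                     as.character(GenomicRanges::strand(g)), kind)
  }
  list(genes = take(gene_types, "gene"), tes = take(te_types, "TE"))
}

#' Write gene/TE feature tables to GFF3
#'
#' @param genes,tes [genomic_features] tables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, tes, path) {
  feats <- rbind(genes, tes)
  type <- ifelse(feats$kind == "TE", "transposable_element", "gene")
  if (nrow(feats) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start + 1L, feats$end),
    strand = ifelse(feats$strand == "*", "*", feats$strand))
  gr$type <- type
  gr$ID <- feats$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.overlap_any <- function(dmrs, feats) {
  if (nrow(dmrs) == 0L) return(logical(0))
  if (nrow(feats) == 0L) return(rep(FALSE, nrow(dmrs)))
  hits <- rep(FALSE, nrow(dmrs))
  for (ch in unique(dmrs$chrom)) {
    di <- which(dmrs$chrom == ch)
    fi <- which(feats$chrom == ch)
    if (!length(fi)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(dmrs$start[di] + 1L, dmrs$end[di]),
      IRanges::IRanges(feats$start[fi] + 1L, feats$end[fi]))
    hits[di] <- ov
  }
  hits
}

#' Classify the genomic location of DMRs
#'
#' Each DMR is assigned exactly one category with priority
#' TE > genic > intergenic: `TE` if it overlaps any TE by at least 1 bp,
#' otherwise `genic` if it overlaps any gene transcription unit,
#' otherwise `intergenic`.
#'
#' @param dmrs DMR data frame (0-based half-open `start`/`end`).
#' @param genes,tes [genomic_features] tables.
#' @return Character vector, one category per DMR.
#' @export
classify_dmr_location <- function(dmrs, genes, tes) {
  in_te <- .overlap_any(dmrs, tes)
  in_gene <- .overlap_any(dmrs, genes)
  ifelse(in_te, "TE", ifelse(in_gene, "genic", "intergenic"))
}

#' Associate DMRs with nearby genes
#'
#' A gene is associated with a DMR when the DMR lies within `window` bp
#' of the gene's transcription unit (strand-independent, matching the
#' "within 500 bp up- and downstream" convention): overlap, or an
#' inter-interval gap of at most `window`. A DMR ending exactly
#' `window` bp upstream of a gene start is associated; one bp further
#' is not.
#'
#' @param dmrs DMR data frame.
#' @param genes Gene [genomic_features] table.
#' @param window Flank in bp.
#' @return Data frame of association pairs with columns `gene_id`,
#'   `dmr_index` (row index into `dmrs`).
#' @export
associate_genes <- function(dmrs, genes, window = 500L) {
  out <- data.frame(gene_id = character(0), dmr_index = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(out)
  for (ch in unique(dmrs$chrom)) {
    di <- which(dmrs$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(dmrs$start[di] + 1L, dmrs$end[di]),
      IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi]),
      maxgap = as.integer(window))
    out <- rbind(out, data.frame(
      gene_id = genes$id[gi][S4Vectors::subjectHits(hits)],
      dmr_index = di[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE))
  }
  out[order(out$gene_id, out$dmr_index), , drop = FALSE]
}

#' Does a DMR lie in the 5'-region of a gene?
#'
#' The 5'-region is taken as the strand-aware window of `window` bp
#' immediately upstream of the transcription start: `[start - window,
#' start)` for a `+`-strand gene and `[end, end + window)` for a
#' `-`-strand gene. Returns whether the DMR overlaps that window.
#'
#' @param dmr One-row DMR data frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param gene One-row [genomic_features] entry with `strand`.
#' @param window Upstream window in bp.
#' @return Logical scalar.
#' @export
flag_5prime <- function(dmr, gene, window = 500L) {
  if (gene$strand == "-") {
    up_start <- gene$end
    up_end <- gene$end + window
  } else {
    up_start <- max(gene$start - window, 0L)
    up_end <- gene$start
  }
  dmr$start < up_end && dmr$end > up_start
}

#' Fraction of genes with a TE nearby
#'
#' A gene is TE-proximal when any TE overlaps its transcription unit or
#' lies within `window` bp of it up- or downstream
#' (strand-independent gap rule, as for [associate_genes()]).
#'
#' @param genes,tes [genomic_features] tables.
#' @param window Flank in bp.
#' @return List with `fraction` (TE-proximal genes / all genes) and
#'   `flags` (named logical vector per gene).
#' @export
te_proximal_fraction <- function(genes, tes, window = 500L) {
  if (nrow(genes) == 0L)
    return(list(fraction = NA_real_, flags = logical(0)))
  flags <- rep(FALSE, nrow(genes))
  if (nrow(tes)) {
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      ti <- which(tes$chrom == ch)
      if (!length(ti)) next
      flags[gi] <- IRanges::overlapsAny(
        IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi]),
        IRanges::IRanges(tes$start[ti] + 1L, tes$end[ti]),
        maxgap = as.integer(window))
    }
  }
  names(flags) <- genes$id
  list(fraction = mean(flags), flags = flags)
}

#' Annotate DMRs with location category, gene association and 5' flag
#'
#' Convenience composition of [classify_dmr_location()],
#' [associate_genes()] and [flag_5prime()]: per DMR, the location
#' category, the comma-separated associated gene ids, and whether the
#' DMR lies in the 5'-region of at least one associated gene.
#'
#' @param dmrs DMR data frame.
#' @param genes,tes [genomic_features] tables.
#' @param window Association flank in bp (also used for the 5' window).
#' @return `dmrs` with added columns `category`, `associated_genes`,
#'   `in_5prime`.
#' @export
annotate_dmrs <- function(dmrs, genes, tes, window = 500L) {
  dmrs$category <- classify_dmr_location(dmrs, genes, tes)
  assoc <- associate_genes(dmrs, genes, window)
  dmrs$associated_genes <- vapply(seq_len(nrow(dmrs)), function(i)
    paste(sort(assoc$gene_id[assoc$dmr_index == i]), collapse = ","),
    "")
  dmrs$in_5prime <- vapply(seq_len(nrow(dmrs)), function(i) {
    gids <- assoc$gene_id[assoc$dmr_index == i]
    if (!length(gids)) return(FALSE)
    any(vapply(gids, function(g)
      flag_5prime(dmrs[i, ], genes[genes$id == g, ][1L, ], window), TRUE))
  }, TRUE)
  dmrs
}
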