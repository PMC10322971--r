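#' @importFrom rtracklayer import export
NULL

#' Write an AnnotatedGenome to FASTA + GFF3 (+ protein FASTA)
#'
#' Coordinates are 1-based inclusive in GFF3 per the format convention; the
#' protein-family id travels in the `family` attribute.
#'
#' @param genome an [AnnotatedGenome].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, genome@strain)
  fa <- paste0(base, ".fna")
  writeXStringSet(genome@seqs, fa)
  gff <- paste0(base, ".gff3")
  g <- genome@genes
  mcols(g)$ID <- g$locus_tag
  mcols(g)$source <- "panMGE"
  mcols(g)$phase <- ifelse(g$type == "CDS", 0L, NA_integer_)
  export(g, gff, format = "gff3")
  paths <- c(fa, gff)
  if (length(genome@proteins)) {
    faa <- paste0(base, ".faa")
    writeXStringSet(genome@proteins, faa)
    paths <- c(paths, faa)
  }
  if (length(genome@depth)) {
    bg <- paste0(base, ".depth.bedGraph")
    writeBedGraph(genome@depth, bg)
    paths <- c(paths, bg)
  }
  invisible(paths)
}

#' Read an AnnotatedGenome from FASTA + GFF3 written by [writeGenome()]
#'
#' @param strain strain name (file base name).
#' @param dir directory holding `<strain>.fna` / `.gff3` / optional `.faa`.
#' @param circular optional named logical of circular replicons.
#' @return an [AnnotatedGenome].
#' @export
readGenome <- function(strain, dir, circular = NULL) {
  fa <- file.path(dir, paste0(strain, ".fna"))
  gff <- file.path(dir, paste0(strain, ".gff3"))
  if (!file.exists(fa) || !file.exists(gff))
    stop("missing FASTA/GFF3 for strain ", strain, " in ", dir)
  seqs <- readDNAStringSet(fa)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  gr <- tryCatch(import(gff, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", gff, ": ",
                                          conditionMessage(e)))
  gr <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)),
                strand = strand(gr),
                locus_tag = gr$locus_tag,
                type = as.character(gr$type),
                family = if (!is.null(gr$family)) gr$family else NA_character_,
                product = if (!is.null(gr$product)) gr$product else NA_character_,
                label = if (!is.null(gr$label)) ifelse(is.na(gr$label), "", gr$label)
                        else "")
  faa <- file.path(dir, paste0(strain, ".faa"))
  prot <- if (file.exists(faa)) {
    p <- readAAStringSet(faa)
    names(p) <- sub("\\s.*", "", names(p))
    p
  } else AAStringSet()
  AnnotatedGenome(strain, seqs, gr, prot, circular = circular)
}

#' Write SAM-convention read records
#'
#' Headerless SAM text (qname, flag, rname, pos, mapq, cigar, the
#' conventional placeholder mate fields and the sequence column).
#' @param reads read data.frame (see [simulateReseq()]).
#' @param path output file.
#' @export
writeSam <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   reads$qname, reads$flag, reads$rname, reads$pos,
                   reads$mapq, reads$cigar, reads$seq)
  writeLines(lines, path)
  invisible(path)
}

#' Read SAM-convention records into the package's read data.frame
#' @param path SAM file (header lines skipped).
#' @return read data.frame.
#' @export
readSamRecords <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^@", ln) & nzchar(ln)]
  if (!length(ln))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      stringsAsFactors = FALSE))
  fld <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  data.frame(qname = fld[, 1L], flag = as.integer(fld[, 2L]),
             rname = fld[, 3L], pos = as.integer(fld[, 4L]),
             mapq = as.integer(fld[, 5L]), cigar = fld[, 6L],
             seq = fld[, 10L], stringsAsFactors = FALSE)
}

#' Write a per-contig depth list as bedGraph
#' @param depth named list of per-base numeric vectors.
#' @param path output file.
#' @export
writeBedGraph <- function(depth, path) {
  grl <- lapply(names(depth), function(ctg) {
    r <- rle(depth[[ctg]])
    e <- cumsum(r$lengths)
    s <- c(1L, utils::head(e, -1L) + 1L)
    GRanges(ctg, IRanges(s, e), score = r$values)
  })
  export(suppressWarnings(do.call(c, grl)), path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph depth track into a per-contig list
#' @param path bedGraph file.
#' @return named list of per-base numeric vectors.
#' @export
readBedGraph <- function(path) {
  gr <- import(path, format = "bedGraph")
  out <- list()
  for (ctg in unique(as.character(seqnames(gr)))) {
    sub <- gr[as.character(seqnames(gr)) == ctg]
    v <- numeric(max(end(sub)))
    for (i in seq_along(sub)) v[start(sub)[i]:end(sub)[i]] <- sub$score[i]
    out[[ctg]] <- v
  }
  out
}
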