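#' Reciprocal-best-hit anchors between two annotated genomes
#'
#' Anchors are paralog-free reciprocal best protein hits, reported as gene
#' order indices on each genome (CDS in contig-then-coordinate order) plus
#' relative orientation.
#'
#' @param a,b [AnnotatedGenome] objects with protein annotations.
#' @return data.frame with columns `idxA`, `idxB`, `ori` (+1/-1), `locusA`,
#'   `locusB`, sorted by `idxA`.
#' @export
rbhAnchors <- function(a, b) {
  ga <- .cdsInOrder(a); gb <- .cdsInOrder(b)
  if (!length(a@proteins) || !length(b@proteins))
    stop("both genomes must carry protein annotations")
  ab <- .proteinBestHits(a@proteins, b@proteins)
  ba <- .proteinBestHits(b@proteins, a@proteins)
  if (is.null(ab) || is.null(ba)) return(.emptyAnchors())
  back <- setNames(ba$target, ba$query)
  rbh <- ab[!is.na(back[ab$target]) & back[ab$target] == ab$query, ]
  ia <- match(rbh$query, ga$locus_tag)
  ib <- match(rbh$target, gb$locus_tag)
  keep <- !is.na(ia) & !is.na(ib)
  out <- data.frame(idxA = ia[keep], idxB = ib[keep],
                    ori = ifelse(ga$strand[ia[keep]] == gb$strand[ib[keep]], 1L, -1L),
                    locusA = rbh$query[keep], locusB = rbh$target[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$idxA) & !duplicated(out$idxB), ]
  out[order(out$idxA), ]
}

.emptyAnchors <- function()
  data.frame(idxA = integer(), idxB = integer(), ori = integer(),
             locusA = character(), locusB = character(), stringsAsFactors = FALSE)

# CDS gene order: contig name, then coordinate
.cdsInOrder <- function(g) {
  gr <- g@genes[g@genes$type == "CDS"]
  ord <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[ord]
  data.frame(locus_tag = gr$locus_tag,
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

# Chain anchors (sorted by idxA) into colinear blocks at gap tolerance delta:
# consecutive anchors must be <= delta intervening genes apart on both
# genomes, move in a consistent direction on B, and keep a uniform relative
# orientation matching that direction.
.chainAnchors <- function(anchors, delta) {
  n <- nrow(anchors)
  if (n == 0L) return(integer(0))
  block <- integer(n)
  bid <- 1L
  block[1L] <- bid
  dir <- 0L
  for (i in seq_len(n - 1L)) {
    gapA <- anchors$idxA[i + 1L] - anchors$idxA[i] - 1L
    dB <- anchors$idxB[i + 1L] - anchors$idxB[i]
    gapB <- abs(dB) - 1L
    ok <- gapA <= delta && gapB <= delta && dB != 0L &&
      anchors$ori[i + 1L] == anchors$ori[i] &&
      sign(dB) == anchors$ori[i]
    if (ok && dir != 0L && sign(dB) != dir) ok <- FALSE
    if (ok) {
      if (dir == 0L) dir <- sign(dB)
      block[i + 1L] <- bid
    } else {
      bid <- bid + 1L
      block[i + 1L] <- bid
      dir <- 0L
    }
  }
  block
}

#' Synteny coverage fraction between two genomes
#'
#' Reconstructs synteny blocks (chains of reciprocal-best-hit anchors,
#' colinear on both genomes with gaps of at most `delta` intervening genes
#' and consistent strand) for each gap tolerance, and reports
#' coverage(delta) = anchored genes inside blocks of >= 2 anchors divided by
#' the gene count. The default mode averages the two genomes' fractions;
#' `mode = "directed"` divides by the query (`a`) gene count only.
#'
#' @param a,b annotated genomes.
#' @param deltas gap tolerances (default 2:10, the nine-anchor ladder).
#' @param mode "mean" (average of both genomes) or "directed" (relative to
#'   `a`).
#' @param anchors optional precomputed [rbhAnchors()] result.
#' @return list with `coverage` (named numeric per delta), `mean_coverage`,
#'   `blocks` (data.frame of anchors with per-delta block ids), `n_anchors`.
#' @export
syntenyCoverage <- function(a, b, deltas = 2:10, mode = c("mean", "directed"),
                            anchors = NULL) {
  mode <- match.arg(mode)
  if (is.null(anchors)) anchors <- rbhAnchors(a, b)
  na <- sum(a@genes$type == "CDS")
  nb <- sum(b@genes$type == "CDS")
  if (na == 0L || nb == 0L) stop("unannotated genome")
  cov <- setNames(numeric(length(deltas)), paste0("delta", deltas))
  blocks <- anchors
  for (k in seq_along(deltas)) {
    bl <- .chainAnchors(anchors, deltas[k])
    blocks[[paste0("block_d", deltas[k])]] <- bl
    if (length(bl)) {
      sizes <- table(bl)
      inblock <- sum(bl %in% as.integer(names(sizes)[sizes >= 2L]))
    } else inblock <- 0L
    cov[k] <- if (mode == "mean") mean(c(inblock / na, inblock / nb))
              else inblock / na
  }
  list(coverage = cov, mean_coverage = mean(cov), blocks = blocks,
       n_anchors = nrow(anchors))
}
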