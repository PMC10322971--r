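#' @importFrom stats hclust cutree as.dist
#' @importFrom utils head tail combn
NULL

#' Species/sublineage delimitation thresholds
#'
#' Fixed defaults matching the conventional genomic-species cut-offs:
#' ANI > 96 percent and dDDH > 70 percent delimit a genomic species; the
#' `sublineage_gap` (ANI points) is the separation a sublineage split must
#' show between its smallest within-group and largest between-group identity.
#'
#' @param ani_species ANI species threshold (percent).
#' @param ddh_species dDDH species threshold (percent).
#' @param sublineage_gap required ANI separation for a sublineage split.
#' @return a list of thresholds.
#' @export
delimitationThresholds <- function(ani_species = 96, ddh_species = 70,
                                   sublineage_gap = 0.5) {
  list(ani_species = ani_species, ddh_species = ddh_species,
       sublineage_gap = sublineage_gap)
}

#' dDDH logistic transform configuration
#'
#' The digital DDH estimate is a logistic transform of the alignment-based
#' distance d = 1 - (summed identities / summed HSP length). The logistic
#' coefficients are calibrated from the two published threshold anchors of
#' the genome-to-genome distance method (dDDH 70 percent at d = 0.0359 and
#' 79 percent at d = 0.0250) and can be overridden.
#'
#' @param anchors two-row data.frame with columns `d` and `y` (fractions).
#' @return list with logistic coefficients `a`, `b` such that
#'   `dDDH = 100 / (1 + exp(a + b * d))`.
#' @export
ddhTransform <- function(anchors = data.frame(d = c(0.0359, 0.0250),
                                              y = c(0.70, 0.79))) {
  stopifnot(nrow(anchors) == 2L)
  lo <- log((1 - anchors$y) / anchors$y)   # a + b*d = logit complement
  b <- (lo[1] - lo[2]) / (anchors$d[1] - anchors$d[2])
  a <- lo[1] - b * anchors$d[1]
  list(a = a, b = b)
}

#' Fragment-based average nucleotide identity (ANIb-style)
#'
#' The query is chopped into fixed-size fragments, each placed on the
#' subject with the k-mer-seeded ungapped aligner; placements are retained
#' at identity >= 30 percent over >= 70 percent fragment coverage and ANI is
#' the mean identity of retained placements. Both directions are computed
#' and averaged.
#'
#' @param a,b [AnnotatedGenome] objects (or named [Biostrings::DNAStringSet]).
#' @param fragment fragment size in bp (default 1020).
#' @param min_identity minimum retained fragment identity (fraction).
#' @param min_cov minimum fragment coverage (fraction).
#' @param index_a,index_b optional prebuilt subject indices (internal reuse).
#' @return list with `anib` (percent; `NA` with `defined = FALSE` when no
#'   fragment is retained), `defined`, `n_fragments_used`, and the per-
#'   direction means `anib_ab`, `anib_ba`.
#' @export
anibPair <- function(a, b, fragment = 1020L, min_identity = 0.3, min_cov = 0.7,
                     index_a = NULL, index_b = NULL) {
  sa <- if (is(a, "AnnotatedGenome")) a@seqs else a
  sb <- if (is(b, "AnnotatedGenome")) b@seqs else b
  if (!length(sa) || !length(sb) || !sum(BiocGenerics::width(sa)) ||
      !sum(BiocGenerics::width(sb)))
    stop("empty assembly")
  hab <- .fragmentAlignments(sa, sb, fragment, min_identity, min_cov, index_b)
  hba <- .fragmentAlignments(sb, sa, fragment, min_identity, min_cov, index_a)
  mean_id <- function(h) if (is.null(h)) NA_real_ else 100 * mean(h$identity)
  iab <- mean_id(hab); iba <- mean_id(hba)
  vals <- c(iab, iba)
  defined <- any(!is.na(vals))
  list(anib = if (defined) mean(vals, na.rm = TRUE) else NA_real_,
       defined = defined,
       n_fragments_used = sum(!is.null(hab) && nrow(hab),
                              !is.null(hba) && nrow(hba)),
       anib_ab = iab, anib_ba = iba)
}

#' Digital DNA-DNA hybridization (formula-2 style)
#'
#' Collects high-scoring fragment placements (both directions) as HSPs,
#' computes d = 1 - (sum of identical bases / sum of HSP lengths), and maps
#' d to a dDDH percentage through the logistic transform of [ddhTransform()].
#'
#' @inheritParams anibPair
#' @param transform logistic coefficients from [ddhTransform()].
#' @param index_a,index_b optional prebuilt subject indices (internal reuse).
#' @return list with `d2` (distance), `dDDH` (percent), `defined`,
#'   `hsp_length` (total aligned bases).
#' @export
ddhPair <- function(a, b, fragment = 1020L, min_identity = 0.3, min_cov = 0.7,
                    transform = ddhTransform(), index_a = NULL, index_b = NULL) {
  sa <- if (is(a, "AnnotatedGenome")) a@seqs else a
  sb <- if (is(b, "AnnotatedGenome")) b@seqs else b
  hab <- .fragmentAlignments(sa, sb, fragment, min_identity, min_cov, index_b)
  hba <- .fragmentAlignments(sb, sa, fragment, min_identity, min_cov, index_a)
  h <- rbind(hab, hba)
  if (is.null(h) || !nrow(h))
    return(list(d2 = NA_real_, dDDH = NA_real_, defined = FALSE, hsp_length = 0L))
  tot <- sum(h$aln_len)
  idb <- sum(h$aln_len - h$mismatches)
  d2 <- 1 - idb / tot
  list(d2 = d2, dDDH = 100 / (1 + exp(transform$a + transform$b * d2)),
       defined = TRUE, hsp_length = tot)
}

#' All-pairs relatedness matrices for a strain set
#'
#' @param genomes named list of [AnnotatedGenome] objects.
#' @param fragment ANIb fragment size.
#' @param ddh also compute dDDH (slower; default TRUE).
#' @return list with symmetric `ani` and (optionally) `ddh` percent
#'   matrices (self = 100) and the long-format `pairs` data.frame.
#' @export
relatednessMatrix <- function(genomes, fragment = 1020L, ddh = TRUE) {
  strains <- sort(names(genomes))
  n <- length(strains)
  ani <- matrix(100, n, n, dimnames = list(strains, strains))
  dd <- matrix(100, n, n, dimnames = list(strains, strains))
  pairs <- list()
  seqsets <- lapply(genomes[strains], function(g)
    if (is(g, "AnnotatedGenome")) g@seqs else g)
  indices <- lapply(seqsets, .subjectIndex)
  tr <- ddhTransform()
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    # one set of fragment alignments serves both indexes
    hab <- .fragmentAlignments(seqsets[[i]], seqsets[[j]], fragment,
                               index = indices[[j]])
    hba <- .fragmentAlignments(seqsets[[j]], seqsets[[i]], fragment,
                               index = indices[[i]])
    mean_id <- function(h) if (is.null(h)) NA_real_ else 100 * mean(h$identity)
    ani[i, j] <- ani[j, i] <- mean(c(mean_id(hab), mean_id(hba)), na.rm = TRUE)
    dv <- NA_real_
    if (ddh) {
      h <- rbind(hab, hba)
      if (!is.null(h) && nrow(h)) {
        d2 <- 1 - sum(h$aln_len - h$mismatches) / sum(h$aln_len)
        dv <- 100 / (1 + exp(tr$a + tr$b * d2))
      }
      dd[i, j] <- dd[j, i] <- dv
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = strains[i], b = strains[j], anib = ani[i, j], dDDH = dv,
      stringsAsFactors = FALSE)
  }
  if (ddh) {
    tr <- ddhTransform()
    diag(dd) <- 100 / (1 + exp(tr$a))  # d = 0 on self-comparison
  }
  list(ani = ani, ddh = if (ddh) dd else NULL,
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

#' Delimit species and sublineages from a relatedness matrix
#'
#' Species are connected components of the graph joining pairs above the
#' species thresholds (ANI; dDDH too when supplied). Within each species,
#' sublineages are single-linkage clusters accepted at the finest cut whose
#' smallest within-group ANI exceeds the largest between-group ANI by the
#' configured gap. Strains whose comparisons straddle the separation band
#' are flagged ambiguous.
#'
#' @param ani symmetric ANI percent matrix (complete; self = 100).
#' @param ddh optional symmetric dDDH percent matrix.
#' @param thresholds from [delimitationThresholds()].
#' @return list with `species` (named integer memberships), `sublineage`
#'   (named character like "1.2"), and `ambiguous` (named logical).
#' @export
delimitGroups <- function(ani, ddh = NULL, thresholds = delimitationThresholds()) {
  strains <- sort(rownames(ani))
  if (is.null(strains) || !identical(sort(colnames(ani)), strains))
    stop("ANI matrix must be square with matching dimnames")
  ani <- ani[strains, strains, drop = FALSE]
  if (any(is.na(ani))) stop("incomplete relatedness matrix")
  if (!is.null(ddh)) ddh <- ddh[strains, strains, drop = FALSE]
  n <- length(strains)
  adj <- ani > thresholds$ani_species
  if (!is.null(ddh)) adj <- adj & (ddh > thresholds$ddh_species)
  diag(adj) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  names(comp) <- strains
  # stable component numbering by first strain name
  comp <- match(comp, unique(comp[order(strains)]))
  names(comp) <- strains

  subl <- character(n); names(subl) <- strains
  ambig <- setNames(rep(FALSE, n), strains)
  for (sp in sort(unique(comp))) {
    mem <- strains[comp == sp]
    if (length(mem) == 1L) { subl[mem] <- paste0(sp, ".1"); next }
    d <- as.dist(100 - ani[mem, mem])
    hc <- hclust(d, method = "single")
    chosen <- setNames(rep(1L, length(mem)), mem)
    ks <- if (length(mem) > 2L) seq(length(mem) - 1L, 2L) else integer(0)
    for (k in ks) {
      ct <- cutree(hc, k = k)
      within_min <- Inf; between_max <- -Inf
      for (i in seq_along(mem)) for (j in seq_along(mem)) {
        if (i >= j) next
        v <- ani[mem[i], mem[j]]
        if (ct[i] == ct[j]) within_min <- min(within_min, v)
        else between_max <- max(between_max, v)
      }
      # a valid split needs at least one within pair as reference
      if (is.finite(within_min) &&
          within_min - between_max >= thresholds$sublineage_gap) {
        chosen <- ct
        break
      }
    }
    # renumber clusters by first member for order invariance
    chosen <- match(chosen, unique(chosen[order(mem)]))
    names(chosen) <- mem
    subl[mem] <- paste0(sp, ".", chosen)
    # ambiguity: a strain nearly equidistant to two sublineages straddles
    # the separation band (margin between its two closest clusters < gap)
    if (length(unique(chosen)) > 1L) {
      for (s in mem) {
        prox <- vapply(sort(unique(chosen)), function(cl) {
          others <- mem[chosen[mem] == cl & mem != s]
          if (!length(others)) return(NA_real_)
          max(ani[s, others])
        }, numeric(1))
        prox <- sort(prox[!is.na(prox)], decreasing = TRUE)
        if (length(prox) >= 2L &&
            prox[1] - prox[2] < thresholds$sublineage_gap)
          ambig[s] <- TRUE
      }
    }
  }
  # species-level crossing flag: held in a component by transitivity only
  for (sp in unique(comp)) {
    mem <- strains[comp == sp]
    if (length(mem) > 1L) for (s in mem) {
      if (any(ani[s, setdiff(mem, s)] <= thresholds$ani_species))
        ambig[s] <- TRUE
    }
  }
  list(species = comp, sublineage = subl, ambiguous = ambig)
}
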