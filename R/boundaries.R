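#' @importFrom Biostrings letterFrequency nucleotideSubstitutionMatrix nindel
#'   aligned
NULL

.SIGNATURE_RE <- paste0(
  "integrase|transposase|\\btnp|recombinase|virb[0-9]*|relaxase|\\bmob|",
  "t4cp|coupling|vird[24]|toxin|antitoxin|vap[bc]|maz[ef]|higa|phd|doc|",
  "par[abg]\\b|\\brep\\b|replicase")

#' Per-gene contextual evidence track
#'
#' For every annotated gene: GC deviation (z-score of the gene's GC content
#' against the genome-wide gene GC distribution), depth anomaly (z-score of
#' the gene's mean depth against the median/MAD of all genes; `NA` when no
#' depth track is attached — absent, not zero), pangenome compartment, and a
#' mobility-signature flag from the annotation labels. A cumulative
#' (G-C)/(G+C) skew track is attached for display.
#'
#' @param genome an [AnnotatedGenome].
#' @param ft a compartmentalized [FamilyTable] (or `NULL`; compartments NA).
#' @param signature_regex regex applied to `label`/`product` for the MGE
#'   signature flag.
#' @return data.frame, one row per gene: `locus_tag`, `contig`, `start`,
#'   `end`, `strand`, `type`, `gc`, `gc_z`, `depth_z`, `compartment`,
#'   `signature`. Attribute `gc_skew` carries the per-contig cumulative skew.
#' @export
contextualProfile <- function(genome, ft = NULL, signature_regex = .SIGNATURE_RE) {
  g <- genome@genes
  ord <- order(as.character(seqnames(g)), start(g))
  g <- g[ord]
  n <- length(g)
  gc <- numeric(n); dz <- rep(NA_real_, n)
  has_depth <- length(genome@depth) > 0L
  dmeans <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ctg <- as.character(seqnames(g)[i])
    s <- subseq(genome@seqs[[ctg]], start(g)[i], end(g)[i])
    gc[i] <- sum(letterFrequency(s, c("G", "C"))) / length(s)
    if (has_depth && ctg %in% names(genome@depth))
      dmeans[i] <- mean(genome@depth[[ctg]][start(g)[i]:end(g)[i]])
  }
  # robust z: the backbone defines the baseline, so shifted cargo cannot
  # inflate its own reference scale
  gz <- (gc - median(gc)) / max(mad(gc), 1e-9)
  if (has_depth) {
    md <- median(dmeans, na.rm = TRUE)
    s <- max(mad(dmeans, na.rm = TRUE), 1e-9)
    dz <- (dmeans - md) / s
  }
  comp <- rep(NA_character_, n)
  if (!is.null(ft) && length(ft@compartment)) {
    fam_comp <- ft@compartment
    m <- ft@members[ft@members$strain == genome@strain, ]
    byloc <- setNames(fam_comp[m$family], m$locus)
    comp <- unname(byloc[g$locus_tag])
  }
  lab <- paste(tolower(g$label), tolower(g$product))
  out <- data.frame(
    locus_tag = g$locus_tag,
    contig = as.character(seqnames(g)),
    start = start(g), end = end(g),
    strand = as.character(strand(g)), type = g$type,
    gc = gc, gc_z = gz, depth_z = dz,
    compartment = comp,
    signature = grepl(signature_regex, lab),
    stringsAsFactors = FALSE)
  skew <- lapply(names(genome@seqs), function(ctg) {
    v <- as.integer(charToRaw(as.character(genome@seqs[[ctg]])))
    gq <- cumsum((v == 71L) - (v == 67L))  # G minus C
    gq / pmax(seq_along(gq), 1)
  })
  names(skew) <- names(genome@seqs)
  attr(out, "gc_skew") <- skew
  out
}

.isMobileCompartment <- function(x)
  !is.na(x) & x %in% c("flexible", "exclusive")

#' Reconstruct candidate elements around seed hits
#'
#' Seed hits at most `window` genes apart are clustered; each cluster is
#' extended outward over consecutive flexible/exclusive genes, tolerating
#' isolated core genes but stopping at `core_run_stop` consecutive core
#' genes; contigs that are entirely flexible/exclusive and carry a seed hit
#' are absorbed whole. Segments on different contigs are merged into one
#' candidate when they match the same seed element over disjoint seed-protein
#' subsets with combined coverage of at least half the seed. Candidates are
#' ranked by evidence support (seed hits plus compositional deviation of the
#' member genes).
#'
#' @param genome an [AnnotatedGenome].
#' @param seed_hits named list (by seed element id) of [seedSearch()] hit
#'   tables against this genome.
#' @param evidence the [contextualProfile()] track for this genome.
#' @param window seed-clustering gap in genes (default 10).
#' @param core_run_stop consecutive core genes that terminate extension.
#' @param seed_sizes optional named integer: seed element id -> number of
#'   seed proteins (needed for the multi-contig merge rule; inferred from
#'   hits when omitted).
#' @return list of [CandidateElement] objects, ranked by support.
#' @export
reconstructElements <- function(genome, seed_hits, evidence, window = 10L,
                                core_run_stop = 2L, seed_sizes = NULL) {
  if (!length(seed_hits) || !sum(vapply(seed_hits, nrow, integer(1))))
    return(list())
  ev <- evidence[order(evidence$contig, evidence$start), ]
  locus2row <- setNames(seq_len(nrow(ev)), ev$locus_tag)
  mobile <- .isMobileCompartment(ev$compartment)
  # seed-hit map per gene row
  hit_seeds <- vector("list", nrow(ev))
  hit_queries <- vector("list", nrow(ev))
  for (sid in names(seed_hits)) {
    h <- seed_hits[[sid]]
    if (!nrow(h)) next
    for (k in seq_len(nrow(h))) {
      r <- locus2row[h$target_locus[k]]
      if (is.na(r)) next
      hit_seeds[[r]] <- union(hit_seeds[[r]], sid)
      hit_queries[[r]] <- union(hit_queries[[r]], paste0(sid, "::", h$query[k]))
    }
  }
  has_seed <- lengths(hit_seeds) > 0L
  cands <- list()
  for (ctg in unique(ev$contig)) {
    rows <- which(ev$contig == ctg)
    seed_rows <- rows[has_seed[rows]]
    if (!length(seed_rows)) next
    # cluster seed rows by gene-index gap
    pos_in_ctg <- match(seed_rows, rows)
    cl <- cumsum(c(1L, diff(pos_in_ctg) > window))
    for (cid in unique(cl)) {
      sr <- seed_rows[cl == cid]
      lo <- min(match(sr, rows)); hi <- max(match(sr, rows))
      # extend left
      i <- lo - 1L; run <- 0L; last_keep <- lo
      while (i >= 1L) {
        if (mobile[rows[i]]) { last_keep <- i; run <- 0L }
        else { run <- run + 1L; if (run >= core_run_stop) break }
        i <- i - 1L
      }
      lo <- last_keep
      i <- hi + 1L; run <- 0L; last_keep <- hi
      while (i <= length(rows)) {
        if (mobile[rows[i]]) { last_keep <- i; run <- 0L }
        else { run <- run + 1L; if (run >= core_run_stop) break }
        i <- i + 1L
      }
      hi <- last_keep
      span <- rows[lo:hi]
      member <- span[mobile[span] | has_seed[span]]
      seeds <- sort(unique(unlist(hit_seeds[span])))
      queries <- sort(unique(unlist(hit_queries[span])))
      support <- length(queries) +
        mean(abs(ev$gc_z[member]) >= 2, na.rm = TRUE)
      notes <- if (length(member) <= 1L) "low-confidence: single-gene candidate" else ""
      seg <- GRanges(ctg, IRanges(min(ev$start[span]), max(ev$end[span])))
      cands[[length(cands) + 1L]] <- list(
        segments = seg, genes = ev$locus_tag[member], seeds = seeds,
        queries = queries, support = support, notes = notes)
    }
  }
  if (!length(cands)) return(list())
  # multi-contig merge on shared primary seed with disjoint query subsets
  if (is.null(seed_sizes))
    seed_sizes <- vapply(seed_hits, function(h) length(unique(sub("^.*::", "", h$query))),
                         integer(1))
  primary <- vapply(cands, function(cd)
    if (length(cd$seeds)) cd$seeds[[1L]] else "", character(1))
  merged <- rep(FALSE, length(cands))
  out <- list()
  for (sid in unique(primary[primary != ""])) {
    grp <- which(primary == sid & !merged)
    if (length(grp) < 2L) next
    qsets <- lapply(cands[grp], function(cd)
      sub("^.*::", "", grep(paste0("^", sid, "::"), cd$queries, value = TRUE)))
    disjoint <- length(unlist(qsets)) == length(unique(unlist(qsets)))
    covered <- length(unique(unlist(qsets))) / max(1L, seed_sizes[[sid]])
    multi_ctg <- length(unique(vapply(cands[grp], function(cd)
      as.character(seqnames(cd$segments))[1L], character(1)))) > 1L
    if (disjoint && covered >= 0.5 && multi_ctg) {
      m <- cands[[grp[1L]]]
      for (k in grp[-1L]) {
        m$segments <- suppressWarnings(c(m$segments, cands[[k]]$segments))
        m$genes <- c(m$genes, cands[[k]]$genes)
        m$seeds <- union(m$seeds, cands[[k]]$seeds)
        m$queries <- union(m$queries, cands[[k]]$queries)
        m$support <- m$support + cands[[k]]$support
      }
      m$notes <- paste0("merged across ", length(grp), " contigs")
      out[[length(out) + 1L]] <- m
      merged[grp] <- TRUE
    }
  }
  for (i in which(!merged)) out[[length(out) + 1L]] <- cands[[i]]
  ordix <- order(-vapply(out, function(cd) cd$support, numeric(1)))
  out <- out[ordix]
  lapply(seq_along(out), function(i) {
    cd <- out[[i]]
    new("CandidateElement",
        element_id = sprintf("%s_cand%02d", genome@strain, i),
        strain = genome@strain, segments = cd$segments,
        genes = cd$genes, seeds = cd$seeds, support = cd$support,
        att = list(), inventory = list(), type = "", notes = cd$notes)
  })
}

#' Recover the att quartet of a candidate element
#'
#' Globally compares the two terminal windows of the candidate with a local
#' (repeat-seeking) alignment and reports the best shared direct repeat of at
#' least `min_dr` bp with at most `max_mismatch` mismatches as the attL/attR
#' pair; the empty chromosomal site (attB) and the excised-circle junction
#' (attP) are reconstructed by in-silico excision. The nearest upstream
#' tRNA/gene is recorded as the integration feature.
#'
#' @param candidate a [CandidateElement] with resolved termini on one contig.
#' @param genome the [AnnotatedGenome] it lives in.
#' @param min_dr minimum direct-repeat length (bp).
#' @param max_mismatch maximum mismatches tolerated in the repeat.
#' @param search_window window (bp) around each terminus searched.
#' @param flank flank length used when composing attB/attP sequences.
#' @return list (`attL`, `attR` integer start/end pairs, `dr_seq`,
#'   `dr_length`, `attB_seq`, `attP_seq`, `integration_feature`) or `NULL`
#'   when no repeat passes the thresholds (or termini are unresolved, with a
#'   notice).
#' @export
findAttSites <- function(candidate, genome, min_dr = 12L, max_mismatch = 1L,
                         search_window = 1000L, flank = 40L) {
  seg <- candidate@segments
  if (length(unique(as.character(seqnames(seg)))) != 1L) {
    message("att search skipped: candidate termini span multiple contigs")
    return(NULL)
  }
  ctg <- as.character(seqnames(seg))[1L]
  s <- min(start(seg)); e <- max(end(seg))
  chrom <- genome@seqs[[ctg]]
  L <- length(chrom)
  # repeat copies flank the cargo genes: search strictly outside the
  # candidate's gene span, so interior sequence cannot masquerade as a repeat
  lw_s <- max(1L, s - search_window); lw_e <- max(1L, s - 1L)
  rw_s <- min(L, e + 1L); rw_e <- min(L, e + search_window)
  if (lw_e <= lw_s || rw_e <= rw_s) {
    message("att search skipped: no flanking sequence at the termini")
    return(NULL)
  }
  left <- subseq(chrom, lw_s, lw_e)
  right <- subseq(chrom, rw_s, rw_e)
  # shared substrings arise by chance between windows of this size; require
  # the expected number of chance matches of the reported length to be
  # below 1e-3 per search, so reported repeats are significant
  space <- as.numeric(length(left)) * length(right)
  need_exact <- max(min_dr, ceiling(log(space * 1000, 4)))
  # exact pass first: a prohibitive mismatch penalty turns the local
  # alignment into a longest-common-substring search, so an exactly planted
  # repeat is recovered without chance mismatch extensions
  exact_mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1000,
                                            baseOnly = TRUE)
  pa <- pairwiseAlignment(left, right, type = "local",
                          substitutionMatrix = exact_mat,
                          gapOpening = 1000, gapExtension = 1000)
  need <- need_exact
  if (nchar(pa) < need_exact && max_mismatch > 0L) {
    mat <- nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
    pa <- pairwiseAlignment(left, right, type = "local",
                            substitutionMatrix = mat,
                            gapOpening = 25, gapExtension = 10)
    need <- need_exact + 3L               # mismatched repeats need more signal
  }
  alen <- nchar(pa)
  ind <- nindel(pa)
  n_ind <- sum(ind@insertion[, "WidthSum"], ind@deletion[, "WidthSum"])
  if (alen < need || nmismatch(pa) > max_mismatch || n_ind > 0L)
    return(NULL)
  l1 <- lw_s + start(pattern(pa)) - 1L
  l2 <- lw_s + end(pattern(pa)) - 1L
  r1 <- rw_s + start(subject(pa)) - 1L
  r2 <- rw_s + end(subject(pa)) - 1L
  dr_seq <- as.character(subseq(chrom, l1, l2))
  attB <- paste0(as.character(subseq(chrom, max(1L, l1 - flank), l2)),
                 as.character(subseq(chrom, r2 + 1L, min(L, r2 + flank))))
  attP <- paste0(as.character(subseq(chrom, max(1L, r1 - flank), r2)),
                 as.character(subseq(chrom, l2 + 1L, min(L, l2 + flank))))
  g <- genome@genes[as.character(seqnames(genome@genes)) == ctg]
  up <- g[end(g) <= l1]
  feat <- NA_character_; feat_len <- NA_integer_
  if (length(up)) {
    up <- up[order(end(up), decreasing = TRUE)]
    trna <- up[up$type == "tRNA" & end(up) >= l1 - 500L]
    pick <- if (length(trna)) trna[1L] else up[1L]
    feat <- pick$product
    feat_len <- BiocGenerics::width(pick)
  }
  list(attL = c(start = l1, end = l2), attR = c(start = r1, end = r2),
       dr_seq = dr_seq, dr_length = nchar(dr_seq),
       attB_seq = attB, attP_seq = attP, integration_feature = feat,
       notation = sprintf("DR(%s,%d)",
                          if (is.na(feat_len)) "-" else feat_len,
                          nchar(dr_seq)))
}

#' Excise an element through its att quartet
#'
#' Removes the element plus one direct-repeat copy from a chromosome,
#' reconstituting the empty (attB) chromosome; with an exact repeat this is
#' the exact inverse of integration.
#'
#' @param chrom a [Biostrings::DNAString] (or character) chromosome.
#' @param att an att quartet from [findAttSites()].
#' @return the excised chromosome as a `DNAString`.
#' @export
exciseElement <- function(chrom, att) {
  if (is.character(chrom)) chrom <- DNAString(chrom)
  l2 <- att$attL[["end"]]; r2 <- att$attR[["end"]]
  Biostrings::xscat(subseq(chrom, 1L, l2),
                    if (r2 < length(chrom)) subseq(chrom, r2 + 1L, length(chrom))
                    else DNAString(""))
}

#' In-silico PCR
#'
#' Finds opposing-orientation matches of a primer pair within `max_len` and
#' reports amplicons; length is the distance between the outer primer 5'
#' ends, inclusive. Circular templates are searched across the origin.
#'
#' @param templates named [Biostrings::DNAStringSet] (or character vector).
#' @param fwd,rev primer sequences (>= 15 nt).
#' @param max_mismatch mismatches tolerated per primer site (default 0).
#' @param max_len maximum amplicon length (default 6000).
#' @param circular named logical per template (default all linear).
#' @return data.frame: `template`, `start`, `end`, `length`, `fwd_primer`
#'   (which primer annealed on the plus strand).
#' @export
insilicoPcr <- function(templates, fwd, rev, max_mismatch = 0L,
                        max_len = 6000L, circular = NULL) {
  if (is.character(templates)) templates <- DNAStringSet(templates)
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primers must be >= 15 nt")
  if (is.null(circular))
    circular <- setNames(rep(FALSE, length(templates)), names(templates))
  out <- list()
  for (tn in names(templates)) {
    tpl <- templates[[tn]]
    L <- length(tpl)
    search_seq <- if (circular[[tn]]) Biostrings::xscat(tpl, tpl) else tpl
    site <- function(p) {
      plus <- start(matchPattern(DNAString(p), search_seq,
                                 max.mismatch = max_mismatch))
      minus <- start(matchPattern(reverseComplement(DNAString(p)), search_seq,
                                  max.mismatch = max_mismatch))
      if (length(plus) + length(minus) > 100L)
        stop("ambiguity: primer has more than 100 binding sites")
      list(plus = plus, minus = minus)
    }
    sf <- site(fwd); sr <- site(rev)
    pairs <- rbind(
      if (length(sf$plus) && length(sr$minus))
        expand.grid(s = sf$plus, e2 = sr$minus, fp = "fwd", klen = nchar(rev)),
      if (length(sr$plus) && length(sf$minus))
        expand.grid(s = sr$plus, e2 = sf$minus, fp = "rev", klen = nchar(fwd)))
    if (is.null(pairs) || !nrow(pairs)) next
    pairs$end <- pairs$e2 + pairs$klen - 1L
    pairs <- pairs[pairs$end > pairs$s & pairs$end - pairs$s + 1L <= max_len, ,
                   drop = FALSE]
    if (circular[[tn]] && nrow(pairs)) {
      pairs <- pairs[pairs$s <= L & pairs$end - pairs$s + 1L <= L, , drop = FALSE]
    }
    if (!nrow(pairs)) next
    amp <- data.frame(template = tn, start = pairs$s, end = pairs$end,
                      length = pairs$end - pairs$s + 1L,
                      fwd_primer = as.character(pairs$fp),
                      stringsAsFactors = FALSE)
    amp <- amp[!duplicated(amp[, c("start", "length")]), ]
    out[[tn]] <- amp
  }
  if (!length(out))
    return(data.frame(template = character(), start = integer(),
                      end = integer(), length = integer(),
                      fwd_primer = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
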