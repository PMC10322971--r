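#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   vmatchPattern matchPattern neditStartingAt subseq reverseComplement
#'   translate writeXStringSet readDNAStringSet readAAStringSet
#'   pairwiseAlignment nmismatch nchar pattern subject score
#' @importFrom IRanges IRanges start end width
NULL

# Deterministic stream splitting: one master integer seed per operation,
# sub-streams derived by index. Keeps every derived seed below 2^31.
.splitSeed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 69621 + i * 30269) %% 2147483647)
}

# Karlin-Altschul parameters for ungapped BLOSUM62 comparisons.
.KA_LAMBDA <- 0.3176
.KA_K <- 0.134

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# E-value of an ungapped protein alignment score over an m x n search space.
.kaEvalue <- function(score, m, n) {
  .KA_K * as.numeric(m) * as.numeric(n) * exp(-.KA_LAMBDA * score)
}

# ---------------------------------------------------------------------------
# Seeded ungapped nucleotide placement.
#
# The forge introduces substitutions only, so a correct placement of a query
# window on a subject contig is ungapped; exact k-mer seeds anchor the
# placement and neditStartingAt counts mismatches at C speed. This is the
# pluggable local-alignment backend used by the ANIb/dDDH and IS-scan layers.
# ---------------------------------------------------------------------------

# Prebuilt k-mer hash index of a subject assembly (both strands): one
# environment per contig/strand mapping each k-mer to its start positions.
.subjectIndex <- function(subject, k = 16L) {
  strands <- list(`+` = subject, `-` = reverseComplement(subject))
  idx <- list()
  for (sname in names(strands)) {
    sub <- strands[[sname]]
    ctgidx <- list()
    for (ci in seq_along(sub)) {
      s <- as.character(sub[[ci]])
      n <- nchar(s)
      if (n < k) next
      st <- seq_len(n - k + 1L)
      km <- substring(s, st, st + k - 1L)
      ctgidx[[names(sub)[ci]]] <- list2env(split(st, km), hash = TRUE)
    }
    idx[[sname]] <- ctgidx
  }
  list(k = k, idx = idx, seqs = strands)
}

# Trim an ungapped placement to its best-scoring contiguous segment
# (match +1, mismatch -2), as a local aligner's HSP would. Vectorized
# maximum-subarray on the prefix sums.
.trimHSP <- function(fragchars, subjchars) {
  v <- ifelse(fragchars == subjchars, 1, -2)
  pre <- cumsum(v)
  P0 <- c(0, pre)
  minpre <- cummin(P0[-length(P0)])
  gain <- pre - minpre
  j <- which.max(gain)
  i <- which.max(P0[seq_len(j)] == minpre[j])  # first index achieving the min
  mm <- sum(fragchars[i:j] != subjchars[i:j])
  list(from = i, to = j, mismatches = mm)
}

# Best ungapped placement of `frag` on an indexed subject.
.placeFragmentIdx <- function(frag, index, max_candidates = 24L, min_cov = 0.7) {
  flen <- nchar(frag)
  k <- index$k
  if (flen < k) return(NULL)
  offs <- unique(pmax(1L, as.integer(seq(1L, flen - k + 1L, length.out = 5L))))
  fr_dna <- DNAString(frag)
  best <- NULL
  for (sname in names(index$idx)) {
    for (off in offs) {
      seed <- substr(frag, off, off + k - 1L)
      found <- FALSE
      for (ctg in names(index$idx[[sname]])) {
        st <- index$idx[[sname]][[ctg]][[seed]]
        if (is.null(st)) next
        if (length(st) > max_candidates) st <- st[seq_len(max_candidates)]
        cseq <- index$seqs[[sname]][[ctg]]
        clen <- length(cseq)
        for (q in st) {
          a <- q - off + 1L
          lo <- max(1L, a)
          hi <- min(clen, a + flen - 1L)
          alen <- hi - lo + 1L
          if (alen < flen * min_cov) next
          fsub <- if (alen == flen) fr_dna else subseq(fr_dna, lo - a + 1L, lo - a + alen)
          mm <- neditStartingAt(fsub, cseq, starting.at = lo)
          ident <- (alen - mm) / alen
          found <- TRUE
          if (is.null(best) || ident > best$identity ||
              (ident == best$identity && alen > best$aln_len)) {
            best <- data.frame(
              contig = ctg, strand = sname, subj_lo = lo,
              frag_from = lo - a + 1L,
              start = if (sname == "+") lo else clen - hi + 1L,
              aln_len = alen, mismatches = as.integer(mm),
              identity = ident, coverage = alen / flen)
          }
        }
      }
      if (!is.null(best) && best$identity == 1 && best$coverage == 1)
        return(best[setdiff(names(best), c("subj_lo", "frag_from"))])
      if (found && !is.null(best) && best$identity >= 0.9) break
    }
    if (!is.null(best) && best$identity == 1 && best$coverage == 1)
      return(best[setdiff(names(best), c("subj_lo", "frag_from"))])
  }
  # trim chimeric placements (element/backbone junction fragments) to their
  # best local segment, the HSP a local aligner would return; clean
  # placements are left untouched so identities match the Hamming count
  if (!is.null(best) && best$identity < 0.9) {
    ctgseq <- index$seqs[[best$strand]][[best$contig]]
    lo <- best$subj_lo
    subjchars <- strsplit(as.character(subseq(ctgseq, lo, lo + best$aln_len - 1L)),
                          "", fixed = TRUE)[[1L]]
    fc <- strsplit(frag, "", fixed = TRUE)[[1L]][
      seq.int(best$frag_from, length.out = best$aln_len)]
    tr <- .trimHSP(fc, subjchars)
    new_len <- tr$to - tr$from + 1L
    best$mismatches <- tr$mismatches
    best$identity <- (new_len - tr$mismatches) / new_len
    best$coverage <- new_len / nchar(frag)
    best$start <- if (best$strand == "+") lo + tr$from - 1L else
      length(ctgseq) - (lo + tr$to - 1L) + 1L
    best$aln_len <- new_len
  }
  if (!is.null(best)) best <- best[setdiff(names(best), c("subj_lo", "frag_from"))]
  best
}

# Best ungapped placements of `frag` (character or DNAString) on a
# DNAStringSet `subject` (both strands). Returns a data.frame with one row
# (the best placement) or zero rows.
.placeFragment <- function(frag, subject, k = 16L, max_candidates = 24L,
                           min_cov = 0.7) {
  frag <- as.character(frag)
  flen <- nchar(frag)
  if (flen < k) return(NULL)
  offs <- unique(pmax(1L, as.integer(seq(1L, flen - k + 1L, length.out = 5L))))
  strands <- list(`+` = subject, `-` = reverseComplement(subject))
  best <- NULL
  fr_dna <- DNAString(frag)
  for (sname in names(strands)) {
    sub <- strands[[sname]]
    for (off in offs) {
      seed <- substr(frag, off, off + k - 1L)
      hits <- vmatchPattern(seed, sub)
      found <- FALSE
      for (ci in seq_along(hits)) {
        st <- start(hits[[ci]])
        if (!length(st)) next
        if (length(st) > max_candidates) st <- st[seq_len(max_candidates)]
        ctg <- sub[[ci]]
        clen <- length(ctg)
        for (q in st) {
          a <- q - off + 1L           # placement start of full fragment
          lo <- max(1L, a)
          hi <- min(clen, a + flen - 1L)
          alen <- hi - lo + 1L
          if (alen < flen * min_cov) next
          fsub <- subseq(fr_dna, lo - a + 1L, lo - a + alen)
          mm <- neditStartingAt(fsub, ctg, starting.at = lo)
          ident <- (alen - mm) / alen
          found <- TRUE
          if (is.null(best) || ident > best$identity ||
              (ident == best$identity && alen > best$aln_len)) {
            best <- data.frame(
              contig = names(sub)[ci], strand = sname,
              start = if (sname == "+") lo else clen - hi + 1L,
              aln_len = alen, mismatches = as.integer(mm),
              identity = ident, coverage = alen / flen)
          }
        }
      }
      # a perfect full-length placement cannot be improved
      if (!is.null(best) && best$identity == 1 && best$coverage == 1) return(best)
      # a confident placement ends the seed search for this strand
      if (found && !is.null(best) && best$identity >= 0.9) break
    }
    if (!is.null(best) && best$identity == 1 && best$coverage == 1) return(best)
  }
  best
}

# Chop query contigs into consecutive fragments and place each on the
# subject. Returns a data.frame of retained fragment alignments. A
# precomputed [.subjectIndex()] avoids re-indexing the subject per fragment.
.fragmentAlignments <- function(query, subject, fragment = 1020L,
                                min_identity = 0.3, min_cov = 0.7,
                                index = NULL) {
  if (is.null(index)) index <- .subjectIndex(subject)
  out <- vector("list", 64L)
  n <- 0L
  for (ci in seq_along(query)) {
    ctg <- query[[ci]]
    clen <- length(ctg)
    starts <- seq(1L, clen, by = fragment)
    for (s in starts) {
      e <- min(clen, s + fragment - 1L)
      if (e - s + 1L < 100L) next
      hit <- .placeFragmentIdx(as.character(subseq(ctg, s, e)), index,
                               min_cov = min_cov)
      if (is.null(hit)) next
      if (hit$identity < min_identity || hit$coverage < min_cov) next
      n <- n + 1L
      if (n > length(out)) out <- c(out, vector("list", length(out)))
      hit$query_contig <- names(query)[ci]
      hit$query_start <- s
      out[[n]] <- hit
    }
  }
  if (n == 0L) return(NULL)
  do.call(rbind, out[seq_len(n)])
}

# ---------------------------------------------------------------------------
# Protein best-hit search (k-mer prefiltered; ungapped fast path for
# equal-length pairs, pairwiseAlignment otherwise).
# ---------------------------------------------------------------------------

# k-mer index: named list kmer -> integer protein indices
.aaKmerIndex <- function(prots, k = 5L, stride = 3L) {
  seqs <- as.character(prots)
  idx <- rep.int(seq_along(seqs), pmax(0L, (nchar(seqs) - k) %/% stride + 1L))
  starts <- unlist(lapply(nchar(seqs), function(n)
    if (n >= k) seq(1L, n - k + 1L, by = stride) else integer()))
  kmers <- substring(seqs[idx], starts, starts + k - 1L)
  split(idx, kmers)
}

# Alignment stats for one protein pair.
.aaPairStats <- function(s1, s2) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 == n2) {
    c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
    c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
    B <- .blosum62()
    ok <- c1 %in% rownames(B) & c2 %in% rownames(B)
    sc <- sum(B[cbind(c1[ok], c2[ok])])
    nid <- sum(c1 == c2)
    list(score = sc, identity = nid / n1, coverage = 1, aln_len = n1,
         n_ident = nid)
  } else {
    pa <- pairwiseAlignment(AAString(s1), AAString(s2), type = "local",
                            substitutionMatrix = .blosum62(),
                            gapOpening = 11, gapExtension = 1)
    alen <- nchar(pa)
    nid <- alen - nmismatch(pa)  # counts substitutions, not indels
    list(score = score(pa), identity = if (alen > 0) nid / alen else 0,
         coverage = alen / min(n1, n2), aln_len = alen, n_ident = nid)
  }
}

# Best hit of each query protein in a subject proteome.
# Returns a data.frame: query, target, score, evalue, identity, coverage.
.proteinBestHits <- function(query, subject, k = 5L) {
  if (!length(query) || !length(subject)) return(NULL)
  sidx <- .aaKmerIndex(subject, k = k, stride = 1L)
  qseq <- as.character(query)
  sseq <- as.character(subject)
  m <- sum(nchar(sseq))
  rows <- vector("list", length(query))
  for (qi in seq_along(qseq)) {
    s <- qseq[qi]
    n <- nchar(s)
    if (n < k) next
    st <- seq(1L, n - k + 1L, by = 3L)
    kms <- substring(s, st, st + k - 1L)
    cand <- unique(unlist(sidx[kms], use.names = FALSE))
    if (!length(cand)) next
    # rank candidates by shared seed count, examine the top few
    if (length(cand) > 8L) {
      cnt <- table(unlist(sidx[kms], use.names = FALSE))
      cand <- as.integer(names(sort(cnt, decreasing = TRUE)))[1:8]
    }
    best <- NULL
    for (ti in cand) {
      stt <- .aaPairStats(s, sseq[ti])
      if (is.null(best) || stt$score > best$score) {
        best <- stt
        best$target <- names(subject)[ti]
      }
    }
    rows[[qi]] <- data.frame(
      query = names(query)[qi], target = best$target,
      score = best$score, evalue = .kaEvalue(best$score, n, m),
      identity = best$identity, coverage = best$coverage,
      aln_len = best$aln_len)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
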