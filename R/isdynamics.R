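#' Inventory IS copies in an assembly
#'
#' Each library IS is placed on the assembly (both strands) with the seeded
#' ungapped aligner; copies are counted when identity is at least
#' `min_similarity` percent over at least `min_coverage` percent of the IS
#' length; overlapping placements of one family are merged.
#'
#' @param genome an [AnnotatedGenome] (or named [Biostrings::DNAStringSet]).
#' @param is_library named [Biostrings::DNAStringSet] of IS reference
#'   sequences.
#' @param min_similarity percent identity threshold (default 90).
#' @param min_coverage percent of IS length that must align (default 100).
#' @return data.frame: `is_family`, `contig`, `start`, `end`, `strand`,
#'   `identity` (percent), `coverage` (percent); zero rows when none.
#' @export
scanISCopies <- function(genome, is_library, min_similarity = 90,
                         min_coverage = 100) {
  if (!length(is_library)) stop("empty IS library")
  seqs <- if (is(genome, "AnnotatedGenome")) genome@seqs else genome
  out <- list()
  for (fam in names(is_library)) {
    isseq <- as.character(is_library[[fam]])
    Lis <- nchar(isseq)
    k <- 12L
    offs <- unique(pmax(1L, as.integer(seq(1L, Lis - k + 1L, by = 25L))))
    for (sname in c("+", "-")) {
      sub <- if (sname == "+") seqs else reverseComplement(seqs)
      starts_by_ctg <- list()
      for (off in offs) {
        seed <- substr(isseq, off, off + k - 1L)
        hits <- vmatchPattern(seed, sub)
        for (ci in seq_along(hits)) {
          st <- start(hits[[ci]]) - off + 1L
          if (length(st))
            starts_by_ctg[[names(sub)[ci]]] <-
              c(starts_by_ctg[[names(sub)[ci]]], st)
        }
      }
      for (ctg in names(starts_by_ctg)) {
        cseq <- sub[[ctg]]
        clen <- length(cseq)
        cand <- sort(unique(starts_by_ctg[[ctg]]))
        # collapse near-identical candidate starts (seed noise) later via
        # identity; evaluate each candidate placement
        for (a in cand) {
          lo <- max(1L, a); hi <- min(clen, a + Lis - 1L)
          alen <- hi - lo + 1L
          covp <- 100 * alen / Lis
          if (covp < min_coverage) next
          fsub <- subseq(DNAString(isseq), lo - a + 1L, lo - a + alen)
          mm <- neditStartingAt(fsub, cseq, starting.at = lo)
          idp <- 100 * (alen - mm) / alen
          if (idp < min_similarity) next
          s_fwd <- if (sname == "+") lo else clen - hi + 1L
          e_fwd <- if (sname == "+") hi else clen - lo + 1L
          out[[length(out) + 1L]] <- data.frame(
            is_family = fam, contig = ctg, start = s_fwd, end = e_fwd,
            strand = sname, identity = idp, coverage = covp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(is_family = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, out))
  # merge overlapping placements of one family (keep the best identity)
  df <- df[order(df$is_family, df$contig, df$start, -df$identity), ]
  keep <- rep(TRUE, nrow(df))
  last_end <- -1L; last_key <- ""
  for (i in seq_len(nrow(df))) {
    key <- paste(df$is_family[i], df$contig[i])
    if (key == last_key && df$start[i] <= last_end) { keep[i] <- FALSE; next }
    last_key <- key; last_end <- df$end[i]
  }
  df <- df[keep, ]
  rownames(df) <- NULL
  df
}

# parse simple cigars of the simulator's convention
.parseCigar <- function(cig) {
  ops <- regmatches(cig, gregexpr("[0-9]+[MIDSH]", cig))[[1]]
  data.frame(len = as.integer(sub("[MIDSH]", "", ops)),
             op = sub("[0-9]+", "", ops), stringsAsFactors = FALSE)
}

# identity of a clipped tail against an IS terminus (both orientations)
.clipMatchesIS <- function(clip, isseq, side, min_id = 0.9) {
  n <- nchar(clip)
  Lis <- length(isseq)
  if (n < 10L || n > Lis) return(FALSE)
  cand <- if (side == "start") {
    c(as.character(subseq(isseq, 1L, n)),
      as.character(subseq(reverseComplement(isseq), 1L, n)))
  } else {
    c(as.character(subseq(isseq, Lis - n + 1L, Lis)),
      as.character(subseq(reverseComplement(isseq), Lis - n + 1L, Lis)))
  }
  for (s in cand) {
    mm <- sum(strsplit(clip, "")[[1]] != strsplit(s, "")[[1]])
    if (1 - mm / n >= min_id) return(TRUE)
  }
  FALSE
}

#' Call new IS transposition events from clipped reads
#'
#' Soft-clipped reads whose clipped tails match an IS terminus are clustered
#' by junction coordinate; a left-junction cluster (reference then IS start)
#' and a right-junction cluster (IS end then reference) of the same family
#' within a direct-repeat-sized window are paired into one event. The
#' reported position is the last reference base before the target-site
#' duplication; the DR length is the junction offset.
#'
#' @param genome reference [AnnotatedGenome].
#' @param reads SAM-convention data.frame (qname/flag/rname/pos/mapq/cigar/
#'   seq), e.g. from [simulateReseq()] or [readSamRecords()].
#' @param is_library named [Biostrings::DNAStringSet] of IS sequences.
#' @param min_support minimum junction reads on each side (default 5).
#' @param window maximum junction offset = maximum target-site DR (bp).
#' @return data.frame of events: `is_family`, `contig`, `pos`, `dr_len`,
#'   `target_gene`, `support_left`, `support_right`, `allele_fraction`.
#' @export
detectInsertions <- function(genome, reads, is_library, min_support = 5L,
                             window = 15L) {
  if (nrow(reads) && !all(reads$rname %in% names(genome@seqs)))
    stop("reads aligned to contigs absent from the reference")
  empty <- data.frame(is_family = character(), contig = character(),
                      pos = integer(), dr_len = integer(),
                      target_gene = character(), support_left = integer(),
                      support_right = integer(), allele_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  junc <- list()
  for (i in seq_len(nrow(reads))) {
    cg <- .parseCigar(reads$cigar[i])
    if (nrow(cg) != 2L || !"S" %in% cg$op) next
    if (cg$op[1] == "M" && cg$op[2] == "S") {
      jpos <- reads$pos[i] + cg$len[1] - 1L
      clip <- substring(reads$seq[i], cg$len[1] + 1L)
      side <- "L"   # reference ends, IS begins -> clip matches IS start
      isside <- "start"
    } else if (cg$op[1] == "S" && cg$op[2] == "M") {
      jpos <- reads$pos[i]
      clip <- substring(reads$seq[i], 1L, cg$len[1])
      side <- "R"
      isside <- "end"
    } else next
    fam_hit <- NA_character_
    for (fam in names(is_library)) {
      if (.clipMatchesIS(clip, is_library[[fam]], isside)) { fam_hit <- fam; break }
    }
    if (is.na(fam_hit)) next
    junc[[length(junc) + 1L]] <- data.frame(
      side = side, fam = fam_hit, contig = reads$rname[i], pos = jpos,
      stringsAsFactors = FALSE)
  }
  if (!length(junc)) return(empty)
  jd <- do.call(rbind, junc)
  # cluster identical/adjacent positions per (side, family, contig)
  clust <- function(sub) {
    sub <- sub[order(sub$pos), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$pos) > 1L))
    do.call(rbind, lapply(split(sub, grp), function(x)
      data.frame(fam = x$fam[1], contig = x$contig[1],
                 pos = as.integer(round(median(x$pos))), n = nrow(x),
                 stringsAsFactors = FALSE)))
  }
  lefts <- jd[jd$side == "L", ]; rights <- jd[jd$side == "R", ]
  events <- list()
  if (nrow(lefts) && nrow(rights)) {
    lc <- clust(lefts); rc <- clust(rights)
    for (li in seq_len(nrow(lc))) for (ri in seq_len(nrow(rc))) {
      if (lc$fam[li] != rc$fam[ri] || lc$contig[li] != rc$contig[ri]) next
      dr <- lc$pos[li] - rc$pos[ri] + 1L
      if (dr < 0L || dr > window) next
      if (lc$n[li] < min_support || rc$n[ri] < min_support) next
      pos <- rc$pos[ri] - 1L
      g <- genome@genes[as.character(seqnames(genome@genes)) == lc$contig[li]]
      tg <- g[start(g) <= pos + 1L & end(g) >= pos]
      # wild-type support: fully aligned reads spanning both junctions
      span <- 0L
      full <- reads$rname == lc$contig[li] & grepl("^[0-9]+M$", reads$cigar)
      if (any(full)) {
        rl <- nchar(reads$seq[full])
        span <- sum(reads$pos[full] < rc$pos[ri] &
                    reads$pos[full] + rl - 1L > lc$pos[li])
      }
      mut <- lc$n[li] + rc$n[ri]
      events[[length(events) + 1L]] <- data.frame(
        is_family = lc$fam[li], contig = lc$contig[li], pos = pos,
        dr_len = dr, target_gene = if (length(tg)) tg$locus_tag[1] else NA_character_,
        support_left = lc$n[li], support_right = rc$n[ri],
        allele_fraction = mut / (mut + span),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) return(empty)
  res <- do.call(rbind, events)
  rownames(res) <- NULL
  res
}

#' Track allele fractions of called events across passages
#'
#' For each passage, the mutant-junction and wild-type-spanning reads at the
#' known event location are counted; the allele fraction is
#' mutant / (mutant + wild), detection requires `min_support` mutant-junction
#' reads in total (the junctions jointly support one breakpoint), and loss is
#' called at the first passage where a previously detected event stops being
#' detected.
#'
#' @param events events called once by [detectInsertions()].
#' @param passage_reads ordered list of SAM-convention read data.frames.
#' @param genome reference [AnnotatedGenome].
#' @param is_library IS sequence library.
#' @param min_support detection threshold per junction.
#' @return data.frame with one row per event x passage: `event`, `passage`,
#'   `allele_fraction`, `detected`; attribute `loss_passage` (named integer
#'   per event, NA when never lost).
#' @export
trackAlleles <- function(events, passage_reads, genome, is_library,
                         min_support = 5L) {
  rows <- list()
  loss <- setNames(rep(NA_integer_, nrow(events)),
                   paste0(events$is_family, "@", events$pos))
  for (p in seq_along(passage_reads)) {
    calls <- detectInsertions(genome, passage_reads[[p]], is_library,
                              min_support = 1L)
    for (e in seq_len(nrow(events))) {
      ev <- events[e, ]
      m <- calls[calls$is_family == ev$is_family &
                 calls$contig == ev$contig &
                 abs(calls$pos - ev$pos) <= 2L, , drop = FALSE]
      det <- nrow(m) > 0L &&
        m$support_left[1] + m$support_right[1] >= min_support
      af <- if (nrow(m)) m$allele_fraction[1] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        event = names(loss)[e], passage = p, allele_fraction = af,
        detected = det, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  for (e in names(loss)) {
    tr <- out[out$event == e, ]
    seen <- which(tr$detected)
    if (length(seen)) {
      after <- which(!tr$detected & tr$passage > min(tr$passage[seen]))
      if (length(after)) loss[e] <- tr$passage[min(after)]
    }
  }
  attr(out, "loss_passage") <- loss
  out
}

#' Depth fold of replicons relative to the chromosome
#'
#' @param depth named list of per-contig per-base depth vectors.
#' @param replicon_contigs contig names of the replicon (e.g. the plasmid).
#' @param chromosome_contigs contig names of the chromosome; defaults to all
#'   other contigs.
#' @return fold = median replicon depth / median chromosome depth.
#' @export
repliconDepthFold <- function(depth, replicon_contigs,
                              chromosome_contigs = NULL) {
  if (is.null(chromosome_contigs))
    chromosome_contigs <- setdiff(names(depth), replicon_contigs)
  stopifnot(length(replicon_contigs) > 0, length(chromosome_contigs) > 0)
  rp <- median(unlist(depth[replicon_contigs], use.names = FALSE))
  ch <- median(unlist(depth[chromosome_contigs], use.names = FALSE))
  rp / ch
}
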