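.VIRB_SET <- paste0("virB", 1:11)

#' Motif defaults for plasmid replication-origin evidence
#'
#' DnaA-box consensus and IHF-binding consensus (IUPAC), overridable.
#' @param dnaa_box DnaA box consensus.
#' @param dnaa_max_mismatch mismatches tolerated in a DnaA box hit.
#' @param ihf IHF consensus (IUPAC codes allowed).
#' @param window bp scanned around the rep gene.
#' @return list of motif parameters.
#' @export
oriVMotifs <- function(dnaa_box = "TTATCCACA", dnaa_max_mismatch = 1L,
                       ihf = "WATCAANNNNTTR", window = 500L) {
  list(dnaa_box = dnaa_box, dnaa_max_mismatch = dnaa_max_mismatch,
       ihf = ihf, window = window)
}

#' Functional-module inventory of an element
#'
#' Label-driven detection of the canonical mobile-element modules:
#' integrases/transposases, T4SS components (virB1-virB11), relaxase and
#' coupling protein, toxin-antitoxin pairs, partition and replication genes.
#' When a genome is supplied, DnaA-box and IHF motifs are scanned within
#' `motifs$window` bp of the rep gene as oriV evidence.
#'
#' @param labels character vector of functional labels / product strings of
#'   the element's proteins (unlabelled entries count as cargo).
#' @param genome optional [AnnotatedGenome] for the oriV motif scan.
#' @param rep_locus optional locus tag of the rep gene (oriV scan anchor).
#' @param motifs motif configuration from [oriVMotifs()].
#' @return list: `integrase` (count), `transposase` (count), `virb`
#'   (character subset of virB1-11), `relaxase`, `t4cp`, `ta_pairs`,
#'   `partition`, `rep` (logicals/counts), `dnaa_hits`, `ihf_hits`,
#'   `cargo` (unmatched label count), `conjugation_complete` (>= 5 distinct
#'   virB components, configurable downstream).
#' @export
detectModules <- function(labels, genome = NULL, rep_locus = NULL,
                          motifs = oriVMotifs()) {
  lab <- tolower(labels)
  virb <- unique(regmatches(lab, regexpr("virb([1-9]|1[01])\\b", lab)))
  virb <- sub("virb", "virB", virb)
  inv <- list(
    integrase = sum(grepl("integrase|recombinase|\\bint\\b|rita", lab)),
    transposase = sum(grepl("transposase|\\btnp", lab)),
    virb = sort(intersect(paste0("virB", 1:11),
                          sub("virb", "virB", virb))),
    relaxase = any(grepl("relaxase|vird2|\\bmob[a-z_]*\\b", lab)),
    t4cp = any(grepl("t4cp|vird4|coupling", lab)),
    ta_pairs = sum(grepl("vap[bc]|maz[ef]|higa|phd|doc|toxin|antitoxin", lab)),
    partition = sum(grepl("par[abg]\\b", lab)),
    rep = any(grepl("\\brep\\b|replicase|replication initiat", lab)),
    dnaa_hits = 0L, ihf_hits = 0L,
    cargo = sum(!grepl(.SIGNATURE_RE, lab))
  )
  if (!is.null(genome) && !is.null(rep_locus) && inv$rep) {
    gi <- which(genome@genes$locus_tag == rep_locus)
    if (length(gi)) {
      ctg <- as.character(seqnames(genome@genes)[gi])
      s <- max(1L, start(genome@genes)[gi] - motifs$window)
      e <- min(length(genome@seqs[[ctg]]),
               end(genome@genes)[gi] + motifs$window)
      reg <- subseq(genome@seqs[[ctg]], s, e)
      cnt <- function(pat, mm, fixed) {
        length(matchPattern(DNAString(pat), reg, max.mismatch = mm,
                            fixed = fixed)) +
          length(matchPattern(reverseComplement(DNAString(pat)), reg,
                              max.mismatch = mm, fixed = fixed))
      }
      inv$dnaa_hits <- cnt(motifs$dnaa_box, motifs$dnaa_max_mismatch, TRUE)
      inv$ihf_hits <- cnt(motifs$ihf, 0L, FALSE)
    }
  }
  inv$conjugation_complete <- length(inv$virb) >= 5L ||
    (inv$relaxase && inv$t4cp)
  inv
}

#' Type an element from its module inventory and genomic context
#'
#' Decision rules: integrase plus a conjugation module (>= `min_virb`
#' distinct virB components, or relaxase plus coupling protein) in an
#' integrated element is an ICE; an integrase/recombinase without
#' conjugation machinery is a GI; a transposase-bounded element without
#' integrase or tRNA att is a Tn; rep on a circular (or stand-alone
#' oriV-bearing) replicon is a plasmid; anything else is a fragment.
#'
#' @param inventory from [detectModules()].
#' @param context list with logical flags `integrated`, `circular`,
#'   `att_present`.
#' @param min_virb distinct virB components accepted as a complete T4SS.
#' @return list with `type` (one of ICE/GI/Tn/plasmid/fragment) and `notes`.
#' @export
typeElement <- function(inventory, context, min_virb = 5L) {
  stopifnot(all(c("integrated", "circular", "att_present") %in% names(context)))
  if (isTRUE(context$integrated) && isTRUE(context$circular))
    stop("contradictory context flags: integrated and circular")
  conj <- length(inventory$virb) >= min_virb ||
    (isTRUE(inventory$relaxase) && isTRUE(inventory$t4cp))
  type <- if (inventory$integrase > 0L && conj && isTRUE(context$integrated)) {
    "ICE"
  } else if (isTRUE(inventory$rep) &&
             (isTRUE(context$circular) ||
              (!isTRUE(context$integrated) && inventory$dnaa_hits > 0L))) {
    "plasmid"
  } else if (inventory$integrase > 0L) {
    "GI"
  } else if (inventory$transposase > 0L && !isTRUE(context$att_present)) {
    "Tn"
  } else {
    "fragment"
  }
  notes <- sprintf("virB=%d relaxase=%s t4cp=%s int=%d tnp=%d rep=%s",
                   length(inventory$virb), inventory$relaxase,
                   inventory$t4cp, inventory$integrase,
                   inventory$transposase, inventory$rep)
  list(type = type, notes = notes)
}

#' Detect and trim a circular contig
#'
#' A contig assembled from a circular replicon carries one duplicated
#' terminus; the longest exact terminal repeat of at least `min_overlap` bp
#' is detected, the contig reported circular and returned with the duplicate
#' copy trimmed.
#'
#' @param contig [Biostrings::DNAString] (or character).
#' @param min_overlap minimum terminal overlap (bp).
#' @param max_mismatch mismatches tolerated in the overlap (default 0).
#' @return list: `topology` ("circular"/"linear"), `sequence` (trimmed for
#'   circular), `overlap` (bp, 0 for linear).
#' @export
circularizeContig <- function(contig, min_overlap = 50L, max_mismatch = 0L) {
  if (is.character(contig)) contig <- DNAString(contig)
  L <- length(contig)
  cand <- integer(0)
  for (k in seq(min(L %/% 2L, 5000L), min_overlap)) {
    pre <- subseq(contig, 1L, k)
    suf <- subseq(contig, L - k + 1L, L)
    mm <- neditStartingAt(pre, suf, starting.at = 1L)
    if (mm <= max_mismatch) { cand <- c(cand, k); if (length(cand) > 1L) break }
  }
  # nested shorter overlaps are implied by a longer one only when periodic;
  # a second independent candidate is ambiguous
  if (length(cand) > 1L)
    stop("ambiguous circularization: multiple terminal overlap candidates")
  if (!length(cand))
    return(list(topology = "linear", sequence = contig, overlap = 0L))
  k <- cand[1L]
  list(topology = "circular", sequence = subseq(contig, 1L, L - k),
       overlap = k)
}

#' In-silico restriction digestion
#'
#' @param sequence [Biostrings::DNAString] or character.
#' @param topology "circular" or "linear".
#' @param site recognition site (IUPAC allowed), e.g. "GGATCC" for BamHI.
#' @param cut_offset cut position within the site (bases after the site
#'   start on the top strand; default 1, the G^GATCC convention).
#' @return sorted integer vector of fragment lengths; a circular sequence
#'   with no site yields one full-length (uncut) fragment.
#' @export
digestFragments <- function(sequence, topology = c("linear", "circular"),
                            site = "GGATCC", cut_offset = 1L) {
  topology <- match.arg(topology)
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site))
    stop("invalid IUPAC recognition site: ", site)
  L <- length(sequence)
  scan_seq <- if (topology == "circular")
    Biostrings::xscat(sequence, subseq(sequence, 1L, min(L, nchar(site))))
  else sequence
  hits <- start(matchPattern(DNAString(site), scan_seq, fixed = FALSE))
  hits <- hits[hits <= L]                     # one representative per site
  # cut falls after base (start + cut_offset - 1) on the top strand
  cuts <- hits + cut_offset - 1L
  if (topology == "linear") {
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < L]))
    frags <- diff(c(0L, cuts, L))
  } else {
    cuts <- sort(unique(((cuts - 1L) %% L) + 1L))
    if (!length(cuts)) return(L)
    frags <- diff(c(cuts, cuts[1L] + L))
  }
  sort(as.integer(frags[frags > 0L]))
}
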