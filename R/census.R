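#' Build a SeedElement from a planted truth record
#'
#' Convenience for tests and pipelines on forged complexes: collect a planted
#' element's proteins from its source strain and wrap them as a census seed.
#'
#' @param complex a [SpeciesComplex].
#' @param element_id planted element id.
#' @param strain source strain (defaults to the first strain carrying it).
#' @return a [SeedElement].
#' @export
seedFromTruth <- function(complex, element_id, strain = NULL) {
  tr <- complex@truth[complex@truth$element_id == element_id, ]
  if (!nrow(tr)) stop("no truth record for element ", element_id)
  if (is.null(strain)) strain <- tr$strain[1L]
  tr <- tr[tr$strain == strain, ]
  lt <- unlist(strsplit(tr$genes, ",", fixed = TRUE))
  g <- complex@genomes[[strain]]
  lt <- lt[lt %in% names(g@proteins)]
  seedElement(element_id, strain, g@proteins[lt],
              type = tr$kind[1L], integration_site = tr$integration_site[1L])
}

# six-frame translation of an assembly into stop-delimited peptides >= 30 aa,
# used as a fallback proteome when a genome has no protein annotations
.sixFrameProteome <- function(seqs, min_len = 30L) {
  pep <- character(0)
  for (ci in seq_along(seqs)) {
    for (str in c("+", "-")) {
      s <- if (str == "+") seqs[[ci]] else reverseComplement(seqs[[ci]])
      for (f in 0:2) {
        sub <- subseq(s, f + 1L, f + 1L + 3L * ((length(s) - f) %/% 3L) - 1L)
        aa <- as.character(suppressWarnings(translate(sub, if.fuzzy.codon = "solve")))
        parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
        off <- c(0L, cumsum(nchar(parts) + 1L))
        keep <- nchar(parts) >= min_len
        if (any(keep)) {
          nm <- sprintf("%s:%s:f%d:%d", names(seqs)[ci], str, f + 1L,
                        off[which(keep)] + 1L)
          pp <- parts[keep]
          names(pp) <- nm
          pep <- c(pep, pp)
        }
      }
    }
  }
  AAStringSet(pep)
}

#' Map seed-element proteins onto a target genome
#'
#' Protein-vs-proteome best-hit search (falling back to a six-frame
#' translation of the assembly when the target carries no protein
#' annotations), filtered at `evalue_max`; each retained hit is confirmed by
#' a reciprocal best hit against the seed's source proteome.
#'
#' @param seed a [SeedElement].
#' @param target an [AnnotatedGenome].
#' @param evalue_max retention cut-off (default 0.001).
#' @param source_proteome proteome of the seed's source strain used for the
#'   reciprocal search; defaults to the seed's own proteins.
#' @return data.frame of retained hits: `query`, `target_locus`, `evalue`,
#'   `identity`, `coverage`, `rbh_confirmed` (zero rows when nothing passes).
#' @export
seedSearch <- function(seed, target, evalue_max = 0.001,
                       source_proteome = NULL) {
  stopifnot(is(seed, "SeedElement"))
  if (!length(seed@proteins)) stop("empty seed")
  tp <- target@proteins
  if (!length(tp)) tp <- .sixFrameProteome(target@seqs)
  if (is.null(source_proteome)) source_proteome <- seed@proteins
  hits <- .proteinBestHits(seed@proteins, tp)
  empty <- data.frame(query = character(), target_locus = character(),
                      evalue = numeric(), identity = numeric(),
                      coverage = numeric(), rbh_confirmed = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(hits)) return(empty)
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  back <- .proteinBestHits(tp[unique(hits$target)], source_proteome)
  back_best <- if (is.null(back)) character(0) else
    setNames(back$target, back$query)
  confirmed <- !is.na(back_best[hits$target]) &
    back_best[hits$target] == hits$query
  confirmed[is.na(confirmed)] <- FALSE
  data.frame(query = hits$query, target_locus = hits$target,
             evalue = hits$evalue, identity = hits$identity,
             coverage = hits$coverage,
             rbh_confirmed = unname(confirmed),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Seed occurrence/coverage matrix with strain clustering
#'
#' Percent of each seed element's proteins with retained hits per strain;
#' occurrence is called present at >= `occurrence_min` percent. Strains are
#' clustered hierarchically (average linkage, Euclidean distance on the
#' coverage rows; ties broken by strain name) and the dendrogram returned in
#' Newick form.
#'
#' @param seeds list of [SeedElement]s.
#' @param genomes named list of [AnnotatedGenome]s.
#' @param evalue_max seed-search retention cut-off.
#' @param occurrence_min occurrence call threshold (percent).
#' @param require_rbh count only RBH-confirmed hits (default TRUE).
#' @return list with `coverage` (element x strain percent matrix),
#'   `occurrence` (logical matrix), `hits` (per-pair hit tables),
#'   `dendrogram` (ape phylo) and `newick` (character).
#' @export
coverageMatrix <- function(seeds, genomes, evalue_max = 0.001,
                           occurrence_min = 95, require_rbh = TRUE) {
  enames <- vapply(seeds, function(s) s@element_id, character(1))
  strains <- sort(names(genomes))
  cov <- matrix(0, length(seeds), length(strains),
                dimnames = list(enames, strains))
  hits <- list()
  for (i in seq_along(seeds)) for (s in strains) {
    h <- seedSearch(seeds[[i]], genomes[[s]], evalue_max)
    if (require_rbh) h <- h[h$rbh_confirmed, , drop = FALSE]
    hits[[paste0(enames[i], ":", s)]] <- h
    cov[i, s] <- 100 * length(unique(h$query)) / length(seeds[[i]]@proteins)
  }
  occ <- cov >= occurrence_min
  dend <- NULL; nwk <- NULL
  if (length(strains) > 2L) {
    d <- stats::dist(t(cov), method = "euclidean")
    hc <- stats::hclust(d, method = "average")
    dend <- ape::as.phylo(hc)
    nwk <- ape::write.tree(dend)
  }
  list(coverage = cov, occurrence = occ, hits = hits,
       dendrogram = dend, newick = nwk)
}
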