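.COG_VOCAB <- letters[1:21]  # functional category vocabulary a-u

#' Mobilome cargo census
#'
#' Aggregates the reconstructed candidate elements into a cargo census:
#' which protein families are MGE-associated (member of any candidate
#' element's flexible/exclusive gene set), the mobilome fraction of the
#' pangenome, and per-functional-category counts split by the occurrence
#' pattern of each family across sublineages (exclusive = single strain;
#' intra-lineage = several strains of one sublineage; inter-lineage =
#' strains of both).
#'
#' @param ft a compartmentalized [FamilyTable].
#' @param elements named list (by strain) of [CandidateElement] lists, as
#'   returned by [reconstructElements()].
#' @param genomes named list of [AnnotatedGenome]s (locus -> family lookup).
#' @param groups strain -> sublineage map.
#' @param labels named character: family -> functional category (letters
#'   a-u); missing or out-of-vocabulary labels are coerced to "unknown" with
#'   a warning.
#' @return list: `census` (data.frame per family: `family`, `mge_associated`,
#'   `compartment`, `category`, `pattern`), `mobilome_fraction`,
#'   `summary` (long-format category x pattern counts).
#' @export
cargoCensus <- function(ft, elements, genomes, groups, labels = NULL) {
  fams <- rownames(ft@occupancy)
  locus2fam <- setNames(ft@members$family, ft@members$locus)
  mge_fams <- character(0)
  for (s in names(elements)) for (cand in elements[[s]]) {
    f <- locus2fam[cand@genes]
    mge_fams <- union(mge_fams, f[!is.na(f)])
  }
  comp <- ft@compartment[fams]
  # keep only flexible/exclusive families in the mobilome per the boundary rule
  mge <- fams %in% mge_fams & comp %in% c("flexible", "exclusive", "soft-core")
  if (is.null(labels)) labels <- setNames(rep("unknown", length(fams)), fams)
  cat_lab <- unname(labels[fams])
  cat_lab[is.na(cat_lab)] <- "unknown"
  bad <- !(cat_lab %in% c(.COG_VOCAB, "unknown"))
  if (any(bad)) {
    warning(sum(bad), " labels outside the a-u vocabulary coerced to unknown")
    cat_lab[bad] <- "unknown"
  }
  present <- ft@occupancy > 0L
  strains <- colnames(present)
  pattern <- vapply(seq_along(fams), function(i) {
    st <- strains[present[i, ]]
    if (length(st) == 1L) return("exclusive")
    gs <- unique(groups[st])
    if (length(gs) == 1L) "intra-lineage" else "inter-lineage"
  }, character(1))
  census <- data.frame(family = fams, mge_associated = mge,
                       compartment = comp, category = cat_lab,
                       pattern = pattern, stringsAsFactors = FALSE)
  if (any(census$mge_associated)) {
    summary <- as.data.frame(table(
      category = census$category[census$mge_associated],
      pattern = census$pattern[census$mge_associated]),
      stringsAsFactors = FALSE)
    names(summary)[3] <- "n_families"
  } else {
    summary <- data.frame(category = character(), pattern = character(),
                          n_families = integer(), stringsAsFactors = FALSE)
  }
  list(census = census,
       mobilome_fraction = sum(mge) / length(fams),
       summary = summary)
}
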