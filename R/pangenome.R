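#' Protein-family table across a strain set
#'
#' @slot members data.frame: one row per protein with columns `protein`
#'   (strain|locus), `strain`, `locus`, `family`.
#' @slot occupancy integer matrix family x strain (member counts).
#' @slot compartment named character per family ("core", "soft-core",
#'   "flexible", "exclusive"; empty before [compartmentalize()]).
#' @slot group_exclusive named character per family ("" or sublineage name).
#' @slot identity named numeric per family (mean within-family identity,
#'   percent; NA until computed).
#' @export
setClass("FamilyTable",
  representation(
    members        = "data.frame",
    occupancy      = "matrix",
    compartment    = "character",
    group_exclusive = "character",
    identity       = "numeric"
  )
)

setMethod("show", "FamilyTable", function(object) {
  cat("FamilyTable:", nrow(object@occupancy), "families across",
      ncol(object@occupancy), "strains\n")
  if (length(object@compartment)) {
    tb <- table(object@compartment)
    cat(" ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @describeIn FamilyTable per-protein membership data.frame
#' @param x a FamilyTable.
#' @export
familyMembers <- function(x) x@members

#' @describeIn FamilyTable family-by-strain occupancy matrix
#' @export
familyOccupancy <- function(x) x@occupancy

#' @describeIn FamilyTable named compartment labels per family
#' @export
familyCompartments <- function(x) x@compartment

#' Cluster proteomes into protein families
#'
#' All-vs-all protein comparison (k-mer prefiltered, BLOSUM62-scored);
#' edges are kept at alignment coverage >= `min_cov`, e-value <=
#' `evalue_max` and identity >= `id_floor`; families are the connected
#' components of the resulting graph. Every protein belongs to exactly one
#' family (singletons included), so families partition the input proteomes.
#'
#' @param proteomes named list of [Biostrings::AAStringSet] (one per strain),
#'   or a list of [AnnotatedGenome] objects.
#' @param min_cov minimum alignment coverage of the shorter protein.
#' @param evalue_max maximum e-value for an edge.
#' @param id_floor minimum identity (fraction) for an edge.
#' @return a [FamilyTable] (compartments unassigned).
#' @export
clusterFamilies <- function(proteomes, min_cov = 0.75, evalue_max = 1e-5,
                            id_floor = 0.4) {
  if (length(proteomes) && is(proteomes[[1]], "AnnotatedGenome"))
    proteomes <- lapply(proteomes, proteins)
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  if (any(!vapply(proteomes, length, integer(1))))
    stop("empty proteome in input")
  strains <- names(proteomes)
  ids <- unlist(lapply(strains, function(s)
    paste0(s, "|", names(proteomes[[s]]))), use.names = FALSE)
  allp <- do.call(c, unname(lapply(proteomes, as.character)))
  names(allp) <- ids
  aa <- AAStringSet(allp)
  total_len <- sum(nchar(allp))

  idx <- .aaKmerIndex(aa, k = 5L, stride = 2L)
  # candidate pairs share at least one seed k-mer
  cand <- new.env(hash = TRUE)
  for (v in idx) {
    v <- unique(v)
    if (length(v) < 2L || length(v) > 50L) next
    for (i in seq_len(length(v) - 1L)) for (j in (i + 1L):length(v)) {
      key <- paste0(v[i], "_", v[j])
      if (is.null(cand[[key]])) cand[[key]] <- TRUE
    }
  }
  pair_keys <- ls(cand)
  edges <- character(0)
  for (key in pair_keys) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    s <- .aaPairStats(allp[ij[1]], allp[ij[2]])
    ev <- .kaEvalue(s$score, nchar(allp[ij[1]]), total_len)
    if (s$coverage >= min_cov && ev <= evalue_max && s$identity >= id_floor)
      edges <- c(edges, ids[ij[1]], ids[ij[2]])
  }
  gr <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (length(edges)) gr <- gr + igraph::edges(edges)
  comp <- igraph::components(gr)$membership
  # deterministic family ids ordered by first member id
  fam <- match(comp, unique(comp[order(names(comp))]))
  fam_id <- sprintf("PF%05d", fam)
  members <- data.frame(
    protein = ids,
    strain = sub("\\|.*", "", ids),
    locus = sub("^[^|]*\\|", "", ids),
    family = fam_id[match(ids, names(comp))],
    stringsAsFactors = FALSE)
  occ <- table(members$family, members$strain)
  occ <- matrix(as.integer(occ), nrow = nrow(occ),
                dimnames = dimnames(occ))
  new("FamilyTable", members = members, occupancy = occ,
      compartment = character(0), group_exclusive = character(0),
      identity = setNames(rep(NA_real_, nrow(occ)), rownames(occ)))
}

#' Assign pangenome compartments to protein families
#'
#' Core = present in every strain; exclusive = present in exactly one
#' strain; flexible = present in more than one but fewer than
#' `softcore_frac` of the strains; families at or above `softcore_frac` but
#' not universal are labelled soft-core (and counted with the flexible pool
#' in census summaries). A family is group-exclusive for sublineage G when
#' present in more than `group_majority` of G's strains and absent from all
#' non-G strains.
#'
#' @param ft a [FamilyTable].
#' @param groups named character strain -> sublineage.
#' @param softcore_frac soft-core occupancy fraction (default 0.95).
#' @param group_majority group-exclusivity occupancy fraction (default 0.90).
#' @return the [FamilyTable] with `compartment` and `group_exclusive` set.
#' @export
compartmentalize <- function(ft, groups, softcore_frac = 0.95,
                             group_majority = 0.90) {
  strains <- colnames(ft@occupancy)
  if (!all(strains %in% names(groups)))
    stop("strain missing from group map: ",
         paste(setdiff(strains, names(groups)), collapse = ","))
  n <- length(strains)
  present <- ft@occupancy > 0L
  occ <- rowSums(present)
  comp <- ifelse(occ == n, "core",
          ifelse(occ == 1L, "exclusive",
          ifelse(occ >= softcore_frac * n, "soft-core", "flexible")))
  names(comp) <- rownames(ft@occupancy)
  gx <- setNames(rep("", nrow(ft@occupancy)), rownames(ft@occupancy))
  for (g in unique(groups[strains])) {
    ing <- strains[groups[strains] == g]
    outg <- setdiff(strains, ing)
    hit <- rowSums(present[, ing, drop = FALSE]) > group_majority * length(ing) &
      (if (length(outg)) rowSums(present[, outg, drop = FALSE]) == 0L else TRUE)
    gx[hit] <- g
  }
  ft@compartment <- comp
  ft@group_exclusive <- gx
  ft
}

#' Within-family identity distributions
#'
#' Mean pairwise percent identity per family, either across the whole
#' species set or restricted to pairs within one sublineage.
#'
#' @param ft a [FamilyTable].
#' @param proteomes named list of [Biostrings::AAStringSet] (or
#'   [AnnotatedGenome]s) matching the table.
#' @param scope "species" (all member pairs) or "within-group".
#' @param groups strain -> sublineage map (required for "within-group").
#' @param group for "within-group", which sublineage.
#' @return named numeric (percent identity per family; families with fewer
#'   than two in-scope members are dropped with a message).
#' @export
familyIdentityStats <- function(ft, proteomes, scope = c("species", "within-group"),
                                groups = NULL, group = NULL) {
  scope <- match.arg(scope)
  if (length(proteomes) && is(proteomes[[1]], "AnnotatedGenome"))
    proteomes <- lapply(proteomes, proteins)
  seqs <- unlist(lapply(names(proteomes), function(s) {
    x <- as.character(proteomes[[s]])
    names(x) <- paste0(s, "|", names(proteomes[[s]]))
    x
  }))
  m <- ft@members
  if (scope == "within-group") {
    if (is.null(groups) || is.null(group))
      stop("within-group scope needs groups and group")
    m <- m[groups[m$strain] == group, ]
  }
  skipped <- 0L
  out <- c()
  for (f in unique(m$family)) {
    mem <- m$protein[m$family == f]
    if (length(mem) < 2L) { skipped <- skipped + 1L; next }
    pr <- utils::combn(mem, 2L)
    idv <- apply(pr, 2L, function(p) .aaPairStats(seqs[[p[1]]], seqs[[p[2]]])$identity)
    out[f] <- 100 * mean(idv)
  }
  if (skipped) message(skipped, " families skipped (fewer than 2 in-scope members)")
  out
}
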