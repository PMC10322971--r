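#' Default pipeline parameters
#'
#' Every stage threshold in one place; unknown keys passed to
#' [runPipeline()] are rejected.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    fragment = 1020L,             # ANIb fragment size (bp)
    ani_species = 96,             # species ANI threshold (percent)
    ddh_species = 70,             # species dDDH threshold (percent)
    sublineage_gap = 0.5,         # ANI separation for a sublineage split
    deltas = 2:10,                # synteny gap tolerances
    family_min_cov = 0.75,        # pangenome edge coverage
    family_evalue = 1e-5,         # pangenome edge e-value
    family_id_floor = 0.4,        # pangenome edge identity floor
    census_evalue = 0.001,        # seed-search retention e-value
    cluster_evalue = 1e-10,       # stricter e-value for clustering display
    occurrence_min = 95,          # occurrence call (percent coverage)
    window = 10L,                 # seed-clustering window (genes)
    core_run_stop = 2L,           # consecutive core genes ending extension
    min_dr = 12L,                 # att direct-repeat minimum (bp)
    att_max_mismatch = 1L,
    att_window = 1000L,
    min_virb = 5L,                # distinct virB components for conjugation
    run_relatedness = TRUE,
    run_ddh = TRUE,
    run_synteny = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the integrated comparative-genomics pipeline on a species complex
#'
#' Stages run in dependency order: relatedness (+ delimitation) and synteny;
#' pangenome clustering and compartments; seed census; boundary
#' reconstruction with att-site recovery; element typing; mobilome cargo
#' census. Reports are written as TSV/JSON under `outdir` when given, and
#' the full result bundle is returned.
#'
#' @param complex a [SpeciesComplex] (or named list of [AnnotatedGenome]s
#'   plus an explicit `groups` map).
#' @param seeds list of [SeedElement]s used for the census (defaults to
#'   seeds derived from the complex's truth records, one per planted
#'   integrated element).
#' @param outdir optional output directory.
#' @param params from [pipelineConfig()].
#' @param groups optional strain -> sublineage map (defaults to the
#'   complex's own).
#' @param labels optional family -> functional-category labels for the cargo
#'   census.
#' @return list with components `relatedness`, `delimitation`, `synteny`,
#'   `families`, `census`, `elements`, `mobilome`, `params`.
#' @export
runPipeline <- function(complex, seeds = NULL, outdir = NULL,
                        params = pipelineConfig(), groups = NULL,
                        labels = NULL) {
  if (is(complex, "SpeciesComplex")) {
    genomes <- complex@genomes
    if (is.null(groups)) groups <- complex@groups
    if (is.null(seeds)) {
      ids <- unique(complex@truth$element_id[complex@truth$kind != "plasmid"])
      seeds <- lapply(ids, function(i) seedFromTruth(complex, i))
    }
  } else {
    genomes <- complex
    if (is.null(groups)) stop("groups map required for a plain genome list")
    if (is.null(seeds)) stop("seeds required for a plain genome list")
  }
  if (!length(genomes)) stop("no input genomes")

  rel <- NULL; delim <- NULL
  if (params$run_relatedness) {
    rel <- relatednessMatrix(genomes, fragment = params$fragment,
                             ddh = params$run_ddh)
    delim <- delimitGroups(rel$ani, rel$ddh,
                           delimitationThresholds(params$ani_species,
                                                  params$ddh_species,
                                                  params$sublineage_gap))
  }
  syn <- NULL
  if (params$run_synteny) {
    strains <- sort(names(genomes))
    syn <- list()
    for (i in seq_along(strains)) for (j in seq_along(strains)) {
      if (i >= j) next
      key <- paste0(strains[i], ":", strains[j])
      syn[[key]] <- syntenyCoverage(genomes[[strains[i]]],
                                    genomes[[strains[j]]],
                                    deltas = params$deltas)
    }
  }

  ft <- clusterFamilies(genomes, min_cov = params$family_min_cov,
                        evalue_max = params$family_evalue,
                        id_floor = params$family_id_floor)
  ft <- compartmentalize(ft, groups)

  cm <- coverageMatrix(seeds, genomes, evalue_max = params$census_evalue,
                       occurrence_min = params$occurrence_min)

  elements <- list()
  for (s in names(genomes)) {
    ev <- contextualProfile(genomes[[s]], ft)
    hits <- lapply(seeds, function(sd) cm$hits[[paste0(sd@element_id, ":", s)]])
    names(hits) <- vapply(seeds, function(sd) sd@element_id, character(1))
    seed_sizes <- setNames(vapply(seeds, function(sd) length(sd@proteins),
                                  integer(1)), names(hits))
    cands <- reconstructElements(genomes[[s]], hits, ev,
                                 window = params$window,
                                 core_run_stop = params$core_run_stop,
                                 seed_sizes = seed_sizes)
    cands <- lapply(cands, function(cd) {
      att <- suppressMessages(
        findAttSites(cd, genomes[[s]], min_dr = params$min_dr,
                     max_mismatch = params$att_max_mismatch,
                     search_window = params$att_window))
      if (!is.null(att)) cd@att <- att
      g <- genomes[[s]]@genes
      lab <- g$label[match(cd@genes, g$locus_tag)]
      cd@inventory <- detectModules(lab)
      ty <- typeElement(cd@inventory,
                        list(integrated = TRUE, circular = FALSE,
                             att_present = length(cd@att) > 0L),
                        min_virb = params$min_virb)
      cd@type <- ty$type
      cd
    })
    elements[[s]] <- cands
  }

  mob <- cargoCensus(ft, elements, genomes, groups, labels = labels)

  res <- list(relatedness = rel, delimitation = delim, synteny = syn,
              families = ft, census = cm, elements = elements,
              mobilome = mob, params = params)
  if (!is.null(outdir)) .writeReports(res, genomes, outdir)
  res
}

.writeReports <- function(res, genomes, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$relatedness))
    utils::write.table(res$relatedness$ani, file.path(outdir, "ani_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(res$relatedness) && !is.null(res$relatedness$ddh))
    utils::write.table(res$relatedness$ddh, file.path(outdir, "ddh_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(res$families@members, file.path(outdir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$census$coverage, file.path(outdir, "coverage_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(res$census$newick))
    writeLines(res$census$newick, file.path(outdir, "strain_dendrogram.nwk"))
  el <- list()
  for (s in names(res$elements)) for (cd in res$elements[[s]]) {
    seg <- cd@segments
    el[[length(el) + 1L]] <- data.frame(
      element = cd@element_id, strain = s, type = cd@type,
      contig = as.character(seqnames(seg)),
      start = start(seg), end = end(seg),
      n_genes = length(cd@genes),
      seeds = paste(cd@seeds, collapse = ","),
      dr = if (length(cd@att)) cd@att$dr_length else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(el))
    utils::write.table(do.call(rbind, el), file.path(outdir, "elements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_strains = length(genomes),
    species = if (!is.null(res$delimitation))
      as.list(res$delimitation$species) else NULL,
    sublineage = if (!is.null(res$delimitation))
      as.list(res$delimitation$sublineage) else NULL,
    n_families = nrow(res$families@occupancy),
    compartments = as.list(table(res$families@compartment)),
    mobilome_fraction = res$mobilome$mobilome_fraction,
    n_elements = sum(lengths(res$elements)),
    params = res$params)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
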