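#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' AnnotatedGenome: assembly plus gene models, proteins and optional depth
#'
#' The universal input bundle of the package: one strain's assembly
#' (possibly multi-contig), its gene models, protein translations and an
#' optional per-base read-depth track.
#'
#' @slot strain single strain identifier.
#' @slot seqs [Biostrings::DNAStringSet] of contigs (named).
#' @slot genes [GenomicRanges::GRanges] of gene models. Metadata columns:
#'   `locus_tag`, `type` ("CDS" or "tRNA"), `family` (protein-family id or
#'   NA), `product` (annotation product string), `label` (functional label
#'   used by module detection, e.g. "integrase", "virB4", "rep", "cargo").
#' @slot proteins [Biostrings::AAStringSet] named by `locus_tag` (CDS only).
#' @slot depth list of per-contig numeric per-base depth vectors (may be
#'   empty when no resequencing evidence is attached).
#' @slot circular named logical, one per contig; `TRUE` marks a circular
#'   replicon (plasmid).
#'
#' @export
setClass("AnnotatedGenome",
  representation(
    strain   = "character",
    seqs     = "DNAStringSet",
    genes    = "GRanges",
    proteins = "AAStringSet",
    depth    = "list",
    circular = "logical"
  )
)

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  ctg <- names(object@seqs)
  if (is.null(ctg) || anyDuplicated(ctg))
    msg <- c(msg, "contigs must be uniquely named")
  if (length(object@genes)) {
    gseq <- as.character(GenomicRanges::seqnames(object@genes))
    if (!all(gseq %in% ctg))
      msg <- c(msg, "gene models reference unknown contigs")
    lens <- BiocGenerics::width(object@seqs)[match(gseq, ctg)]
    if (any(GenomicRanges::end(object@genes) > lens) ||
        any(GenomicRanges::start(object@genes) < 1L))
      msg <- c(msg, "gene models exceed contig bounds")
    lt <- object@genes$locus_tag
    if (anyDuplicated(lt))
      msg <- c(msg, "locus tags must be unique")
    cds <- lt[object@genes$type == "CDS"]
    if (length(object@proteins) && !all(names(object@proteins) %in% cds))
      msg <- c(msg, "protein names must be CDS locus tags")
  }
  if (length(object@circular) &&
      !identical(sort(names(object@circular)), sort(ctg)))
    msg <- c(msg, "circular flags must cover every contig")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param strain strain identifier.
#' @param seqs named [Biostrings::DNAStringSet] of contigs.
#' @param genes [GenomicRanges::GRanges] of gene models (see class slots).
#' @param proteins [Biostrings::AAStringSet] named by locus tag.
#' @param depth optional list of per-contig per-base depth vectors.
#' @param circular optional named logical marking circular replicons;
#'   defaults to all-linear.
#' @return an `AnnotatedGenome` object.
#' @export
AnnotatedGenome <- function(strain, seqs, genes, proteins = Biostrings::AAStringSet(),
                            depth = list(), circular = NULL) {
  if (is.null(circular)) {
    circular <- rep(FALSE, length(seqs))
    names(circular) <- names(seqs)
  }
  new("AnnotatedGenome", strain = strain, seqs = seqs, genes = genes,
      proteins = proteins, depth = depth, circular = circular)
}

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", object@strain, "\n")
  cat(" ", length(object@seqs), "contig(s),",
      sum(BiocGenerics::width(object@seqs)), "bp",
      if (any(object@circular)) sprintf("(%d circular)", sum(object@circular)) else "",
      "\n")
  cat(" ", sum(object@genes$type == "CDS"), "CDS,",
      sum(object@genes$type == "tRNA"), "tRNA;",
      length(object@proteins), "proteins\n")
  if (length(object@depth)) cat("  depth track attached\n")
  invisible(NULL)
})

#' @describeIn AnnotatedGenome strain identifier accessor
#' @param x an AnnotatedGenome.
#' @export
strainName <- function(x) x@strain

#' @describeIn AnnotatedGenome contig sequences accessor
#' @export
contigs <- function(x) x@seqs

#' @describeIn AnnotatedGenome gene model accessor
#' @export
geneModels <- function(x) x@genes

#' @describeIn AnnotatedGenome protein accessor
#' @export
proteins <- function(x) x@proteins

#' @describeIn AnnotatedGenome per-contig depth track accessor
#' @export
depthTrack <- function(x) x@depth

#' @describeIn AnnotatedGenome named logical of circular replicon flags
#' @export
circularReplicons <- function(x) x@circular

#' Configuration of a forged two-sublineage species complex
#'
#' @slot n_strains_per_group strains per sublineage.
#' @slot ancestral_length chromosome length (bp).
#' @slot gene_length_mean mean CDS length (bp).
#' @slot within_group_divergence expected pairwise substitutions/site within
#'   a sublineage.
#' @slot between_group_divergence expected pairwise substitutions/site
#'   between sublineages.
#' @slot gc_background backbone GC fraction.
#' @slot rng_seed integer master seed.
#' @export
setClass("ComplexConfig",
  representation(
    n_strains_per_group      = "integer",
    ancestral_length         = "integer",
    gene_length_mean         = "integer",
    within_group_divergence  = "numeric",
    between_group_divergence = "numeric",
    gc_background            = "numeric",
    rng_seed                 = "integer"
  )
)

setValidity("ComplexConfig", function(object) {
  msg <- character()
  w <- object@within_group_divergence
  b <- object@between_group_divergence
  if (w < 0 || w > 0.2 || b < 0 || b > 0.2)
    msg <- c(msg, "divergences must lie in [0, 0.2]")
  if (w > b)
    msg <- c(msg, "within_group_divergence must not exceed between_group_divergence")
  if (object@gc_background <= 0.3 || object@gc_background >= 0.7)
    msg <- c(msg, "gc_background must lie in (0.3, 0.7)")
  if (object@n_strains_per_group < 1L)
    msg <- c(msg, "need at least one strain per group")
  if (length(msg)) msg else TRUE
})

#' Build a ComplexConfig
#'
#' Divergences are expected *pairwise* substitution densities: two strains of
#' the same sublineage differ at ~`within_group_divergence` of sites, strains
#' of different sublineages at ~`between_group_divergence`.
#'
#' @param n_strains_per_group strains per sublineage (default 4).
#' @param ancestral_length chromosome length in bp (default 50000).
#' @param gene_length_mean mean CDS length in bp (default 900).
#' @param within_group_divergence within-sublineage pairwise divergence
#'   (default 0.005).
#' @param between_group_divergence between-sublineage pairwise divergence
#'   (default 0.03).
#' @param gc_background backbone GC fraction (default 0.55).
#' @param rng_seed integer master seed.
#' @return a validated `ComplexConfig`.
#' @export
complexConfig <- function(n_strains_per_group = 4L, ancestral_length = 50000L,
                          gene_length_mean = 900L,
                          within_group_divergence = 0.005,
                          between_group_divergence = 0.03,
                          gc_background = 0.55, rng_seed = 1L) {
  if (within_group_divergence > between_group_divergence)
    stop("invalid divergence ordering: within must not exceed between")
  new("ComplexConfig",
      n_strains_per_group = as.integer(n_strains_per_group),
      ancestral_length = as.integer(ancestral_length),
      gene_length_mean = as.integer(gene_length_mean),
      within_group_divergence = within_group_divergence,
      between_group_divergence = between_group_divergence,
      gc_background = gc_background,
      rng_seed = as.integer(rng_seed))
}

#' Specification of a mobile element to plant
#'
#' @slot element_id unique element identifier (shared across strains where
#'   the same element is planted, so cargo families cluster across strains).
#' @slot kind one of "ICE", "GI", "Tn", "plasmid", "IS".
#' @slot length approximate element length (bp).
#' @slot n_genes number of cargo genes.
#' @slot cargo_gc_offset signed GC offset of cargo relative to the genome
#'   background.
#' @slot integration_site locus tag or tRNA name (ignored for plasmids).
#' @slot dr_length target-site direct-repeat length (bp, >= 0).
#' @slot module_genes functional labels assigned in order to the first cargo
#'   genes (e.g. "integrase", "virB4", "relaxase", "parA", "rep").
#' @export
setClass("ElementSpec",
  representation(
    element_id      = "character",
    kind            = "character",
    length          = "integer",
    n_genes         = "integer",
    cargo_gc_offset = "numeric",
    integration_site = "character",
    dr_length       = "integer",
    module_genes    = "character"
  )
)

setValidity("ElementSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("ICE", "GI", "Tn", "plasmid", "IS"))
    msg <- c(msg, "kind must be ICE, GI, Tn, plasmid or IS")
  if (object@dr_length < 0L) msg <- c(msg, "dr_length must be >= 0")
  lab <- tolower(object@module_genes)
  if (object@kind == "ICE" &&
      !(any(grepl("integrase", lab)) && any(grepl("^virb", lab))))
    msg <- c(msg, "ICE specs must include an integrase and at least one virB label")
  if (object@kind == "plasmid" && !any(grepl("\\brep\\b|replicase", lab)))
    msg <- c(msg, "plasmid specs must include a rep label")
  # element length must roughly accommodate n_genes of typical size plus spacers
  if (object@n_genes > 0L) {
    per_gene <- object@length / object@n_genes
    if (per_gene < 150 || per_gene > 6000)
      msg <- c(msg, "length inconsistent with n_genes (needs 150-6000 bp per gene)")
  }
  if (length(msg)) msg else TRUE
})

#' Build an ElementSpec
#'
#' @param element_id element identifier.
#' @param kind element kind: "ICE", "GI", "Tn", "plasmid" or "IS".
#' @param n_genes number of cargo genes.
#' @param length total element length in bp (default `n_genes * 1000`).
#' @param cargo_gc_offset signed GC offset of cargo vs background (default 0.04).
#' @param integration_site target locus tag or tRNA name ("" for plasmids).
#' @param dr_length direct repeat length in bp.
#' @param module_genes functional labels for the leading cargo genes.
#' @return a validated `ElementSpec`.
#' @export
elementSpec <- function(element_id, kind, n_genes, length = n_genes * 1000L,
                        cargo_gc_offset = 0.04, integration_site = "",
                        dr_length = 0L, module_genes = character()) {
  new("ElementSpec", element_id = element_id, kind = kind,
      length = as.integer(length), n_genes = as.integer(n_genes),
      cargo_gc_offset = cargo_gc_offset, integration_site = integration_site,
      dr_length = as.integer(dr_length), module_genes = module_genes)
}

#' A forged species complex with ground truth
#'
#' @slot genomes named list of [AnnotatedGenome] objects.
#' @slot groups named character: strain -> sublineage ("A"/"B").
#' @slot truth data.frame of planted-element truth records (one row per
#'   element segment; see [emptyTruth()] for columns).
#' @slot ancestral the ancestral chromosome (DNAStringSet) for oracle use.
#' @slot mutlog named list of per-strain substitution logs
#'   (data.frame pos/from/to applied to the ancestral sequence, in order).
#' @slot config the [ComplexConfig] used.
#' @export
setClass("SpeciesComplex",
  representation(
    genomes   = "list",
    groups    = "character",
    truth     = "data.frame",
    ancestral = "DNAStringSet",
    mutlog    = "list",
    config    = "ComplexConfig"
  )
)

setMethod("show", "SpeciesComplex", function(object) {
  cat("SpeciesComplex:", length(object@genomes), "strains in",
      length(unique(object@groups)), "sublineage(s)\n")
  cat("  strains:", paste(names(object@genomes), collapse = " "), "\n")
  cat("  planted elements:", length(unique(object@truth$element_id)), "\n")
  invisible(NULL)
})

#' @describeIn SpeciesComplex list of member genomes
#' @param x a SpeciesComplex.
#' @export
complexGenomes <- function(x) x@genomes

#' @describeIn SpeciesComplex strain-to-sublineage map
#' @export
complexGroups <- function(x) x@groups

#' @describeIn SpeciesComplex planted-element truth table
#' @export
complexTruth <- function(x) x@truth

#' A seed mobile element used as census query
#'
#' @slot element_id identifier (e.g. "iMGE1").
#' @slot source_strain strain the seed was defined in.
#' @slot proteins ordered [Biostrings::AAStringSet] of the element's proteins.
#' @slot type declared type ("ICE", "GI", "Tn", ...).
#' @slot integration_site integration-site label.
#' @export
setClass("SeedElement",
  representation(
    element_id      = "character",
    source_strain   = "character",
    proteins        = "AAStringSet",
    type            = "character",
    integration_site = "character"
  )
)

setValidity("SeedElement", function(object) {
  if (length(object@proteins) < 1L) "seed must contain at least one protein"
  else TRUE
})

#' Build a SeedElement
#' @param element_id identifier.
#' @param source_strain source strain name.
#' @param proteins ordered AAStringSet of member proteins.
#' @param type declared element type.
#' @param integration_site integration-site label.
#' @export
seedElement <- function(element_id, source_strain, proteins,
                        type = "GI", integration_site = "") {
  new("SeedElement", element_id = element_id, source_strain = source_strain,
      proteins = proteins, type = type, integration_site = integration_site)
}

setMethod("show", "SeedElement", function(object) {
  cat("SeedElement", object@element_id, "from", object@source_strain,
      sprintf("(%s, %d proteins)\n", object@type, length(object@proteins)))
  invisible(NULL)
})

#' A reconstructed candidate mobile element
#'
#' @slot element_id candidate identifier.
#' @slot strain strain the candidate lives in.
#' @slot segments [GenomicRanges::GRanges] of the ordered genomic segments
#'   (one per contig piece).
#' @slot genes member gene locus tags (flexible/exclusive compartment only).
#' @slot seeds seed element ids matched inside the candidate.
#' @slot support numeric evidence-support score.
#' @slot att att-site quartet as returned by [findAttSites()], or empty list.
#' @slot inventory functional-module inventory (see [detectModules()]), or
#'   empty list before classification.
#' @slot type assigned element type ("ICE","GI","Tn","plasmid","fragment" or
#'   "" before typing).
#' @slot notes free-text confidence notes.
#' @export
setClass("CandidateElement",
  representation(
    element_id = "character",
    strain     = "character",
    segments   = "GRanges",
    genes      = "character",
    seeds      = "character",
    support    = "numeric",
    att        = "list",
    inventory  = "list",
    type       = "character",
    notes      = "character"
  )
)

setMethod("show", "CandidateElement", function(object) {
  cat("CandidateElement", object@element_id, "in", object@strain, "\n")
  cat(sprintf("  %d segment(s), %d genes, seeds: %s\n",
              length(object@segments), length(object@genes),
              if (length(object@seeds)) paste(object@seeds, collapse = ",") else "-"))
  if (nzchar(object@type)) cat("  type:", object@type, "\n")
  invisible(NULL)
})

#' @describeIn CandidateElement genomic segments of the candidate
#' @param x a CandidateElement.
#' @export
elementSegments <- function(x) x@segments

#' @describeIn CandidateElement member gene locus tags
#' @export
elementGenes <- function(x) x@genes

#' @describeIn CandidateElement assigned type
#' @export
elementType <- function(x) x@type
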