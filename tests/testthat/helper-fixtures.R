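# Shared fixtures, built once per test session and memoised.

.fx <- new.env(parent = emptyenv())

rand_dna <- function(n, gc = 0.5, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# canonical element specs used across tests; identical (spec, seed) planted
# in several strains yields identical cargo
fx_ice_spec <- function()
  elementSpec("EL1", "ICE", 8, cargo_gc_offset = 0.05,
              integration_site = "tRNA-Ala-GGC", dr_length = 48L,
              module_genes = c("integrase", "virB4", "virB5", "virB6",
                               "virB9", "virB11", "relaxase MOBP",
                               "t4cp coupling protein"))

fx_gi_spec <- function()
  elementSpec("EL2", "GI", 5, cargo_gc_offset = -0.04,
              integration_site = "tRNA-Arg-TCT", dr_length = 17L,
              module_genes = c("integrase"))

fx_plasmid_spec <- function()
  elementSpec("EL3", "plasmid", 6, length = 9000L,
              module_genes = c("rep replicase", "parA"))

# 2+2 strain complex, 30 kb, ICE in A1/A2, GI in A1, plasmid in A1/A2
fx_complex <- function() {
  if (is.null(.fx$cx)) {
    cx <- forgeComplex(complexConfig(n_strains_per_group = 2,
                                     ancestral_length = 30000,
                                     rng_seed = 11))
    cx <- plantElements(cx, fx_ice_spec(), c("A1", "A2"), seed = 101)
    cx <- plantElements(cx, fx_gi_spec(), "A1", seed = 102)
    cx <- plantElements(cx, fx_plasmid_spec(), c("A1", "A2"), seed = 103)
    .fx$cx <- cx
  }
  .fx$cx
}

# the same complex before any planting (pre-insertion oracle)
fx_preplant <- function() {
  if (is.null(.fx$pre))
    .fx$pre <- forgeComplex(complexConfig(n_strains_per_group = 2,
                                          ancestral_length = 30000,
                                          rng_seed = 11))
  .fx$pre
}

fx_pipeline <- function() {
  if (is.null(.fx$pipe))
    .fx$pipe <- runPipeline(fx_complex(),
                            params = pipelineConfig(run_synteny = FALSE))
  .fx$pipe
}

fx_family_table <- function() fx_pipeline()$families

fx_is_library <- function() {
  if (is.null(.fx$isl)) {
    isl <- Biostrings::DNAStringSet(c(ISAfe1_like = rand_dna(1200, 0.52, 77)))
    .fx$isl <- isl
  }
  .fx$isl
}

# build a bare AnnotatedGenome from explicit parts (test scaffolding)
mk_genome <- function(strain, seq, genes_df, circular = NULL) {
  seqs <- Biostrings::DNAStringSet(seq)
  names(seqs) <- paste0(strain, "_chr")
  gr <- GenomicRanges::GRanges(names(seqs),
                               IRanges::IRanges(genes_df$start, genes_df$end),
                               strand = genes_df$strand)
  S4Vectors::mcols(gr)$locus_tag <- genes_df$locus_tag
  S4Vectors::mcols(gr)$type <- genes_df$type
  S4Vectors::mcols(gr)$family <- genes_df$family
  S4Vectors::mcols(gr)$product <- genes_df$product
  S4Vectors::mcols(gr)$label <- genes_df$label
  AnnotatedGenome(strain, seqs, gr, circular = circular)
}

# gene-level precision/recall of reconstructed candidates vs truth
recovery_stats <- function(cx, elements_by_strain) {
  tr <- complexTruth(cx)
  prec <- c(); rec <- c()
  for (s in names(elements_by_strain)) {
    truth_genes <- unlist(strsplit(
      tr$genes[tr$strain == s & tr$kind != "plasmid"], ","))
    pred <- unlist(lapply(elements_by_strain[[s]], elementGenes))
    if (!length(truth_genes)) next
    prec <- c(prec, if (length(pred)) mean(pred %in% truth_genes) else 0)
    rec <- c(rec, mean(truth_genes %in% pred))
  }
  list(precision = mean(prec), recall = mean(rec))
}
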