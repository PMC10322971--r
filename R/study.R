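#' Forge the standard study complex
#'
#' The canonical synthetic study conditions used throughout the package's
#' validation: a two-sublineage complex (four strains per sublineage,
#' within-sublineage pairwise divergence 0.005, between 0.03) carrying three
#' planted integrated elements — an ICE with a 48-bp target-site repeat at a
#' tRNA, a GI with a 17-bp repeat at a second tRNA, and a transposase-bounded
#' Tn with an 8-bp repeat inside the backbone — with one ICE copy split
#' across two contigs by draft fragmentation.
#'
#' @param seed integer master seed.
#' @param n_strains_per_group strains per sublineage (default 4).
#' @param ancestral_length chromosome length in bp (default 24000; desk
#'   scale, see the methods vignette).
#' @param with_plasmid also plant a multi-copy circular plasmid in the
#'   ICE-bearing strains (default FALSE).
#' @return a [SpeciesComplex] with truth records for all planted elements.
#' @export
forgeStudyComplex <- function(seed, n_strains_per_group = 4L,
                              ancestral_length = 24000L,
                              with_plasmid = FALSE) {
  cx <- forgeComplex(complexConfig(n_strains_per_group = n_strains_per_group,
                                   ancestral_length = ancestral_length,
                                   rng_seed = seed))
  strains <- names(cx@genomes)
  a <- strains[cx@groups == "A"]
  b <- strains[cx@groups == "B"]
  ice <- elementSpec("ICE1", "ICE", 8, cargo_gc_offset = 0.05,
                     integration_site = "tRNA-Ala-GGC", dr_length = 48L,
                     module_genes = c("integrase", "virB4", "virB5", "virB6",
                                      "virB9", "virB11", "relaxase MOBP",
                                      "t4cp coupling protein"))
  gi <- elementSpec("GI1", "GI", 5, cargo_gc_offset = -0.04,
                    integration_site = "tRNA-Arg-TCT", dr_length = 17L,
                    module_genes = c("integrase"))
  # Tn goes downstream of a backbone gene ~70% into the gene order
  g1 <- cx@genomes[[a[1]]]@genes
  cds_fams <- g1$family[g1$type == "CDS" & !is.na(g1$family)]
  tn_site <- paste0("family:", cds_fams[max(1L, round(0.7 * length(cds_fams)))])
  tn <- elementSpec("TN1", "Tn", 3, cargo_gc_offset = 0.04,
                    integration_site = tn_site, dr_length = 8L,
                    module_genes = c("transposase"))
  cx <- plantElements(cx, ice, a[seq_len(min(3L, length(a)))],
                      seed = .splitSeed(seed, 51L))
  cx <- plantElements(cx, gi, unique(c(a[1], a[length(a)])),
                      seed = .splitSeed(seed, 52L))
  cx <- plantElements(cx, tn, b[seq_len(min(2L, length(b)))],
                      seed = .splitSeed(seed, 53L))
  if (with_plasmid) {
    pl <- elementSpec("PL1", "plasmid", 6, length = 9000L,
                      module_genes = c("rep replicase", "parA"))
    cx <- plantElements(cx, pl, a[seq_len(min(2L, length(a)))],
                        seed = .splitSeed(seed, 54L))
  }
  # split the second strain's ICE across two contigs: break between its
  # 4th and 5th cargo genes
  split_strain <- a[2]
  tr <- cx@truth
  icetr <- tr[tr$element_id == "ICE1" & tr$strain == split_strain, ]
  if (nrow(icetr) == 1L) {
    g <- cx@genomes[[split_strain]]@genes
    chrom <- icetr$contig
    g <- g[as.character(seqnames(g)) == chrom]
    g <- g[order(start(g))]
    inside <- which(start(g) > icetr$start & end(g) < icetr$end)
    if (length(inside) >= 5L) {
      brk <- (end(g)[inside[4L]] + start(g)[inside[5L]]) %/% 2L
      cx <- draftComplex(cx, split_strain, 1L,
                         at = stats::setNames(list(brk), split_strain))
    }
  }
  cx
}

#' Reconstruct all planted elements of a study complex
#'
#' Runs the discovery stages (pangenome clustering + compartments, seed
#' census, boundary reconstruction with att-site recovery) over a complex
#' and scores gene-level recovery against the truth records.
#'
#' @param cx a [SpeciesComplex] with planted elements.
#' @param params from [pipelineConfig()].
#' @return list: `elements` (per strain), `families`, `census`,
#'   `precision`, `recall` (gene-level, macro-averaged over element-bearing
#'   strains), `att` (data.frame of recovered repeats vs truth).
#' @export
recoverStudyElements <- function(cx, params = pipelineConfig(
                                   run_relatedness = FALSE,
                                   run_synteny = FALSE, run_ddh = FALSE)) {
  res <- runPipeline(cx, params = params)
  tr <- complexTruth(cx)
  prec <- c(); rec <- c()
  att_rows <- list()
  for (s in names(res$elements)) {
    truth_genes <- unlist(strsplit(
      tr$genes[tr$strain == s & tr$kind != "plasmid"], ","))
    pred <- unlist(lapply(res$elements[[s]], elementGenes))
    if (length(truth_genes)) {
      prec <- c(prec, if (length(pred)) mean(pred %in% truth_genes) else 0)
      rec <- c(rec, mean(truth_genes %in% pred))
    }
    for (cd in res$elements[[s]]) {
      if (length(cd@att) == 0L || length(cd@seeds) != 1L) next
      truth_dr <- tr$dr_seq[tr$strain == s & tr$element_id == cd@seeds]
      truth_dr <- truth_dr[!is.na(truth_dr)][1L]
      att_rows[[length(att_rows) + 1L]] <- data.frame(
        strain = s, element = cd@seeds, recovered = cd@att$dr_seq,
        planted = truth_dr, exact = identical(cd@att$dr_seq, truth_dr),
        stringsAsFactors = FALSE)
    }
  }
  list(elements = res$elements, families = res$families,
       census = res$census,
       precision = mean(prec), recall = mean(rec),
       att = if (length(att_rows)) do.call(rbind, att_rows) else NULL)
}
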