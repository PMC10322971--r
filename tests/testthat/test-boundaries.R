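test_that("GC-shifted cargo stands out in the evidence track", {
  cx <- fx_complex()
  ft <- fx_family_table()
  g <- complexGenomes(cx)[["A1"]]
  ev <- contextualProfile(g, ft)
  tr <- complexTruth(cx)
  ice_genes <- strsplit(tr$genes[tr$element_id == "EL1" & tr$strain == "A1"],
                        ",")[[1]]
  z <- ev$gc_z[ev$locus_tag %in% ice_genes]
  expect_gte(mean(abs(z) >= 2), 0.8)
  # backbone core gene: no signature, core compartment, depth channel absent
  bb <- ev[ev$locus_tag == "A1_g0001", ]
  expect_identical(bb$compartment, "core")
  expect_false(bb$signature)
  expect_true(is.na(bb$depth_z))
  # plasmid genes at 6x depth score high depth anomaly
  sim <- simulateReseq(g, data.frame(), fx_is_library(), depth = 30,
                       plasmid_fold = 6, seed = 9)
  g2 <- AnnotatedGenome(strainName(g), contigs(g), geneModels(g), proteins(g),
                        depth = sim$depth, circular = circularReplicons(g))
  ev2 <- contextualProfile(g2, ft)
  pz <- ev2$depth_z[ev2$contig == "p_EL3"]
  expect_true(all(pz > 5))
})

test_that("reconstruction recovers planted boundaries at gene resolution", {
  res <- fx_pipeline()
  cx <- fx_complex()
  st <- recovery_stats(cx, res$elements)
  expect_gte(st$precision, 0.9)
  expect_gte(st$recall, 0.9)
  # candidate genes are flexible/exclusive only
  ft <- res$families
  m <- familyMembers(ft)
  comp <- familyCompartments(ft)
  for (s in names(res$elements)) for (cd in res$elements[[s]]) {
    fams <- m$family[match(elementGenes(cd), m$locus)]
    expect_true(all(comp[fams] %in% c("flexible", "exclusive")))
  }
})

test_that("a seed hit walled in by core genes yields a low-confidence singleton", {
  cx <- fx_complex()
  ft <- fx_family_table()
  g <- complexGenomes(cx)[["B1"]]          # carries no planted element
  ev <- contextualProfile(g, ft)
  target <- ev$locus_tag[ev$type == "CDS"][10]
  fake <- data.frame(query = "q1", target_locus = target, evalue = 1e-30,
                     identity = 1, coverage = 1, rbh_confirmed = TRUE,
                     stringsAsFactors = FALSE)
  cands <- reconstructElements(g, list(SEEDX = fake), ev)
  expect_length(cands, 1L)
  expect_match(cands[[1]]@notes, "low-confidence")
  expect_length(elementGenes(cands[[1]]), 1L)
  # no seeds at all: empty list, not an error
  expect_identical(reconstructElements(g, list(), ev), list())
})

test_that("att quartets are recovered exactly for exact planted repeats", {
  cx <- fx_complex()
  res <- fx_pipeline()
  tr <- complexTruth(cx)
  for (strain in c("A1", "A2")) {
    g <- complexGenomes(cx)[[strain]]
    for (cd in res$elements[[strain]]) {
      if (!"EL1" %in% cd@seeds) next
      att <- findAttSites(cd, g)
      truth <- tr[tr$element_id == "EL1" & tr$strain == strain, ]
      expect_identical(att$dr_seq, truth$dr_seq)
      expect_equal(unname(att$attL["start"]), truth$attL_start)
      expect_equal(unname(att$attR["end"]), truth$attR_end)
      expect_identical(att$notation, "DR(76,48)")
      expect_identical(att$integration_feature, "tRNA-Ala-GGC")
      # excision through the quartet restores the pre-insertion locus
      chrom <- contigs(g)[[as.character(GenomicRanges::seqnames(cd@segments))[1]]]
      exc <- exciseElement(chrom, att)
      pre_chrom <- contigs(complexGenomes(fx_preplant())[[strain]])[[1]]
      # A1 also carries the GI and plasmid; compare against the genome with
      # only the remaining elements by re-planting them on the pre-plant
      expected <- pre_chrom
      if (strain == "A1")
        expected <- contigs(plantElement(
          complexGenomes(fx_preplant())[["A1"]], fx_gi_spec(),
          seed = 102)$genome)[["A1_chr"]]
      expect_identical(as.character(exc), as.character(expected))
    }
  }
})

test_that("elements planted without repeats report no att sites", {
  pre <- fx_preplant()
  sp <- elementSpec("NODR", "GI", 4, integration_site = "tRNA-Thr-TGT",
                    dr_length = 0L, module_genes = "integrase")
  pg <- plantElement(complexGenomes(pre)[["B1"]], sp, seed = 55)
  t1 <- pg$truth
  cand <- new("CandidateElement", element_id = "c1", strain = "B1",
              segments = GenomicRanges::GRanges(
                t1$contig, IRanges::IRanges(t1$start, t1$end)),
              genes = strsplit(t1$genes, ",")[[1]], seeds = "NODR",
              support = 1, att = list(), inventory = list(), type = "",
              notes = "")
  expect_null(findAttSites(cand, pg$genome))
  # unresolved multi-contig termini: skipped with a notice
  cand2 <- cand
  cand2@segments <- GenomicRanges::GRanges(c("c1", "c2"),
                                           IRanges::IRanges(c(1, 1), c(10, 10)))
  expect_message(expect_null(findAttSites(cand2, pg$genome)), "skipped")
})

test_that("in-silico PCR reproduces the wild-type and transposition amplicons", {
  backbone <- rand_dna(4000, 0.55, 91)
  fwd <- substr(backbone, 1001, 1020)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(backbone, 1935, 1954))))
  wt <- insilicoPcr(c(locus = backbone), fwd, rev)
  expect_equal(nrow(wt), 1L)
  expect_equal(wt$length, 954L)
  # insert an IS (1302 bp) with an 8-bp target-site duplication between the
  # primers: the mutant allele amplifies at 954 + 1302 + 8 = 2264 bp
  is_seq <- rand_dna(1302, 0.5, 92)
  p <- 1500L
  mutant <- paste0(substr(backbone, 1, p + 8), is_seq,
                   substr(backbone, p + 1, nchar(backbone)))
  mu <- insilicoPcr(c(locus = mutant), fwd, rev)
  expect_equal(mu$length, 2264L)
  expect_equal(mu$length - wt$length, 1302L + 8L)
  # primers with no match: empty result
  none <- insilicoPcr(c(locus = backbone), strrep("ACGT", 5), rev)
  expect_equal(nrow(none), 0L)
  # circular templates amplify across the origin
  circ_seq <- paste0(substr(backbone, 1500, 4000), substr(backbone, 1, 1499))
  circ <- insilicoPcr(c(locus = circ_seq), fwd, rev,
                      circular = c(locus = TRUE))
  expect_equal(circ$length, 954L)
  expect_error(insilicoPcr(c(l = backbone), "ACGTACGTACGT", rev), ">= 15")
})
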