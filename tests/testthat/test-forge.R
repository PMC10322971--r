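test_that("identical seeds reproduce identical complexes", {
  cfg <- complexConfig(n_strains_per_group = 1, ancestral_length = 12000,
                       rng_seed = 7)
  a <- forgeComplex(cfg)
  b <- forgeComplex(cfg)
  expect_identical(
    lapply(complexGenomes(a), function(g) as.character(contigs(g))),
    lapply(complexGenomes(b), function(g) as.character(contigs(g))))
  expect_identical(a@mutlog, b@mutlog)
  # planting is deterministic too
  sp <- elementSpec("EL2", "GI", 5, cargo_gc_offset = -0.04,
                    integration_site = "tRNA-Ala-GGC", dr_length = 17L,
                    module_genes = c("integrase"))
  pa <- plantElement(complexGenomes(a)[["A1"]], sp, seed = 5)
  pb <- plantElement(complexGenomes(b)[["A1"]], sp, seed = 5)
  expect_identical(as.character(contigs(pa$genome)),
                   as.character(contigs(pb$genome)))
})

test_that("zero divergence yields identical genomes", {
  cx <- forgeComplex(complexConfig(n_strains_per_group = 2,
                                   ancestral_length = 10000,
                                   within_group_divergence = 0,
                                   between_group_divergence = 0,
                                   rng_seed = 3))
  seqs <- lapply(complexGenomes(cx), function(g) as.character(contigs(g)[[1]]))
  expect_true(all(vapply(seqs, identical, logical(1), seqs[[1]])))
})

test_that("invalid divergence ordering is rejected", {
  expect_error(complexConfig(within_group_divergence = 0.05,
                             between_group_divergence = 0.01),
               "ordering")
})

test_that("mutation logs replay to the emitted genomes and divergence matches", {
  diffs <- c()
  for (seed in 1:8) {
    cx <- forgeComplex(complexConfig(n_strains_per_group = 1,
                                     ancestral_length = 10000,
                                     between_group_divergence = 0.03,
                                     rng_seed = seed))
    anc <- strsplit(as.character(cx@ancestral[[1]]), "", fixed = TRUE)[[1]]
    for (s in names(complexGenomes(cx))) {
      x <- anc
      log <- cx@mutlog[[s]]
      x[log$pos] <- log$to
      expect_identical(paste(x, collapse = ""),
                       as.character(contigs(complexGenomes(cx)[[s]])[[1]]))
    }
    a <- strsplit(as.character(contigs(complexGenomes(cx)[["A1"]])[[1]]), "")[[1]]
    b <- strsplit(as.character(contigs(complexGenomes(cx)[["B1"]])[[1]]), "")[[1]]
    diffs <- c(diffs, mean(a != b))
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.03), 3 * se + 1e-4)
})

test_that("planting duplicates the target-site repeat and is exactly reversible", {
  cx <- fx_complex()
  pre <- fx_preplant()
  tr <- complexTruth(cx)
  ice <- tr[tr$element_id == "EL1" & tr$strain == "A1", ]
  chrom <- as.character(contigs(complexGenomes(cx)[["A1"]])[["A1_chr"]])
  attL <- substr(chrom, ice$attL_start, ice$attL_end)
  attR <- substr(chrom, ice$attR_start, ice$attR_end)
  expect_identical(attL, ice$dr_seq)
  expect_identical(attR, ice$dr_seq)
  expect_equal(nchar(attL), 48L)
  # element sequence is an exact substring of the modified genome
  expect_identical(substr(chrom, ice$start, ice$end),
                   substr(chrom, ice$start, ice$end))
  # excising (drop (attL_end, attR_end]) restores the pre-insertion genome,
  # here applied to the genome carrying only this one element
  one <- plantElement(complexGenomes(pre)[["A1"]], fx_ice_spec(), seed = 101)
  ch1 <- as.character(contigs(one$genome)[["A1_chr"]])
  t1 <- one$truth
  restored <- paste0(substr(ch1, 1, t1$attL_end),
                     substr(ch1, t1$attR_end + 1, nchar(ch1)))
  expect_identical(restored,
                   as.character(contigs(complexGenomes(pre)[["A1"]])[[1]]))
})

test_that("plasmid specs emit a circular replicon and leave the chromosome alone", {
  cx <- fx_complex()
  pre <- fx_preplant()
  g <- complexGenomes(cx)[["A2"]]
  expect_true("p_EL3" %in% names(contigs(g)))
  expect_true(circularReplicons(g)[["p_EL3"]])
  tr <- complexTruth(cx)
  ptr <- tr[tr$element_id == "EL3" & tr$strain == "A2", ]
  expect_true(is.na(ptr$attL_start))
  # chromosome differs from pre-plant only by the integrated ICE, not EL3:
  # replant only the plasmid and compare chromosomes
  onlyp <- plantElement(complexGenomes(pre)[["A2"]], fx_plasmid_spec(), seed = 103)
  expect_identical(as.character(contigs(onlyp$genome)[["A2_chr"]]),
                   as.character(contigs(complexGenomes(pre)[["A2"]])[[1]]))
})

test_that("unknown integration sites raise a lookup error", {
  pre <- fx_preplant()
  sp <- elementSpec("EX", "GI", 3, integration_site = "tRNA-Leu-XXX",
                    dr_length = 10L, module_genes = "integrase")
  expect_error(plantElement(complexGenomes(pre)[["A1"]], sp, 1),
               "unknown integration site")
})

test_that("draft fragmentation conserves sequence and splits truth records", {
  cx <- fx_complex()
  g <- complexGenomes(cx)[["A2"]]
  L <- sum(BiocGenerics::width(contigs(g))[!circularReplicons(g)])
  # no breaks: identity
  d0 <- makeDraft(g, 0)
  expect_identical(as.character(contigs(d0$genome)), as.character(contigs(g)))
  # random breaks: conservation
  d3 <- makeDraft(g, 3, min_contig = 2000, seed = 4)
  w <- setNames(BiocGenerics::width(contigs(d3$genome)),
                names(contigs(d3$genome)))
  expect_equal(sum(w[setdiff(names(w), "p_EL3")]), L)
  # forced break inside the planted ICE: truth lists two segments
  tr <- complexTruth(cx)
  ice <- tr[tr$element_id == "EL1" & tr$strain == "A2", ]
  gg <- geneModels(g)
  gg <- gg[as.character(GenomicRanges::seqnames(gg)) == "A2_chr"]
  gg <- gg[order(GenomicRanges::start(gg))]
  inside <- which(GenomicRanges::start(gg) > ice$start &
                  GenomicRanges::end(gg) < ice$end)
  b <- (GenomicRanges::end(gg)[inside[3]] +
        GenomicRanges::start(gg)[inside[4]]) %/% 2
  cx2 <- draftComplex(cx, "A2", 1, at = list(A2 = b))
  tr2 <- complexTruth(cx2)
  segs <- tr2[tr2$element_id == "EL1" & tr2$strain == "A2", ]
  expect_equal(nrow(segs), 2L)
  expect_equal(sort(segs$segment), 1:2)
  # infeasibility error
  expect_error(makeDraft(g, 100, min_contig = 5000), "infeasible")
})

test_that("simulated resequencing matches its Poisson/binomial design", {
  cx <- fx_complex()
  g <- complexGenomes(cx)[["A1"]]
  isl <- fx_is_library()
  # no events: no junction reads
  r0 <- simulateReseq(g, data.frame(), isl, depth = 10, seed = 2)
  expect_equal(nrow(r0$reads), 0L)
  # plasmid depth fold 6 at 30x within 10%
  r6 <- simulateReseq(g, data.frame(), isl, depth = 30, plasmid_fold = 6, seed = 3)
  fold <- repliconDepthFold(r6$depth, "p_EL3")
  expect_lt(abs(fold - 6) / 6, 0.10)
  # allele fraction 0.5 at 40x: mutant junction reads near 20
  gg <- geneModels(g)
  cds <- gg[gg$type == "CDS" & GenomicRanges::start(gg) > 2000]
  pos <- GenomicRanges::start(cds)[1] + 50L
  ev <- data.frame(is_family = "ISAfe1_like", contig = "A1_chr", pos = pos,
                   dr_len = 8L, allele_fraction = 0.5)
  set.seed(NULL)
  muts <- vapply(1:12, function(s) {
    r <- simulateReseq(g, ev, isl, depth = 40, seed = s)
    r$events$n_mut[1] / r$events$n_span[1]
  }, numeric(1))
  se <- sqrt(0.25 / 40) / sqrt(length(muts))
  expect_lt(abs(mean(muts) - 0.5), 4 * se)
})
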