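test_that("identical seed proteins hit their targets with RBH confirmation", {
  cx <- fx_complex()
  seed <- seedFromTruth(cx, "EL1", "A1")
  h <- seedSearch(seed, complexGenomes(cx)[["A1"]])
  expect_equal(length(unique(h$query)), length(seed@proteins))
  expect_true(all(h$rbh_confirmed))
  expect_true(all(h$evalue < 0.001))
  # a genome without the element yields no retained hits
  h0 <- seedSearch(seedFromTruth(cx, "EL2", "A1"), complexGenomes(cx)[["B1"]])
  expect_equal(nrow(h0), 0L)
  # empty seeds are rejected at construction
  expect_error(seedElement("x", "s", Biostrings::AAStringSet()),
               "at least one protein")
})

test_that("coverage matrix scores sources at 100 and half-elements at 50", {
  cx <- fx_complex()
  seed8 <- seedFromTruth(cx, "EL1", "A1")
  # plant only the first half of the same element (same id + seed -> the
  # cargo generator emits the identical leading genes) into a fresh strain
  pre <- fx_preplant()
  half_spec <- elementSpec("EL1", "GI", 4, length = 4000L,
                           cargo_gc_offset = 0.05,
                           integration_site = "tRNA-Ala-GGC", dr_length = 48L,
                           module_genes = c("integrase", "virB4", "virB5",
                                            "virB6"))
  half <- plantElement(complexGenomes(pre)[["B2"]], half_spec, seed = 101)
  genomes <- list(A1 = complexGenomes(cx)[["A1"]],
                  B1 = complexGenomes(cx)[["B1"]],
                  B2 = half$genome)
  cm <- coverageMatrix(list(seed8), genomes)
  expect_equal(unname(cm$coverage["EL1", "A1"]), 100)
  expect_equal(unname(cm$coverage["EL1", "B2"]), 50)
  expect_equal(unname(cm$coverage["EL1", "B1"]), 0)
  expect_true(cm$occurrence["EL1", "A1"])
  expect_false(cm$occurrence["EL1", "B2"])
})

test_that("raising the e-value cut-off never lowers coverage", {
  cx <- fx_complex()
  seeds <- list(seedFromTruth(cx, "EL1", "A1"), seedFromTruth(cx, "EL2", "A1"))
  g <- complexGenomes(cx)[c("A1", "A2")]
  strict <- coverageMatrix(seeds, g, evalue_max = 1e-10)
  loose <- coverageMatrix(seeds, g, evalue_max = 1e-3)
  expect_true(all(loose$coverage >= strict$coverage))
})

test_that("strains cluster by coverage pattern, invariant to input order", {
  cx <- fx_complex()
  res <- fx_pipeline()
  cov <- res$census$coverage
  # the ICE separates A-strains from B-strains in coverage space
  d <- as.matrix(dist(t(cov)))
  expect_lt(d["A1", "A2"], d["A1", "B1"])
  expect_true(!is.null(res$census$newick))
  # order invariance
  seeds <- list(seedFromTruth(cx, "EL1", "A1"))
  g <- complexGenomes(cx)
  cm1 <- coverageMatrix(seeds, g)
  cm2 <- coverageMatrix(seeds, rev(g))
  expect_identical(cm1$coverage, cm2$coverage)
})

test_that("six-frame fallback finds seed proteins in unannotated assemblies", {
  cx <- fx_complex()
  g <- complexGenomes(cx)[["A1"]]
  naked <- AnnotatedGenome("naked", contigs(g), GenomicRanges::GRanges())
  seed <- seedFromTruth(cx, "EL2", "A1")
  h <- seedSearch(seed, naked, source_proteome = proteins(g))
  expect_gte(length(unique(h$query)), length(seed@proteins) - 1L)
})
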