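mk_is_host <- function(n_copies, identity = 1, seed = 201) {
  isl <- fx_is_library()
  is_seq <- as.character(isl[[1]])
  set.seed(seed)
  host <- rand_dna(30000, 0.55, seed)
  gaps <- sort(sample(seq(2000, 28000, by = 3000), n_copies))
  for (p in rev(gaps)) {
    copy <- strsplit(is_seq, "")[[1]]
    if (identity < 1) {
      pos <- sample(seq_along(copy), round((1 - identity) * length(copy)))
      for (q in pos) copy[q] <- sample(setdiff(c("A", "C", "G", "T"), copy[q]), 1)
    }
    host <- paste0(substr(host, 1, p), paste(copy, collapse = ""),
                   substr(host, p + 1, nchar(host)))
  }
  seqs <- Biostrings::DNAStringSet(host)
  names(seqs) <- "host_chr"
  AnnotatedGenome("host", seqs, GenomicRanges::GRanges())
}

test_that("the IS scan counts planted copies at the configured thresholds", {
  g5 <- mk_is_host(5)
  hits <- scanISCopies(g5, fx_is_library())
  expect_equal(nrow(hits), 5L)
  expect_true(all(hits$identity == 100))
  expect_true(all(hits$coverage == 100))
  # an 85%-identity copy is excluded at defaults, included at 80
  g85 <- mk_is_host(1, identity = 0.85, seed = 207)
  expect_equal(nrow(scanISCopies(g85, fx_is_library())), 0L)
  h80 <- scanISCopies(g85, fx_is_library(), min_similarity = 80)
  expect_equal(nrow(h80), 1L)
  expect_lt(h80$identity, 90)
  expect_error(scanISCopies(g85, Biostrings::DNAStringSet()), "empty")
})

test_that("copy counts are monotone non-increasing in the similarity threshold", {
  g <- mk_is_host(3, identity = 0.93, seed = 208)
  counts <- vapply(c(80, 90, 95, 99),
                   function(th) nrow(scanISCopies(g, fx_is_library(),
                                                  min_similarity = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a single planted transposition is called at base resolution", {
  cx <- fx_complex()
  g <- complexGenomes(cx)[["B1"]]
  isl <- fx_is_library()
  gg <- geneModels(g)
  cds <- gg[gg$type == "CDS"]
  target <- cds[8]
  pos <- GenomicRanges::start(target) + 101L
  ev <- data.frame(is_family = "ISAfe1_like", contig = "B1_chr", pos = pos,
                   dr_len = 8L, allele_fraction = 1.0)
  sim <- simulateReseq(g, ev, isl, depth = 40, seed = 13)
  calls <- detectInsertions(g, sim$reads, isl)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$pos - pos), 1L)
  expect_identical(calls$target_gene, target$locus_tag)
  expect_identical(calls$is_family, "ISAfe1_like")
  expect_equal(calls$dr_len, 8L)
  expect_gte(calls$allele_fraction, 0.9)
  # no events: no calls
  sim0 <- simulateReseq(g, data.frame(), isl, depth = 40, seed = 14)
  expect_equal(nrow(detectInsertions(g, sim0$reads, isl)), 0L)
  # foreign reads are an input error
  bad <- sim$reads; bad$rname <- "unknown_contig"
  expect_error(detectInsertions(g, bad, isl), "absent")
})

test_that("the allele-fraction estimator is unbiased at a 50/50 mixture", {
  cx <- fx_complex()
  g <- complexGenomes(cx)[["B1"]]
  isl <- fx_is_library()
  gg <- geneModels(g)
  pos <- GenomicRanges::start(gg[gg$type == "CDS"][5]) + 60L
  ev <- data.frame(is_family = "ISAfe1_like", contig = "B1_chr", pos = pos,
                   dr_len = 5L, allele_fraction = 0.5)
  fr <- c()
  for (s in 1:25) {
    sim <- simulateReseq(g, ev, isl, depth = 40, seed = 1000 + s)
    calls <- detectInsertions(g, sim$reads, isl, min_support = 2)
    if (nrow(calls)) fr <- c(fr, calls$allele_fraction)
  }
  expect_gte(length(fr), 20L)
  se <- sqrt(0.25 / 40) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se)
})

test_that("allele trajectories are tracked and loss is called after the decay", {
  cx <- fx_complex()
  g <- complexGenomes(cx)[["B1"]]
  isl <- fx_is_library()
  gg <- geneModels(g)
  pos <- GenomicRanges::start(gg[gg$type == "CDS"][12]) + 90L
  schedule <- c(1.0, 0.6, 0.3, 0.1, 0.0, 0.0)
  passages <- lapply(seq_along(schedule), function(p) {
    ev <- data.frame(is_family = "ISAfe1_like", contig = "B1_chr", pos = pos,
                     dr_len = 8L, allele_fraction = schedule[p])
    simulateReseq(g, ev, isl, depth = 100, seed = 2000 + p)$reads
  })
  ev1 <- data.frame(is_family = "ISAfe1_like", contig = "B1_chr", pos = pos,
                    dr_len = 8L)
  sim1 <- simulateReseq(g, transform(ev1, allele_fraction = 1), isl,
                        depth = 40, seed = 1999)
  events <- detectInsertions(g, sim1$reads, isl)
  tra <- trackAlleles(events, passages, g, isl)
  expect_equal(nrow(tra), length(schedule))
  expect_true(all(tra$detected[1:4]))
  expect_false(any(tra$detected[5:6]))
  expect_equal(unname(attr(tra, "loss_passage")[1]), 5L)
  # fractions follow the programmed decay
  expect_true(all(diff(tra$allele_fraction) <= 0.15))
  expect_lt(abs(tra$allele_fraction[1] - 1), 0.05)
})

test_that("replicon depth fold is recovered from the depth track", {
  expect_equal(repliconDepthFold(list(chr = rep(10, 1000), p = rep(60, 200)),
                                 "p", "chr"), 6)
  cx <- fx_complex()
  g <- complexGenomes(cx)[["A1"]]
  for (fold in c(5, 6)) {
    sim <- simulateReseq(g, data.frame(), fx_is_library(), depth = 30,
                         plasmid_fold = fold, seed = 300 + fold)
    est <- repliconDepthFold(sim$depth, "p_EL3")
    expect_lt(abs(est - fold) / fold, 0.10)
  }
})
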