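test_that("module detection reads the functional labels", {
  labs <- c("integrase", "virB4", "virB5", "virB6", "virB9", "virB11",
            "relaxase MOBP", "t4cp coupling protein", "hypothetical protein")
  inv <- detectModules(labs)
  expect_equal(inv$integrase, 1L)
  expect_equal(inv$virb, c("virB11", "virB4", "virB5", "virB6", "virB9"))
  expect_true(inv$relaxase)
  expect_true(inv$t4cp)
  expect_true(inv$conjugation_complete)
  # empty protein list -> empty inventory
  inv0 <- detectModules(character(0))
  expect_equal(inv0$integrase, 0L)
  expect_length(inv0$virb, 0L)
  expect_false(inv0$conjugation_complete)
})

test_that("oriV evidence is found next to a rep gene", {
  rep_orf <- rand_dna(300, 0.5, 41)
  seq <- paste0(rand_dna(200, 0.5, 42), rep_orf,
                rand_dna(50, 0.5, 43),
                "TTATCCACA",                      # DnaA box
                rand_dna(30, 0.5, 44),
                "AATCAAGGGGTTA",                  # IHF consensus (W=A, R=A)
                rand_dna(200, 0.5, 45))
  gdf <- data.frame(start = 201L, end = 500L, strand = "+", type = "CDS",
                    locus_tag = "rep1", family = NA, product = "rep replicase",
                    label = "rep replicase", stringsAsFactors = FALSE)
  g <- mk_genome("plas", seq, gdf)
  inv <- detectModules("rep replicase", genome = g, rep_locus = "rep1")
  expect_true(inv$rep)
  expect_gte(inv$dnaa_hits, 1L)
  expect_gte(inv$ihf_hits, 1L)
})

test_that("typing follows the decision rules over all toggle combinations", {
  oracle <- function(inv, ctx, min_virb = 5L) {
    conj <- length(inv$virb) >= min_virb || (inv$relaxase && inv$t4cp)
    if (inv$integrase > 0 && conj && ctx$integrated) "ICE"
    else if (inv$rep && (ctx$circular || (!ctx$integrated && inv$dnaa_hits > 0)))
      "plasmid"
    else if (inv$integrase > 0) "GI"
    else if (inv$transposase > 0 && !ctx$att_present) "Tn"
    else "fragment"
  }
  grid <- expand.grid(int = c(0L, 1L), virb_n = c(0L, 7L),
                      relax = c(FALSE, TRUE), tnp = c(0L, 1L),
                      rep = c(FALSE, TRUE), integrated = c(FALSE, TRUE),
                      circular = c(FALSE, TRUE), att = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    if (gr$integrated && gr$circular) next     # contradictory, tested below
    inv <- list(integrase = gr$int, transposase = gr$tnp,
                virb = if (gr$virb_n) paste0("virB", 1:7) else character(0),
                relaxase = gr$relax, t4cp = gr$relax, rep = gr$rep,
                dnaa_hits = if (gr$rep) 1L else 0L, ihf_hits = 0L,
                ta_pairs = 0L, partition = 0L, cargo = 0L)
    ctx <- list(integrated = gr$integrated, circular = gr$circular,
                att_present = gr$att)
    expect_identical(typeElement(inv, ctx)$type, oracle(inv, ctx),
                     info = paste(unlist(gr), collapse = ","))
  }
  inv <- list(integrase = 1L, transposase = 0L, virb = character(0),
              relaxase = FALSE, t4cp = FALSE, rep = FALSE, dnaa_hits = 0L,
              ihf_hits = 0L, ta_pairs = 0L, partition = 0L, cargo = 0L)
  expect_error(typeElement(inv, list(integrated = TRUE, circular = TRUE,
                                     att_present = FALSE)),
               "contradictory")
  # integrase-only island: GI by rule
  expect_identical(typeElement(inv, list(integrated = TRUE, circular = FALSE,
                                         att_present = TRUE))$type, "GI")
})

test_that("pipeline candidates are typed from their planted modules", {
  res <- fx_pipeline()
  types <- list()
  for (s in names(res$elements)) for (cd in res$elements[[s]])
    types[[paste(s, cd@seeds[1])]] <- elementType(cd)
  expect_identical(types[["A1 EL1"]], "ICE")
  expect_identical(types[["A1 EL2"]], "GI")
  expect_identical(types[["A2 EL1"]], "ICE")
})

test_that("a duplicated terminus circularizes and trims the contig", {
  plasmid <- rand_dna(9000, 0.55, 71)
  contig <- paste0(plasmid, substr(plasmid, 1, 120))
  res <- circularizeContig(contig)
  expect_identical(res$topology, "circular")
  expect_equal(res$overlap, 120L)
  expect_equal(length(res$sequence), 9000L)
  expect_identical(as.character(res$sequence), plasmid)
  lin <- circularizeContig(rand_dna(5000, 0.5, 72))
  expect_identical(lin$topology, "linear")
  expect_equal(lin$overlap, 0L)
})

test_that("digestion matches a naive site-scan oracle and conserves length", {
  naive_circular <- function(seq, site) {
    L <- nchar(seq)
    dbl <- paste0(seq, substr(seq, 1, nchar(site)))
    hits <- gregexpr(site, dbl, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits <= L]
    if (!length(hits)) return(L)
    cuts <- sort(unique((hits - 1L) %% L + 1L))
    sort(diff(c(cuts, cuts[1] + L)))
  }
  set.seed(61)
  for (i in 1:20) {
    L <- sample(2000:12000, 1)
    s <- rand_dna(L, runif(1, 0.4, 0.6), seed = 6100 + i)
    fr <- digestFragments(s, "circular", "GGATCC")
    expect_equal(fr, naive_circular(s, "GGATCC"))
    expect_equal(sum(fr), L)
    frl <- digestFragments(s, "linear", "GGATCC")
    expect_equal(sum(frl), L)
  }
  # no site on a circle: one uncut full-length record
  clean <- gsub("GGATCC", "GGATCG", rand_dna(4000, 0.5, 66), fixed = TRUE)
  expect_equal(digestFragments(clean, "circular", "GGATCC"), 4000L)
  expect_error(digestFragments("ACGT", "linear", "GGAUCC"), "IUPAC")
})

test_that("a 17,826-bp circle with the printed site spacings yields the gel bands", {
  # synthetic plasmid built to the published geometry: BamHI sites spaced to
  # release 3,077 / 4,155 / 10,594 bp fragments
  L <- 17826L
  base <- gsub("GGATCC", "GGATCG",
               rand_dna(L, 0.55, 81), fixed = TRUE)
  sites <- c(100L, 3177L, 7332L)
  for (s in sites)
    base <- paste0(substr(base, 1, s - 1), "GGATCC", substr(base, s + 6, L))
  expect_equal(nchar(base), L)
  fr <- digestFragments(base, "circular", "GGATCC")
  expect_equal(fr, c(3077L, 4155L, 10594L))
  expect_equal(sum(fr), 17826L)
})
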