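test_that("identical proteomes collapse into one family per protein", {
  set.seed(31)
  prots <- Biostrings::AAStringSet(vapply(1:10, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                 replace = TRUE), collapse = ""), character(1)))
  names(prots) <- paste0("p", 1:10)
  ft <- clusterFamilies(list(s1 = prots, s2 = prots, s3 = prots))
  occ <- familyOccupancy(ft)
  expect_equal(nrow(occ), 10L)
  expect_true(all(occ == 1L))
  # partition property: every protein in exactly one family
  m <- familyMembers(ft)
  expect_equal(nrow(m), 30L)
  expect_false(anyDuplicated(m$protein) > 0)
  expect_error(clusterFamilies(list(s1 = prots)), "two proteomes")
})

test_that("clustering recovers the forged family structure (ARI >= 0.95)", {
  skip_if_not_installed("mclust")
  cx <- fx_complex()
  ft <- fx_family_table()
  m <- familyMembers(ft)
  truth <- unlist(unname(lapply(complexGenomes(cx), function(g) {
    gg <- geneModels(g)
    setNames(gg$family[gg$type == "CDS"],
             paste0(strainName(g), "|", gg$locus_tag[gg$type == "CDS"]))
  })))
  ari <- mclust::adjustedRandIndex(m$family, truth[m$protein])
  expect_gte(ari, 0.95)
})

test_that("compartment labels match direct rule evaluation", {
  set.seed(8)
  strains <- paste0("s", 1:15)
  groups <- setNames(rep(c("A", "B"), c(11, 4)), strains)
  for (rep_i in 1:5) {
    occ <- matrix(rbinom(40 * 15, 1, runif(1, 0.3, 0.9)), 40, 15,
                  dimnames = list(sprintf("F%02d", 1:40), strains))
    occ[1:3, ] <- 1L  # guarantee some core
    ft <- new("FamilyTable",
              members = data.frame(protein = character(), strain = character(),
                                   locus = character(), family = character()),
              occupancy = occ, compartment = character(0),
              group_exclusive = character(0),
              identity = setNames(rep(NA_real_, 40), rownames(occ)))
    ft <- compartmentalize(ft, groups)
    comp <- familyCompartments(ft)
    for (f in rownames(occ)) {
      k <- sum(occ[f, ] > 0)
      want <- if (k == 15) "core" else if (k == 1) "exclusive"
              else if (k >= 0.95 * 15) "soft-core" else "flexible"
      expect_identical(unname(comp[f]), want)
    }
    # compartment counts sum to the family count
    expect_equal(sum(table(comp)), 40L)
    # group-exclusivity rule: > 90% of the group, absent elsewhere
    gx <- ft@group_exclusive
    for (f in rownames(occ)) {
      inA <- sum(occ[f, groups == "A"] > 0); inB <- sum(occ[f, groups == "B"] > 0)
      want <- if (inA > 0.9 * 11 && inB == 0) "A"
              else if (inB > 0.9 * 4 && inA == 0) "B" else ""
      expect_identical(unname(gx[f]), want)
    }
  }
})

test_that("a family in all strains is core; in one strain, exclusive", {
  ft <- fx_family_table()
  cx <- fx_complex()
  m <- familyMembers(ft)
  # backbone families occur in all four strains -> core
  bb <- m$family[m$locus == "A1_g0001"]
  expect_identical(unname(familyCompartments(ft)[bb]), "core")
  # the GI cargo lives only in A1 -> exclusive
  tr <- complexTruth(cx)
  gi_gene <- strsplit(tr$genes[tr$element_id == "EL2"], ",")[[1]][1]
  gif <- m$family[m$locus == gi_gene]
  expect_identical(unname(familyCompartments(ft)[gif]), "exclusive")
  # the ICE cargo lives in A1+A2 of four strains -> flexible
  ice_gene <- strsplit(tr$genes[tr$element_id == "EL1" & tr$strain == "A1"],
                       ",")[[1]][1]
  icef <- m$family[m$locus == ice_gene]
  expect_identical(unname(familyCompartments(ft)[icef]), "flexible")
})

test_that("within-group protein identities dominate the species-wide ones", {
  cx <- fx_complex()
  ft <- fx_family_table()
  prots <- lapply(complexGenomes(cx), proteins)
  suppressMessages({
    sp <- familyIdentityStats(ft, prots, scope = "species")
    wg <- familyIdentityStats(ft, prots, scope = "within-group",
                              groups = complexGroups(cx), group = "A")
  })
  shared <- intersect(names(sp), names(wg))
  expect_gt(median(wg[shared]), median(sp[shared]))
})
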