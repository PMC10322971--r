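test_that("self-comparison gives ANI 100 and distance zero", {
  g <- complexGenomes(fx_preplant())[["A1"]]
  r <- anibPair(g, g)
  expect_equal(r$anib, 100)
  d <- ddhPair(g, g)
  expect_equal(d$d2, 0)
})

test_that("a uniformly 2%-diverged pair matches the Hamming oracle", {
  n <- 20000L
  set.seed(21)
  a <- strsplit(rand_dna(n, 0.5, 21), "", fixed = TRUE)[[1]]
  b <- a
  pos <- sample.int(n, round(0.02 * n))
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
  sa <- Biostrings::DNAStringSet(paste(a, collapse = "")); names(sa) <- "c1"
  sb <- Biostrings::DNAStringSet(paste(b, collapse = "")); names(sb) <- "c1"
  r <- anibPair(sa, sb)
  # Hamming oracle: mean per-fragment identity over the same 1020-bp tiling
  frs <- seq(1, n, by = 1020L)
  oid <- vapply(frs, function(s) {
    e <- min(n, s + 1019L)
    mean(a[s:e] == b[s:e])
  }, numeric(1))
  expect_equal(r$anib, 100 * mean(oid), tolerance = 1e-10)
  expect_lt(abs(r$anib - 98.0), 0.1)
  # dDDH distance equals global mismatch density for the full-length HSPs
  d <- ddhPair(sa, sb)
  expect_equal(d$d2, mean(a != b), tolerance = 1e-10)
})

test_that("anib decreases monotonically with divergence", {
  n <- 10000L
  set.seed(5)
  a <- strsplit(rand_dna(n, 0.5, 5), "", fixed = TRUE)[[1]]
  anis <- vapply(c(0.005, 0.02, 0.05), function(rate) {
    b <- a
    pos <- sample.int(n, round(rate * n))
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    sa <- Biostrings::DNAStringSet(paste(a, collapse = "")); names(sa) <- "c"
    sb <- Biostrings::DNAStringSet(paste(b, collapse = "")); names(sb) <- "c"
    anibPair(sa, sb)$anib
  }, numeric(1))
  expect_true(all(diff(anis) < 0))
})

test_that("the dDDH logistic transform honors its calibration anchors", {
  tr <- ddhTransform()
  expect_equal(100 / (1 + exp(tr$a + tr$b * 0.0359)), 70, tolerance = 1e-6)
  expect_equal(100 / (1 + exp(tr$a + tr$b * 0.0250)), 79, tolerance = 1e-6)
})

test_that("delimitation recovers block structure and matches a brute-force search", {
  strains <- paste0("s", 1:8)
  grp <- rep(c(1, 2), each = 4)
  ani <- matrix(96.5, 8, 8, dimnames = list(strains, strains))
  ani[grp == 1, grp == 1] <- 99
  ani[grp == 2, grp == 2] <- 99
  diag(ani) <- 100
  d <- delimitGroups(ani)
  expect_equal(length(unique(d$species)), 1L)
  expect_equal(length(unique(d$sublineage)), 2L)
  expect_equal(unname(split(strains, d$sublineage)),
               unname(split(strains, grp)))
  expect_false(any(d$ambiguous))
  # brute-force: among all bipartitions, only the true one satisfies the rule
  gap <- 0.5
  valid <- list()
  for (mask in 1:(2^8 - 2)) {
    side <- as.logical(bitwAnd(mask, 2^(0:7)))
    if (!any(side) || all(side)) next
    within <- c(ani[side, side, drop = FALSE][upper.tri(matrix(0, sum(side), sum(side)))],
                ani[!side, !side, drop = FALSE][upper.tri(matrix(0, sum(!side), sum(!side)))])
    between <- ani[side, !side]
    if (length(within) && min(within) - max(between) >= gap)
      valid[[length(valid) + 1]] <- sort(strains[side])
  }
  valid <- unique(lapply(valid, function(v)
    if (strains[1] %in% v) v else sort(setdiff(strains, v))))
  expect_equal(length(valid), 1L)
  expect_equal(valid[[1]], strains[grp == 1])
})

test_that("a single strain forms one group and straddlers get flagged", {
  one <- matrix(100, 1, 1, dimnames = list("x", "x"))
  d1 <- delimitGroups(one)
  expect_equal(unname(d1$sublineage), "1.1")
  # a ninth strain nearly equidistant to both sublineages straddles the
  # separation band: it becomes its own (tentative) sublineage, flagged
  strains <- paste0("s", 1:9)
  ani <- matrix(96.6, 9, 9, dimnames = list(strains, strains))
  ani[1:4, 1:4] <- 99; ani[5:8, 5:8] <- 99
  ani[9, 1:4] <- ani[1:4, 9] <- 97.1
  ani[9, 5:8] <- ani[5:8, 9] <- 96.8
  diag(ani) <- 100
  d <- delimitGroups(ani)
  expect_true(d$ambiguous[["s9"]])
  expect_false(any(d$ambiguous[paste0("s", 1:8)]))
  expect_equal(length(unique(d$sublineage)), 3L)
})

test_that("the partition is invariant under strain-order permutation", {
  strains <- paste0("s", 1:6)
  ani <- matrix(96.8, 6, 6, dimnames = list(strains, strains))
  ani[1:3, 1:3] <- 99.2; ani[4:6, 4:6] <- 99.2
  diag(ani) <- 100
  d1 <- delimitGroups(ani)
  perm <- c(4, 2, 6, 1, 3, 5)
  d2 <- delimitGroups(ani[perm, perm])
  expect_identical(d1$sublineage[strains], d2$sublineage[strains])
  # missing pairs are an input error
  ani_na <- ani; ani_na[1, 2] <- ani_na[2, 1] <- NA
  expect_error(delimitGroups(ani_na), "incomplete")
})
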