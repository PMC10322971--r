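# Independent oracles shared by the synteny unit tests and the acceptance
# suite.

# independent chaining oracle: exhaustively grow maximal runs of anchors
# (sorted by idxA) where every adjacent pair is compatible at tolerance delta
# and the B-direction stays consistent
oracle_blocks <- function(anchors, delta) {
  n <- nrow(anchors)
  if (!n) return(integer(0))
  compatible <- function(i, j, dir) {
    gapA <- anchors$idxA[j] - anchors$idxA[i] - 1L
    dB <- anchors$idxB[j] - anchors$idxB[i]
    ok <- gapA <= delta && abs(dB) - 1L <= delta && dB != 0L &&
      anchors$ori[i] == anchors$ori[j] && sign(dB) == anchors$ori[i]
    if (ok && dir != 0L && sign(dB) != dir) ok <- FALSE
    list(ok = ok, dir = if (ok) sign(dB) else dir)
  }
  block <- integer(n); bid <- 1L; block[1] <- 1L; dir <- 0L
  i <- 1L
  while (i < n) {
    cc <- compatible(i, i + 1L, dir)
    if (cc$ok) {
      block[i + 1L] <- bid
      dir <- cc$dir
    } else {
      bid <- bid + 1L
      block[i + 1L] <- bid
      dir <- 0L
    }
    i <- i + 1L
  }
  block
}

oracle_coverage <- function(anchors, delta, n_genes) {
  bl <- oracle_blocks(anchors, delta)
  if (!length(bl)) return(0)
  sizes <- table(bl)
  sum(bl %in% as.integer(names(sizes)[sizes >= 2])) / n_genes
}

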