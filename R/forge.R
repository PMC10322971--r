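#' @importFrom GenomicRanges GRanges seqnames start end strand start<- end<-
#' @importFrom stats rbinom rpois median mad sd setNames
NULL

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.baseProbs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

.randChars <- function(n, gc) {
  if (n <= 0L) return(character())
  sample(.BASES, n, replace = TRUE, prob = .baseProbs(gc))
}

.CODONS <- local({
  b <- c("A", "C", "G", "T")
  cs <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L,
              paste, collapse = "")
  cs[!cs %in% c("TAA", "TAG", "TGA")]
})
.CODON_GC <- vapply(strsplit(.CODONS, ""), function(x)
  sum(x %in% c("G", "C")), integer(1))

# codon-structured ORF: ATG + non-stop codons + TAA. After sampling, body
# codons are swapped toward the target GC so gene-level composition tracks
# the requested value closely (makes planted GC offsets a clean signal).
.randomORF <- function(len, gc) {
  n_codons <- max(3L, len %/% 3L)
  p <- .baseProbs(gc)
  w <- p[substr(.CODONS, 1, 1)] * p[substr(.CODONS, 2, 2)] *
    p[substr(.CODONS, 3, 3)]
  body <- sample(.CODONS, n_codons - 2L, replace = TRUE, prob = w)
  gc_now <- sum(.CODON_GC[match(body, .CODONS)]) + 1L   # ATG + TAA add 1 GC
  total <- 3L * n_codons
  target <- round(gc * total)
  for (it in seq_len(1200L)) {
    if (abs(gc_now - target) < 2L) break
    i <- sample.int(length(body), 1L)
    old_gc <- .CODON_GC[match(body[i], .CODONS)]
    # graded swaps (one GC step at a time, any codon of the next class)
    # keep composition adjustment from generating low-complexity runs
    if (gc_now < target && old_gc < 3L) {
      body[i] <- sample(.CODONS[.CODON_GC == old_gc + 1L], 1L)
      gc_now <- gc_now + 1L
    } else if (gc_now > target && old_gc > 0L) {
      body[i] <- sample(.CODONS[.CODON_GC == old_gc - 1L], 1L)
      gc_now <- gc_now - 1L
    }
  }
  unlist(strsplit(c("ATG", body, "TAA"), "", fixed = TRUE), use.names = FALSE)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# ---------------------------------------------------------------------------
# substitution machinery (ORF-preserving inside CDS)
# ---------------------------------------------------------------------------

# geneAt: integer vector, 0 = unconstrained, otherwise row of genesDF (CDS)
.geneAtVector <- function(L, genesDF) {
  geneAt <- integer(L)
  cds <- which(genesDF$type == "CDS")
  for (i in cds) geneAt[genesDF$start[i]:genesDF$end[i]] <- i
  geneAt
}

# Substitute at `n` uniformly chosen sites. Within a CDS the substitution is
# accepted only if the codon stays non-stop and the start/stop codons are
# untouched (purifying selection keeps ORFs translatable, so identity
# oracles on proteins stay exact). Returns list(chars, log).
.applyMutations <- function(chars, n, genesDF, geneAt) {
  L <- length(chars)
  if (n <= 0L) return(list(chars = chars, log = .emptyMutLog()))
  n <- min(n, L)
  keep_pos <- integer(0); keep_from <- character(0); keep_to <- character(0)
  accepted <- 0L; attempts <- 0L
  while (accepted < n && attempts < 20L * n) {
    attempts <- attempts + 1L
    p <- sample.int(L, 1L)
    old <- chars[p]
    alts <- setdiff(.BASES, old)
    gi <- geneAt[p]
    if (gi == 0L) {
      newb <- sample(alts, 1L)
    } else {
      s <- genesDF$start[gi]; e <- genesDF$end[gi]
      o <- if (genesDF$strand[gi] == "+") p - s else e - p      # 0-based ORF offset
      ci <- o %/% 3L
      n_codons <- (e - s + 1L) %/% 3L
      if (ci == 0L || ci == n_codons - 1L) next                  # protect start/stop
      gpos <- if (genesDF$strand[gi] == "+") s + 3L * ci + 0:2 else e - 3L * ci - (0:2)
      codon_chars <- chars[gpos]
      if (genesDF$strand[gi] == "-") codon_chars <- unname(.COMP[codon_chars])
      cp <- o %% 3L + 1L
      newb <- NA_character_
      for (alt in sample(alts)) {
        cc <- codon_chars
        cc[cp] <- if (genesDF$strand[gi] == "+") alt else unname(.COMP[alt])
        if (!paste(cc, collapse = "") %in% .STOPS) { newb <- alt; break }
      }
      if (is.na(newb)) next
    }
    chars[p] <- newb
    accepted <- accepted + 1L
    keep_pos <- c(keep_pos, p); keep_from <- c(keep_from, old); keep_to <- c(keep_to, newb)
  }
  list(chars = chars,
       log = data.frame(pos = keep_pos, from = keep_from, to = keep_to,
                        stringsAsFactors = FALSE))
}

.emptyMutLog <- function()
  data.frame(pos = integer(), from = character(), to = character(),
             stringsAsFactors = FALSE)

# ---------------------------------------------------------------------------
# ancestral layout
# ---------------------------------------------------------------------------

.TRNA_NAMES <- c("tRNA-Ala-GGC", "tRNA-Arg-TCT", "tRNA-Thr-TGT",
                 "tRNA-Arg-CCT", "tRNA-Ala-CGC", "tRNA-Gly-CCC")
.TRNA_LEN <- 76L

# lay out non-overlapping features with 50-200 bp spacers; a handful of tRNA
# genes (canonical island integration sites) interspersed among the CDS
.ancestralLayout <- function(L, gene_mean) {
  rows <- list(); pos <- 1L; i <- 0L; trna_left <- .TRNA_NAMES
  repeat {
    gap <- sample(50:200, 1L)
    i <- i + 1L
    is_trna <- length(trna_left) > 0L && i %% 13L == 4L
    glen <- if (is_trna) .TRNA_LEN else {
      g <- round(gene_mean * stats::runif(1, 0.9, 1.1))
      max(300L, as.integer(3L * (g %/% 3L)))
    }
    s <- pos + gap
    e <- s + glen - 1L
    if (e + 200L > L) break
    rows[[i]] <- data.frame(
      start = s, end = e, strand = sample(c("+", "-"), 1L),
      type = if (is_trna) "tRNA" else "CDS",
      product = if (is_trna) trna_left[1L] else "hypothetical protein",
      stringsAsFactors = FALSE)
    if (is_trna) trna_left <- trna_left[-1L]
    pos <- e + 1L
  }
  df <- do.call(rbind, rows)
  df$family <- ifelse(df$type == "CDS",
                      sprintf("fam%04d", cumsum(df$type == "CDS")), NA)
  df
}

.ancestralSequence <- function(L, layout, gc) {
  chars <- .randChars(L, gc)
  for (i in seq_len(nrow(layout))) {
    if (layout$type[i] != "CDS") next
    orf <- .randomORF(layout$end[i] - layout$start[i] + 1L, gc)
    if (layout$strand[i] == "-") orf <- rev(unname(.COMP[orf]))
    chars[layout$start[i]:layout$end[i]] <- orf
  }
  chars
}

# Assemble an AnnotatedGenome from a base character vector and a feature
# layout (single chromosome contig).
.assembleGenome <- function(strain, chars, layout, contig = NULL) {
  if (is.null(contig)) contig <- paste0(strain, "_chr")
  seqs <- DNAStringSet(paste(chars, collapse = ""))
  names(seqs) <- contig
  lt <- sprintf("%s_g%04d", strain, seq_len(nrow(layout)))
  gr <- GRanges(contig, IRanges(layout$start, layout$end), strand = layout$strand)
  mcols(gr)$locus_tag <- lt
  mcols(gr)$type <- layout$type
  mcols(gr)$family <- layout$family
  mcols(gr)$product <- layout$product
  mcols(gr)$label <- if (!is.null(layout$label)) layout$label else
    ifelse(layout$type == "CDS", "backbone", "tRNA")
  prot <- .translateCDS(seqs[[1]], layout, lt)
  AnnotatedGenome(strain, seqs, gr, prot)
}

.translateCDS <- function(dna, layout, locus_tags) {
  cds <- which(layout$type == "CDS")
  if (!length(cds)) return(AAStringSet())
  segs <- DNAStringSet(lapply(cds, function(i) {
    s <- subseq(dna, layout$start[i], layout$end[i])
    if (layout$strand[i] == "-") s <- reverseComplement(s)
    subseq(s, 1L, length(s) - 3L)                       # drop stop codon
  }))
  aa <- translate(segs, if.fuzzy.codon = "solve")
  names(aa) <- locus_tags[cds]
  aa
}

.emptyTruth <- function()
  data.frame(strain = character(), element_id = character(), kind = character(),
             contig = character(), segment = integer(), start = integer(),
             end = integer(), strand = character(),
             attL_start = integer(), attL_end = integer(),
             attR_start = integer(), attR_end = integer(),
             dr_seq = character(), genes = character(),
             gene_families = character(), integration_site = character(),
             stringsAsFactors = FALSE)

#' Empty planted-element truth table
#'
#' Returns the zero-row data.frame whose columns define the truth-record
#' schema used throughout the forge (one row per element segment).
#' @return a zero-row data.frame.
#' @export
emptyTruth <- .emptyTruth

#' Forge a two-sublineage species complex
#'
#' Generates an ancestral chromosome (non-overlapping codon-structured CDS
#' with 50-200 bp spacers and a handful of tRNA genes), derives two
#' sublineage ancestors and the member strains by ORF-preserving random
#' substitution, and returns the bundle with per-strain mutation logs as the
#' oracle for downstream identity checks. Divergence is substitution-only so
#' all coordinates are shared across strains until elements are planted.
#'
#' @param config a [ComplexConfig].
#' @return a [SpeciesComplex]; strains are named `A1..An` / `B1..Bn` and
#'   carry an empty truth table.
#' @examples
#' cx <- forgeComplex(complexConfig(n_strains_per_group = 2,
#'                                  ancestral_length = 20000, rng_seed = 1))
#' cx
#' @export
forgeComplex <- function(config) {
  stopifnot(is(config, "ComplexConfig"))
  validObject(config)
  set.seed(.splitSeed(config@rng_seed, 0L))
  L <- config@ancestral_length
  layout <- .ancestralLayout(L, config@gene_length_mean)
  anc <- .ancestralSequence(L, layout, config@gc_background)
  geneAt <- .geneAtVector(L, layout)

  rb <- (config@between_group_divergence - config@within_group_divergence) / 2
  rw <- config@within_group_divergence / 2
  genomes <- list(); groups <- character(); mutlog <- list()
  gi <- 0L
  for (grp in c("A", "B")) {
    gi <- gi + 1L
    set.seed(.splitSeed(config@rng_seed, gi))
    ga <- .applyMutations(anc, rbinom(1L, L, rb), layout, geneAt)
    for (j in seq_len(config@n_strains_per_group)) {
      strain <- paste0(grp, j)
      set.seed(.splitSeed(config@rng_seed, 100L * gi + j))
      st <- .applyMutations(ga$chars, rbinom(1L, L, rw), layout, geneAt)
      genomes[[strain]] <- .assembleGenome(strain, st$chars, layout)
      groups[strain] <- grp
      mutlog[[strain]] <- rbind(ga$log, st$log)
    }
  }
  ancset <- DNAStringSet(paste(anc, collapse = ""))
  names(ancset) <- "ancestor"
  new("SpeciesComplex", genomes = genomes, groups = groups,
      truth = .emptyTruth(), ancestral = ancset, mutlog = mutlog,
      config = config)
}

# ---------------------------------------------------------------------------
# element planting
# ---------------------------------------------------------------------------

# deterministic cargo builder: gene layout + sequence for one element;
# identical (spec, seed) give identical cargo wherever planted
.buildCargo <- function(spec, gc_background, seed) {
  set.seed(.splitSeed(seed, 7L))
  gc <- min(0.95, max(0.05, gc_background + spec@cargo_gc_offset))
  n <- spec@n_genes
  glen <- max(150L, as.integer(3L * ((spec@length * 0.85 / n) %/% 3L)))
  gap <- max(30L, as.integer((spec@length - n * glen) / (n + 1L)))
  labels <- c(spec@module_genes, rep("cargo", max(0L, n - length(spec@module_genes))))[seq_len(n)]
  rows <- list(); pos <- 1L; chars <- character(0)
  for (i in seq_len(n)) {
    # per-gene streams: gene i's content is a function of (seed, i) alone,
    # so a truncated spec sharing the element id emits identical leading genes
    set.seed(.splitSeed(seed, 200L + i))
    chars <- c(chars, .randChars(gap, gc))
    s <- pos + gap
    set.seed(.splitSeed(seed, 100L + i))
    orf <- .randomORF(glen, gc)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") orf <- rev(unname(.COMP[orf]))
    chars <- c(chars, orf)
    rows[[i]] <- data.frame(
      start = s, end = s + glen - 1L, strand = strand, type = "CDS",
      product = labels[i], label = labels[i],
      family = sprintf("%s_f%02d", spec@element_id, i),
      stringsAsFactors = FALSE)
    pos <- s + glen
  }
  chars <- c(chars, .randChars(gap, gc))
  list(chars = chars, layout = do.call(rbind, rows))
}

.findIntegrationSite <- function(genome, site) {
  g <- genome@genes
  hit <- if (startsWith(site, "family:")) {
    which(!is.na(g$family) & g$family == sub("^family:", "", site))
  } else {
    which(g$locus_tag == site | g$product == site)
  }
  if (!length(hit))
    stop("unknown integration site: ", site)
  hit[1L]
}

#' Plant a mobile element into a genome
#'
#' Integrated kinds (ICE/GI/Tn/IS) are inserted immediately downstream of the
#' integration-site feature with a target-site direct repeat of
#' `dr_length` bp duplicated at both element termini (attL/attR); plasmid
#' specs instead emit a separate circular replicon and leave the chromosome
#' untouched. Cargo sequence is generated at the background GC plus
#' `cargo_gc_offset` and is a deterministic function of `(spec, seed)`, so
#' the same element planted in several strains yields identical cargo (and
#' hence shared protein families).
#'
#' @param genome an [AnnotatedGenome].
#' @param spec an [ElementSpec].
#' @param seed integer seed controlling cargo generation.
#' @param gc_background backbone GC fraction the cargo offset is relative to.
#' @return list with components `genome` (modified [AnnotatedGenome]) and
#'   `truth` (one-row truth data.frame).
#' @export
plantElement <- function(genome, spec, seed, gc_background = 0.55) {
  stopifnot(is(genome, "AnnotatedGenome"), is(spec, "ElementSpec"))
  validObject(spec)
  cargo <- .buildCargo(spec, gc_background, seed)
  E <- cargo$chars
  lenE <- length(E)
  strain <- genome@strain

  if (spec@kind == "plasmid") {
    ctg <- paste0("p_", spec@element_id)
    pseq <- DNAStringSet(paste(E, collapse = ""))
    names(pseq) <- ctg
    lt <- sprintf("%s_%s_g%02d", strain, spec@element_id, seq_len(nrow(cargo$layout)))
    gr <- GRanges(ctg, IRanges(cargo$layout$start, cargo$layout$end),
                  strand = cargo$layout$strand)
    mcols(gr)$locus_tag <- lt
    mcols(gr)$type <- cargo$layout$type
    mcols(gr)$family <- cargo$layout$family
    mcols(gr)$product <- cargo$layout$product
    mcols(gr)$label <- cargo$layout$label
    prot <- .translateCDS(pseq[[1L]], cargo$layout, lt)
    g2 <- AnnotatedGenome(strain,
                          c(genome@seqs, pseq),
                          suppressWarnings(c(genome@genes, gr)),
                          c(genome@proteins, prot),
                          genome@depth,
                          c(genome@circular, setNames(TRUE, ctg)))
    tr <- .emptyTruth()[0, ]
    tr[1L, ] <- list(strain, spec@element_id, "plasmid", ctg, 1L, 1L, lenE, "+",
                     NA_integer_, NA_integer_, NA_integer_, NA_integer_,
                     NA_character_, paste(lt, collapse = ","),
                     paste(cargo$layout$family, collapse = ","), "")
    return(list(genome = g2, truth = tr))
  }

  si <- .findIntegrationSite(genome, spec@integration_site)
  ctg <- as.character(seqnames(genome@genes)[si])
  p0 <- end(genome@genes)[si]
  dr <- spec@dr_length
  chars <- strsplit(as.character(genome@seqs[[ctg]]), "", fixed = TRUE)[[1L]]
  L0 <- length(chars)
  if (p0 + dr > L0) stop("integration site too close to contig end")
  same <- as.character(seqnames(genome@genes)) == ctg
  nxt <- start(genome@genes)[same & start(genome@genes) > p0]
  if (dr > 0L && length(nxt) && min(nxt) <= p0 + dr)
    stop("direct repeat region overlaps the next gene; reduce dr_length")
  D <- if (dr > 0L) chars[(p0 + 1L):(p0 + dr)] else character(0)
  if (dr > 0L) {
    # pin the repeat to exactly dr bp: the element's first base must differ
    # from the base following the target site, and its last base from the
    # base preceding it, so no chance extension enlarges the repeat
    after <- if (p0 + dr < L0) chars[p0 + dr + 1L] else "A"
    if (E[1L] == after) E[1L] <- setdiff(.BASES, after)[1L]
    if (E[lenE] == chars[p0]) E[lenE] <- setdiff(.BASES, chars[p0])[1L]
  }
  ins_point <- p0 + dr
  newchars <- c(chars[seq_len(ins_point)], E, D,
                if (ins_point < L0) chars[(ins_point + 1L):L0] else character(0))
  IL <- lenE + dr

  # shift downstream annotations, then add cargo genes
  g <- genome@genes
  shift_idx <- which(as.character(seqnames(g)) == ctg & start(g) > ins_point)
  if (length(shift_idx)) {
    end(g)[shift_idx] <- end(g)[shift_idx] + IL
    start(g)[shift_idx] <- start(g)[shift_idx] + IL
  }
  lay <- cargo$layout
  lt <- sprintf("%s_%s_g%02d", strain, spec@element_id, seq_len(nrow(lay)))
  gr <- GRanges(ctg, IRanges(lay$start + ins_point, lay$end + ins_point),
                strand = lay$strand)
  mcols(gr)$locus_tag <- lt
  mcols(gr)$type <- lay$type
  mcols(gr)$family <- lay$family
  mcols(gr)$product <- lay$product
  mcols(gr)$label <- lay$label
  seqs <- genome@seqs
  seqs[[ctg]] <- DNAString(paste(newchars, collapse = ""))
  prot_new <- .translateCDS(seqs[[ctg]], transform(lay, start = start + ins_point,
                                                   end = end + ins_point), lt)
  gall <- suppressWarnings(c(g, gr))
  gall <- gall[order(as.character(seqnames(gall)), start(gall))]
  g2 <- AnnotatedGenome(strain, seqs, gall,
                        c(genome@proteins, prot_new),
                        genome@depth, genome@circular)
  el_start <- if (dr > 0L) p0 + 1L else p0 + 1L
  el_end <- p0 + dr + lenE + dr
  tr <- .emptyTruth()[0, ]
  tr[1L, ] <- list(strain, spec@element_id, spec@kind, ctg, 1L,
                   el_start, el_end, "+",
                   if (dr > 0L) p0 + 1L else NA_integer_,
                   if (dr > 0L) p0 + dr else NA_integer_,
                   if (dr > 0L) p0 + dr + lenE + 1L else NA_integer_,
                   if (dr > 0L) p0 + 2L * dr + lenE else NA_integer_,
                   if (dr > 0L) paste(D, collapse = "") else NA_character_,
                   paste(lt, collapse = ","),
                   paste(lay$family, collapse = ","),
                   spec@integration_site)
  list(genome = g2, truth = tr)
}

# shift truth coordinates of earlier-planted elements after a new insertion
.shiftTruth <- function(truth, strain, ctg, ins_point, IL) {
  if (!nrow(truth)) return(truth)
  hit <- truth$strain == strain & truth$contig == ctg & truth$start > ins_point
  for (col in c("start", "end", "attL_start", "attL_end", "attR_start", "attR_end"))
    truth[[col]][hit] <- truth[[col]][hit] + IL
  truth
}

#' Plant one element into several strains of a complex
#'
#' Wrapper over [plantElement()] that keeps the complex-level truth table
#' coherent (coordinates of previously planted elements are shifted when a
#' new element lands upstream of them).
#'
#' @param complex a [SpeciesComplex].
#' @param spec an [ElementSpec].
#' @param strains strain names to plant into.
#' @param seed integer cargo seed (same seed -> identical cargo everywhere).
#' @return the updated [SpeciesComplex].
#' @export
plantElements <- function(complex, spec, strains, seed) {
  stopifnot(all(strains %in% names(complex@genomes)))
  truth <- complex@truth
  for (s in strains) {
    res <- plantElement(complex@genomes[[s]], spec, seed,
                        gc_background = complex@config@gc_background)
    if (spec@kind != "plasmid") {
      ins_point <- res$truth$start[1L] + spec@dr_length - 1L
      IL <- res$truth$end[1L] - res$truth$start[1L] + 1L - spec@dr_length
      truth <- .shiftTruth(truth, s, res$truth$contig[1L], ins_point, IL)
    }
    complex@genomes[[s]] <- res$genome
    truth <- rbind(truth, res$truth)
  }
  complex@truth <- truth
  complex
}

# ---------------------------------------------------------------------------
# draft fragmentation
# ---------------------------------------------------------------------------

#' Fragment a genome into a draft assembly
#'
#' Splits the (single) chromosome contig at intergenic positions into
#' `n_breaks + 1` contigs of at least `min_contig` bp; plasmid replicons are
#' carried through unchanged. Per-contig coordinates are remapped.
#'
#' @param genome an [AnnotatedGenome] whose chromosome is a single contig.
#' @param n_breaks number of breakpoints (>= 0).
#' @param min_contig minimum contig length.
#' @param seed integer seed for breakpoint choice.
#' @param at optional explicit breakpoint positions (1-based; the new contig
#'   starts at `at + 1`); must fall between genes. Overrides random choice.
#' @return list with `genome` (multi-contig [AnnotatedGenome]) and `map`
#'   (data.frame old_contig/old_start/old_end/new_contig/offset) for
#'   coordinate remapping of external records.
#' @export
makeDraft <- function(genome, n_breaks, min_contig = 1000L, seed = 1L, at = NULL) {
  stopifnot(n_breaks >= 0L)
  chrom <- names(genome@seqs)[!genome@circular][1L]
  L <- BiocGenerics::width(genome@seqs)[match(chrom, names(genome@seqs))]
  if (min_contig * (n_breaks + 1L) > L)
    stop("infeasible fragmentation: min_contig * (n_breaks+1) exceeds genome length")
  if (n_breaks == 0L && is.null(at)) {
    map <- data.frame(old_contig = chrom, old_start = 1L, old_end = L,
                      new_contig = chrom, offset = 0L, stringsAsFactors = FALSE)
    return(list(genome = genome, map = map))
  }
  g <- genome@genes[as.character(seqnames(genome@genes)) == chrom]
  g <- g[order(start(g))]
  gaps <- data.frame(from = head(end(g), -1L) + 1L, to = tail(start(g), -1L) - 1L)
  gaps <- gaps[gaps$to >= gaps$from, ]
  cand <- as.integer((gaps$from + gaps$to) %/% 2L)
  if (is.null(at)) {
    set.seed(.splitSeed(seed, 3L))
    ok <- FALSE
    for (try in seq_len(500L)) {
      if (length(cand) < n_breaks) break
      br <- sort(sample(cand, n_breaks))
      pieces <- diff(c(0L, br, L))
      if (all(pieces >= min_contig)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place breakpoints satisfying min_contig")
  } else {
    br <- sort(as.integer(at))
    inside <- vapply(br, function(p) any(p >= start(g) & p < end(g)), logical(1))
    if (any(inside)) stop("explicit breakpoints must fall between genes")
  }
  bounds <- data.frame(s = c(1L, br + 1L), e = c(br, L))
  strain <- genome@strain
  new_names <- sprintf("%s_c%02d", strain, seq_len(nrow(bounds)))
  chrom_seq <- genome@seqs[[chrom]]
  pieces <- DNAStringSet(lapply(seq_len(nrow(bounds)), function(i)
    subseq(chrom_seq, bounds$s[i], bounds$e[i])))
  names(pieces) <- new_names
  # remap genes
  gall <- genome@genes
  on_chrom <- as.character(seqnames(gall)) == chrom
  gc_keep <- gall[!on_chrom]
  gg <- gall[on_chrom]
  piece_of <- findInterval(start(gg), bounds$s)
  newg <- GRanges(new_names[piece_of],
                  IRanges(start(gg) - bounds$s[piece_of] + 1L,
                          end(gg) - bounds$s[piece_of] + 1L),
                  strand = strand(gg))
  mcols(newg) <- mcols(gg)
  other_seqs <- genome@seqs[names(genome@seqs) != chrom]
  seqs <- c(pieces, other_seqs)
  circular <- c(setNames(rep(FALSE, length(new_names)), new_names),
                genome@circular[names(other_seqs)])
  depth <- genome@depth
  if (length(depth) && chrom %in% names(depth)) {
    dchr <- depth[[chrom]]
    depth[[chrom]] <- NULL
    for (i in seq_len(nrow(bounds)))
      depth[[new_names[i]]] <- dchr[bounds$s[i]:bounds$e[i]]
  }
  gboth <- suppressWarnings(c(newg, gc_keep))
  gboth <- gboth[order(as.character(seqnames(gboth)), start(gboth))]
  g2 <- AnnotatedGenome(strain, seqs, gboth, genome@proteins, depth, circular)
  map <- data.frame(old_contig = chrom, old_start = bounds$s, old_end = bounds$e,
                    new_contig = new_names, offset = bounds$s - 1L,
                    stringsAsFactors = FALSE)
  list(genome = g2, map = map)
}

#' Remap a truth table through a draft-fragmentation map
#'
#' Splits element truth rows whose span crosses a breakpoint into multiple
#' segment rows with per-contig coordinates. att coordinates are remapped
#' when they stay on one contig, otherwise set to NA.
#'
#' @param truth truth data.frame (see [emptyTruth()]).
#' @param map the `map` component returned by [makeDraft()].
#' @param strain strain whose rows to remap.
#' @return the remapped truth data.frame.
#' @export
remapTruth <- function(truth, map, strain) {
  if (!nrow(truth)) return(truth)
  keep <- truth[truth$strain != strain | !(truth$contig %in% map$old_contig), ]
  todo <- truth[truth$strain == strain & truth$contig %in% map$old_contig, ]
  out <- list(keep)
  for (i in seq_len(nrow(todo))) {
    row <- todo[i, ]
    segs <- map[map$old_end >= row$start & map$old_start <= row$end, , drop = FALSE]
    remap1 <- function(p) {
      j <- which(map$old_start <= p & map$old_end >= p)
      if (length(j) != 1L) return(c(NA, NA))
      c(j, p - map$offset[j])
    }
    for (k in seq_len(nrow(segs))) {
      r2 <- row
      r2$segment <- k
      r2$contig <- segs$new_contig[k]
      r2$start <- max(row$start, segs$old_start[k]) - segs$offset[k]
      r2$end <- min(row$end, segs$old_end[k]) - segs$offset[k]
      for (pre in c("attL", "attR")) {
        ps <- row[[paste0(pre, "_start")]]; pe <- row[[paste0(pre, "_end")]]
        if (is.na(ps)) next
        a <- remap1(ps); b <- remap1(pe)
        if (!is.na(a[1]) && !is.na(b[1]) && a[1] == b[1] &&
            segs$new_contig[k] == map$new_contig[a[1]]) {
          r2[[paste0(pre, "_start")]] <- a[2]
          r2[[paste0(pre, "_end")]] <- b[2]
        } else {
          r2[[paste0(pre, "_start")]] <- NA_integer_
          r2[[paste0(pre, "_end")]] <- NA_integer_
        }
      }
      out[[length(out) + 1L]] <- r2
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fragment selected strains of a complex into drafts
#'
#' @param complex a [SpeciesComplex].
#' @param strains strains to fragment.
#' @param n_breaks breaks per strain.
#' @param min_contig minimum contig length.
#' @param seed integer seed.
#' @param at optional named list of explicit breakpoints per strain.
#' @return the updated [SpeciesComplex] with remapped truth.
#' @export
draftComplex <- function(complex, strains, n_breaks, min_contig = 1000L,
                         seed = 1L, at = NULL) {
  for (s in strains) {
    res <- makeDraft(complex@genomes[[s]], n_breaks, min_contig,
                     seed = .splitSeed(seed, match(s, names(complex@genomes))),
                     at = if (!is.null(at)) at[[s]] else NULL)
    complex@genomes[[s]] <- res$genome
    complex@truth <- remapTruth(complex@truth, res$map, s)
  }
  complex
}

# ---------------------------------------------------------------------------
# resequencing evidence simulation
# ---------------------------------------------------------------------------

#' Simulate resequencing evidence (depth track + junction reads)
#'
#' Produces a per-base Poisson depth track (`depth` over linear contigs,
#' `depth * plasmid_fold` over circular replicons) and, for each requested IS
#' transposition event, soft-clipped reads spanning both new junctions at the
#' configured mutant allele fraction plus wild-type reads spanning the
#' unmodified site. Reads are SAM-convention records in a data.frame
#' (qname, flag, rname, pos, mapq, cigar, seq) aligned to the *reference*
#' genome.
#'
#' Event rows: `is_family`, `contig`, `pos` (last reference base before the
#' target-site duplication), `dr_len`, `allele_fraction`.
#'
#' @param genome reference [AnnotatedGenome].
#' @param events data.frame of IS insertion events (possibly zero rows).
#' @param is_library named [Biostrings::DNAStringSet] of IS sequences.
#' @param depth mean chromosome depth (fold coverage).
#' @param plasmid_fold depth multiplier for circular replicons.
#' @param read_len read length (bp).
#' @param seed integer seed.
#' @return list with `reads` (data.frame), `depth` (per-contig numeric list)
#'   and `events` (the input annotated with simulated read counts).
#' @export
simulateReseq <- function(genome, events, is_library, depth = 30,
                          plasmid_fold = 1, read_len = 150L, seed = 1L) {
  set.seed(.splitSeed(seed, 11L))
  dt <- list()
  for (ctg in names(genome@seqs)) {
    lam <- depth * if (genome@circular[[ctg]]) plasmid_fold else 1
    dt[[ctg]] <- rpois(BiocGenerics::width(genome@seqs)[match(ctg, names(genome@seqs))],
                       lam)
  }
  reads <- list()
  qn <- 0L
  mkread <- function(rname, pos, cigar, sq) {
    qn <<- qn + 1L
    data.frame(qname = sprintf("r%06d", qn), flag = 0L, rname = rname,
               pos = as.integer(pos), mapq = 60L, cigar = cigar, seq = sq,
               stringsAsFactors = FALSE)
  }
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (!ev$contig %in% names(genome@seqs))
        stop("event contig not in genome: ", ev$contig)
      ctgseq <- genome@seqs[[ev$contig]]
      Lc <- length(ctgseq)
      if (ev$pos < read_len || ev$pos + ev$dr_len + read_len > Lc)
        stop("event position outside usable genome range")
      if (!ev$is_family %in% names(is_library))
        stop("event IS family not in library: ", ev$is_family)
      isseq <- is_library[[ev$is_family]]
      Lis <- length(isseq)
      n <- rpois(1L, depth)
      mut <- rbinom(1L, n, ev$allele_fraction)
      events$n_span[i] <- n
      events$n_mut[i] <- mut
      p <- ev$pos; d <- ev$dr_len
      for (m_i in seq_len(mut)) {
        s <- sample(30:70, 1L)
        m <- read_len - s
        if (m_i %% 2L == 1L) {   # left junction: ref ... then IS start
          sq <- paste0(as.character(subseq(ctgseq, p + d - m + 1L, p + d)),
                       as.character(subseq(isseq, 1L, s)))
          reads[[length(reads) + 1L]] <-
            mkread(ev$contig, p + d - m + 1L, sprintf("%dM%dS", m, s), sq)
        } else {                 # right junction: IS end then ref
          sq <- paste0(as.character(subseq(isseq, Lis - s + 1L, Lis)),
                       as.character(subseq(ctgseq, p + 1L, p + m)))
          reads[[length(reads) + 1L]] <-
            mkread(ev$contig, p + 1L, sprintf("%dS%dM", s, m), sq)
        }
      }
      for (w_i in seq_len(n - mut)) {
        st <- p - read_len + sample(10:(read_len - 10L), 1L) + d %/% 2L
        st <- max(1L, min(st, Lc - read_len + 1L))
        sq <- as.character(subseq(ctgseq, st, st + read_len - 1L))
        reads[[length(reads) + 1L]] <-
          mkread(ev$contig, st, sprintf("%dM", read_len), sq)
      }
    }
  }
  reads <- if (length(reads)) do.call(rbind, reads) else
    data.frame(qname = character(), flag = integer(), rname = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               seq = character(), stringsAsFactors = FALSE)
  list(reads = reads, depth = dt, events = events)
}
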