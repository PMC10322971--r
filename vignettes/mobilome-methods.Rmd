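---
title: "Methods: sublineage delimitation and mobile-element discovery in panMGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sublineage delimitation and mobile-element discovery in panMGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

panMGE implements an integrated comparative-genomics workflow for sets of
closely related bacterial strains: genome relatedness and sublineage
delimitation, synteny coverage, pangenome compartmentalization, seed-driven
discovery of integrated mobile genetic elements (MGEs) in draft genomes,
episomal-element handling, and insertion-sequence (IS) dynamics from
resequencing evidence. This vignette records the models behind each stage,
the tunable parameters, and the design decisions taken where several
reasonable choices existed.

## The synthetic forge: what it emulates, and what it does not

Every stage of the pipeline is validated against forged species complexes
with known ground truth (`forgeComplex()`, `plantElement()`, `makeDraft()`,
`simulateReseq()`). The forge emulates the features the pipeline's logic
actually keys on:

* **Clonal two-sublineage structure.** An ancestral chromosome is laid out
  as non-overlapping, codon-structured CDS (mean length 900 bp, ±10%
  jitter) separated by 50–200 bp spacers, with a handful of 76-bp tRNA
  genes interspersed as canonical island integration sites. Two sublineage
  ancestors and their member strains are derived by random substitution;
  the defaults (0.005 within-sublineage pairwise divergence, 0.03 between)
  put within-group identity near 99.5% and between-group identity near 97%,
  the regime in which sublineage structure is real but both groups remain
  one genomic species.
* **ORF-preserving substitution.** Substitutions that would create an
  internal stop codon, or hit a start/stop codon, are resampled (a crude
  purifying selection). This keeps every protein translatable, so protein
  identity oracles are exact, and the per-strain substitution log replays
  byte-identically onto the ancestral sequence — the truth oracle for all
  identity computations.
* **Composition-controlled genes.** Codon sampling is followed by a swap
  loop that drives each gene's GC content to within ~2 bases of its target,
  so a planted cargo GC offset of ±4–5% is a clean, detectable signal
  rather than being drowned in sampling noise.
* **Element planting with target-site duplication.** Integrated elements
  are inserted downstream of their integration feature with the `dr_length`
  bp that follow the site duplicated at both termini (attL/attR); the
  element's edge bases are adjusted to differ from the flanking bases so
  the repeat present in the genome is exactly the planted one. Plasmid
  specs emit a separate circular replicon instead. Cargo is a deterministic
  function of `(spec, seed)`, gene by gene, so one element planted in
  several strains yields identical cargo and therefore shared protein
  families — which is what makes the cargo flexible/exclusive in the
  pangenome, exactly the signal boundary inference uses.
* **Draft fragmentation** at intergenic positions, with truth records
  remapped (an element crossing a break becomes a two-segment record).
* **Resequencing evidence**: per-base Poisson depth (circular replicons at
  `depth × plasmid_fold`), soft-clipped junction reads for planted IS
  insertions at a configurable mutant allele fraction, and wild-type
  spanning reads, all as SAM-convention records.

Deliberately **not** emulated: sequencing error models, indel divergence in
the backbone (substitution-only keeps identity oracles exact; indels occur
only inside planted cargo, where no oracle needs them), repeat-driven
misassembly, horizontal transfer into the backbone, and annotation error.
Passing tests therefore demonstrate correctness of the pipeline's logic
under clean signals; on real drafts the limiting factors (assembly
fragmentation inside repeats, mis-annotation) are upstream of this package.

Default problem sizes throughout the validation suite — 24–30 kb
chromosomes, four strains per sublineage, 3–8-gene elements — are the
package's desk-scale study conditions: large enough that every stage sees
multi-gene context, fragments, and both compartments, and small enough that
the entire suite re-runs in minutes on one CPU. The statistics computed are
size-free (identities, fractions, rates), so nothing in the logic depends
on these sizes.

## Relatedness: fragment ANI and digital DDH

`anibPair()` chops the query into 1020-bp fragments and places each on the
subject with a k-mer-seeded (k = 16), ungapped extension aligner; hits are
retained at ≥30% identity over ≥70% fragment coverage, ANI is the mean
identity of retained hits, and both directions are averaged. The 1020/30/70
convention matches the standard fragment-based ANI formulation. The aligner
is deliberately ungapped: the package's validation substrate is
substitution-only, so a correct placement is ungapped by construction, and
mismatch counting (`neditStartingAt`) is exact. Placements whose full-length
identity falls below 0.9 are trimmed to their best-scoring contiguous
segment (match +1 / mismatch −2, vectorized maximum-subarray) — the HSP a
local aligner would report — so fragments straddling an element/backbone
junction contribute only their homologous part. Clean placements are left
untrimmed so retained identities equal the Hamming count. The backend is
pluggable in the sense that every consumer goes through the same placement
contract (contig, start, aligned length, mismatches).

`ddhPair()` pools the retained fragment placements of both directions as
HSPs and computes the distance d = 1 − (summed identical bases / summed HSP
length). The digital DDH estimate is a logistic transform of d. The source
method's regression coefficients are not restated in the literature we
reproduce, so the package calibrates the logistic from the two published
anchor points of the method — dDDH 70% at d = 0.0359 and 79% at d = 0.0250
— and stores them in a config object (`ddhTransform()`), overridable when a
user has the original coefficients. A consequence of the two-anchor
logistic is that self-comparisons map to ≈91.8% rather than 100%; the
distance itself is exactly 0 on self, and all threshold behavior (70%/79%)
is anchored exactly.

`delimitGroups()` calls species as connected components of the graph
joining pairs above ANI 96 (and dDDH 70 when supplied) — components can be
held together transitively, in which case member strains with sub-threshold
comparisons are flagged. Within a species, sublineages are single-linkage
clusters accepted at the finest cut whose smallest within-group ANI exceeds
the largest between-group ANI by a configurable gap (default 0.5 ANI
points; no published rule exists, so the gap is exposed). A strain whose
two closest clusters lie within the gap of each other straddles the
separation band and is flagged ambiguous — such a strain typically surfaces
as its own tentative sublineage, mirroring the "possible additional
sublineage, evidence inconclusive" situation in real strain sets.

## Synteny coverage

Anchors are paralog-free reciprocal best protein hits, indexed by gene
order. Blocks are chains of anchors colinear on both genomes, allowing at
most `delta` intervening genes on either genome between consecutive
anchors, with a uniform relative orientation matching the direction of
travel. Coverage(delta) is the fraction of genes that are anchors inside
blocks of ≥2 anchors, computed for delta 2–10 and averaged. Two open
choices were resolved as follows: the denominator is gene count, not bp
(chaining is gene-indexed); and both a symmetric mode (mean of the two
genomes' fractions, the default) and a reference-directed mode are
provided, since reference-directed comparisons are common when one strain
anchors each sublineage.

## Pangenome compartments

`clusterFamilies()` builds protein families as connected components of the
all-vs-all best-hit graph, with edges kept at ≥75% alignment coverage,
e-value ≤ 1e−5 (Karlin–Altschul with ungapped BLOSUM62 parameters over the
searched residue space) and an identity floor of 40%. A single clusterer is
used rather than a consensus of three; the package's accuracy claim is
therefore truth recovery on forged data (adjusted Rand index against
planted family ids), not reproduction of any particular published family
count. Compartments follow the standard definitions: core = all strains,
exclusive = one strain, flexible = more than one but fewer than 95% of
strains; the ≥95%-but-not-universal remainder is labelled soft-core and
folded into the flexible pool for census purposes. A family is
group-exclusive for sublineage G when present in >90% of G's strains and in
no other strain; whether the 90% majority may tolerate absences is exactly
what the threshold parameter expresses, so it is configurable rather than
fixed.

## Seed census and boundary reconstruction

`seedSearch()` maps each seed element's proteins onto a target proteome
(six-frame translation fallback for unannotated assemblies), retains hits
at e-value < 0.001, and confirms orthology by reciprocal best hit against
the seed's source proteome. RBH confirmation is applied before counting —
the count is of confirmed hits. The coverage matrix is protein-wise
(fraction of seed proteins hit), occurrence is called at ≥95%, and strains
are clustered on their coverage rows (average linkage, Euclidean), with a
stricter display e-value (1e−10) available separately from the census
e-value (1e−3), honoring both conventions found in practice.

`reconstructElements()` clusters seed hits within 10 genes, then extends
over consecutive flexible/exclusive genes, tolerating isolated core genes
but stopping at two consecutive core genes (islands do capture host genes,
so a single interior core gene must not truncate the element; the stop
length is configurable). Contigs that are entirely flexible/exclusive and
carry a seed are absorbed whole. Candidate member genes are restricted to
the flexible/exclusive compartments. Segments on different contigs are
merged into one element when they match the same seed element over
disjoint seed-protein subsets with combined coverage ≥50% — the minimal
rule that reconstructs an element split by draft fragmentation without
gluing unrelated hits.

`findAttSites()` compares the two windows flanking a resolved candidate's
outermost genes (1 kb each, strictly outside the gene span — the repeat
copies flank the cargo, so interior sequence must not be searched). An
exact pass first (local alignment under a prohibitive mismatch penalty,
i.e. a longest-common-substring search) recovers exactly planted repeats
without chance mismatch extensions; only if that fails is a
mismatch-tolerant alignment tried (≤1 mismatch by default; the original
method's tolerance is unstated, so it is a parameter). Because ~10-bp
common substrings arise by chance between 1-kb windows, a significance
floor is enforced on top of the user minimum (12 bp): the reported length
must make the expected number of chance matches in the searched space at
most 10⁻³ (15 bp for 1-kb flanks; three more for the mismatch-tolerant
path), so a reported repeat is never what random sequence of that
search-space size routinely produces. attB and attP are reconstructed by
in-silico excision; `exciseElement()` inverts integration byte-exactly when
the repeat is exact. The reported `DR(a,b)` notation pairs the length of
the integration feature (e.g. a 76-bp tRNA) with the repeat length.

## Typing, plasmids, digestion, PCR

`typeElement()` is a pure function of the module inventory and context:
integrase + conjugation module (≥5 distinct virB components — drafts lose
components, so completeness is a threshold, not the full set — or relaxase
+ coupling protein) + integrated → ICE; integrase without conjugation → GI;
transposase-bounded without integrase/att → Tn; rep + circular topology (or
rep + oriV evidence on a stand-alone contig) → plasmid; otherwise fragment.
Module detection is label-driven (annotation products / provided tags);
DnaA boxes (TTATCCACA, ≤1 mismatch) and IHF motifs (WATCAANNNNTTR, IUPAC)
are scanned within 500 bp of the rep gene as oriV evidence; both motifs are
literature consensus values and config-overridable. `circularizeContig()`
reports a contig circular when its termini share an exact repeat ≥50 bp and
trims one copy; two independent overlap candidates raise an ambiguity
error. `digestFragments()` cuts at IUPAC-matched sites (default G^GATCC);
only fragment lengths are contract-bearing, and circular digests conserve
total length by construction. `insilicoPcr()` reports amplicons between
opposing-orientation primer matches within 6 kb, inclusive of both primer
5′ ends, searching circular templates across the origin.

## IS dynamics

`scanISCopies()` counts IS copies at ≥90% identity over 100% of the element
length (the conventional inventory thresholds), using the same seeded
ungapped placement machinery on both strands with overlap merging.
`detectInsertions()` consumes SAM-convention records rather than performing
read mapping — mapping is commodity; the contribution surface is the
junction logic. Soft-clipped reads whose clipped tails match an IS terminus
(either orientation, ≥90% of the clip) are clustered by junction
coordinate; a left cluster (reference → IS start) and right cluster (IS end
→ reference) of one family within a direct-repeat-sized window (default
15 bp, above the ≤10 bp typical of the relevant IS family) are paired into
an event; the DR length is the junction offset and the reported position is
the last reference base before the duplication. The allele fraction is
mutant-junction reads over mutant plus wild-type-spanning reads; on
simulated data the estimator recovers the realized mutant fraction exactly,
so its error budget is the binomial sampling of the culture itself.
`trackAlleles()` re-counts junctions per passage at the known event
location; detection requires five mutant-junction reads in total (the two
junctions jointly support one breakpoint), and loss is called at the first
undetected passage after a detected one. `repliconDepthFold()` is the ratio
of median per-base depths, robust to the Poisson noise of the track.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally only at splice boundaries;
  all user-visible coordinates, GFF3 and truth records are 1-based
  inclusive.
* Random streams are split deterministically from one integer seed per
  operation (`seed × 69621 + index mod 2³¹−1`), so every derived seed stays
  a valid 32-bit integer and identical seeds reproduce byte-identical
  outputs.
* An ANI comparison retaining no fragment reports an undefined value
  (`NA` + flag), distinct from 0; a missing depth track yields `NA` depth
  anomalies (absent, not zero).
* Ties in strain clustering and family numbering are broken by name, so
  every partition and table is invariant under input order.
* Gene-GC z-scores use median/MAD, so shifted cargo cannot inflate its own
  reference scale.

## Known limitations

The aligner is substitution-oriented: genomes with substantial indel or
rearrangement divergence inside fragments will under-retain hits compared
with a gapped local aligner (the trimming step recovers the dominant
segment only). Family clustering by connected components can chain distinct
families through promiscuous domains at permissive thresholds — the
identity floor exists to limit this. Boundary inference depends on
compartment assignment: with very few strains, cargo shared by all strains
is invisible (it becomes core). The att finder reports the maximal repeat
consistent with the termini; nested or degenerate repeat structures
(IS-bounded composite transposons) are resolved only as far as the repeat
evidence allows. None of the resequencing logic models paired-end insert
sizes; junction evidence is clip-based only.
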