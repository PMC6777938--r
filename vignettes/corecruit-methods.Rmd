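---
title: "Methods: models, conventions and design choices in corecruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in corecruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corecruit)
```

# The biological question

In *Drosophila*, the Notch-pathway transcription factor Suppressor of
Hairless, Su(H), represses its targets indirectly: the adaptor protein
Hairless binds Su(H) and recruits the two global co-repressors Groucho
(Gro) and C-terminal Binding Protein (CtBP). Hairless, however, exists
only in the Pancrustacea. Most other protostomes appear to use the
ancestral route: short linear motifs (SLiMs) inside Su(H) itself that
bind CtBP (the canonical P&phi;D&phi;S class, &phi; &isin; {I,L,M,V})
and Gro (a GSLTPPDKV-like motif). Myriapods and Chelicerates instead
encode S-CAP, an adaptor sharing the Su(H)-binding domain (SBD) of
Hairless, and both adaptor genes are typically found immediately next to
an MTA (Metastasis-associated, NuRD-complex) gene — evidence that
Hairless and S-CAP arose from a tandem duplication of *MTA*.

`corecruit` packages the comparative machinery this argument needs:
degenerate and PSSM motif scanning, motif-to-splice-junction mapping,
microsynteny classification, binary-character parsimony on species
trees, and verification of the printed expression constructs used for
the binding assays — plus a seeded generator of synthetic data with
ground truth, so every stage is testable without downloads.

# Motif models

## Strict patterns and the relaxed PSSM mode

The canonical CtBP motif is a residue-class pattern,
`P[ILMV]D[ILMV]S`. A strict scan (`scan_strict()`) reports every window
satisfying all columns. But the curated survey shipped with the package
annotates functional instances that violate the strict class (PLDLT,
PLDLR, PLNLT), so a scored, relaxed mode is required. We deliberately
use a position-specific scoring matrix rather than an edit-distance
rule: the source material names near-matches without stating a
criterion, and a PSSM trained on the annotated instances with a
minimum-training-score threshold reproduces exactly the annotated
instance set *by construction*. That circularity is intentional and
documented: the default threshold is calibration, not inference.
`build_pssm(..., leave_one_out = TRUE)` offers the honest alternative,
thresholding on instances scored by matrices that exclude them.

Scores are log-odds in bits with additive smoothing:

$$s_j(a) = \log_2 \frac{c_j(a) + \kappa\, b_a}{N + \kappa} - \log_2 b_a$$

with counts $c_j(a)$ over $N$ training instances, background $b_a$
(uniform $1/20$ by default; a composition-matched background can be
supplied), and pseudocount $\kappa = 0.5$. The defaults are ordinary
motif-scanning practice: $\kappa$ of order one prevents $-\infty$
columns at this training-set size without washing out strong columns,
and the uniform background keeps the two shipped models comparable
across proteomes of different composition.

Two details are deliberate:

* The Gro model has **width 9** (the GSLTPPDKV core named in the text),
  trained on the first 9 residues of each annotated 12-mer span. The
  survey's bold spans are longer, but the core is what the text names;
  which of the two is "the motif" is genuinely unresolved, so the width
  is a package decision, recorded here.
* Hits outside a protein's stated scan window (the non-conserved
  N-terminal region, `region_boundary`) are **reported and flagged**
  `in_region = FALSE`, never suppressed: the biological claim is about
  location, and suppression would hide counterevidence.

## Contact-residue checks

SBD-like hits can be screened with `check_contacts()`: the four
hydrophobic main-body contacts at motif offsets 3, 5, 13 and 15
(L235/F237/L245/L247 in the fly protein) plus the distinguished
non-contiguous tryptophan up to 20 residues downstream, which must be
followed by a hydrophobic residue (typically V or I). The 20-residue
window is our default; the printed wild-type constructs place the W 11
residues after the motif.

# Splice-junction conservation

The evolutionary argument leans on motifs being encoded "in two exons
with the same splice junction". `junctions_in_window()` expresses each
intron as a `(codon index, phase)` pair where **phase is the number of
nucleotides of the interrupted codon on the upstream exon**; phase 0
junctions fall between codons and are assigned to the following codon
index (which can therefore be window width + 1). This
motif-interruption phase is *not* the GFF3 phase column (bases to
discard to reach a codon start); the conversion is
`gff3_phase = (3 - phase) %% 3`, and `read_gff_genes()` checks the
stated column against cumulative CDS length, warning and recomputing on
mismatch. Cross-gene comparison (`compare_junctions()`) assumes a
gap-free motif alignment, as all compared motifs are presented
gap-free; gapped cases are out of scope and reported `incomparable`,
as is any single-exon encoding.

Because no genomic coordinates are printed for the real loci, this
module is validated on synthetic gene models only (see below) — a green
test establishes coordinate arithmetic, not the biological claim.

# Microsynteny

`neighbor_pairs()` reports every cross-family gene pair on a shared
scaffold with at most `max_intervening` annotated genes strictly
between them. "Immediately adjacent" is `intervening == 0`; the default
cap of 2 is our reading of "near-proximate linkage" and is
configurable, since the source does not quantify it. Orientation is
classified from genomic order and strand pair (`tandem_ab`,
`tandem_ba`, `divergent`, `convergent`); overlapping or nested gene
spans are rejected rather than silently ordered. All qualifying pairs
are reported — paralogous copies (e.g. the three horseshoe-crab
pairings) produce multiple rows, with no one-to-one matching imposed.

# Parsimony on species trees

Characters are binary presence/absence (Hairless, S-CAP, the two Su(H)
motifs, MTA linkage); missing data (`?`) contributes both states at
zero cost. `fitch_parsimony()` computes the **exact** minimum number of
state changes by a two-state dynamic program over node costs (Sankoff
recursion). On binary trees this is precisely Fitch's
intersection/union procedure; on polytomies the set rule can
undercount (four children in states 0,0,1,1 need two changes, not
one), so we chose the exact DP — a deliberate deviation from the naive
set-rule generalization. One most-parsimonious reconstruction is
materialized with root preference for state 0 on ties and
parent-state preference below; the reconstruction is flagged
`non_unique` when alternatives exist, because only the *count* is ever
unambiguous and the downstream claims rest on counts.

`dollo_parsimony()` formalizes single-origin characters: one gain on
the stem of the smallest clade containing all state-1 leaves, one loss
per maximal all-0 subtree within it. Placing the gain at that MRCA is
optimal because any higher placement only adds loss subtrees, and the
maximal all-0 subtrees are disjoint, each requiring its own loss.

`hybrid_species()` flags the "hybrid intermediate" condition: a species
scoring 1 for Hairless *and* both Su(H) motif characters, i.e.
possessing the novel indirect and the ancestral direct recruitment
mechanisms simultaneously.

The two newick fixtures shipped under `extdata` are the package's own
transcription of published figure topologies; they are labelled
`_synthetic` and serve as fixtures, not as ground-truth phylogenies.

# Expression-construct verification

The printed His-tag fusion inserts carry an unprinted vector linker at
the N terminus, so coordinates are anchored at the C terminus: the
unique reading frame containing exactly one stop codon is found
(`find_single_orf()`; the printed inserts carry four complete vector
codons *after* the stop, so "terminal" is defined by stop count, not
position), and the last pre-stop residue is assigned the stated range
end (e.g. 389 for the fly Hairless 192–389 construct). Under this
anchoring the five wild-type/mutant substitution sites map to
235/237/245/247 and the downstream tryptophan to 258 — recomputed, not
asserted, by the tests and acceptance script. The centipede Su(H)
exon 2–3 construct has no stated range; its segment length is reported
but not asserted, since the linker length for that construct is never
stated.

Mutagenic reverse primers are verified by reverse-complementing,
translating the single-stop frame, and reading the residues between the
template-derived block and the stop. The printed case convention
(lowercase adapter vs uppercase template) is preserved in the fixtures
but is *not* a reliable boundary — one printed primer renders its
replacement uppercase and contiguous with the template block — so the
boundary is located by the template's trailing residues instead
(`template_tail`, default `"GPM"`, the C terminus of the truncated
helix-loop-helix template common to all three printed primers).

# The synthetic-data generator

`gen_proteome()`, `gen_genes()` and `gen_characters()` emit inputs with
the statistical and structural properties the analyses assume, plus a
ground-truth table. All randomness flows through one mandatory seed
(default 0); runs are byte-reproducible.

What the generator emulates: i.i.d. background residues at a stated
composition with planted motif instances at three similarity levels
(consensus, training instance, or decoy rejection-sampled to ≥ 2 bits
below threshold); multi-exon gene models whose CDS encodes the
generated protein exactly, with introns placed at exact
(codon index, phase) marks and arbitrary strand/adjacency layouts; and
binary characters propagated from stated gain/loss events. What it does
**not** emulate: realistic sequence evolution (indels, substitution
models, codon bias), intron sequence realism beyond GT..AG, or
assembly artifacts. A green closure test therefore establishes that the
pipeline recovers what it is defined to recover — it does not validate
the biological conclusions on real genomes, which would require
external assemblies and are explicitly out of scope.

Generator defaults mirror the data regimes of the source material where
stated (e.g. 35-instance CtBP training set, 9-mer Gro core, 10-species
plantings); where nothing is stated we fixed ordinary values once
(150-residue proteins, 60 nt introns, ~200 nt intergenic spacers) and
did not revisit them.

# Numerical and formatting choices

* Fold ratios round **half-up** to one decimal (1614/343 = 4.705… →
  4.7), matching the printed figure; R's banker's rounding would too,
  but half-up is the stated contract and is implemented explicitly.
* PSSM hit ties are broken by start position, then descending score.
* Coordinates are genomic 1-based inclusive (GFF3) and protein 1-based
  throughout, matching the printed residue numbering.
* Translation uses the standard genetic code only (the constructs are
  codon-optimized but standard); ambiguity codes and selenocysteine are
  rejected, trailing stops stripped, internal stops are errors naming
  the codon index.
* Pipeline configs are JSON rather than YAML (no YAML parser among the
  package's dependencies); motif tables and reports are TSV/JSON.

# Known limitations

* The PSSM thresholds are calibrated on the curated instances they are
  then shown to recover; use leave-one-out thresholds for any claim of
  generalization.
* Parsimony is unweighted and binary; no likelihood model, no
  divergence times (statements like "gained at least 500 Mya" are not
  computed here).
* Junction comparison is gap-free; a motif alignment requiring gaps
  must be resolved upstream.
* Microsynteny works on annotated gene models as given; it does not
  detect unannotated genes between a pair, and `max_intervening` is a
  reporting cap, not a statistical test.

# A worked example

```{r example}
survey <- motif_survey()
models <- survey_motif_models(survey)
models$ctbp$threshold

# the strict pattern misses a functional near-match; the PSSM does not
scan_strict(models$ctbp_strict, protein_set("mgro", "LHYDNPLDLTNRLDE"))
scan_pssm(models$ctbp, protein_set("mgro", "LHYDNPLDLTNRLDE"))

# construct verification: the anchored contact coordinates
cs <- load_constructs()
v <- verify_constructs(cs)
v[["DmelHairless192-389"]]$substitution_coordinates
```
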