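# corecruit

Comparative-genomics toolkit for the evolution of **co-repressor
recruitment** by the Notch-pathway transcription factor Su(H)
(Suppressor of Hairless), and for the origin of its adaptor proteins
Hairless and S-CAP from the MTA (Metastasis-associated / NuRD) gene
family.

## Who this is for

Molecular evolution and evo-devo researchers asking questions of the
form: *does this transcription factor recruit Gro/CtBP directly through
short linear motifs, or indirectly through an adaptor; where did the
adaptor come from; and what does a species tree say about when each
mechanism was gained or lost?* The package turns the comparative
procedure behind those questions into tested, reusable parts:

* **Motif scanning** — strict degenerate patterns such as the canonical
  CtBP motif `P[ILMV]D[ILMV]S`, and a relaxed PSSM mode (log-odds in
  bits, pseudocount smoothing, threshold calibrated on training
  instances) for motifs annotated only by example, like the
  GSLTPPDKV-class Gro motif. Su(H)-contact residue checks for
  SBD-like hits, including the non-contiguous downstream tryptophan.
* **Splice-junction conservation** — map protein motifs through gene
  models to genomic coordinates and test whether two genes encode
  homologous motifs with the same junction and phase.
* **Microsynteny** — classify adjacency and orientation of two gene
  families across scaffolds (intervening-gene counts, tandem /
  divergent / convergent classes).
* **Parsimony** — exact minimum-change (Fitch) and single-gain (Dollo)
  reconstruction of binary characters on species trees, plus detection
  of "hybrid intermediate" species retaining both recruitment
  mechanisms.
* **Construct verification** — translate printed expression-construct
  inserts in their unique single-stop reading frame, count designed
  substitutions, anchor peptide positions onto full-protein
  coordinates, and decode mutagenic reverse primers.
* **Synthetic data** — a seeded generator of proteomes, gene models and
  character histories with ground truth, so the whole pipeline is
  testable offline.

The PSSM score of residue $a$ at column $j$, trained on $N$ aligned
instances with counts $c_j(a)$, background $b_a$ and pseudocount
$\kappa$, is

$$s_j(a) = \log_2\frac{c_j(a)+\kappa b_a}{N+\kappa} - \log_2 b_a ,$$

and a window scores the sum of its per-column terms; the default
threshold is the minimum training-instance score (leave-one-out
calibration available). Fitch reconstruction minimizes state changes by
the two-state Sankoff recursion (exact on polytomies); Dollo places one
gain on the stem of the smallest clade containing all presence leaves
and one loss per maximal absence subtree inside it.

## Worked example

The package ships a curated survey of Su(H) co-repressor motifs in 35
protostome species (`motif_survey()`); `survey_motif_models()` builds
the calibrated CtBP and Gro models from it.

```r
library(corecruit)
models <- survey_motif_models()
round(models$ctbp$threshold, 2)
#> [1] 9.1

# A functional near-match (PLDLT) is invisible to the strict pattern...
scan_strict(models$ctbp_strict, protein_set("mgro", "LHYDNPLDLTNRLDE"))
#> [1] protein_id pattern  start  end  matched  score  in_region   <0 rows>

# ...but scores well above the survey-calibrated PSSM threshold:
scan_pssm(models$ctbp, protein_set("mgro", "LHYDNPLDLTNRLDE"))
#>   protein_id pattern start end matched    score in_region
#> 1       mgro    CtBP     6  10   PLDLT 14.15214        NA
```

The printed expression constructs verify end to end: translating the
fly Hairless 192–389 wild-type/5xAla pair in the unique single-stop
frame and anchoring the last pre-stop residue at coordinate 389 places
the five designed substitutions at the known Su(H)-contact residues.

```r
v <- verify_constructs()
v[["DmelHairless192-389"]]$substitution_coordinates
#> [1] 235 237 245 247 258        # L235, F237, L245, L247 and W258, all -> A
length_summary(c(Eulimnadia_texana = 343, Protophormia_terraenovae = 1614))$fold_ratio
#> [1] 4.7                        # the known adaptor-protein size extremes
```

Here 235/237/245/247 are the four hydrophobic main-body SBD contacts,
258 the downstream tryptophan, and 4.7 the max/min protein-length fold
ratio across the surveyed species.

## Pipeline and CLI

`run_pipeline(config, out)` orchestrates all stages from one JSON
config (proteins, motif definitions, gene models + genome, synteny
families, tree + character matrix) and writes TSV/JSON reports plus a
log; outputs are byte-deterministic for fixed inputs. The same stages
are exposed as subcommands:

```sh
Rscript -e 'corecruit::corecruit_cli()' report --config config.json --out out/
Rscript -e 'corecruit::corecruit_cli()' constructs-verify --out out/
```

## Package data

`inst/extdata/` contains text fixtures only: the 35-species motif
survey (TSV + FASTA), the six printed construct inserts and eight
primers (FASTA, case preserved as printed), and two small newick trees
with a character matrix. The trees and matrix are *synthetic* fixtures
(the package's own transcription of published figure topologies), named
accordingly. See `vignettes/corecruit-methods.Rmd` for the models,
conventions, design decisions and limitations.
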