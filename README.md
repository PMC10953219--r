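# rhsurvey

Tools for genome-wide gene-family surveys of the kind used for plant
RNA-helicase (DEAD/DEAH-box) families: family identification and
protein characterization, neighbor-joining phylogeny with bootstrap,
tandem/segmental duplication calling with Nei–Gojobori Ka/Ks and
molecular-clock dating, promoter cis-element scanning, and qPCR
relative expression by the comparative Ct method.

The package is aimed at researchers who want each step of such a survey
as a small, tested, scriptable function instead of a chain of web
tools. The genome-scale inputs of the original rapeseed survey are
downloads; the package instead ships transcriptions of its printed
result tables as fixtures and a synthetic-data generator with planted
ground truth, so the whole pipeline runs and is verified at desk scale.

## The statistics at the core

* **Ka/Ks (Nei–Gojobori 1986).** Per codon, each of the 9
  single-nucleotide neighbors contributes 1/3 of a synonymous or
  nonsynonymous site (`s + n = 3`); differences between two codons are
  averaged over all minimal mutational pathways avoiding stop codons;
  proportions are Jukes–Cantor corrected, `d = -(3/4) ln(1 - (4/3)p)`;
  `ω = Ka/Ks` measures selection (ω < 1 purifying, ≈ 1 neutral).
* **Divergence dating.** `T = Ks / (2λ)` years with
  `λ = 6.5×10⁻⁹` substitutions/synonymous site/year.
* **Duplication classes.** Called pairs (identity ≥ 80%, e-value ≤
  1e-10) are *tandem* when on one chromosome within 5 Mb (nearest
  edges), otherwise *segmental*.
* **Neighbor joining** (Saitou–Nei Q-criterion, deterministic
  tie-breaks, exact on additive matrices) with column-bootstrap
  supports.
* **Comparative Ct.** `ΔCt = Ct_target − Ct_ref`,
  `ΔΔCt = ΔCt_treat − ΔCt_control`, `FC = 2^(−ΔΔCt)`, Welch t-tests on
  per-replicate ΔCt.

See `vignettes/survey-methods.Rmd` for the full model descriptions and
design decisions.

## Worked example

The survey is organized as numbered drivers under `analysis/`, each a
thin script over the exported functions:

```sh
Rscript analysis/01_simulate_family.R 1   # synthetic family + truth
Rscript analysis/02_family_survey.R 1     # identification + properties
Rscript analysis/03_phylogeny.R 1         # NJ + bootstrap + groups
Rscript analysis/04_duplications.R 1      # pairs, Ka/Ks, dating
Rscript analysis/05_promoters.R 1         # cis-element scan
Rscript analysis/06_expression.R 1        # ddCt + heat matrix
```

With seed 1 this prints, among other lines:

```
simulated 10 family members + 3 decoys; 8 true pairs (6 tandem, 2 segmental); config 010f7a3b
domain scan: 10 of 13 representatives carry DEXDC
published table: 133 genes, 294-2188 aa, top chromosome 3 (27%)
called 45 pairs (12 tandem, 33 segmental); 8/8 planted pairs recovered, classes correct for 8/8
estimated omega: median 0.209 (planted 0.20); dated 2.91-8.42 Mya
scanned 13 promoters x 3 elements; top element S000453 (26 hits); planted counts exact for 13/13 genes
analyzed 8 genes x 3 conditions; 1 up-regulated cells (RH079); 11 significant at p<0.05
```

Reading the key numbers: the domain scan recovers exactly the 10
planted family members out of 13 candidates; every planted duplicate
pair is re-called with its true tandem/segmental class; the median
estimated ω of 0.209 recovers the planted purifying pressure of 0.2;
and promoter element counts equal the planted truth for all genes.
Stage outputs are plain TSV/FASTA/Newick under `results/`.

Individual functions work stand-alone:

```r
library(rhsurvey)
ng86_sites("TTT")              #  s = 1/3, n = 8/3
divergence_time(0.013)$t_years #  1e6 years
kk <- kaks_pair(cds_a, cds_b)  #  NG86 on a protein-threaded alignment
```

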