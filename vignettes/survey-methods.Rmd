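---
title: "Methods of the gene-family survey pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods of the gene-family survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhsurvey)
```

# What this package computes

`rhsurvey` re-implements, as a tested pipeline, the chain of analyses
used in genome-wide surveys of plant gene families such as the RNA
helicases (DEAD/DEAH-box proteins) of rapeseed: delimit the family in a
candidate protein set, characterize the proteins, build a
neighbor-joining phylogeny with bootstrap supports, call duplicate gene
pairs and classify them as tandem or segmental, quantify selection with
Ka/Ks and date duplications with a synonymous molecular clock, scan
promoters for stress-responsive cis-elements, and analyze qPCR
expression by the comparative Ct method.

The genome-scale inputs of such surveys (a full proteome, real promoter
sequences) are downloads; this package instead ships (a) transcriptions
of the survey's printed result tables as fixtures and (b) a
synthetic-data generator that plants known truth, so every stage has an
exact recovery test that runs at desk scale.

# Family identification and characterization

**Redundancy reduction** is greedy single-linkage in descending length
order: a sequence joins the first kept representative whose
global-alignment identity reaches the cutoff (default 1.0, i.e. only
duplicates collapse). Descending length with an id tie-break makes the
result independent of input order.

**Domain detection** is a transparent consensus-pattern scanner rather
than a profile HMM: a sliding window counts matching positions against a
consensus (with `X` wildcards) and reports windows reaching `min_score`,
merging overlaps to the best window. The published surveys delegate this
step to Pfam/SMART; a scanner keeps the stage fully testable and
swappable (an external HMM hit table can replace it, since stages only
communicate through files).

**Molecular weight** sums average-isotope residue masses plus one water
(18.0153 Da) — the ProtParam convention. **Isoelectric point** solves
`charge(pH) = 0` by bisection on `[0, 14]` to `|charge| < 1e-4`, with
Henderson–Hasselbalch terms for the termini and the D, E, C, Y, H, K, R
side chains. The pKa set is the EMBOSS-style constant table, declared in
code; published pI columns computed with other constant sets are
therefore *comparable, not bit-identical*, which is why the acceptance
checks on the printed gene table use the transcribed pI column rather
than recomputation.

**Chromosome distribution** reports per-chromosome counts and integer
percentages (ties rounded away from zero). Percentages are over
*assigned* genes; label `"0"` (unknown location) is counted separately.
This convention is what makes the printed "27% on chromosome 3" exact:
35 of 131 assigned genes is 26.7% → 27%, while 35/133 would print 26%.

# Alignment and phylogeny

Pairwise global alignment is Needleman–Wunsch/Gotoh with affine gaps
(BLOSUM62 default), delegated to `Biostrings::pairwiseAlignment`; a
brute-force dynamic-programming oracle checks scores on tiny cases in
the test suite. Identity is identical columns over aligned columns
*excluding terminal-gap columns*, so full-length homologs of different
lengths (294–2188 aa in the published family) are not penalized for
overhangs. The e-value attached to a score is an explicit Karlin–
Altschul style proxy `E = K·m·n·N·exp(-λs)` with gapped-BLOSUM62
folklore constants (0.267, 0.041); the survey's `1e-10` cutoff is
applied to it.

Distances from an alignment are p-distance or its Poisson correction
`-ln(1 - p)`, over columns where both rows are ungapped.
**Neighbor joining** is implemented in the package (Saitou–Nei
Q-criterion; ties broken by the lexicographically smallest label pair;
negative branch estimates clamped to zero and logged). On additive
matrices NJ is exact, which the tests exploit: 50 random 6–10-leaf trees
are converted to path-length matrices and must be recovered to 1e-9,
with `ape::nj` as an independent topological cross-check.
**Bootstrap** resamples columns with replacement, rebuilds the tree, and
reports for each internal edge of the full-data tree the percentage of
replicates containing that bipartition; replicates with an undefined
distance (an all-gap pair, a saturated Poisson distance) are discarded
and logged, and more than 50% discarded is an error.

The published tree is split into a "main group" and a "subgroup" without
a printed criterion; `group_by_longest_edge()` implements the declared
heuristic of cutting the longest internal edge and labelling the larger
side "main".

The pipeline does not re-implement ClustalX. It accepts an externally
aligned FASTA, or — for the synthetic families, which evolve without
indels — stacks the equal-length sequences column-wise (`msa_stack()`).
A thin `mafft` wrapper is provided for real data.

# Duplication, Ka/Ks and dating

Paralog pairs are called from all-vs-all alignments at identity ≥ 0.80
and e-value ≤ 1e-10, each unordered pair once. Classification uses a
single boundary: same chromosome with nearest-edge distance ≤ 5 Mb is
**tandem**; anything else — farther apart on one chromosome, different
chromosomes, or an unknown ("0") chromosome — is **segmental**. The
printed rules ("contiguous genes" vs "> 5 Mb") leave a gap for
same-chromosome pairs below 5 Mb that are not literally adjacent; making
5 Mb the single boundary is the simplest rule consistent with both
statements, and nearest-edge (not midpoint) distance reads "contiguous"
as physical adjacency.

Ka/Ks is **Nei–Gojobori (1986)** with Jukes–Cantor correction, computed
on a codon alignment threaded through the protein alignment (protein
gaps become `---`; gapped columns are excluded). The printed survey
names DnaSP but not an algorithm; NG86 is chosen because it is fully
specifiable. Per codon, each of the 9 single-nucleotide neighbors
contributes 1/3 of a site, synonymous or not (changes to stops count as
nonsynonymous), so `s + n = 3` exactly. Differences are averaged with
equal weight over all minimal mutational pathways that avoid stop
codons; a codon pair whose every pathway crosses a stop is excluded from
the difference counts (it still contributes sites) and logged.
`ω = Ka/Ks` is 0 when both distances are 0 and undefined (`NA`) when
`Ks = 0 < Ka`. The correction `d = -(3/4) ln(1 - (4/3)p)` fails at
`p ≥ 3/4`, which is reported as saturation rather than silently clamped.

Divergence time is the strict synonymous clock `T = Ks/(2λ)` with
`λ = 6.5e-9` substitutions per synonymous site per year. The printed
divergence columns of the source tables sit uniformly at ≈ 0.991 of
`Ks/(2λ)` recomputed from the printed Ks — consistent with an unprinted
higher-precision Ks or a slightly different λ. The package implements
the stated formula; the constant ratio is itself asserted (band
0.985–0.995) on cleanly printed rows.

Orthologs across two proteomes are paired by **reciprocal best hit**,
with score ties broken lexicographically and logged.

# Promoter cis-element scanning

The promoter is the 2000 bp upstream of the transcription start: on the
plus strand `contig[start-2000, start)`, on the minus strand the reverse
complement of `contig[end, end+2000)`, truncated (and flagged) at contig
boundaries. Elements are IUPAC patterns (e.g. ACGTG for the drought-
associated element S000415); every start position is tested, so
overlapping occurrences all count, and both strands are scanned by
default (palindromic patterns then double-count by construction — a
forward-only mode exists). Elements whose patterns the printed survey
does not give must come from a user-supplied library.

# Expression and physiology

The comparative Ct method averages Ct over replicates per (gene,
condition), normalizes to the reference gene (`ΔCt`), compares to the
control condition (`ΔΔCt`) and reports `FC = 2^(-ΔΔCt)` under the Livak
assumption of amplification efficiency 2. Per-cell significance is a
two-sided Welch t-test on per-replicate ΔCt (treatment vs control) —
the published survey names only "SAS at the 5% level", and Welch-on-ΔCt
is standard qPCR practice; marks are `*` (< 0.05) and `**` (< 0.01),
uncorrected to mirror per-cell marks, with a Benjamini–Hochberg column
emitted additionally. "Unchanged" is assigned only at FC = 1 exactly.
The log2 fold-change matrix is clustered with Euclidean distance and
average linkage, cut into `k` groups.

`rwc()` (relative water content, `100(WF-WD)/(WS-WD)`) and
`na_k_ratio()` are the physiology indices; the wet-lab assays that
produce their inputs are out of scope.

# The synthetic study system

`simulate_family()` generates the conditions the recovery tests run
under. Defaults, chosen once as a realistic desk-scale family: 6
chromosomes of 30 Mb; 2 tandem clusters of 3 members (within-cluster
gaps ≤ 1 Mb, well inside the 5 Mb cutoff) and 2 segmental pairs (one
cross-chromosome, one same-chromosome > 5 Mb apart); 300-codon genes;
planted ω = 0.2 (purifying, as in most published pairs) at 0.1
proposals/codon of divergence; 3 non-family decoys. All members descend
from one founder CDS, so the family is a true homology group and — with
indel evolution deliberately out of scope — equal-length, making the MSA
an ungapped stack. The planted domain consensus is held fixed at the
amino-acid level (synonymous-only proposals inside the domain), so
domain-scan recovery of exactly the family members is guaranteed by
construction, as in a family defined by an intact diagnostic domain.

`simulate_codon_pair()` imposes dN/dS by acceptance–rejection rather
than a continuous-time codon model: proposals are drawn
`Poisson(n_codons × expected_subs_per_codon)` per lineage, synonymous
proposals always accepted, nonsynonymous accepted with probability
`min(ω, 1)`, stops rejected. This is transparent and sufficient for
estimator-recovery testing; it is not a simulator of real codon
evolution (no transition/transversion bias, no codon frequencies, no
rate variation). Estimator-recovery checks use 300 codons at 0.3
proposals/codon — enough signal to estimate ω, far from saturation.

Promoter backgrounds are drawn uniform and then *repaired* until no
library element matches on either strand, after which exactly the
planted occurrence counts are inserted at non-overlapping positions and
the whole promoter re-verified; planted counts are therefore exact
ground truth, not a statistical expectation.

`simulate_ct_table()` keeps the reference gene's expected Ct constant
across conditions and shifts each target's treatment Ct by
`-log2(true FC)` plus Gaussian noise per replicate, so the ΔΔCt analysis
recovers planted fold changes exactly at zero noise. The planted
fold change 1.7 used in the recovery checks mirrors the one up-regulated
drought observation highlighted in the source survey; replicate noise
0.2 Ct with 3 replicates is typical bench variation.

What passing these tests shows — and does not show: the pipeline's
arithmetic and decision rules are correct on data satisfying its
assumptions (no indels, clean frames, exact domain conservation,
element-free promoter background). Real data violate all of these; the
generator makes no claim to realism for intergenic composition,
transposons, or polyploid segmental structure.

# Numerical and reproducibility choices

* Coordinates are 0-based end-exclusive throughout, so
  `length = end - start` — the convention under which every row of the
  transcribed gene table is internally consistent; GFF-style 1-based
  input must be shifted by one.
* All randomness flows from explicit integer seeds; stage outputs embed
  a digest of the configuration, and identical seeds give byte-identical
  generator output.
* NJ tie-breaks and negative-branch clamping are deterministic and
  logged; bootstrap supports are integers in [0, 100].
* Problem sizes in tests and the acceptance script (300-codon pairs, 20
  seeds per ω, 50 random trees of 6–10 leaves, 50 Ct-table seeds, a
  13-gene synthetic family) were chosen as the smallest sizes at which
  the statistical recovery bands are comfortably stable.
* The analysis is exposed as numbered driver scripts under `analysis/`
  over exported functions rather than a monolithic command-line binary;
  each stage reads and writes plain TSV/FASTA/Newick so any stage can be
  replaced by an external tool.

# Known limitations

* The e-value is a proxy, not a BLAST statistic; only its ordering and
  the survey's cutoff semantics are meaningful.
* pI depends on the pKa constant set; absolute values differ between
  calculators by ~0.1–0.5 units.
* The progressive-MSA path is deliberately absent: for gapped real
  data, align externally (e.g. mafft) and load the aligned FASTA.
* NG86 underestimates ω > 1 slightly under the Jukes–Cantor assumptions
  and the equal-pathway weighting; likelihood methods (codeml-style) are
  out of scope.
* The two-group tree split is a declared heuristic; with no printed
  criterion in the source, any published grouping can only be matched
  qualitatively.
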