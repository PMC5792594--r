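# ccminer

Clade-specific gene subfamily mining and candidate prioritization for
enzyme discovery in plant specialized metabolism.

## The problem

Large enzyme superfamilies — cytochrome P450s being the canonical case —
hold hundreds of members per plant genome, and functional screening of all
of them is impractical. When the target activity (for example flavone
6-hydroxylation, the committed step toward scutellarin in *Erigeron
breviscapus*) is phylogenetically restricted to one clade, candidates can
be narrowed by comparative genomics: find all superfamily members in the
focal genome and its relatives, partition them into subfamilies, keep the
subfamilies that exist **only** in the producing clade, and rank those
genes by expression. `ccminer` implements this discovery chain end to end,
plus the Michaelis–Menten kinetics and fermentation-yield arithmetic used
to characterize the enzymes it surfaces.

## The method

* **Domain mining.** Ungapped log-odds profile scan; per-sequence null
  from seeded residue shuffles with a Gumbel (extreme-value) tail fit;
  hits kept when `E < 1e-10` and the whole protein length `L` satisfies
  `350 < L < 650` (strict bounds).
* **Subfamily classification.** All-pairs Needleman–Wunsch identity
  (BLOSUM62, gap open/extend 10/1, free terminal gaps); neighbor-joining
  tree on `d = 1 − identity` (Saitou–Nei, negative branches clamped with
  the deficit moved to the sibling edge, so additive matrices are inverted
  exactly); subfamilies are the maximal monophyletic clades in which every
  pair has identity `> τ = 0.55`.
* **Clade specificity.** A subfamily is clade-specific iff its species
  multiset lies inside the declared ingroup; class counts are conserved
  (specific + shared = focal superfamily size).
* **Prioritization.** Wilcoxon rank-sum comparison of
  `log2(mean expression + 1)` between specific and shared members, and a
  top-*k* (default 36) expression-ranked shortlist of clade-specific genes.
* **Quantitation.** `v = Vmax·S/(Km+S)` fitted by Levenberg–Marquardt with
  Lineweaver–Burk initialization (`kcat = Vmax/E0`), and yield accounting
  (fold change, titer totals, intra/extracellular split).
* **Synthetic data.** A generator plants gene families with controlled
  within/between-subfamily identity on a 13-species guide tree
  (5-species ingroup + 8 outgroup), expression tables (5 wild + 6
  cultivated samples) with planted high-expression pathway genes, and
  kinetic datasets — so the whole analysis runs and is tested with no
  downloads.

## Worked example

The whole pipeline runs from one config:

```r
library(ccminer)
report <- run_pipeline(pipeline_config(seed = 42), outdir = "results/run")
```

which logs the stages and returns a structured report:

```
[input] simulating synthetic bundle (seed 42)
[mine] scanning 128 proteins
[mine] 108 of 121 scanned proteins pass the screen
[cluster] identity matrix and NJ tree for 108 genes
[cluster] 12 subfamilies
[specificity] 6 clade-specific and 6 shared subfamilies
[rank] shortlist of 6 candidates
```

All 108 planted superfamily members pass the screen (none of the 20 decoys
do; 7 decoys are too short to scan at all), the 12 planted subfamilies
are recovered exactly, the 6 ingroup-only subfamilies are called
clade-specific, and the shortlist holds the focal species' clade-specific
genes ranked by mean expression. Step-by-step drivers of the same analysis
live under `analysis/` (`01_simulate.R` … `06_kinetics_yield.R`) and write
their tables to `results/`; for instance step 6 prints

```
Michaelis-Menten fit (n = 12): Km = 9.24 uM (SE 0), Vmax = 0.0057 uM/s (SE 0), kcat = 0.57 1/s, R2 = 1.0000
Total titer: 293 mg/L (~300 mg/L)
Specific yield: 15.5 mg/gDCW
Fold change over baseline: 1.68
Intracellular 26.6% / extracellular 73.4%
```

i.e. the kinetic fit recovers the generating constants exactly on
noise-free data, and the yield arithmetic reproduces the characteristic
fermentation figures (108 + 185 = 293 ≈ 300 mg l⁻¹ total;
15.5/9.2 = 1.68-fold; 100 − 73.4 = 26.6% intracellular).

See `vignettes/candidate-mining-methods.Rmd` for the full model
description, parameter meanings, and design rationale.

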