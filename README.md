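# pepcation

Conformer ensembles of amino acids and dipeptides bound to divalent cations:
backbone-motif classification, energy hierarchies, binding-energy trends,
coordination diagnostics and toxicity-trend correlation — with a fully
labelled synthetic benchmark generator built in.

## What it does, and for whom

Structural chemists and bioinformaticians studying how divalent metal
cations (Ca²⁺, Ba²⁺, Sr²⁺, Cd²⁺, Pb²⁺, Hg²⁺) interact with the building
blocks of proteins work with large per-system conformer ensembles. The
interesting structure lives in a small taxonomy of backbone motifs and in a
few cross-ion statistics:

* **Free amino acids** adopt one of three forms: *type I* (neutral carboxyl,
  backbone N–H···O=C), *type II* (carboxyl O–H···N) or the *zwitterion*
  (carboxylate + protonated amine). With a cation they bind either as a
  *salt bridge* (cation on the carboxylate of a zwitterionic backbone) or
  *charge-solvated* (cation on the lone pairs of the neutral amine and
  carbonyl).
* **Dipeptides** (acetylated and amino-methylated residues) form
  hydrogen-bonded pseudocycles **C5** or **C7** (axial/equatorial by the
  side-chain orientation to the ring plane); a bound cation bridges the two
  backbone oxygens and closes an otherwise *incomplete* seven-ring,
  **iC7ax** / **iC7eq**.
* **Binding energies** are defined on the lowest-energy conformers of the
  separated constituents,

  `E_bind = (E_ligand_min + E_ion) − E_complex_min`  (positive = favourable),

  and ordered across the ion series; rank concordance between two ions is
  Kendall τ-b. Cation coordination is summarised by pooled cation–O distance
  histograms with kernel-density mode counting (one-peak vs multi-modal),
  and the cross-ion binding trend is correlated against the acute
  toxicities (chloride-salt LD₅₀) of the ions, with a leave-one-out scan
  that flags the outlier ion.

The package implements the full chain — extended-XYZ I/O, torsion and
hydrogen-bond geometry, proton assignment, pseudocycle tracing, Kabsch-RMSD
deduplicated energy hierarchies, trend tables, coordination histograms, a
packaged ion reference table (Shannon radii, hydration enthalpies, LD₅₀
values with citations) — plus a seeded generator of labelled synthetic
conformer ensembles driven by a toy electrostatic energy model and a
torsional basin-hopping search, so every analysis step is exercised against
constructive ground truth.

## Worked example

```r
library(pepcation)
library(dplyr)

suite <- generate_labeled_ensembles(seed = 1)   # 140 systems, ~650 conformers
cls   <- classify_conformers(suite$ensembles)
mean(cls$class == cls$label) * 100
#> [1] 100

rec   <- binding_records(cls)
trend <- binding_trend(rec, backbone = "capped")
affinity_ranking(trend, "Ca")
#> # A tibble: 10 x 4
#>   ligand e_bind  rank tied
#> 1 glu      2.95     1 FALSE
#> 2 asp      2.81     2 FALSE
#> 3 gly      2.63     3 FALSE
#> 4 phe      2.58     4 FALSE
#> # ...

rank_concordance("Ca", "Pb", trend = trend)
#> $tau          [1] 1
#> $max_abs_diff [1] 0

gm <- global_minima(filter(cls, complexation != "none", backbone == "capped"))
median_shift_report(
  cation_o_histogram(filter(gm, complexation == "Cd")),
  cation_o_histogram(filter(gm, complexation == "Hg"))
)
#>   median_a median_b median_shift modes_a modes_b
#> 1     2.25     2.43        0.185       1       2

means <- summarise(group_by(rec, ion), e_bind = mean(e_bind))
toxicity_correlation(means)
#> <pepc_toxcor> Kendall tau = -0.276 over 6 ions; leave-one-out outlier: Ba
```

Reading the numbers: the classifier recovers every ground-truth label; the
anionic-side-chain ligand binds every ion most strongly; the Ca-like and
Pb-like series agree exactly (τ = 1, max deviation 0 eV — the ion-mimicry
condition); the Cd-like cation–O distances are unimodal while the Hg-like
ion splits its coordination shell into a short and a long mode; and the
binding-toxicity correlation is negative with barium flagged as the
outlier (toxic despite binding weakly).

`plot_ramachandran()`, `plot_hierarchy()`, `plot_binding_trend()` and
`autoplot()` on histograms give the standard displays; `tidy()`/`glance()`
methods cover hierarchies, trend tables, histograms and toxicity reports.
`run_synth()` writes a suite to disk and `run_pipeline(pipeline_config(...))`
executes the whole chain into a CSV/JSON report bundle. The methods
vignette (`vignettes/conformer-cation-trends.Rmd`) documents the model,
every tunable threshold and the design decisions.

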