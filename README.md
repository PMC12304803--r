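# xlspan

Secondary-structure analysis of short-range cross-links from
cross-linking mass spectrometry (XL-MS).

## The problem

XL-MS experiments covalently bridge residue pairs and identify them by
mass spectrometry. Cross-links joining residues **fewer than 20 sequence
positions apart** ("short-range", spacing `s = |pos_b − pos_a| ≤ 19`) are
usually discarded as structurally trivial. They are not: the spacing
statistics of short-range cross-links carry a clear secondary-structure
signature, because a cross-linker can only bridge side chains that the
local fold co-orients.

`xlspan` is for proteomics and structural-biology groups who want to mine
that signal from system-wide XL-MS datasets mapped onto predicted protein
models: to infer local secondary structure, to benchmark model confidence
(pLDDT), and to grade dataset quality.

## The method

Each intra-protein cross-link within the spacing ceiling is mapped onto a
predicted model of its protein. Three-state secondary structure
(H / E / C) is assigned from backbone coordinates with the
Kabsch–Sander hydrogen-bond formalism: bond energy

    E = 27.888 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)  kcal/mol,  bond ⇔ E < −0.5,

helices from runs of consecutive i→i+4 turns, strands from
parallel/antiparallel bridge patterns. A cross-linked span is **helix**,
**strand** or **coil** only when every residue between and including the
two sites carries that label within one continuous element; otherwise it
is **mixed**. Helix/strand spans are kept only at high model confidence
(min pLDDT over the span > 80); coils and mixed spans are kept at any
confidence.

From the annotated atlas the package computes, per category over spacings
1–19: counts, frequencies normalized to a maximum of 100, and subset-based
standard errors (three equal seeded random subsets, sd/√3); the
conditional probabilities `P(category | spacing)`; pLDDT-stratified
distributions (0–60 / 60–80 / 80–100); amino-acid composition "grammar"
around cross-linked lysines (percentage difference against the proteome
background, `100·(f−g)/g`); and geodesic solvent-accessible surface
distances between reactive side-chain atoms (26-connected Dijkstra on a
voxel grid inflated by probe + linker half-thickness).

The helix curve of a clean dataset oscillates at the α-helical pitch of
≈ 3.6 residues/turn on a decaying exponential. Because random false
positives follow the flat background spacing law instead, the spectral
power at period 3.6 of the detrended helix curve — the **periodicity
score** — drops monotonically with the false-positive fraction, which
makes it a dataset-level quality metric.

## Worked example

```r
library(xlspan)

spec   <- synthetic_spec(seed = 7)            # 40 proteins, 2000 links
bundle <- write_fixture_bundle(spec, "bundle")
res    <- xl_run(run_config(bundle$csv, "bundle", "out", seed = 7))
res$stage_counts
#>                stage    n
#> 1        acquisition 2000
#> 2 redundancy_removed  669
#> 3 proximity_filtered  669
#> 4          annotated  669
#> 5     plddt_filtered  576

res$distribution
#> <spacing_distribution> 576 cross-links; category totals: helix=107, strand=0, coil=113, mixed=356

round(res$probability[c("2", "3", "7"), ], 2)
#>   helix strand coil mixed
#> 2  0.15      0 0.85  0.00
#> 3  0.41      0 0.46  0.13
#> 7  0.24      0 0.24  0.51

periodicity_score(res$distribution)
#> [1] 0.699
```

Reading the output: the per-stage counts never increase (acquisition →
redundancy removal → proximity filter → annotation → confidence filter).
At a spacing of 2 the span is most likely a coil (side chains of helical
residues two apart point to opposite helix faces, a minimum of the helix
curve); spacings 3–4 and 7 sit on helical turns. The periodicity score
near 0.7 says the helix curve of this (clean, simulated) dataset retains
most of its 3.6-residue oscillation; contaminating the set with
background-drawn false positives drives it toward 0.

A command-line front end wrapping the same functions is installed at
`inst/cli/xlspan.R` (subcommands `run`, `simulate`, `sasd`, `background`,
`grammar`).

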