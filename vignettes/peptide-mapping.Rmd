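---
title: "Peptide mapping onto membrane topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide mapping onto membrane topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmapr)
```

## The problem and the model

Quantitative shotgun proteomics with stable-isotope labeling yields, per
identified peptide, a linear light:heavy (L:H) abundance ratio, and per
protein a probability that the identification is correct (PeptideProphet
and ProteinProphet posteriors, ASAPRatio/XPRESS quantitation, all carried
in protXML). Protein-level ratios average over the whole sequence. That
average is misleading exactly where biology is most interesting for
membrane proteins: proteolytic shedding releases the ectodomain, and
intramembrane proteases such as SPPL2a/b then clear the remaining
membrane-bound fragment. When the protease is absent, the short
cytoplasmic tail *accumulates* while the shed ectodomain is *depleted* —
opposite signs that cancel in a protein-level mean dominated by the more
numerous ectodomain peptides.

`pepmapr` therefore quantifies per topological region. Each peptide is
placed on its protein's precursor sequence and assigned to the region it
lies in; for the cytoplasmic and extra-cytoplasmic domains the package
reports the arithmetic mean of the clamped log2 ratios of the
contributing peptides:

$$\bar F_{r} = \frac{1}{n_r} \sum_{i \in r} \mathrm{clamp}\big(\log_2 \rho_i,\ r_{\min},\ r_{\max}\big)$$

where $\rho_i$ is the selected linear L:H ratio of peptide $i$ and the
sum runs over deduplicated, quantified, validation-passing peptides
wholly inside region $r$. Averaging is done in log space: up- and
down-regulation are then symmetric around 0, and the region mean is the
geometric mean of the linear ratios, which is the natural location
statistic for ratio data.

## Pipeline and parameters

1. **Parse** protXML (`read_protxml()`): one row per protein, peptides
   nested. ASAPRatio is the reported quantitation; when a recomputed
   ("adjusted") protein-level ASAPRatio is present it is preferred, as it
   reflects the pipeline's own post-hoc correction. The format's
   negative sentinel ("not computed") becomes `NA`; no record ever
   carries a negative ratio.
2. **Filter** (`filter_proteins()`): proteins with ProteinProphet
   probability strictly below the cutoff are discarded.
   **`threshold` = 0.90** by default; the boundary value 0.90 is kept,
   since the rejection rule is a strict "less than".
3. **Annotate** (`read_annotations()`): per accession, the precursor
   sequence, name, molecular weight and the topological features
   `SIGNAL`, `TRANSMEM`, `TOPO_DOM` with 1-based inclusive coordinates
   (the UniProt convention, preserved end to end). A local annotation
   file (tabular or UniProt flat text) keeps the pipeline hermetic; an
   online fetcher exists for interactive use and degrades to
   "unannotated" on failure.
4. **Map** (`map_protein()`): exact substring search for every
   occurrence, region assignment, transformation, classification.
5. **Summarize / screen / report**.

User-facing parameters, all in `run_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `threshold` | 0.90 | probability | ProteinProphet rejection cutoff |
| `rmin`, `rmax` | -3.0, 3.0 | log2 | clamp bounds; also the colour-scale endpoints |
| `zn`, `zp` | -0.25, 0.25 | log2 | inclusive no-change zone |
| `invert` | off | — | report heavy:light (negate log2) |
| `validate` | off | — | cross-check ASAPRatio against XPRESS |
| `validation_tolerance` | 1.0 | log2 | max allowed \|log2 ASAP − log2 XPRESS\| |
| `elaborate` | off | — | keep every occurrence of repeated peptides |

Clamping implements the "minimum/maximum allowed ratio" semantics as
saturation: a single extreme peptide (including the 0 and ≥9999
infinite-ratio conventions, mapped to ∓∞ before clamping) can pull a
region mean at most to the bound. The same bounds anchor the red-green
colour scale, so colour saturation and numeric saturation coincide.

## Region assignment rules

`classify_feature()` maps stored annotation onto four categories:
cytoplasmic, extra-cytoplasmic (Extracellular, Lumenal, plus a
configurable synonym list — Periplasmic, Vesicular — matched
case-insensitively), transmembrane, and signal. Residues covered by
overlapping features resolve by priority *signal > transmembrane >
cytoplasmic > extra-cytoplasmic*; real annotation occasionally overlaps
(e.g. a topological domain drawn over a signal peptide), and the
cleaved signal peptide must win such conflicts. Assignment is therefore
invariant under feature order.

A peptide span is then classed:

* wholly inside one category → that category;
* touching two or more categories, **or crossing from annotated into
  unannotated sequence** → `spanning`. The second clause is a
  deliberate choice for a case the rules above leave open: a peptide
  half inside a domain and half in an annotation gap crosses an
  annotation boundary and its quantity cannot be attributed to the
  domain alone, so it is treated like any other boundary-crossing
  peptide;
* no classified feature touched → `unannotated`;
* not found in the sequence → `unmapped`; found at several positions
  with disagreeing categories → `ambiguous`.

Only `cytoplasmic` and `extra_cytoplasmic` peptides enter region means.
Spanning, ambiguous, signal, unannotated and unmapped peptides are
displayed but excluded: spanning/ambiguous because attribution is
unclear, signal because the signal peptide is cleaved from the mature
protein and its quantity would distort the ectodomain estimate.
Isoleucine and leucine are *not* folded together in matching — the
upstream database search already committed to a residue sequence.

## Duplicate resolution and validation

A peptide sequence identified several times (different charge states,
modification variants — modifications are stripped to the plain residue
sequence for mapping) contributes once: the occurrence with the highest
PeptideProphet probability, ties broken by more quantified spectra, then
by first occurrence. With `elaborate` all occurrences stay visible,
grouped by sequence, but averages still use the primary occurrence — so
display mode never changes the numbers.

XPRESS validation is interpreted quantitatively: a peptide passes when
its two quantitations agree within `validation_tolerance` on the log2
scale (default 1.0, i.e. within 2-fold). Failing peptides remain visible
per peptide but are dropped from region means; with XPRESS absent the
check is `untestable` and the peptide is kept. The tolerance is
configurable because the cross-check itself is only loosely specified in
practice.

## The substrate screen

Known SPPL2a/b substrates are single-pass type 2 proteins with a short
cytoplasmic tail and a large shed ectodomain. `screen_sppl_candidates()`
flags a protein when (a) it has exactly one transmembrane segment,
(b) a cytoplasmic domain starts before that segment and an
extra-cytoplasmic domain follows it (type 2 orientation, read from the
stored annotation, never predicted), and (c) the cytoplasmic domain
mean exceeds `fc_cutoff` (default 1.0 log2 — more than 2-fold
accumulation). Tail shortness is characteristic of known substrates but
is not one of the three criteria, so `max_tail_length` exists and is
disabled by default. Candidates report both domain means, making the
opposing-regulation signature directly visible.

## Synthetic data: what it emulates, what it does not

The generator builds proteins from four topology templates (soluble;
type 1 with signal peptide; type 2 with a tail-length parameter —
mirroring substrates whose ~29-residue tail yields a single tryptic
peptide; multi-pass with alternating loops), digests them in silico
(trypsin: cleave after K/R, not before P, 0 missed cleavages by default,
retained length 6–30), and simulates quantitation: each peptide's true
log2 ratio is its region's effect, observed with `N(0, σ)` noise
(default σ = 0.2 log2, a typical peptide-level spread for isotope-label
quantitation), PeptideProphet-style probabilities from `Beta(9, 1)`
(median ≈ 0.93, with a tail of poor identifications), charge 2–3, and a
configurable fraction of absent-ratio sentinels. Cohorts draw per-region
effects from `N(0, 0.5)`, reproducing the near-normal fold-change
distribution of a perturbation that leaves most of the membrane proteome
unchanged, and give a configurable fraction of proteins sub-threshold
probabilities. Everything is deterministic under a seed.

What it does **not** emulate: real amino-acid composition (uniform over
the 20 canonical residues — irrelevant to the logic under test), missed
cleavages' abundance structure, shared peptides between homologous
proteins, intensity-dependent noise, or retention-time artefacts. Tests
passing on synthetic data therefore demonstrate correctness of parsing,
mapping, arithmetic and screening logic — not robustness to every
pathology of real LC-MS/MS data; the published caveat stands that
domain-level quantitation rests on fewer peptides than protein-level
quantitation and deserves case-by-case scrutiny.

`recovery_cohort()` encodes the effect-recovery study design: type 2
proteins (600 residues, 150-residue tail) with true effects +1.5
(cytoplasmic) and −0.5 (extra-cytoplasmic) log2, rejection-sampled so
every protein has ≥ 5 quantified peptides per domain. With σ = 0.2 the
per-protein domain mean recovers the true effect within $3σ/\sqrt{n}$
essentially always; with σ = 0 recovery is exact up to clamping.
Problem sizes used in the tests (40-protein recovery cohorts, a
625-protein report fixture, 10,000 random peptide/protein pairs against
a brute-force locator) were chosen to exercise the report at the scale of
a realistic run while keeping the suite quick to iterate on.

## Numerical and degenerate-input choices

* Boundary conventions: the probability filter keeps `probability ==
  threshold` (the stated rejection rule is strict); the no-change zone
  is inclusive at both ends; clamping is idempotent.
* A protein without a probability attribute is kept with probability 0
  (and a warning) — it then fails any sensible filter, but parsing never
  silently drops records.
* Ratio 0 → −∞, ratio ≥ 9999 (the XPRESS infinity convention) → +∞;
  both saturate at the clamp bounds. Negative ratios are a contract
  violation upstream of the transform (the parser maps the format's
  negative sentinels to `NA` first).
* Features outside `[1, length]` are dropped at load time with a
  warning; the entry survives with the parsable subset. Overlaps are
  permitted and logged, and resolved by the priority above.
* Colour scale: within the no-change zone neutral grey `#808080`;
  outside it the red (down) or green (up) channel rises linearly from a
  floor of 64 at the zone edge — pure black would make faint changes
  invisible — to 255 at the clamp bound. The direction (green = up) is a
  documented default and configurable, since "red-green scale" alone
  does not fix a sign convention.
* The report bundle is written with a pure-R ZIP writer (DEFLATE, fixed
  member timestamps, canonical member order): identical input, config
  and seed give byte-identical archives, which makes shared result
  bundles diffable and cacheable. The browser-compatibility note keeps
  its historical file name `suppoted_browsers_and_os.txt` by default for
  drop-in compatibility with consumers of the original bundle layout;
  `corrected_browser_note = TRUE` fixes the spelling.
* IPI identifiers are recognized and normalized (version suffix
  stripped), but cannot be fetched online — the International Protein
  Index is retired — so IPI runs require a local annotation file or a
  user-supplied mapping to UniProt accessions.

## Known limitations

* Region assignment trusts stored annotation; proteins without topology
  annotation contribute to totals but never to domain means.
* Indistinguishable peptides listed under several proteins of a group
  are attached to each listing; no arbitration is attempted.
* Decoy entries are not specially detected; they simply fail annotation
  lookup and surface as unannotated.
* The per-protein table exposes both the protein-level ASAPRatio and the
  peptide-derived domain means; they answer different questions and are
  deliberately not merged.

## A complete example

```{r example, eval = FALSE}
fx  <- synth_fixture(n = 50, dir = tempfile(), seed = 42)
res <- pepmap(fx$protxml, fx$annotations)
glance(res)
autoplot(res, "cytoplasmic_domains")
plot_protein_map(res, res$proteins$accession[1])
screen_sppl_candidates(res, fc_cutoff = 1.0)
render_html(res, "report"); bundle("report")
```
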