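---
title: "Cross-linked peptide search: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-linked peptide search: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlms)
```

## The problem

Chemical cross-linking mass spectrometry maps protein-protein contacts:
a bifunctional reagent covalently bridges two residues that are close in
space, the proteins are digested (here with trypsin), and the cross-linked
peptide pairs are identified from their MS/MS spectra. Two features make
this search hard. First, the candidate space is quadratic: every pair of
digested peptides, times modification states, times (for metabolic-labeling
experiments) label combinations, is a potential precursor. Second,
cross-linked precursors carry high charge (typically 4+ and above for
tryptic pairs), so their CID fragments are often multiply charged and are
poorly handled by scoring schemes built for 1+/2+ fragments of linear
peptides.

`xlms` implements a complete search stack for this problem: candidate
database construction with the filters that keep the quadratic blow-up in
check, precursor matching, a fragment-level filter and count-based score
built around b/y ion complementarity, cross-link site localization,
decoy-based FDR control, and a relaxed-specificity ROC validation of site
assignment. A seeded simulator of cross-linked CID spectra makes the whole
stack testable without external data.

## Mass arithmetic

All masses are monoisotopic. The charge carrier is the hydrogen **atom**:

$$ M = z \cdot (m/z) - z \cdot 1.007825\ \mathrm{Da} $$

rather than the proton (1.007276 Da). This is the convention under which
the package's m/z, charge and neutral-mass columns are mutually consistent,
and it is applied uniformly to precursors and fragments. A peptide's
neutral mass is the sum of its residue masses plus water, plus positioned
modification deltas, plus — for a uniformly ^15^N-labeled chain —
0.9970349 Da per nitrogen atom in its residues. Nitrogen introduced by
chemical modifications after purification is natural-abundance and is
deliberately excluded from the label shift.

Fragment ladders run over cleavage sites $i = 1..n-1$: $b_i$ is the prefix
of length $i$, $y_j$ the suffix of length $j$ plus water, and
$b_i + y_{n-i} = M$ for every $i$ — an identity the test suite checks with
and without cross-link deltas. A cross-link at residue $s$ is treated as a
site modification of mass (bridge + partner-chain mass): every $b_i$ with
$i \ge s$ and every $y_j$ spanning $s$ shifts by that delta.

## Candidate database

`digest()` enumerates every peptide with up to `max_missed` missed
cleavages (default 2; trypsin cleaves C-terminal of K/R, not before P).
`filter_candidates()` then applies three rules before pairing:

1. peptides shorter than 3 residues are dropped;
2. peptides with no residue compatible with either linker end are dropped;
3. peptides whose **only** linkable site is a C-terminal cleavage residue
   are dropped. A cross-link on the C-terminal Lys of a tryptic peptide
   would have blocked cleavage there, so the true cross-linked peptide
   must extend past it — the filter *forces a missed cleavage*.

The protein N-terminal α-amine counts as a site for amine-reactive ends
when the peptide starts at position 1; it is encoded as the distinct site
token `0`, not as residue position 0, because residue 1 may independently
be a Lys. `build_pair_database()` then forms every unordered pair
(including a peptide with itself — homodimeric complexes genuinely produce
same-same links), expands variable modifications (capped at 2 per peptide
by default, configurable), and, when `labeling = TRUE`, enumerates the
^14^N/^15^N chain label combinations that let a search distinguish
intra-complex from inter-complex contacts in mixing experiments. Decoy
candidates come from reversed protein sequences (`build_decoy()`), pushed
through the identical pipeline but searched separately.

Built-in reagents: DSS (amine-to-amine, bridge C~8~H~10~O~2~ =
138.06808 Da once both NHS esters have reacted) and SDA (amine at one end;
after UV photolysis the diazirine loses N~2~ and the carbene inserts into
any residue — bridge C~5~H~6~O = 82.04186 Da). Custom linkers, enzymes and
modifications can be supplied programmatically or via a plain-text config
(`read_xl_config()`). A wildcard ("any residue") specificity is allowed on
end 2 or on both ends; the search cost grows linearly with the number of
candidate sites, which is what makes semi-specific reagents tractable
here.

## The b → complementary-y filter and the score

Under collision-induced dissociation the mobile protons of a cross-linked
tryptic pair stay on their own chains, so a charge-4+ pair fragments like
two independent charge-2 peptides. When a $b_i$ ion at charge
$z_b < z_\mathrm{precursor}$ is observed, the complementary $y_{n-i}$ ion
of the same chain tends to be observed at the remaining charge
$z_\mathrm{precursor} - z_b$. The matcher exploits this: for every
theoretical b ion of each chain and every $z_b$ below the precursor
charge, the spectrum is searched within the fragment tolerance; only when
a b ion matches is its complementary y ion looked up, at the remaining
charge. This prunes most of the theoretical spectrum and simultaneously
annotates the multiply charged fragments that high-charge precursors
produce.

Counts: a (chain, index) ion contributes once to $N_{mb}$ however many
charge states matched, keeping $N_{mb} \le N_{tb}$ well defined;
$N_{tb} = N_{ty}$ is the number of cleavage sites summed over both chains.
The score is

$$ \mathrm{score} = \frac{N_{mb}}{N_{tb}} +
   \frac{N_{my}}{N_{ty}} \cdot \frac{1}{R_{yb}(z)} $$

where $R_{yb}(z)$ is the median per-spectrum ratio of complementary y ions
to sub-precursor-charge b ions at precursor charge $z$, estimated from an
annotated library. The $1/R_{yb}$ weight up-values complementary y
evidence exactly where it is rare (high charge). Two genuinely open
choices are resolved as follows and kept switchable:

* **Grouping.** The weight applies to the y term only (default
  `score_grouping = "y"`); dividing the whole sum by $R_{yb}$ is available
  as `"global"`. The ratio is defined as a y-to-b correction, which only
  motivates weighting the y term.
* **Peak consumption.** A fragment match is "any peak within the Da
  tolerance", and one peak may satisfy several theoretical ions. No
  intensity weighting: the score is count-based by design.

Default tolerances are 10 ppm (precursor) and 0.5 Da (ion-trap CID
fragments); 0.02 Da suits FT-acquired fragment spectra. MGF blocks without
a CHARGE line are searched at charges 3–8 (configurable) since
cross-linked precursors are expected at 4+.

The shipped `default_ryb()` table (0.50/0.40/0.30/0.25 for z = 2/3/4/5+)
is an explicit placeholder with round values, not an empirical estimate:
regenerate the table from any annotated library with `ryb_table()` and
pass it to `search_config()`. Because scores are not comparable across
ratio tables, the table in use is echoed into the run manifest.

## Site localization

`localize_sites()` scores every valid (site A, site B) combination —
honoring both linker-end orientations — and returns the maximum. Ties go
to the lexicographically lowest pair and are flagged, with the co-optimal
set attached. Ties are not an edge case to hide: identical chains in a
self-pair, or chains where one is a prefix of the other, produce fragment
sets that genuinely cannot distinguish shared positions, and the
N-terminus token and residue 1 always carry the same fragment evidence.
The ambiguity flag is the honest report of that.

## Validation

**Decoy FDR.** Targets and decoys are searched separately (the
concatenated design is deliberately not the default here; with the
candidate filters applied equally to both databases, the separate design
matches how the score distributions are compared). The estimator is
$\#\{d \ge t\} / \max(1, \#\{t \ge t\})$; `fdr_threshold()` returns the
smallest threshold meeting the requested FDR and monotone q-values. When
no threshold qualifies it returns `Inf` with a warning rather than a
fabricated cutoff — with few true cross-links, a handful of decoy hits can
legitimately make every threshold fail, which is why FDR control needs
extra caution in cross-linking searches.

**Relaxed-specificity ROC.** How often is the *site* right, not just the
pair? Re-search data acquired with a residue-specific reagent (Lys-Lys)
declaring one end non-specific; localizations landing outside the known
specificity are false positives by construction. `relaxed_specificity_roc()`
sweeps the score threshold and integrates by the trapezoid rule, which
equals the Mann–Whitney pair-comparison statistic with half credit for
ties — the tests verify that identity exhaustively, and against an
independent ROC implementation.

## The simulator

`simulate_spectrum()` and `generate_dataset()` emulate what the matcher
assumes about CID of cross-linked tryptic pairs: each chain fragments
independently; each theoretical b ion is detected with probability
`p_detect` at a uniformly drawn charge below the precursor's; given a
detected b ion, its complementary y ion appears at the remaining charge
with a per-charge probability `q_comp`; fragment m/z values get uniform
jitter; uniform background peaks are appended; intensities are
exponential with unit mean (they only exercise I/O — the score never reads
them). Precursor charges are drawn from 4–6 by default.

Defaults are fixed at moderate noise — `p_detect = 0.8`, `q_comp`
0.70/0.55/0.40/0.30 for z = 2/3/4/5+, 20 noise peaks in 200–2000 Th,
0.2 Da jitter — chosen once as a plausible ion-trap regime: detection
around 80% and a complementary-y tendency that decays with charge are what
annotated ion-trap libraries qualitatively show, and 0.2 Da jitter sits
inside the 0.5 Da matching tolerance.

What the simulator does **not** emulate — and therefore what passing
closure tests cannot certify about real data: realistic intensity
patterns, isotope envelopes, neutral losses, co-isolated (chimeric)
precursors, mono-links and loop-links, systematic mass-calibration drift,
and retention-time structure. Closure results (planted-pair recovery, ratio
recalibration) validate the *internal consistency* of the stack under its
own fragmentation model, while the mass-arithmetic checks against
published identification tables anchor the conventions to real reported
data.

## Problem sizes and numerical choices

The test suite runs on synthetic proteins of 9–60 residues, pair databases
of up to a few hundred candidates, 200-spectrum recovery runs, and
2000-spectrum annotated libraries and ROC null checks — sizes chosen so the
complete suite exercises every module in well under a minute on one core.
Numerical details worth knowing:

* peak lookup is nearest-neighbour on the sorted m/z vector
  (`findInterval`), so matching cost is logarithmic per theoretical ion;
* report order is score-descending with scan-id tie-break, making repeated
  runs byte-identical;
* the empty peptide list, the empty spectrum, the header-only MGF and the
  all-one-class ROC input all have defined behavior (warning, zero counts,
  empty result + complete manifest, and an error, respectively);
* every stochastic component takes an explicit seed, and the simulator
  records it in its truth-table header.

## Limitations

Only b/y ions are considered (no a/c/x/z series, so ETD spectra are out of
scope), mono-links and loop-links are not modeled, protein-level FDR is
not attempted, and mzML/mzXML readers are not provided — inputs are
centroided MGF peak lists and NIST-style MSP libraries.
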