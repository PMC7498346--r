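---
title: "Models and methods behind srnapaint"
author: "srnapaint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnapaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapaint)
```

# What the package models

srnapaint covers the two computational halves of an sRNA-PAINT experiment:
designing the probe that puts a DNA-PAINT docking strand on a 21--24 nt
small RNA, and turning the resulting single-molecule localization data into
absolute binding-site counts. Because raw microscope acquisitions are
multi-gigabyte and rarely shareable, the package also ships a blink-kinetics
simulator that produces localization tables with known ground truth, so that
every quantitative claim made by the analysis code can be checked end to end
in software.

# Duplex thermodynamics

Probe design needs melting temperatures and screening free energies for
short DNA duplexes. We use the unified nearest-neighbor model: enthalpy and
entropy are summed over the 16 dinucleotide stacks plus two terminal
initiation terms, entropy is corrected for monovalent salt as
$\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$, and

$$T_m = \frac{1000\,\Delta H}{\Delta S' + R\ln(C_T/4)} - 273.15 .$$

Divalent magnesium is folded in as an equivalent sodium concentration
($\mathrm{Na}_{eq} = \mathrm{Na} + 120\sqrt{\mathrm{Mg}}$, all in mM).
Defaults are 50 mM Na$^+$, 0 mM Mg$^{2+}$, 25 °C and a 0.25 µM strand
concentration; the strand concentration is a vendor-style convention and is
exposed in `hybridization_conditions()` because no single value is canonical.
All parameters live in an editable YAML file
(`system.file("extdata", "thermo_params.yml", package = "srnapaint")`), so a
laboratory that calibrates against a particular vendor tool can substitute
its own table without touching code.

Locked nucleic acid (LNA) substitutions raise duplex stability by roughly
2--4 °C per base. Two estimates are provided. The *approximate* mode adds a
configured per-base increment per LNA position --- cheap enough to rank
millions of placement candidates. The *refined* mode re-runs the
nearest-neighbor sum with perturbed $\Delta H/\Delta S$ for each stack whose
5′ base is LNA-modified, falling back to the additive increment where the
table has no entry (for instance the 3′-terminal base). Every result records
which mode produced it. The shipped LNA values are screening-grade defaults
chosen once in the literature-typical range; they are configuration, not
physical constants, and all are constrained stabilizing so that adding an
LNA never lowers a predicted $T_m$ --- an invariant the designer's ranking
relies on.

Self-structure screening is deliberately simple. `self_dimer()` scans every
ungapped antiparallel alignment of the oligo against itself and scores
Watson--Crick complementary runs by stack $\Delta G_{37}$; `hairpin()` scans
every single stem--loop placement and adds a flat +3 kcal/mol loop penalty.
Neither is a partition-function fold: both are used only as filter/sort
keys, where correct *ranking* of obviously bad candidates matters and
absolute free energies do not. Degenerate IUPAC bases are rejected rather
than enumerated.

# The probe designer

A probe is backbone + linker + docking strand. The backbone is a 19--22 nt
window of the reverse complement of the target, preferring the longest
window whose DNA-only $T_m$ stays below a 60 °C ceiling (ties broken toward
lower $T_m$). When no window clears the ceiling the minimum-$T_m$ window
proceeds with a recorded warning --- a design tool that hard-fails on
GC-rich targets is not usable. The ceiling is applied to the DNA-only
$T_m$, before LNA placement, because window selection precedes LNA
placement in the pipeline.

LNA placement is exhaustive: every subset of 5--9 backbone positions that
avoids runs of more than four consecutive LNA bases and any three
consecutive LNA-modified G/C bases (G/C LNA stretches over-stabilize and
promote self-structure) is scored by approximate $T_m$. A 22-nt backbone
has about $10^6$ such subsets and a target has up to 18 windows, so the
enumeration runs as a compiled stream that maintains a top-200 shortlist and
never materializes the candidate set; the R-level
`enumerate_lna_masks()`/`shortlist()` pair implements the same contract at
small scale and serves as its reference in the tests. Ties break
deterministically (earlier window start, then lexicographically smaller
mask) so a design is byte-reproducible.

Each shortlisted candidate is assembled with the linker (default
`tattcgt`) and each requested docking strand, and screened: self-dimer and
hairpin $\Delta G$ of the *full* oligo, refined $T_m$ of the backbone alone
(the docking strand never hybridizes the target, so it cannot change the
probe's $T_m$; LNA positions are likewise confined to the backbone).
Candidates below the $\Delta G$ thresholds (defaults −9 kcal/mol dimer,
−3 kcal/mol hairpin) are dropped and the survivors are ranked by refined
$T_m$; the top 10 per docking strand are reported. A filter-then-sort
scheme was chosen over a composite $T_m$/$\Delta G$ score because $T_m$ is
the primary design quantity and the $\Delta G$ screens are pass/fail in
practice. Both thresholds are configurable; with random mid-GC targets the
defaults reject roughly half of all shortlisted candidates, and for some
target/docking pairs legitimately reject all of them (the design then
returns an empty list with a warning rather than an error).

The shipped docking-strand library is a *synthetic* set of 13 orthogonal
9-nt P-series sequences, generated to have no mutual complementary run of
five or more bases. It exists so the pipeline is runnable and testable out
of the box; real designs should substitute the laboratory's validated
docking/imager pairs via `docking_strands(path)`.

# qPAINT quantification

DNA-PAINT blinking is kinetic, not photophysical: a dye-labeled imager
strand binds its docking strand at rate $\xi = k_{on} c$ and dwells briefly.
With $n$ independent sites in a picked region, events arrive at rate
$n\xi$, so the mean dark time between events is $1/(n\xi)$ and

$$\hat n = \frac{1}{\xi\,\bar\tau_{dark}} .$$

The pipeline from a raw localization table to $\hat n$ is: photon filter
(420--10,000, both ends inclusive), fiducial drift correction, circular
pick (3.18 µm default diameter, 20 pixels at 159 nm/pixel, boundary
inclusive), event linking (consecutive frames merge; single-frame gaps are
bridged, `ignore_gap = 1`), dark times defined as
$(\mathrm{start}_{i+1} - \mathrm{end}_i - 1)\,\Delta t$ — two events in
frames 12 and 14 are one dark frame apart — and finally the estimator. The
off-by-one convention is stated because it shifts every estimate by a
frame. Non-specific binding measured with a scrambled control probe is
subtracted (default 5.12 sites, configurable) and clamped at zero.

Two dark-time estimators are provided, because it is ambiguous which one a
given analysis package reports: the arithmetic mean (requires ≥ 5 dark
times) and a least-squares fit of the empirical CDF to
$1 - e^{-t/\tau}$ (requires ≥ 20, more robust to occasional long
outliers). On simulated data with 200+ dark times the two agree within a
few percent.

Drift correction averages, per frame, the displacement of each fiducial
from its mean position, interpolates gaps, smooths with a 200-frame
centered moving average (suppressing 5--10 nm localization noise while
tracking slow mechanical drift) and anchors the track at zero at frame 0.
Channel registration is translation-only — fiducials are global landmarks
and the mean pairwise displacement is the least-squares translation;
affine registration is out of scope.

# Colocalization

Two-channel colocalization uses DBSCAN (defaults: eps 200 nm, minimum
cluster size 3) plus a per-point degree-of-colocalization score. For each
point, cumulative neighbor counts are profiled over a radius ladder (10 nm
steps to 2500 nm), converted to densities by dividing by $r^2$, and the
*step-to-step gradients* of the same-channel and cross-channel density
profiles are compared by Spearman rank correlation. Correlating gradients
rather than the cumulative profiles matters: cumulative profiles share
smooth trends (global density, field-edge falloff) between channels and
score spuriously high on independent data, while gradients cancel those
trends — identical channels still score +1, channels separated by more
than the maximum radius score 0 (a flat cross profile is defined as score
0), and independent uniform channels score near 0. The colocalized
fraction is the percentage of points at or above a 0.4 score threshold.
DBSCAN labels are canonicalized (clusters numbered by smallest member
index; border points join their nearest core neighbor) so results do not
depend on point order.

# The simulator

`simulate_blinking()` renders each site as an alternating renewal process —
exponential dark dwells at rate $\xi$, exponential bright dwells with mean
`tau_bright_s` (default 0.5 s; unreported in typical experiments, chosen
once so that $\tau_{bright} \ll \tau_{dark}$ holds at nanomolar imager
concentrations, the regime qPAINT assumes) — then rasterizes bright
intervals to frames (a frame counts as bright when the interval covers at
least half of it), placing one localization per bright frame with Gaussian
noise (default 8 nm), cumulative linear drift, and log-normal photon counts
(median 2000, sdlog 0.5, so the photon filter is exercised with realistic
tails). Defaults follow a standard acquisition: 20000 frames at 100 ms.
Multiple sites may be bright simultaneously and are not merged spatially.
All generators are deterministic under their seed.

What the simulator does *not* emulate: raw camera frames and PSF shape,
detection/fitting failures, photobleaching of fiducials, imager depletion,
and spatial overlap artifacts. Passing tests therefore demonstrate the
correctness of the kinetics-to-count chain, not robustness to every
pathology of real acquisitions.

## A known bias, quantified

Rasterization makes the simulated data realistically imperfect: with
$\tau_{bright}$ = 0.5 s and 0.1 s frames, roughly one bright event in
seven is shorter than half a frame and yields no localization at all.
Each lost event fuses two dark intervals, inflating the measured mean dark
time, and single-frame gap bridging adds a smaller effect of the same
sign. The net result is a systematic 10--15% *underestimate* of the site
count under the default conditions — at 20000 frames and 5 nM imager the
median recovery error across seeds sits at 0.10--0.15 depending on the
true count. Real qPAINT data share this bias (short events are lost to
detection thresholds there too), which is one reason practitioners
calibrate against a known-count control. At one true site the same
conditions yield only ~15 binding events in the whole acquisition, too few
for the CDF estimator's 20-dark-time requirement; use the mean estimator,
longer acquisitions, or higher imager concentrations in that regime.

# Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they check:
oracle comparisons use exhaustive enumeration on 10--14-mers (where brute
force is exact), designer audits run ~100 random 21--24 nt targets against
two docking strands, and qPAINT recovery uses 50 seeds per condition at
the full 20000-frame acquisition length. These sizes keep a complete run
in the minutes range on one core while leaving the statistical assertions
comfortably powered.

# Worked example

```{r example, eval = FALSE}
cond <- hybridization_conditions()          # 50 mM Na+, 0 Mg2+, 25 C
target <- random_srna(22, gc_fraction = 0.45, seed = 22)
design <- design_probes(target, cond, docking_ids = c("P0", "P1"))
as.data.frame(design)

k <- kinetic_params(k_on = 1.5e6, c_M = 5e-9)
sim <- simulate_blinking(sim_config(n_sites = 10, kinetics = k, seed = 7))
dk <- dark_times(link_events(sim$table), 0.1)
binding_sites(dk, influx_rate(k), estimator = "mean")
```

# Limitations

* The thermodynamic tables target DNA/DNA duplexes; RNA/DNA hybrid
  parameters and full secondary-structure prediction are out of scope, so
  absolute $T_m$ values for LNA-rich probes against RNA should be treated
  as rankings, not measurements.
* Localization I/O is CSV; binary localization formats should be converted
  upstream.
* Drift correction and registration are translation-only and
  fiducial-based; cross-correlation drift correction is not implemented.
* The DoC score's normalization at very different channel densities is an
  open question in the underlying method; the radius ladder and threshold
  are exposed as parameters rather than fixed.
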