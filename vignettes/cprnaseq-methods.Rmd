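---
title: "Modeling cP-RNA and piRNA sequencing chemistry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cP-RNA and piRNA sequencing chemistry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprnaseq)
```

## The problem

A 2′,3′-cyclic phosphate (cP) at an RNA 3′ end is the chemical signature of
cleavage by a metal-independent endoribonuclease, and it makes the molecule
unligatable — hence invisible — to standard small-RNA sequencing. In animal
germlines a C–A-preferring, mitochondria-associated RNase of the RNase κ
family produces cP-RNAs from transposon transcripts, and the subset that
additionally carries a 5′-monophosphate (P-cP-RNAs) is loaded onto PIWI
proteins as piRNA precursors. Establishing that relationship from sequencing
data requires reasoning simultaneously about (i) which molecules each
protocol can see, and (ii) statistics that connect independently sequenced
populations: shared 5′ ends, shared genomic origin, correlated abundance, a
ping-pong signature, and spike-in-calibrated totals. This package implements
both layers, plus a simulator that generates libraries where every statistic
has a knowable true value.

## The end-chemistry model

A molecule's analysis-relevant state is the triple
(5′ state, 3′ state, destroyed), with 5′ ∈ {phosphate, hydroxyl} and 3′ ∈
{cyclic phosphate, monophosphate, hydroxyl, 2′-O-methylated hydroxyl};
`blocked_by_adapter` marks a consumed end. Treatments are deterministic
transitions:

* **CIP** removes terminal monophosphates (3′-P → OH, 5′-P → OH) but cannot
  open a cyclic phosphate.
* **T4 PNK** opens the cP and removes 3′-P (both → 3′-OH) and
  phosphorylates 5′-OH.
* **Periodate (NaIO₄)** destroys an unprotected 3′ cis-diol (plain 3′-OH);
  cP, 3′-P, and 2′-O-methyl ends resist.
* **Ligations** require a 3′-OH (methylated or not) or a 5′-P respectively;
  failure leaves the molecule intact but unsequencable, mirroring the bench
  reality that an unligated molecule simply never amplifies.

A protocol is an ordered treatment list and a length window; retention =
in-window length ∧ both ends adapter-blocked ∧ not destroyed. Retention is
a function of chemistry and length only — never sequence — which the test
suite asserts as a property.

Three modeling choices deserve justification. First, the 3′-monophosphate
state is included although the protocols are not designed around it: the CIP
control is only interpretable if a CIP-sensitive 3′ state exists, and its
truth-table row (CIP converts it to a periodate-sensitive OH, so cP-RNA-seq
drops it) is exactly why the control discriminates. Second, 2′-O-methylated
3′ ends are treated as ligatable with efficiency 1.0 (configurable 0–1):
mature piRNAs are excluded from cP libraries by the 30–70 nt size window,
not by ligation chemistry, and the model keeps that truthful. Third,
periodate oxidation is complete by default, with a configurable leak
probability (default 0) for robustness experiments only.

One ordering question is genuinely open: whether the cP-RNA-seq CIP step
sits before or after gel purification. Computationally nothing depends on
it — CIP commutes with size selection in this model — so the canonical step
order follows the protocol schematics: piRNA-seq = periodate, 3′-ligate,
5′-ligate; cP-RNA-seq = CIP, periodate, PNK, 3′-ligate, 5′-ligate;
P-cP-RNA-seq ligates the 5′ adapter first and then runs the cP-RNA-seq tail;
OH-RNA-seq ligates directly. A useful, non-obvious consequence the truth
tables expose: removing T4 PNK from cP-RNA-seq retains *nothing* (CIP has
stripped every 5′-P and nothing rephosphorylates it), which is precisely the
no-PNK control's empty gel lane.

## The simulator and what a green test establishes

`make_reference()` draws i.i.d.-uniform random reference sequences; the
spike-ins default to the two published 28-nt and 33-nt synthetic RNAs.
Defaults state the world once: 50 transposons of 1–5 kb (the demo pipeline
uses 20 × 0.4–1.2 kb purely for runtime), one 76-nt tRNA with the anticodon
annotated at position 35, one rRNA decoy, log-normal(0, 1) per-feature
expression so count correlations have dynamic range.

Cleavage cuts bond *i* independently with probability
`cut_rate · w(d_i)/max(w)`. Default weights CA = 1.0, CC = 0.35, AA = 0.35,
GU = 0.05 encode the enzyme's measured *ordering* (strongest → weakest); the
numeric values are configuration defaults, not measured constants. UA = 0.25
represents the C/U–A bias of the insect libraries. Every cut leaves
3′-cP / 5′-OH; outermost ends keep the precursor chemistry, which defaults
to 5′-P / 3′-OH (a processed Pol II-like transcript) because the true 5′
state of long precursors upstream of primary cleavage is not established —
it is a single configurable assumption.

Maturation is population-semantic: a fragment is a species, and derivatives
are *added*, never substituted. With probability `p_load` a fragment gains a
5′-processed P-cP derivative starting at the nearest downstream U (scan
window 10 nt); with `p_mature` that gains a mature piRNA (3′ trimmed to
23–30 nt, 2′-O-methylated); with `p_pingpong` the piRNA gains an antisense
partner at exactly 10 nt 5′–5′ overlap. This matters: if maturation
consumed its input, the cP library and the piRNA library could never share
sequences, and the central cross-mapping statistics would be structurally
zero. Two parameters exist for statistical realism rather than mechanism:
`p_shift5` (default 0) resects a mature 5′ end 1–3 nt so the 5′-anchored
fraction is a real parameter rather than identically 1, and
`background_antisense` (default 0.3) emits antisense reads at uniform non-10
overlaps so the ping-pong signal has a background; with `p_pingpong = 0.7`
the default world sits in the ~70%-signal regime that real piRNA libraries
show. Spike-ins are modeled with a periodate-resistant ligatable 3′ end
because they are added after oxidation, before ligation.

What the generator does *not* emulate: sequencing error, PCR and ligation
sequence bias, quality-score structure, isodecoder families, secondary
structure, and any kinetic realism. A green test therefore establishes that
the *statistics recover what the generator put in* under ideal reads — it
validates the analysis code, not the wet-lab protocol.

## Analysis conventions and numerical choices

* Coordinates are 0-based half-open internally, 1-based closed in every TSV.
* Mapping is Hamming-only (no indels) with `floor(0.05 · length)`
  mismatches, reporting only minimum-mismatch placements — the behavior of
  a short-read aligner run in v-mode. Tier order is spike-ins (when
  present), tRNA, rRNA, transposons; a read is consumed by the first tier
  that accepts it, so tiers partition the mapped reads. Multimapping
  resolves to one seeded uniform choice per read for counting
  ("random-one", the aligner default), while end-composition can use all
  placements.
* tRNA references get CCA appended when the annotation lacks it. tRNA-half
  classification uses a ±4 nt window around the anticodon first position;
  the half/fragment boundary is nowhere numerically defined in the
  literature this models, so the window is a documented decision, not a
  derived constant.
* Adapter trimming is single-pass 3′-only, leftmost qualifying match,
  minimum overlap 6, error fraction 0.1, N counts as mismatch.
* Flank composition uses k = 3 positions per side of each cleavage site;
  flanks come from the reference, covered positions from the read.
* Cross-mapping is sense-strand: the question is whether the piRNA's own
  sequence lies within a cP-RNA species. The terminal-match denominator is
  mapped queries only (recorded in the output metadata); queries hitting
  m species are weighted 1/m.
* Ping-pong pairs are weighted by the product of the two 5′-position read
  counts (the standard convention; the source analyses cite prior work
  without a formula), and the report carries both the pair-level
  `signal_fraction` and the read-level `participant_fraction` because
  "proportion of reads" is ambiguous between them.
* RPM correlation defaults to squared Pearson correlation of log₁₀ RPM
  above a floor of 10 in both libraries; raw-scale Spearman is available.
* Spike-in scale factors are arithmetic means of input/observed over usable
  spike-ins (geometric optional); spike-ins with zero counts in either
  library are dropped with a warning — with the default windows each
  library retains exactly one of the two spike-ins (28 nt fits the piRNA
  window, 33 nt the cP window), so this is the normal path, and it errors
  only when none survive.

## Known limitations

Degenerate inputs are handled explicitly: an empty retained pool names the
protocol in its error; an empty tier makes RPM an error rather than NaN;
fewer than three features above the RPM floor makes correlation an error.
The mapper is exhaustive-scan-based and sized for reference *sets* (tens of
features, desk scale), not genomes. The chemistry model is Boolean — no
partial reaction efficiencies except the two documented knobs — and the
simulator's uniform random references understate the repeat structure of
real transposon families, which would raise multimapping rates well above
what the demo shows.
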