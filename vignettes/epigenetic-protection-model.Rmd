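---
title: "A coupled model of histone methylation, promoter DNA methylation and transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled model of histone methylation, promoter DNA methylation and transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprotect)
```

## The model

`epiprotect` describes one gene promoter by four coupled quantities: the
fractions of promoter nucleosomes tri-methylated at H3K4 (`m4`) and at
H3K27 (`m27`), the fraction of methylated promoter CpGs (`mcpg`), and a
transcription level (`T`). Histone methyltransferase (HMT) complexes for
the two marks compete for the promoter's unmodified nucleosomes; both are
CpG-island binders whose DNA interaction is blocked by CpG methylation;
each is stabilised by nucleosomes already carrying its own mark
(reader–writer feedback). Transcription couples back into the chromatin:
it stabilises the H3K4me3 writer (co-transcriptional recruitment of
MLL/COMPASS-type complexes) and destabilises the H3K27me3 writer
(transcription antagonises Polycomb).

Writer binding probabilities are logistic in a total binding energy
(units of kT):

$$P_k = \sigma\!\big(E_k - \varepsilon_0 - \delta_k\big), \qquad
  \sigma(x) = 1/(1+e^{-x}),$$

$$E_4 = \varepsilon_{BS}\,(1-m_{CpG})\,\phi\,(1+\gamma_4 m_4)
       + \varepsilon_T\,T + \varepsilon_F\,(F_{TF}-1),$$

$$E_{27} = \varepsilon_{BS}\,(1-m_{CpG})\,\phi\,(1+\gamma_{27} m_{27})
       - \varepsilon_x\,T,$$

with $\delta_4 =$ `d0_4` an offset of the H3K4me3 writer threshold
(negative: H3K4 methylation is the lower-barrier, more promiscuous mark)
and $\delta_{27} = 0$. The mean-field dynamics are

$$\dot m_4 = k_m P_4 (1 - m_4 - m_{27}) - k_d m_4,\qquad
  \dot m_{27} = k_m P_{27} (1 - m_4 - m_{27}) - k_d m_{27},$$

$$\dot m_{CpG} = D_{novo}\,\phi\,(1-m_4)(1-m_{CpG})
   - \big(1 - p_{maint}(m_{CpG})\big)\,m_{CpG}/\tau,$$

$$\dot T = k_{tr}\,F_{TF}\,\frac{1 + a_T m_4}{1 + b_T m_{27}} - \lambda T,$$

where maintenance methylation
$p_{maint}(m) = p_0 + (1-p_0)\,m^h/(m^h + K^h)$ increases cooperatively
with the methylation level (methylation-dependent DNMT1 binding). This
cooperativity makes the DNA-methylation subsystem bistable: a low and a
high methylation state separated by an unstable threshold `mcpg_C`
(`mcpg_threshold()`), with the bistable range of de novo activity
`[D_novo_C0, D_novo_C1]` reported by `scan_bifurcation()`.

Three design choices deserve explanation, because the qualitative
dependencies admit several algebraic realisations and we fixed them by
requiring the full five-state structure to exist:

* **Multiplicative cooperativity.** The reader–writer feedback multiplies
  the DNA-binding energy, $\varepsilon_{BS}(1-m_{CpG})(1+\gamma m)$,
  rather than adding an independent $\gamma m$ term. With an additive
  term, the cooperativity strength needed to keep the bivalent state
  locally stable also lets H3K27me3 sustain itself on a fully methylated
  promoter, creating a spurious sixth stable state; the multiplicative
  form guarantees that on the high-methylation branch only the unmodified
  state survives, because the cooperative amplification has no binding
  energy left to amplify.
* **Asymmetric writers.** The H3K27me3 writer is strongly
  mark-cooperative ($\gamma_{27} = 20$) — the Polycomb read-and-spread
  loop — while the H3K4me3 writer combines weaker mark cooperativity
  ($\gamma_4 = 10$) with a lower binding threshold (`d0_4 = -0.5`) and
  transcription/TF coupling. This asymmetry is what lets H3K27me3 states
  be invaded by H3K4me3 (and vice versa) at biologically sensible rates
  while both single-mark states, the bivalent state and the unmodified
  state remain locally stable.
* **Direct TF recruitment of the H3K4me3 writer**
  ($\varepsilon_F (F_{TF}-1)$, zero at the reference activation).
  Promoter-bound activators recruit MLL/COMPASS complexes directly. In
  the stochastic simulations this term is what moves the population
  toward H3K4me3-rich states when the TF input rises: the exit from the
  H3K27me3 state cannot respond to $F_{TF}$ through transcription alone,
  because transcription of that state is always repressed
  ($b_T m_{27} \gg 1$).

## Fixed points and the five regulatory states

At the reference profile (`epi_params()`, $F_{TF}=1$,
$\varepsilon_{BS}=5$, $D_{novo,0}=0.1$) the self-consistent equations
have 13 solutions: five locally stable — H3K27me3 (a), bivalent (b),
H3K4me3 (c) and two unmodified states with low (d) and high (e) DNA
methylation — and eight unstable saddles, including three on the unstable
middle branch of the methylation subsystem.

```{r fixed-points}
fp <- find_fixed_points(epi_params())
fp[fp$stable, c("label", "m4", "m27", "mcpg", "T")]
```

`find_fixed_points()` runs a damped Newton iteration from a multi-start
grid (extra resolution near the unmodified edge of the simplex, where
nucleation saddles have very small basins), deduplicates converged roots
at `1e-4` in the maximum norm, and classifies stability by the eigenvalue
spectrum of a central finite-difference Jacobian (step `1e-6`, stable iff
the largest real part is below `-1e-9`). Labels use the half-maximal
thresholds $\theta = 0.5\,m_{k,max}$; `m4_max = m27_max = 0.75` is the
saturation level $k_m/(k_m+k_d)$ of a fully committed promoter.

## Stochastic population dynamics

The stochastic simulator (`simulate_population()`) represents each cell's
promoter by `N_nuc = 20` nucleosomes (a 4 kb promoter at ~200 bp
spacing). Per time step (`dt = tau/100`) each unmodified nucleosome gains
a mark with probability $k_m P_k\,dt$ (ties broken proportionally to
$P_4 : P_{27}$), each modified nucleosome loses its mark with probability
$k_d\,dt$; transcription is integrated by explicit Euler. Cells divide
every `tau` (phases staggered uniformly to avoid synchronisation
artifacts); at division each modified nucleosome is retained with
probability 1/2 — the histone-dilution perturbation — and the CpG
methylation fraction is updated once by the deterministic per-cycle map.
Suppressing single-CpG fluctuations is deliberate: it separates the low-
and high-methylation basins exactly, so a cell can cross `mcpg_C` only
through a real change of the de novo/maintenance balance, not by noise
accumulation. One daughter is tracked per division (constant population).

The per-label occupancy counts reported by the simulator are snapshot
classifications against the half-maximal thresholds; because division
halves both marks, a resident of a single-mark state spends part of every
cycle just below its threshold, so some of its occupancy is booked to the
unmodified class. The population means are free of this artefact and are
what the acceptance analysis uses.

Under this noise the five attractors become metastable and the population
relaxes to a quasi-steady state whose composition depends on the TF
input: at $F_{TF}=0.7$ the H3K27me3 attractor dominates; at
$F_{TF}=1$ the population is dominated by H3K27me3/bivalent states with
mean transcription below 0.2; at $F_{TF}=1.4$ H3K4me3-rich states take
over and mean transcription exceeds 0.6. The high-methylation state e is
never reached from the low-methylation attractors at the reference
de novo rate.

## H3K4me3 recruitment by reduced de novo methylation

Reducing $D_{novo,0}$ lowers the low-branch methylation level, which
raises both writers' DNA-binding energy. `dnovo_sweep()` reproduces the
binding-energy dependence of this response: at
$\varepsilon_{BS}=5.5$ (the G1-like, high-CpG gene) the population
H3K4me3 level is elevated across the grid and rises further as the rate
drops below its reference value; at 5.2 recruitment appears only at low
rates; at 5.0 (G2-like) the level stays flat. `recruitment_threshold()`
operationalises the threshold as the largest scanned rate whose mean `m4`
exceeds the reference-rate value by half the curve's own response
amplitude (floored at a 0.02 noise floor). Because the response
amplitudes (~0.05 in mean m4) are comparable to the Monte-Carlo spread of
a 500-cell run, the detected threshold position of the intermediate curve
fluctuates by a few grid steps between realisations; the deterministic
basin analysis (`basin_map()`) exposes the underlying attractor growth
noise-free. Because the
recruited state carries high `m4`, it suppresses its own de novo
methylation flux ($1-m_4$), lowering `mcpg` further — the positive
feedback that makes recruitment essentially all-or-none per cell, while
mean transcription changes little (see `analysis/03_dnovo_sweep.R`).

## DNA repair and hyper-methylation

`simulate_repair()` implements the damage protocol: after equilibration,
each cell is hit at most once per cycle with probability
`repair_freq * tau`; a hit raises the effective de novo rate to
`D_repair = 0.3` — above `D_novo_C1`, so the low-methylation state is
transiently unstable — for `duration <= tau` (default the full cycle,
time-weighted into the per-cycle CpG update; the damage is fully repaired
within the cycle in which it occurs). A cell is called hyper-methylated
when its `mcpg` exceeds `mcpg_C` at the end of a cycle whose effective
rate was the baseline, so transient repair excursions do not count; the
call is confirmed by convergence towards the high fixed point, and is
absorbing under baseline dynamics by the bistability of the methylation
map. Single hits are healed within a few cycles (exponentially, as the
methylation map is smooth near the low fixed point); hyper-methylation
requires runs of hits in quick succession. Lowering the baseline rate by
20% (0.08 vs 0.10) lowers the hyper-methylation probability at every
repair frequency and raises the number of repairs endured before
hyper-methylation — the protective effect of the H3K4me3-recruiting,
low-de-novo state. Below `D_novo_C0` the high-methylation state does not
exist and hyper-methylation is impossible.

## Genomic stage

`assign_quadruplets()` encodes each gene, in each of four conditions
(untreated and irradiated wild type, mismatch-repair-deficient untreated
and irradiated), as a 0/1 quadruplet over (H3K4me3, H3K9me3, H3K27me3,
H3K36me3): a bit is 1 iff at least one base of a peak of that mark
overlaps the strand-oriented promoter window `[TSS - 2000, TSS + 2000)`
(0-based, half-open; interval arithmetic via `GenomicRanges`).
`derive_gene_sets()` then forms G0 (all `0010` genes in the untreated
wild type), G1 (G0 genes that switch to `1010` in **all three** stress
conditions) and G2 (G0 genes that never recruit H3K4me3; a strict mode
additionally requires the full state to remain `0010`). Genes with
several annotated starts use the 5'-most TSS.

`profile_promoters()` computes, per promoter, the CpG/GpC dinucleotide
count ratio — CpG density normalised by base composition, since GpC is
not a methylation target — and the high/intermediate/low CpG-density
class from a 500 bp sliding window (HCG: any window with GC $\ge 0.55$
and CpG observed/expected $\ge 0.75$; LCG: no window reaches O/E 0.48;
else ICG). The thresholds are the classical CpG-island promoter criteria;
the window O/E is `#CG * L / (#C * #G)` with N bases excluded.
`ks_two_sample()` wraps the two-sided Kolmogorov–Smirnov test
(`stats::ks.test`; exact for small untied samples) used both for the
G1-vs-G2 promoter comparison and the repair-count comparison.

## The synthetic fixture generator

Real ChIP-seq peak sets for this system are external data; the package
instead ships `generate_fixture()`, which writes a fully synthetic but
structurally faithful data set: 2000 genes on one synthetic chromosome
(10 kb spacing, alternating strand), 16 peak BED files (4 marks × 4
conditions), promoter FASTA, ground truth and a YAML manifest. It plants
319 G1-like and 557 G2-like genes, the set sizes of the experimental
system it emulates. Background
`0010` genes recruit H3K4me3 in a random *proper* subset (1–2 of 3) of
the stress conditions, so they belong to neither planted set — the
generator realises the observation that partial recruitment is common.
Promoter sequences come from a first-order Markov chain whose C→G
transition weight is solved (via the stationary distribution) to hit a
target CpG/GpC ratio exactly in expectation; G1-like promoters target
ratio 0.9 at GC 0.58 (mostly HCG), G2-like 0.55 at GC 0.48 (mostly
ICG/LCG), background intermediate — chosen once as a realistic rendering
of the observed contrast, with a lognormal spread (sd 0.15 on the log
scale). What passing tests on these fixtures show is that the *pipeline*
is correct (overlap logic, set algebra, sequence statistics); they cannot
certify the biological peak-calling upstream of it, which is out of
scope.

## Numerical choices and problem sizes

* Fixed-point solver: damped Newton with an analytic Jacobian inside the
  iteration, residual tolerance `1e-11`, multi-start grid of ~1000
  starts; census robustness was checked against a denser grid.
* Stochastic runs in the analysis scripts use 500–1000 cells and
  50 + 50 cell cycles (the figure-scale protocol is 5000 cells; means
  agree within the Monte-Carlo spread, which the scripts report).
* The per-cycle CpG map shares its fixed points with the continuous-time
  equation, so deterministic and stochastic stages agree on `mcpg_C`.
* Degenerate inputs: sequences without GpC give a flagged undefined
  ratio; comparisons on empty hyper-methylation groups are marked
  undefined rather than fabricated.

## Limitations

* Parameter values are calibrated to reproduce the qualitative state
  structure and population behaviour, not fitted to molecular rate
  measurements; absolute time scales inherit the nominal one-day cell
  cycle.
* The promoter is mean-field inside one locus: no nucleosome spatial
  structure, no linkage between neighbouring genes, no lineage trees.
* H3K9me3 and H3K36me3 are carried through the genomic encoding but not
  modelled dynamically.
* Active (TET-mediated) demethylation is absent by design; the model
  gene's methylation can only fall by replication dilution.
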