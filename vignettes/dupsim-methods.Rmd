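---
title: "Simulating concerted evolution of segmental duplications: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating concerted evolution of segmental duplications: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dupsim` simulates a Wright–Fisher population of `N` diploid individuals in
which every chromosome carries two or three *blocks* of `L` nucleotides. A
block is represented sparsely, as the sorted set of positions (0-based, in
`[0, L)`) at which the chromosome carries a derived mutation. The three-block
layout in chromosome coordinates is: original block `[0, L)`, single-copy
block `[L, 2L)`, duplicated block `[2L, 3L)`. The single-copy block is a
control locus: nothing ever exchanges genetic material with it, so its
equilibrium diversity must equal the neutral expectation `Theta = theta * L`.

Every run has three phases:

1. **Burn-in** (`T1` generations, default `30N`): two-block chromosomes under
   mutation, drift, and crossover, until mutation–drift equilibrium.
2. **Structured phase**: at `t = T1 + 1` the original block of one random
   chromosome is copied and pasted to the right of its single-copy block.
   This unique duplication is carried to fixation along a neutral
   Wright–Fisher trajectory conditioned on fixation: carrier counts
   `s(t')` start at 1 and reach `2N` after `T2` generations (mean close to
   `4N`; trajectories longer than `T2max = 20N` are rejected, a mild extra
   conditioning on the trajectory law).
3. **Concerted evolution** until `t = TT` (default `120N`): all chromosomes
   carry three blocks and interlocus gene conversion (IGC) between the
   paralogous blocks competes with mutation and crossover in shaping
   diversity.

### Mutation

Pseudo infinite-sites: each block mutates with probability `mu * L` per
generation (at most one new mutation per block per generation), and the new
position is drawn uniformly among positions *not currently occupied* by a
derived allele in the relevant registry class. The single-copy block has its
own class; the original and duplicated blocks share a joint class, so a
variant segregating in either paralog blocks that offset in both — and a
variant is only treated as fixed when it is present on all `2N` chromosomes
in both paralogs. Fixed derived mutations are erased right after each
recording; the freed positions may mutate again later, an inherent property
of this mutation scheme which we document rather than patch.

Two small interpretation choices (see the decisions ledger for context): a
position is "occupied" when at least one *materialized* chromosome of the
current generation carries it (the strict present-in-some-but-not-all rule
would make a fixed-but-not-yet-erased position eligible for a degenerate,
invisible re-mutation); and mid-Era the registry is computed over the
materialized (fertile) chromosomes only, which is exact for every quantity
the package ever reports because non-fertile chromosomes leave no
descendants and samples are only drawn at Era ends, where all `2N`
chromosomes are materialized.

### Crossover

Crossover occurs with probability `r = R/(4N)` per meiosis — at most one
junction per meiosis, *irrespective of chromosome length*, so the same mean
number of crossovers happens per generation under every model. The junction
is uniform over the region the model allows:

* **SCC** (single-copy crossover): `[L, 2L)` — the classical "intergenic
  crossover only" assumption of multigene-family models;
* **WRC** (whole-region crossover): `[0, 3L)`;
* **HSC** (hotspot crossover): the union of user-defined intervals.

When the two chromosomes of a meiosis differ in length (pre-fixation), the
junction is instead uniform on their shared length `[0, 2L)` whatever the
model, and the daughter always has as many blocks as its parent: it inherits
coordinates `<= junction` (junction included) from the parent's partner and
the rest from the parent. For an equal-length two-block meiosis the model
region is intersected with `[0, 2L)`, falling back to the full shared length
if the intersection is empty (e.g. an HSC hotspot placed inside the
duplicated block during burn-in).

### Interlocus gene conversion

Per three-block chromosome and generation the number of IGC initiations is
Poisson with mean `2Lg`, where `g` is the per-site initiation probability —
the natural limit of the per-site Bernoulli description, and it permits more
than one event per generation (the literal reading is ambiguous; at
`g << 1` the two coincide). Each event initiates at a uniform site of a
uniform paralog, picks donor and receptor with probability 1/2 each, draws a
tract length `l` from the geometric law `P(l) = q(1-q)^(l-1)`, and converts
the closed tract reaching `floor(l/2)` sites left and right of the
initiation offset, truncated at the block edges (rounding is unspecified in
the source material; symmetric flooring makes the realized tract
`2*floor(l/2)+1` sites before clipping). Conversion is copy-paste: within
the tract the receptor's derived positions become exactly the donor's;
paralogous positions map by identity of offsets, implied by the copy-paste
duplication event.

**The tract-parameter contradiction.** The literature this model descends
from states both that tracts have *mean* `lambda` and that the geometric
parameter is `q = lambda/L` — but a geometric with `q = lambda/L` has mean
`L/lambda` (50 for `lambda = 100`, `L = 5000`), not `lambda`, and the
self-consistency relation `c = g * lambda` then breaks. `dupsim` exposes
both readings: `tract_q_mode = "mean_lambda"` (default, `q = 1/lambda`, so
realized tract lengths average `lambda` and `C = 4N g lambda` is coherent)
and `"literal_eq1"` (`q = lambda/L`). All shipped tests and acceptance runs
use `mean_lambda`.

An optional identity threshold (`igc_identity_threshold`) skips events when
paralog identity `1 - d/L` falls below the cutoff; it is **off** by default,
matching the main-text choice of unconditional IGC.

### Eras: simulating only fertile chromosomes

Under neutrality the genealogy is independent of genetic content, so each
block of `k` generations (an *Era*, default `k = N`) is generated in
advance: every slot is assigned a uniform parent; during the structured
phase exactly `s(t')` uniformly chosen slots are carriers and carriers
descend only from carriers. Walking backward from the Era's final generation
(all fertile), each fertile slot's parent is tagged fertile, and with
probability `r` the parent's *partner* — the other chromosome of the same
individual, slots pairing positionally as `(2i-1, 2i)` — is tagged too.
That Bernoulli draw is recorded and reused as the decision that the meiosis
recombines, so tagging and execution can never disagree (re-drawing at
execution time could require an untagged, unmaterialized partner). Only
fertile slots are instantiated. A sample of `n = 50` individuals (100
chromosomes) is recorded at every Era end, after which fixed mutations are
pruned.

The founding carrier is fertile by construction: all later carriers descend
from it and Era-final generations are entirely fertile, so the conditioned
trajectory is never lost to pruning.

## Statistics

* `pi_w` — mean pairwise difference within a block (computed through the
  derived-count identity `sum_p k_p (n - k_p) / choose(n, 2)`, exactly equal
  to the literal mean over pairs); `pi_b` — between original and duplicated
  blocks on *different* chromosomes (ordered pairs `i != j`, equivalently
  the symmetrized mean — the direction of comparison is immaterial because
  donor and receptor roles are symmetric); `pi_s` — between paralogs on the
  *same* chromosome. The single-copy block's `pi` is the control.
* Site-frequency spectra, segregating sites, and `pi` binned along each
  block (bins partition the block, so bin values sum to the block `pi`).
* Windowed LD: blocks are tiled with 100-bp windows; for every window pair,
  `|D'|` and `r^2` are averaged over all cross-window pairs of
  sample-segregating sites (distinct sites on the diagonal), per run first —
  making window pairs comparable regardless of how many mutations they
  happen to contain — then across runs. Window pairs with no supporting site
  pair are missing, not zero: absence of polymorphism is not linkage
  equilibrium. `|D'|` is used because derived-allele labels across paralogs
  carry no consistent sign. The paralogous-window diagonal (original window
  *i* vs duplicated window *i*) is the "LD between duplicates" readout.

## Scaled acceptance runs

The reference experiments were run at `N = 1000` with thousands of
replicates. The package's acceptance suite reruns them at `N = 100–200`
holding `theta`, `C`, `R` and `lambda` fixed, which preserves all
diffusion-limit equilibrium ratios (`pi_w/Theta`, `pi_s`, LD regimes); the
price is Monte-Carlo noise, paid with replicates and with tail averaging
(equilibrium readouts average all recordings with `t >= 80N`; the
duplication is fixed by `~50N` at the latest, and the trajectories flatten
well before `80N`). This cutoff was chosen once, from the phase structure,
not tuned. Two designed deviations:

* The WRC-vs-SCC equivalence (`R' = (2/3) R`) is tested at `R = 9` with grid
  spacing `R/6 = 1.5`. The `pi_w(R')` curve at `C = 1` saturates above
  `R' ~ 10`, so a grid around `(2/3) * 50` could not be resolved at desk
  scale; on the steep part of the curve the nearest-match criterion is
  well-conditioned, and the equivalence claim itself is
  scale-free.
* `pi_s` at `C = 100, R = 50` is *not* near zero at the stated tolerance
  (`< 0.1 Theta`): a same-chromosome paralog pair coalesces through IGC at
  rate `2c` but is reshuffled into a cross-chromosome pair by crossover at
  rate `r`, giving equilibrium
  `pi_s ~ L (2 mu + r pi_b / L) / (2c + r) ~ 0.2 Theta`
  for these parameters — independent of `N`, so scaling is not the cause
  (the same formula gives `0.04` at `R = 0`, matching simulation). The
  qualitative claim "`pi_s ~ 0` (min)" holds only as `C -> infinity`; the
  corresponding acceptance expectation is left red deliberately, and the
  acceptance report states the honestly simulated value.

## What the synthetic world does and does not establish

The generator *is* the model: constant population size, neutrality, exactly
two duplicate copies separated by one equal-length single-copy block,
uniform mutation along blocks, uniform crossover within the allowed region,
geometric IGC tracts initiating uniformly. A green suite establishes
internal correctness (exact conservation laws, registry bookkeeping,
genealogy pruning that provably does not distort sampled statistics) and
reproduction of the published equilibrium behavior at scaled `N`. It does
not establish anything about demography, selection, more than two copies,
divergence-dependent IGC (the hook exists but defaults to off),
sequence-dependent hotspot motifs, or mutation-rate heterogeneity — all
outside the model by design.

## Numerical and design choices worth knowing

* Both engines (`engine = "cpp"`, `engine = "r"`) implement the identical
  model; the R engine is the readable reference, cross-validated
  distributionally against the C++ engine at small `N` in the test suite.
  Genealogy, mutation, crossover and IGC all draw from R's RNG, so any run
  is bit-reproducible from its seed in either engine.
* Replicate `i` of a multi-replicate call runs under
  `replicate_seed(seed, i) = (seed + i * 1000003) mod (2^31 - 1)`, so any
  single replicate can be reproduced in isolation.
* Conditioned trajectories are sampled by exact rejection of binomial
  Wright–Fisher paths (expected `~2N` attempts per acceptance; failed paths
  die in a few generations). The often-cited pseudo-sampling diffusion
  shortcut is deliberately not used: rejection is exact for the discrete
  process and fast enough at `N <= 1000`.
* Era length `k` defaults to `N`. The original work tuned `k` per parameter
  combination for speed only; `k` has no effect on the law of any recorded
  statistic beyond the recording cadence, so it is simply exposed in the
  configuration.
* Degenerate inputs: a mutation event finding every position occupied is
  skipped and counted (`mut_skipped`); an HSC hotspot entirely outside the
  two-block shared length falls back to the full shared length during
  burn-in; `q = 1` tracts have length exactly 1; junction at the last
  coordinate copies the partner entirely.
* `T1 >= TT` runs are burn-in only (no duplication) — used by the
  control-locus acceptance check; if a sampled trajectory cannot fit
  (`T1 + 1 + T2 > TT`) the run errors rather than silently truncating the
  structured phase.

## Known limitations

Beyond the model scope above: IGC tracts never extend into the single-copy
block or across chromosomes (interallelic conversion is absent); there is no
biased gene conversion; `pi_b`'s early-phase growth is reported per
generation (`~2 mu L` per generation plus standing variation), not in the
scaled shorthand sometimes used for it; and the LD analysis uses one final
sample per run, per the sampling description, rather than pooling recordings
within a run.
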