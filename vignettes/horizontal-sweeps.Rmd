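---
title: "Modelling horizontal gene sweeps under migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling horizontal gene sweeps under migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtsweep)
```

## The scientific question

Horizontal gene transfer can spread a single beneficial allele across many
genomic backgrounds, homogenising one locus in an otherwise diverse
microbial community ("horizontal sweep"). Classical theory predicts this
should be rare: once a competing strain picks up a strongly beneficial
allele, vertical reproduction fixes that strain's whole genome long before
appreciable transfer can occur. `hgtsweep` implements three complementary
models of a well-mixed focal community to quantify when horizontal sweeps
do occur, and shows that immigration of non-adapted cells is the decisive
ingredient: migration stalls the vertical sweep at an interior equilibrium,
keeping a supply of transfer recipients alive indefinitely.

## The compartment model

The community of fixed size $N$ splits into carriers (fraction $C$) and
non-carriers. Carriers have relative fitness $1+s$; non-carriers acquire
the allele with per-capita probability $rC$ per generation; a fraction $m$
of the community is replaced per generation by immigrants that lack the
allele. The drift field is

$$\frac{dC}{dt} = \frac{sC(1-C)}{1+sC} + rC(1-C) - mC .$$

The selection term is logistic growth normalised by mean fitness
$1 + sC$; this specific form is the one whose roots reproduce both
published steady-state sets: without migration $C^*\in\{0,1\}$ (0 unstable,
1 stable), and with migration and $r \approx 0$ the migration–selection
balance $C^* = (s-m)/((m+1)s)$, which exists in $(0,1)$ only when $m < s$.
The community-level *horizontal gene flux* is $rC(1-C)N$ events per
generation, maximal at $C = 1/2$; its time integral (left-endpoint
rectangle rule, grid-refined until the total changes by less than 0.5%) is
the expected number of transfer events.

Two consequences organise all downstream results:

* without migration, the sweep completes and the cumulative flux saturates
  at roughly $(rN/s)\,(1 - C_0 + s(1-C_0^2)/2)$ (obtained by changing the
  integration variable from $t$ to $C$ in the $r \to 0$ limit; used as an
  independent oracle in the tests);
* with migration, flux persists at the steady state forever, and the
  steady flux $r C^*(1-C^*)N$ is maximised where $C^* = 1/2$, i.e. at
  $s = 2m/(1-m)$ — intermediate, not minimal, selection.

The two-patch extension replaces implicit immigration by an explicit
external compartment of relative size $\rho$ where the trait is
disfavoured ($s_{env} \le 0$), with balanced per-capita exchange $x$ (the
coupled fields gain $x(C_{env}-C_f)$ and $(x/\rho)(C_f-C_{env})$). The
exact coupling is this package's own minimal closed form; its contract is
the two limiting behaviours: a large environment reproduces the one-patch
migration model with $m = x$, and a small neutral environment merges with
the focal patch so the allele fixes everywhere.

## The pair-coalescence model

Diversity consequences are computed backward in time for a random pair of
homologous loci sampled at $t_{end}$, tracked through six states: both
lineages in carriers (S11), both in non-carriers (S00), mixed (S01),
coalesced in a carrier (S1) or non-carrier (S0), or at least one lineage in
an immigrant (SM). The generator at carrier fraction $C(t)$:

* within-class coalescence at $1/(NC)$ (S11) and $1/(N(1-C))$ (S00) — the
  neutral within-class approximation; selection acts through $C(t)$ and the
  class sizes only;
* each *uncoalesced* non-carrier lineage is a fresh immigrant at backward
  rate $m/(1-C)$ (all immigrants lack the allele and are unique; SM is
  absorbing and counts as non-identity);
* for the background locus only, a lineage in a carrier was a transfer
  convert with backward rate $r(1-C)$ and then switches to the non-carrier
  class (transfer converts a recipient in place, keeping its background
  genome). Focal-locus lineages instead jump to the donor — another
  carrier — and never leave the carrier class; the donor may be the
  partner lineage, giving a small extra S11 to S1 coalescence rate
  $2r(1-C)/(NC)$ for the focal locus.

Identity conventions: the $C_0 N$ founding carriers are a single clone,
identical at both genomic regions (matching the IBM initialisation);
founding non-carriers and every immigrant are unique. Hence a sampled pair
is identical iff it coalesced before $t = 0$ *or* both lineages are still
in the carrier class at $t = 0$: $F = P(S11) + P(S1) + P(S0)$ at backward
completion. Diversities are $D = 1/F$ (the order-2 Hill number is the
reciprocal of the probability that two random copies are identical) and
$DR = D_{bg}/D_f = F_f/F_b$.

One design choice deserves emphasis: coalesced states do **not** migrate
into SM. Once two lineages coalesce (backward), the sampled copies are
identical descendants of a single ancestor, so identity is decided; letting
S0 leak into SM would misclassify pairs whose common ancestor happens to be
an immigrant. The S1 to S0 class switch is retained (it tracks the class of
the coalesced lineage and is neutral for identity). Under these
conventions, without migration the focal and background processes differ
only by the tiny switching rates, so $DR \approx 1$ — the vertical sweep
purges both genomic regions equally — while with $0 < m < s$ the
background lineages of carriers leak (switch, then emigrate) and
$DR \gg 1$. $DR \ge 1$ holds whenever $s > m > 0$ and $r > 0$, because the
focal process is the background process with the loss paths removed.

On the standard grid ($N = 10^8$, $r = 10^{-6}$, $m = 0.02$,
$t_{end} = 5 \times 10^6$, $s$ scanned in steps of 0.005), this
reconstruction places the DR maximum at $s = 0.035$, one grid step below
the location reported for the original analysis ($s \approx 0.04$); the DR
curve is flat to within a few percent between 0.03 and 0.04, so the peak
location is sensitive to small convention differences in the backward
system, whose published description leaves the exact equations open.

## The individual-based model

Each of $N$ cells is a triple (focal allele, background genotype, niche).
Per generation, in fixed order:

1. **resources** — niche $j$ holds a share $N/n$; a cell of fitness $f$
   ($1+s$ for carriers) assigned to niche $a$ has competitive weight
   $f\sigma_{aj}$ in niche $j$, with $\sigma_{aa} = z$ and
   $\sigma_{aj} = (1-z)/(n-1)$ otherwise; it obtains
   $R = \sum_j (f\sigma_{aj}/\Omega_j)(N/n)$ where $\Omega_j$ is the summed
   weight in niche $j$. Empty niches forfeit their share.
2. **reproduction** — $R$ is the mean offspring number; independent
   Poisson offspring conditioned on fixed total $N$ are drawn, i.e. exact
   multinomial sampling with class weights $count \times R$ (the
   conditioning resolves the tension between "Poisson offspring" and a
   fixed community size).
3. **transfer** — each non-carrier converts with probability $Cr$ using
   the post-reproduction carrier fraction, keeping background and niche.
4. **migration** — a Binomial($N, m$) uniform random subset of cells is
   replaced by immigrants, each a unique genotype with a uniformly random
   niche.

Metrics (carrier fraction, realised flux, order-2 Hill diversities of the
focal and background partitions, DR) are recorded after the full update.
The event order is a convention; its sensitivity is $O(mr)$ per generation
and negligible at the rates used. The engine stores classes of identical
cells rather than individual cells and draws the multinomial as sequential
conditional binomials, so a $N = 10^5$, $10^4$-generation run takes
seconds; all draws come from R's RNG stream, making runs bit-reproducible
from (parameters, seed, package version).

## What the simulations emulate, and what they do not

The generators' defaults are the study conditions of the original
analysis: $N = 10^8$ cells, founding clone $C_0 = 1000/N$, transfer rates
$10^{-6} \le r \le 10^{-4}$ per gene per generation, migration $m = 0.02$,
horizons $10^5$ (flux) and $5\times10^6$ (diversity) generations; IBM niche
scans use $n \in \{1, 10, 20\}$ and $z = 0.2$. The models capture a
well-mixed community with a single transferable locus and one unlinked
background locus; they do not model plasmid/phage mechanics, spatial
structure within a patch, de-novo mutation, recombination maps, or
carrier-carrying immigrants (except through the two-patch extension).
Passing tests therefore demonstrate internal consistency of the three
models and reproduction of the published magnitudes, not calibration to any
particular empirical community.

Full-scale IBM niche scans ($N = 10^6$, $t_{end} = 10^5$, 50 replicates)
are cluster-scale; the package's desk-scale default divides $N$ and
$t_{end}$ by ten (keeping $t_{end}/N$, the coalescent-relative horizon,
fixed) and raises $r$ tenfold so the community-level event rate $rN$
matches the full-scale regime — without this rescaling the expected number
of transfer events per generation drops from ~100 to ~10 and the niche
effect on DR sinks below replicate noise. The same rescaling is used for
the coalescence/IBM cross-validation at $N = 10^4$. Replicate $k$ of a
scan uses seed $base + k$.

## Numerical choices

* ODE solving uses `deSolve::lsoda` with relative tolerance $10^{-8}$ and
  absolute $10^{-12}$ ($10^{-14}$ for the backward pair process, whose
  probabilities can legitimately be tiny); the forward problem is
  non-stiff, the backward one is handled by lsoda's BDF switch.
* When migration overpowers selection, $C(t)$ decays exponentially and
  underflows; the forward solve stops at a terminal root $C = 10^{-30}$
  and pads with zero.
* Backward rates of the form $m/(1-C)$ and $1/(NC)$ diverge as a class
  empties while its occupancy vanishes; each rate is capped at
  $10^3$/generation, which is instantaneous on every timescale used and
  only binds where the affected state mass is below $10^{-20}$.
* The forward solution is interpolated on a log-spaced grid (4000 points)
  so the sweep transient is resolved even on $5\times10^6$-generation
  horizons.
* Cumulative flux uses the left-endpoint rectangle rule with automatic
  grid doubling until the total changes by less than 0.5%.
* Degenerate inputs: $s = r = m = 0$ yields a flat drift field, reported
  as a zero-row steady-state table flagged `flat_field`, and a constant
  trajectory rather than an error.
* In `steady_states()` roots outside $[0,1]$ are reported with
  `admissible = FALSE` rather than dropped.

## Problem sizes used by the test-suite

The packaged checks run at the printed study conditions wherever those are
desk-scale (all compartment and coalescence results, including the 30-point
DR scans at $N = 10^8$, $t_{end} = 5\times10^6$). The stochastic checks
use: 30 IBM replicates at $N = 10^4$, $t_{end} = 2\times10^4$ for the
coalescence cross-validation, and 20 replicates per configuration at
$N = 10^5$, $t_{end} = 10^4$ for the niche-effect orderings — the
desk-scale setting described above. The $n = 1$ versus $n = 10$ mean-DR
gap is small relative to replicate spread at this scale, so that ordering
is the statistically most fragile check in the suite.

## Known limitations

* The backward pair system is a reconstruction from the stated process;
  the original supplementary equations are not reprinted in the main text,
  and small convention differences plausibly move the DR peak by one grid
  step (see above).
* The pair coalescent tracks exactly two lineages; $k$-sample genealogies
  and recombination are out of scope.
* The two-patch coupling is a minimal closed form pinned down only by its
  two published limiting behaviours.
* The coalescence model treats within-class coalescence neutrally; at very
  strong selection with tiny class sizes this underestimates the rate at
  which the founding clone's descendants coalesce, which is harmless here
  because founding carriers are identical by convention anyway.
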