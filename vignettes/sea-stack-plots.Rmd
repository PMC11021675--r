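---
title: "Sea stack plots: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sea stack plots: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seastack)
```

## The plot and what it claims to show

A sea stack plot displays one vertical histogram per data group, drawn
left-facing from the group's baseline, with summary statistics overlaid on
that baseline. It targets the gap between highly aggregated displays (bar
charts and dot-and-whisker plots, which show only a mean and a dispersion
interval) and raw-data displays (univariate scatter and dot plots, which
become unreadable once groups grow beyond a few dozen points). Histogram
counts are an unsmoothed, per-bin representation of the data, so the plot
cannot manufacture mass where there is none — the characteristic failure of
kernel density displays on zero-inflated or sparse data, where smoothing
spreads a point mass at zero into an apparent continuum of small positive
values.

The statistical content is deliberately plain:

* per group, a histogram over **bin edges shared by all groups**, with bar
  length exactly proportional to the bin count;
* a parametric overlay (white diamond at the mean, dark grey bar spanning
  mean ± 1 SD, sample SD with divisor $n-1$) and/or a non-parametric one
  (filled circle at the median, thin bar spanning the quartile range
  $q_1$–$q_3$).

Quartiles use linear interpolation between order statistics
(`stats::quantile()` type 7). This is stated rather than left implicit
because the interquartile range also drives the default bin-width rule, so
any reimplementation needs the same convention to reproduce the same bins.

## Binning model

All groups are pooled before a bin width is chosen, and one edge set serves
every group. The alternative — per-group bins — makes bins incomparable
across groups, which defeats the plot's purpose of cross-group comparison.

Available width rules, for pooled sample size $n$:

| rule | width | default? |
|---|---|---|
| `freedman_diaconis` | $2\,\mathrm{IQR}\,n^{-1/3}$ | yes |
| `scott` | $3.49\,s\,n^{-1/3}$ | |
| `sturges` | $\mathrm{range}/(1+\log_2 n)$ | |
| `fixed` | user-supplied | |

Freedman–Diaconis is the default because it is robust to the skewed and
outlier-contaminated shapes the benchmark generators produce; Scott's rule
inflates widths under heavy tails, and Sturges under-bins large samples. No
data-driven rule is "correct" in general — when the measurement has a
natural unit (lengths in whole centimetres, clutch sizes) a fixed width of
one unit is usually the right choice, and the `fixed` rule exists for
exactly that case.

Degenerate inputs fall back deterministically: zero IQR falls back to
Scott's rule; zero spread (all values equal) falls back to a single
unit-width bin centred on the common value. Edges are anchored at integer
multiples of the width (first edge $w\lfloor \min/w \rfloor$, last edge the
smallest anchored multiple $\ge \max$), so bin boundaries land on round
values rather than on the accidental sample minimum. Intervals are
half-open $[lo, hi)$ with the last bin closed, so the pooled maximum is
counted exactly once and every group's counts sum to its $n$.

## Layout and scaling

Group slots sit at integer positions $1..G$; each slot's baseline is its
right edge at slot centre $+$ `slot_width`/2 (default 0.8), and bars extend
left from it. With the default `count_scaling = "global"` one
count-to-length scale is shared by all groups, so the bin holding the
global maximum count — and only such bins — fills the slot exactly, and bar
lengths are comparable across groups. `per_group` scaling is available for
severely heterogeneous group sizes, at the cost of that comparability; the
global maximum is still recorded and reported by `legend_text()`, since the
count axis deliberately carries only sparse ticks (0 and the maximum per
slot) instead of a cluttered grid.

Summary glyphs are drawn **on the baseline** rather than centred in the
slot, so they never occlude the bars. The mean ± SD bar is intentionally
not clipped to the observed data range: it draws the statistic, not the
data, and for zero-inflated data mean − SD legitimately extends below the
smallest observation.

The vertical orientation is canonical: rotated a quarter turn clockwise,
its value axis runs along the top and still reads left-to-right from small
to large. `orient()` converts to horizontal by exchanging the value-axis
and group-axis coordinates of every primitive, and is an involution —
applying it twice restores the original geometry, which the tests assert.

Below $n = 20$ per group a histogram carries too few counts to say anything
a raw-data display would not say better, so `check_sample_size()` raises an
advisory warning at $n < 20$; the plot is still produced.

## Rendering

SVG output is generated directly as text with fixed-precision,
locale-independent number formatting, so identical geometry yields
byte-identical files — a property worth having for reproducible figure
pipelines and diffable outputs, and one no graphics device guarantees.
PNG and PDF go through the standard `grDevices` devices and are excluded
from the byte-identity contract (font rasterisation differs across
platforms).

## The synthetic benchmark

`figure1_groups()` generates the four-group benchmark used throughout the
examples and tests: `normal`, `zero_inflated`, `skewed_outliers`, and
`bimodal`, each with $n = 50$ by default and each **constrained so its
population mean is exactly the shared target of 10**. Equal means with
radically different shapes is the point: any display showing only means
renders the four groups indistinguishable.

Component choices (our design; only the constraints are fixed):

* **normal**: $N(10, 2^2)$.
* **zero_inflated**: exact zero with probability $p_0 = 0.4$, else a
  $[0,\infty)$-truncated normal with scale 5 whose location is solved by
  root finding so the non-zero component's mean is exactly
  $10/(1-p_0) = 16.\overline{6}$; the mixture mean is then exactly 10. The
  naive choice (location $=$ desired mean) would be biased upward by the
  truncation. Draws use the inverse-CDF transform, so they are exact and
  seed-stable.
* **skewed_outliers**: a lognormal body ($\sigma_{\log} = 0.5$, so median
  < mean) mixed with a 5% outlier component at mean 40
  ($\sigma_{\log} = 0.2$); the body mean is solved as
  $(10 - 0.05 \cdot 40)/0.95$ so the mixture mean is exactly 10. The
  constraint is infeasible when the outlier mass alone exceeds the target,
  which is an error.
* **bimodal**: equal mixture of $N(5, 1)$ and $N(15, 1)$ — mean 10 by
  symmetry; the mode separation must exceed 4 component SDs so the modes
  are actually distinguishable.

Every generator seeds the RNG explicitly and restores the caller's RNG
state, so calls are reproducible and side-effect free; `figure1_groups()`
derives per-group seeds from its single seed by fixed offsets.

What this benchmark does **not** emulate: measurement error structure,
within-group correlation, unequal group sizes, discreteness, or any real
ecological dataset. Tests passing on it demonstrate that the pipeline's
arithmetic and geometry are correct under four qualitatively distinct
shapes — not that any particular real dataset will be well served by a
given bin rule.

## The figure-panel census

The survey module reproduces census arithmetic over a coded table of
figure panels (one row per panel: journal, article, panel, plot type,
component layers when the panel combines plot types, and whether it shows
the distribution and/or raw data). Percentages are integers rounded **half
away from zero** — `percent(50, 270)` is 19, where round-half-to-even
would give 18 — because that is the convention the published counts follow.
The combined-panel breakdown reports counts per canonicalised component
set and the number of combinations containing a boxplot layer. The
breakdown rows are treated as authoritative for totals; the census table's
own aggregate claims are recomputed from rows, never asserted.

## Problem sizes and numerical choices

The test suite exercises the bin-counting path against a brute-force
per-value oracle over 1,000 random vectors, checks mean recovery of all
four generators at $n = 100{,}000$ (bounds set at three standard errors
from each generator's construction), and asserts SVG byte-determinism by
rendering twice; the full suite runs in well under a minute. Equal spacing
of edges is asserted to a relative tolerance of $10^{-9}$; bar-length
proportionality is exact up to one multiplication, with the division
`counts / max_count` performed first so a full bin maps to the slot width
exactly.

## Known limitations

* No faceting, no colour-by-covariate mapping, no interactive output.
* No kernel density estimation and no between-group tests — the package
  draws data, it does not model it.
* PNG/PDF byte-stability across platforms is explicitly not promised.
* The advisory threshold ($n = 20$) is a recommendation encoded as a
  warning, not a hard rule.
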