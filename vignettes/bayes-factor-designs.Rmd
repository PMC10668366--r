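---
title: "Bayes factors for superiority, equivalence, and non-inferiority designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes factors for superiority, equivalence, and non-inferiority designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The inferential problem

Clinical and biomedical two-arm studies rarely ask only "is the new
treatment better?". Three designs recur:

* **Superiority** — is the experimental condition better than control?
* **Equivalence** — are the two conditions practically interchangeable?
* **Non-inferiority** — is the experimental condition not worse than
  control by more than a pre-specified margin?

For a continuous outcome measured in two independent groups (control
$x$, experimental $y$), assumed normal with a common variance
$\sigma^2$, all three are statements about the standardized effect size

$$\delta = \frac{\mu_e - \mu_c}{\sigma}.$$

With a margin $c \ge 0$ on the $\delta$ scale, and after orienting the
outcome so that larger $\delta$ is more favorable, the hypotheses are

| design | $H_0$ | $H_1$ |
|---|---|---|
| superiority | $\delta = 0$ | $\delta > 0$ |
| equivalence | $\delta \in (-c, c)$ (or $\delta = 0$) | $\delta \notin (-c, c)$ |
| non-inferiority | $\delta = -c$ | $\delta > -c$ |

`bfdesign` quantifies the evidence with Bayes factors, the factor by
which data update prior odds into posterior odds:
$\mathrm{BF}_{01} = p(D \mid H_0)/p(D \mid H_1)$, each marginal
likelihood being the prior-weighted average of the likelihood over that
hypothesis' parameters. A Bayes factor of 24 combined with prior odds
of 2 gives posterior odds of 48; orientation is flipped by taking the
reciprocal ($\mathrm{BF}_{10} = 1/\mathrm{BF}_{01}$). Unlike p-values,
a Bayes factor can express evidence *for* equivalence, which is exactly
what an equivalence design needs.

## Model and priors

Both hypotheses share the nuisance parameters: the grand mean (flat
prior) and the common variance $\sigma^2$, which carries the Jeffreys
(right Haar) prior $p(\sigma^2) \propto 1/\sigma^2$. Under the
alternative, $\delta$ carries a Cauchy prior with location 0 and scale
$r$; the default $r = 1/\sqrt{2}$ matches the prevailing default in
general-purpose Bayes factor software. The Cauchy scale has a direct
reading: half of the prior mass lies inside $(-r, r)$. One-sided
hypotheses use the same density truncated to the relevant half line and
renormalized.

Integrating the grand mean and $\sigma^2$ out analytically, the
sampling distribution of the pooled two-sample $t$ statistic given
$\delta$ is noncentral $t$ with $\nu = n_x + n_y - 2$ degrees of
freedom and noncentrality $\delta\sqrt{n_{\mathrm{eff}}}$, where
$n_{\mathrm{eff}} = n_x n_y/(n_x + n_y)$. Every marginal likelihood in
the package is therefore a one-dimensional integral

$$p(t \mid H) = \int f_{\nu,\,\delta\sqrt{n_{\mathrm{eff}}}}(t)\,
  \pi(\delta)\, d\delta,$$

and the data enter only through $(t, \nu, n_{\mathrm{eff}})$. This
reduction is exact, not an approximation; the test suite certifies it
against a brute-force two-dimensional $(\delta, \sigma^2)$ integration
(see below).

## The three Bayes factors

**Superiority.** $H_1$ places a half-Cauchy$(0, r)$ on the favorable
side; $\mathrm{BF}_{10}$ is the marginal likelihood under that prior
divided by the central-$t$ likelihood at $\delta = 0$.

**Non-inferiority.** $H_0$ is the point $\delta = -c$. Under $H_1$ the
Cauchy prior *remains centered at zero effect* and is truncated to
$(-c, \infty)$. The Bayes factor is the marginal likelihood under the
truncated prior divided by the likelihood at the margin — equivalently,
the Savage–Dickey ratio of the truncated prior and posterior densities
at $\delta = -c$. A design alternative exists: re-center the prior at
the margin by shifting the test statistic to
$t' = t + c\sqrt{n_{\mathrm{eff}}}$ and applying the superiority
machinery. That construction concentrates prior mass at "worse by
exactly the margin" rather than at "no effect", changes the resulting
Bayes factors substantially, and contradicts the centered-at-zero prior
semantics used everywhere else in the package, so it was rejected. The
margin-truncated form is also the one whose Savage–Dickey picture
(`plot()`) has both curves cut at the margin with the evidential ratio
read off at the cut. With $c = 0$ the non-inferiority test reduces
exactly to the superiority test.

**Equivalence.** For the default point null $\{0\}$, the Bayes factor
is the Savage–Dickey density ratio under the full Cauchy model:
$\mathrm{BF}_{01} = p(\delta = 0 \mid D)/\pi(\delta = 0)$, computed in
log space as the central-$t$ log likelihood minus the log marginal. For
an interval null $(l, u)$, a single untruncated center-0 model supplies
both prior and posterior, and

$$\mathrm{BF}_{01} =
  \frac{P(\delta \in (l,u) \mid D)\,/\,P(\delta \notin (l,u) \mid D)}
       {P(\delta \in (l,u))\,/\,P(\delta \notin (l,u))}.$$

Sharing one model between numerator and denominator is deliberate: the
odds-ratio identity is defined on a single prior/posterior pair. As the
interval shrinks, this converges to the point-null Savage–Dickey value
(verified in the tests at widths $10^{-2}$ to $10^{-4}$).

## Direction, margins, and input modes

**Direction.** Whether high or low outcome scores are favorable is
declared once (`direction`); internally the data are canonicalized at
the boundary (the mean difference, and raw values if present, are
negated for `direction = "low"`), so there is a single code path and
every Bayes factor is exactly invariant under jointly flipping the
data sign and the direction flag. Equivalence is direction-free.

**Margins.** Margins may be given in standardized units or in outcome
units; unstandardized margins are divided by the pooled SD, as Eq.
$\delta = (\mu_e - \mu_c)/\sigma$ requires. A single equivalence value
$v$ expands to $(-v, v)$; an asymmetric pair is taken verbatim; `0` is
the point null.

**Input modes.** (1) raw vectors; (2) $n$, mean, SD per group (sample
SD, $n-1$ denominator); (3) $n$ and mean per group plus the half-width
`ci_margin` and level `ci_level` of a confidence interval for the mean
difference. In CI mode the standard error is recovered as
`ci_margin / qt((1 + ci_level)/2, df)` — the central Student-$t$
quantile at the stated level with $n_x + n_y - 2$ degrees of freedom,
matching how two-sample intervals are constructed (not the normal
quantile) — and the pooled SD as
`se / sqrt(1/n_x + 1/n_y)`, which is what standardizes margins in this
mode. Confidence levels are accepted only as fractions in $(0,1)$;
`95` is rejected with a hint rather than silently rescaled.

Degenerate inputs are hard errors, never silent coercions: group sizes
below 2, non-finite values, a zero SD in either group, inverted
interval bounds, negative margins, and non-numeric lines in outcome
files all raise classed conditions.

## Numerical policy

All Bayes factor arithmetic stays in log space end to end; decisive
data produce log Bayes factors in the hundreds without overflow, and
the console formatter renders the value from its log (scientific
notation with three significant digits once $|\log_{10}\mathrm{BF}|
\ge 4$, fixed two-decimal notation otherwise).

The noncentral-$t$ log density is computed from the integral
representation $f(t) = \int_0^\infty w\,\phi(wt-\mu)f_W(w)\,dw$ with
$W = \sqrt{\chi^2_\nu/\nu}$: the integrand's mode has a closed form
(the positive root of $(t^2+\nu)w^2 - \mu t w - \nu = 0$), the
integrand is rescaled by its maximum, and adaptive quadrature is
applied on a 13-standard-deviation window around the mode (relative
tolerance $10^{-10}$, falling back to $10^{-8}$ and then to a dense
20,001-point fixed grid). This stays accurate for noncentralities far
beyond the supported range of `stats::dt(ncp = )`, which is used only
as an independent cross-check at moderate noncentrality in the tests.

Marginal likelihoods locate the integrand maximum on a 257-point
candidate grid (always including the observed effect, the prior center,
and the support bounds), rescale, and integrate adaptively over the
support at relative tolerance $10^{-10}$ (infinite limits are handled
by the integrator's variable transformation, which compactifies the
heavy Cauchy tails); failures fall back to a dense fixed grid spanning
50 standardized units around the support interior, and a computation
that still fails raises a numerical-failure error carrying diagnostics.
Interval masses for equivalence use the same machinery on sub-regions,
with region-local rescaling so that tiny tail masses (e.g. a posterior
sitting 10 standard errors outside the interval) remain accurate in log
space.

Savage–Dickey densities are evaluated directly from the model (the
preferred route; the prior density cancels exactly), with linear
interpolation on the exported grid available for curves detached from
their model.

## The certification oracle

`oracle_log_bf()` recomputes every design's Bayes factor with none of
the engine's machinery: the raw-data normal likelihood (through its
sufficient statistics) is integrated on an explicit two-dimensional
grid over $\delta$ and $\log\sigma^2$ — the scale on which the Jeffreys
prior is flat — with the grand mean integrated analytically under a
flat prior. The $\delta$ grid combines wide coverage of the Cauchy body
($\pm 60$), log-spaced tails to $\pm 10^6$ (so grid-summed prior masses
are accurate to $\sim 10^{-6}$), dense refinement under the prior peak
and the likelihood ridge, and focused windows around support bounds and
interval anchors, where a truncated integrand falls on its Gaussian
flank with local decay length $w^2/|b - \hat d|$. Interval masses are
summed on sub-grids so boundary half-cells land on the correct side.

The tests assert self-convergence under grid doubling (below
$10^{-4}$) and engine–oracle agreement below $10^{-3}$ in absolute log
Bayes factor across a 36-condition grid — $t \in \{-10, -1, 0, 0.5, 2,
10\}$, $\nu \in \{4, 30, 396\}$, $r \in \{1/\sqrt 2, 1\}$ — with five
checks per condition (superiority, non-inferiority at $c \in \{0.5,
1\}$, point and interval equivalence), 90 comparisons in total.
Observed discrepancies are at the $10^{-5}$ level. These sizes keep the
full suite around two minutes on one CPU while exercising small-sample,
moderate, and large-sample regimes.

## Companion frequentist tests

Each fit stores the matching frequentist test: the one-sided $t$ test
for superiority; the one-sided test of $\delta = -c$ via
$t + c\sqrt{n_{\mathrm{eff}}}$ for non-inferiority; and the two
one-sided tests (TOST) against the interval bounds for equivalence,
rejecting non-equivalence iff $\max(p_{-c}, p_c) < \alpha$ (default
$\alpha = 0.05$).

## Evidence labels

Reports attach the conventional verbal scale applied to
$\max(\mathrm{BF}_{10}, \mathrm{BF}_{01})$: up to 3, "not worth more
than a bare mention"; 3–20, "positive"; 20–150, "strong"; above 150,
"very strong" — always naming the favored hypothesis.

## Known limitations

* The model assumes a common variance; there is no Welch-style
  unequal-variance variant.
* Priors are Cauchy with center 0 up to truncation; informed
  non-central priors are out of scope.
* Binary endpoints, multi-arm designs, and posterior-probability or
  ROPE decision rules are out of scope.
* In CI mode the package trusts the supplied half-width; it cannot
  detect a full CI width passed as a half-width, and the two differ by
  a factor of two in the implied standard error.
* The oracle is for desk-scale certification; its grids are sized for
  accuracy, not speed, and it requires per-group SDs (raw or
  means-and-SDs mode).
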