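---
title: "Choosing and ordering diagnostic tests by incremental net benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing and ordering diagnostic tests by incremental net benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbdx)
```

## The decision problem

A decision maker faces a patient with pre-test probability of disease $p$
and must choose among three actions: treat immediately, do nothing, or
test first and let the result decide. Treating a diseased patient yields a
utility benefit $b$; treating a healthy one costs a utility loss $l$.
`inbdx` summarises the treatment stakes by the trade-off
$\rho = l/(l+b) \in (0,1)$, which is also the *treatment threshold*: with
no test available, treatment is worthwhile exactly when $p \ge \rho$.
Both $b$ and $l$ can be assembled from health-economic components,
$b = \lambda q_g - c_{Rx}$ and $l = \lambda q_l + c_{Rx}$, with $\lambda$
the willingness to pay per QALY, $q_g, q_l$ the QALYs gained/lost under
treatment and $c_{Rx}$ the treatment cost (`treatment_frame()`).

All utilities inside the package are expressed **in units of $b$**. Every
formula the framework needs involves only the ratios $\rho/(1-\rho) = l/b$
and $l_{Dx}/b$, and two of the three packaged case studies supply nothing
but ratios; absolute currency is a presentation concern left to the
caller. For the same reason $\rho$ is restricted to the *open* interval
$(0,1)$: the degenerate trade-offs 0 and 1 make the odds $\rho/(1-\rho)$
collapse or diverge, and are rejected at the door.

## Value of information and the INB

For a binary test with sensitivity $Se$ and specificity $Sp$, the value
of diagnostic information is the expected-utility gain of the test-based
decision over the default action,

$$VI(p,\rho) = \begin{cases}
p\,Se - (1-p)(1-Sp)\,\dfrac{\rho}{1-\rho}, & p < \rho\\[4pt]
-p(1-Se) + (1-p)\,Sp\,\dfrac{\rho}{1-\rho}, & p \ge \rho.
\end{cases}$$

The two branches agree at $p=\rho$ (both equal $pJ$, $J$ the Youden
index); evaluation at exactly $p=\rho$ uses the treat-default branch, a
choice with no numerical consequence by continuity. Administering the
test itself costs $l_{Dx} = \lambda q_h^{Dx} + c_{Dx}$ (valued harm plus
cost), and the *incremental net benefit* is
$INB = VI - E[\text{testing loss}]/b$. Testing is justified only where
$INB > 0$.

## Aggregation rules and sequential cost

Panels combine under three positivity rules — conjunctive (AND),
disjunctive (OR) and majority — with results assumed **conditionally
independent given disease status**. The composite operating points are
the standard product formulas for AND/OR chains of any length; for
majority panels the package computes the probability of a strict positive
majority exactly, from the Poisson-binomial distribution of the positive
count (an $O(n^2)$ convolution). The published closed forms for the
three-test majority are recovered to $10^{-12}$ by this route, and an
independent $2^n$ outcome-enumeration oracle
(`outcome_enumeration_oracle()`) cross-checks every rule in the test
suite. Symbolic expansion of majority formulas beyond $n = 3$ was
deliberately avoided: enumeration with early stopping is exact, simpler,
and fast at every realistic panel size.

The expected testing loss is where order matters. Test $k$ in a sequence
is administered with a probability determined by the stopping rule — all
previous results positive (AND), all negative (OR), or majority still
undecided (majority; the first two of three tests always run, the third
only on a split). The loss is therefore linear in $p$,
$E[\text{loss}] = p L_D + (1-p) L_H$ with per-status coefficients
$L_D, L_H$, while the composite operating point is order-invariant — so
reordering a protocol changes its INB only through the cost term, and
cheap tests that often terminate the sequence early belong up front.

## Thresholds without iterative solvers

Within each branch of $VI$, the INB is linear in $p$ at fixed $\rho$, and
linear in the odds $r = \rho/(1-\rho)$ at fixed $p$. All thresholds are
therefore solved in closed form:

* **Test / test-treatment thresholds in $p$** — roots of the two linear
  branches. Because $INB \le 0$ at both $p=0$ and $p=1$, a non-empty
  testing interval exists exactly when the INB at the kink $p=\rho$ is
  non-negative, and then each branch contributes one root; the roots are
  clamped to $[0,1]$ against last-bit drift. When the interval is empty
  the components are reported as absent (`NA`), never clamped to a
  boundary — clamping would silently misstate "always test" or "never
  test" regimes.
* **Thresholds in $\rho$** — solved in $r$ and mapped back through
  $\rho = r/(1+r)$; a root is kept only if it satisfies its branch
  condition ($\rho \le p$ for the lower, $\rho > p$ for the upper
  threshold) and lies inside $(0,1)$. For a free, harmless test the
  bounds reduce to $1-NPV$ and $PPV$, which the tests verify against
  Bayes' rule directly.
* **Transitions between protocols** — the INB *difference* of two
  protocols is globally linear in $p$: the default-action utility cancels
  between branches and both cost terms are linear. One root, no kink;
  crossings outside $[0,1]$ or between parallel lines are absent.

## Optimisation and the decision map

`best_action()` maximises INB over an enumerated protocol set (all
ordered sequences under each rule; 33 protocols for three tests) and
falls back to the default action split at $p=\rho$ when no protocol is
worthwhile. Exact INB ties do occur structurally — e.g. majority
protocols differing only in the order of the first two tests have
identical INB — and are broken in favour of fewer tests, then lower
expected testing loss, then lexicographic label, on the view that
unmodelled patient burden grows with the number of tests.

`decision_map()` rasterises this rule over a uniform grid on $(0,1)^2$
excluding the endpoints, by default $501 \times 501$ — fine enough to
resolve the narrow optimal regions that appear in the prostate panel.
Protocols are scanned in tie-break preference order and a cell's label is
replaced only on an improvement exceeding $10^{-12}$, so systematic ties
resolve identically to `best_action()`. Vignette- and test-sized maps use
coarser grids (15–51 per axis); resolution changes labels only within a
cell's width of region boundaries.

## ROC frontier

`roc_frontier()` flags operating points on the upper convex hull in
$(1-Sp, Se)$ space, anchored at $(0,0)$ and $(1,1)$ (the always-negative
and always-positive "tests"). The hull is built with a monotone-chain
scan; a point is efficient if it lies within $10^{-9}$ of the hull height
at its false-positive rate, so collinear points on a hull edge are
retained as *weakly* efficient — they are matched, not beaten, by
mixtures of their neighbours. Distinct operating points are grouped at an
absolute tolerance of $10^{-9}$ per coordinate: the coincidences that
matter (order permutations of the same test set) are algebraically exact,
so the tolerance only guards floating-point noise.

## Packaged case studies and their parameters

* **prostate** — FT, hK2, TRUS with losses $l_{Dx}/b$ = 0.01, 0.01, 0.1
  and reference trade-off $\rho = 0.26$. The benefit is anchored at ten
  times the TRUS loss, so this panel carries ratios only.
* **colorectal** — FIT (USD 19), MT (USD 649), COL (USD 1400 plus a
  perforation harm valued at $6\times10^{-4}$ QALY);
  $\lambda = 10^5$/QALY, $q_g = 1.5$, $c_{Rx} = 75\,000$, hence
  $b = 75\,000$. COL's normalised loss computes to
  $1460/75000 = 1.947\times10^{-2}$.
* **cad** — ETT, SE, MPS, CCTA with $b = 105\,000$, $l = 55\,000$. The
  case study additionally carries the calibration ratio $b/l = 1.9$
  ($\rho = 1/2.9$), chosen so the ETT test threshold lands on the 15%
  guideline bound; the CCTA test-treatment threshold then falls at 87%.
  CCTA's loss is derived from its component cost, $394/105000 =
  3.75\times10^{-3}$; the package treats component values as primary
  wherever both a component and a pre-computed ratio are in circulation.

```{r case}
cad <- case_study("cad")
single_test_thresholds_p(cad$tests[[1]], rho = cad$rho_default)  # ETT
```

## The random-panel generator

`random_panel()` exists for property testing, not realism: it draws
$Se, Sp \sim U(0.5, 1)$ — informative but imperfect tests, the regime
where sequencing decisions are non-trivial — and $l_{Dx}/b \sim
U(0, 0.05)$, spanning free screening markers up to losses of the order of
the invasive tests in the case studies. It emulates *parameter*
heterogeneity only. It does not emulate correlated test results (the
framework itself assumes conditional independence, so a generator could
not exercise that axis), spectrum bias in $Se/Sp$, or uncertainty in the
parameters: passing property tests certify the algebra and the
enumeration machinery, not robustness of a clinical recommendation to
parameter error. The acceptance suite runs the closed forms against the
$2^n$ oracle on 200 panels of up to 5 tests at tolerance $10^{-10}$.

## Known limitations

* Conditional independence is assumed throughout; no correlation
  parameter is exposed. Correlated tests shift composite operating points
  and can reorder protocols.
* Only pure AND, pure OR and majority rules are supported; mixed
  expression trees are out of scope, as is cutoff optimisation for
  continuous markers (the operating point is taken as given).
* Thresholds come without confidence intervals; the framework is a
  deterministic function of its parameters.
* Tests worse than chance ($Se + Sp \le 1$) are accepted with a warning
  rather than rejected — the algebra is well defined and rejection would
  needlessly restrict property tests — but such a test signals a data
  problem upstream.
* Region boundaries in `decision_map()` are rasterised, not derived as
  curves; their placement is accurate to the grid resolution.
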