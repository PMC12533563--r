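# inbdx — incremental net benefit of single and combined diagnostic tests

When several imperfect diagnostic tests are available for the same disease,
a clinician (or screening programme) must decide *whether* to test at all,
*which* tests to combine, under *what* positivity rule, and in *what
order*. `inbdx` answers these questions with a decision-analytic criterion:
the **incremental net benefit (INB)** of a testing protocol, the
expected-utility gain of deciding treatment on the test result rather than
taking the default action, net of the expected cost and harm of testing.

## The model

A patient is characterised by a pre-test probability of disease `p` and a
cost-benefit trade-off of treatment

    rho = l / (l + b),

where `b` is the utility gain of treating a diseased patient and `l` the
utility loss of treating a healthy one (both can be assembled from a
willingness to pay per QALY, QALY gains/losses and treatment cost).
Without testing, treatment is worthwhile iff `p >= rho`. For a test with
sensitivity `Se`, specificity `Sp` and normalised testing loss `lDx/b`
(cost plus valued harm, divided by `b`), the value of diagnostic
information is, in units of `b`,

    VI(p, rho) = p Se − (1−p)(1−Sp) rho/(1−rho)        if p < rho
    VI(p, rho) = −p(1−Se) + (1−p) Sp rho/(1−rho)       if p >= rho

and `INB = VI − E[testing loss]`. Testing pays only where `INB > 0`; the
zero crossings in `p` are the classical **test** and **test-treatment
thresholds**, and the crossings in `rho` generalise decision-curve
analysis.

Tests combine under three positivity rules, assuming conditionally
independent results given disease status:

* **AND (conjunctive / believe-the-negative)** — treat only if all tests
  are positive; testing stops at the first negative.
  `Se = ∏ Se_i`, `Sp = 1 − ∏ (1 − Sp_i)`.
* **OR (disjunctive / believe-the-positive)** — treat if any test is
  positive; testing stops at the first positive.
  `Se = 1 − ∏ (1 − Se_i)`, `Sp = ∏ Sp_i`.
* **MAJORITY** — odd panel; treat if most tests are positive; testing
  stops as soon as the majority is decided.

The composite operating point never depends on the test order; the
*expected testing loss does*, which is what makes sequencing an
optimisation problem. `inbdx` enumerates all protocols over a panel (33
for three tests), selects `argmax INB` per patient state, rasterises
decision regions over the `(p, rho)` unit square, and flags the
informationally efficient protocols on the ROC frontier (upper convex hull
in `(1−Sp, Se)` space).

## Worked example

Prostate cancer testing with free-to-total PSA (FT), human kallikrein 2
(hK2) and transrectal ultrasound (TRUS), at a biopsy trade-off
`rho = 0.26`:

```r
library(inbdx)
pan <- case_study("prostate")
protos <- enumerate_protocols(pan$tests)      # 33 protocols

best_action(p = 0.3, rho = 0.26, protos)
#> TEST with FT (INB = 0.0613784 b)

protocol_thresholds_p(parse_protocol("hK2&FT", pan), rho = 0.26)
#> Thresholds: p in [0.115408, 0.346981], rho in [-, -]

global_test_bounds(protos, rho = 0.26)
#>     p_min     p_max
#> 0.1154076 0.6348466
```

Read: at 30% disease probability the single FT test maximises the INB, at
0.061 in units of the treatment benefit `b`. The conjunctive pair hK2∧FT
(hK2 first, because its higher specificity makes the second test less
likely to be needed) is worthwhile from `p ≈ 0.12`; across all 33
protocols, some testing protocol beats both default actions for
`p` in roughly `[0.12, 0.63]` — below that interval the patient should
not be tested or treated, above it treated without testing.
`decision_map(pan$tests)` rasterises the full optimal-protocol geography
over `(p, rho)`, and `roc_table(protos)` flags frontier efficiency — for
the colorectal panel, 12 distinct operating points with exactly 5 on the
frontier and no single test among them.

A command-line interface wraps the same functions:

```sh
inst=$(Rscript -e 'cat(system.file("exec", "inbdx", package = "inbdx"))')
Rscript "$inst" evaluate --case prostate --protocol "FT" --p 0.3 --rho 0.26
Rscript "$inst" roc --case colorectal --out-dir out/
Rscript "$inst" map --case cad --grid 501 --out-dir out/
```

Custom panels are YAML files with the same schema as the packaged case
studies (`inst/extdata/*.yaml`); `--config my_panel.yaml` and
`--case prostate` are interchangeable.

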