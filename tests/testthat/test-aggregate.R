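test_that("composite operating points follow the aggregation formulas", {
  ft <- pick_test(prostate, "FT"); hk2 <- pick_test(prostate, "hK2")
  and2 <- composite_operating_point(protocol(list(ft, hk2), "AND"))
  expect_equal(round(and2$sensitivity, 2), 0.46)
  expect_equal(round(and2$specificity, 2), 0.87)

  # single-test protocol is the identity
  single <- composite_operating_point(protocol(list(ft)))
  expect_equal(single$sensitivity, ft$sensitivity)
  expect_equal(single$specificity, ft$specificity)

  # majority of three identical tests: 3s^2 - 2s^3
  s <- 0.8
  tri <- protocol(list(dx("a", s, s), dx("b", s, s), dx("c", s, s)),
                  "MAJORITY")
  opm <- composite_operating_point(tri)
  expect_equal(opm$sensitivity, 3 * s^2 - 2 * s^3, tolerance = 1e-12)
  expect_equal(opm$specificity, 3 * s^2 - 2 * s^3, tolerance = 1e-12)

  # colorectal majority sensitivity
  maj <- protocol(colorectal$tests, "MAJORITY")
  expect_equal(round(composite_operating_point(maj)$sensitivity, 2), 0.95)
})

test_that("three-test majority matches the closed-form expansion", {
  for (seed in 1:20) {
    panel <- random_panel(3, seed = 100 + seed)
    se <- vapply(panel, `[[`, numeric(1), "sensitivity")
    sp <- vapply(panel, `[[`, numeric(1), "specificity")
    op <- composite_operating_point(protocol(panel, "MAJORITY"))
    se_closed <- se[1] * se[2] + se[1] * se[3] + se[2] * se[3] -
      2 * prod(se)
    sp_closed <- sp[1] * sp[2] + sp[1] * sp[3] + sp[2] * sp[3] -
      2 * prod(sp)
    expect_equal(op$sensitivity, se_closed, tolerance = 1e-12)
    expect_equal(op$specificity, sp_closed, tolerance = 1e-12)
  }
})

test_that("composite operating points are order-invariant", {
  panel <- random_panel(5, seed = 77)
  for (rule in c("AND", "OR", "MAJORITY")) {
    sizes <- if (rule == "MAJORITY") c(3, 5) else c(2, 4, 5)
    for (k in sizes) {
      base <- composite_operating_point(protocol(panel[1:k], rule))
      for (rep in 1:5) {
        perm <- sample(k)
        shuffled <- composite_operating_point(protocol(panel[perm], rule))
        expect_equal(shuffled$sensitivity, base$sensitivity,
                     tolerance = 1e-12)
        expect_equal(shuffled$specificity, base$specificity,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("appending a test moves AND and OR points monotonically", {
  panel <- random_panel(6, seed = 13)
  for (k in 2:6) {
    and_prev <- composite_operating_point(protocol(panel[1:(k - 1)], "AND"))
    and_now <- composite_operating_point(protocol(panel[1:k], "AND"))
    expect_lte(and_now$sensitivity, and_prev$sensitivity)
    expect_gte(and_now$specificity, and_prev$specificity)
    or_prev <- composite_operating_point(protocol(panel[1:(k - 1)], "OR"))
    or_now <- composite_operating_point(protocol(panel[1:k], "OR"))
    expect_gte(or_now$sensitivity, or_prev$sensitivity)
    expect_lte(or_now$specificity, or_prev$specificity)
  }
})

test_that("expected testing loss tracks the stopping rule", {
  fit <- pick_test(colorectal, "FIT"); mt <- pick_test(colorectal, "MT")
  col <- pick_test(colorectal, "COL")
  trip <- protocol(list(fit, mt, col), "AND")
  # probability that colonoscopy is needed after two positives, at p = 0.02
  expect_equal(round(administration_probability(trip, 0.02, 3), 3), 0.017)

  # single test: loss independent of p
  single <- protocol(list(col))
  expect_equal(expected_test_loss(single, 0.1), col$loss_over_b)
  expect_equal(expected_test_loss(single, 0.9), col$loss_over_b)

  # diseased patient, perfectly sensitive AND chain: every test runs
  chain <- protocol(list(dx("a", 1, 0.8, 0.01), dx("b", 1, 0.7, 0.02),
                         dx("c", 1, 0.9, 0.03)), "AND")
  expect_equal(expected_test_loss(chain, 1), 0.06)
})

test_that("expected loss is linear in p and bounded by first test and total", {
  panel <- random_panel(4, seed = 3)
  for (rule in c("AND", "OR", "MAJORITY")) {
    pr <- protocol(panel[1:3], rule)
    losses <- vapply(panel[1:3], `[[`, numeric(1), "loss_over_b")
    ps <- seq(0, 1, by = 0.1)
    el <- vapply(ps, function(p) expected_test_loss(pr, p), numeric(1))
    expect_true(all(el >= losses[1] - 1e-12))
    expect_true(all(el <= sum(losses) + 1e-12))
    # linearity: second differences vanish
    expect_true(all(abs(diff(diff(el))) < 1e-12))
  }
})

test_that("closed forms match the outcome-enumeration oracle", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(1:5, 1)
    panel <- random_panel(n, seed = 1000 + rep)
    rule <- if (n == 1) "AND"
      else if (n %% 2 == 1) sample(c("AND", "OR", "MAJORITY"), 1)
      else sample(c("AND", "OR"), 1)
    pr <- protocol(panel, rule)
    p <- stats::runif(1)
    oracle <- outcome_enumeration_oracle(pr, p)
    op <- composite_operating_point(pr)
    expect_equal(op$sensitivity, oracle$sensitivity, tolerance = 1e-12)
    expect_equal(op$specificity, oracle$specificity, tolerance = 1e-12)
    expect_equal(expected_test_loss(pr, p), oracle$expected_loss,
                 tolerance = 1e-12)
  }
  expect_error(outcome_enumeration_oracle(protocol(random_panel(13, 1), "AND"), 0.5),
               "12")
})

test_that("protocol INB separates into order-invariant VI and order-dependent loss", {
  ft <- pick_test(prostate, "FT"); hk2 <- pick_test(prostate, "hK2")
  p12 <- protocol(list(ft, hk2), "AND")
  p21 <- protocol(list(hk2, ft), "AND")
  p <- 0.3; rho <- 0.26
  op12 <- composite_operating_point(p12)
  op21 <- composite_operating_point(p21)
  expect_equal(op12, op21)
  expect_equal(inb(p12, p, rho) - inb(p21, p, rho),
               expected_test_loss(p21, p) - expected_test_loss(p12, p))
  # single-test protocol reduces exactly to the single-test INB
  expect_equal(inb(protocol(list(ft)), p, rho), inb(ft, p, rho))
})
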