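test_that("protocol enumeration produces the expected combinatorics", {
  expect_length(enumerate_protocols(prostate$tests), 33L)
  expect_length(enumerate_protocols(prostate$tests[1]), 1L)
  # 2 tests: 2 singles + 2 AND orders + 2 OR orders
  expect_length(enumerate_protocols(prostate$tests[1:2]), 6L)
  too_many <- random_panel(7, seed = 1)
  expect_error(enumerate_protocols(too_many), "6")
})

test_that("protocol thresholds reproduce the prostate testing range", {
  ft <- pick_test(prostate, "FT"); hk2 <- pick_test(prostate, "hK2")
  rho <- 0.26
  and_hf <- protocol(list(hk2, ft), "AND")
  expect_equal(round(protocol_thresholds_p(and_hf, rho)$p_test, 2), 0.12)
  or_fh <- protocol(list(ft, hk2), "OR")
  expect_equal(round(protocol_thresholds_p(or_fh, rho)$p_test_treat, 2), 0.63)
  expect_equal(round(transition_threshold_p(protocol(list(ft)), or_fh, rho), 2),
               0.44)
  bounds <- global_test_bounds(enumerate_protocols(prostate$tests), rho)
  expect_equal(round(unname(bounds), 2), c(0.12, 0.63))
})

test_that("protocol thresholds are exact INB roots and absent when INB < 0", {
  rho <- 0.26
  for (pr in enumerate_protocols(prostate$tests)) {
    ts <- protocol_thresholds_p(pr, rho)
    if (!is.na(ts$p_test))
      expect_lt(abs(inb(pr, ts$p_test, rho)), 1e-10)
    if (!is.na(ts$p_test_treat))
      expect_lt(abs(inb(pr, ts$p_test_treat, rho)), 1e-10)
  }
  # an unaffordable protocol has no testing interval
  dear <- protocol(list(dx("x", 0.9, 0.9, loss = 10)))
  ts <- protocol_thresholds_p(dear, 0.5)
  expect_true(is.na(ts$p_test) && is.na(ts$p_test_treat))
})

test_that("general protocol thresholds agree with the single-test closed forms", {
  panel <- random_panel(12, seed = 31)
  rhos <- seq(0.08, 0.92, length.out = 12)
  for (i in seq_along(panel)) {
    a <- single_test_thresholds_p(panel[[i]], rhos[i])
    b <- protocol_thresholds_p(protocol(panel[i]), rhos[i])
    expect_equal(a$p_test, b$p_test, tolerance = 1e-12)
    expect_equal(a$p_test_treat, b$p_test_treat, tolerance = 1e-12)
    a2 <- single_test_thresholds_rho(panel[[i]], 0.4)
    b2 <- protocol_thresholds_rho(protocol(panel[i]), 0.4)
    expect_equal(a2$rho_lower, b2$rho_lower, tolerance = 1e-12)
    expect_equal(a2$rho_upper, b2$rho_upper, tolerance = 1e-12)
    # and pairwise single-test transitions with the protocol-level solver
    j <- if (i < 12) i + 1 else 1
    expect_equal(pairwise_transition_p(panel[[i]], panel[[j]], rhos[i]),
                 transition_threshold_p(protocol(panel[i]),
                                        protocol(panel[j]), rhos[i]),
                 tolerance = 1e-10)
  }
})

test_that("transition thresholds match a dense grid scan of INB sign changes", {
  rho <- 0.26
  ft <- protocol(prostate$tests[1])
  or_fh <- protocol(list(pick_test(prostate, "FT"), pick_test(prostate, "hK2")),
                    "OR")
  pstar <- transition_threshold_p(ft, or_fh, rho)
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  d <- inb(ft, grid, rho) - inb(or_fh, grid, rho)
  flips <- which(diff(sign(d)) != 0)
  expect_length(flips, 1L)
  expect_lt(abs(grid[flips] - pstar), 2e-4)
  # identical protocols never cross
  expect_true(is.na(transition_threshold_p(ft, ft, rho)))
})

test_that("best_action applies the argmax-INB decision rules", {
  protos <- enumerate_protocols(prostate$tests)
  # inside the FT-optimal band
  act <- best_action(0.30, 0.26, protos)
  expect_identical(act$kind, "TEST")
  expect_identical(protocol_label(act$protocol), "FT")
  expect_gt(act$inb, 0)
  # below the global test threshold
  act2 <- best_action(0.05, 0.26, protos)
  expect_identical(act2$kind, "NO_TEST_NO_TREAT")
  expect_lt(act2$inb, 0)
  # above it, with treatment the default
  act3 <- best_action(0.9, 0.26, protos)
  expect_identical(act3$kind, "TREAT_WITHOUT_TESTING")
  # ruinously costly tests are never used anywhere
  costly <- lapply(prostate$tests, function(t)
    dx(t$name, t$sensitivity, t$specificity, loss = 10))
  for (p in c(0.2, 0.5, 0.8)) for (rho in c(0.2, 0.5, 0.8)) {
    a <- best_action(p, rho, enumerate_protocols(costly))
    expect_true(a$kind %in% c("NO_TEST_NO_TREAT", "TREAT_WITHOUT_TESTING"))
    expect_identical(a$kind == "NO_TEST_NO_TREAT", p < rho)
  }
})

test_that("exact INB ties are broken toward fewer tests then label order", {
  a <- dx("A", 0.8, 0.7, loss = 0.01)
  twin <- dx("Z", 0.8, 0.7, loss = 0.01)   # identical performance
  act <- best_action(0.4, 0.3, list(protocol(list(twin)), protocol(list(a)),
                                    protocol(list(a, twin), "AND")))
  expect_identical(protocol_label(act$protocol), "A")
})

test_that("decision maps are consistent with best_action and the bounds", {
  protos <- enumerate_protocols(prostate$tests)
  dm <- decision_map(prostate$tests, n = 51)
  # sampled cells agree with the pointwise decision
  set.seed(8)
  for (k in 1:25) {
    i <- sample(51, 1); j <- sample(51, 1)
    act <- best_action(dm$p_grid[i], dm$rho_grid[j], protos)
    if (act$kind == "TEST") {
      expect_identical(dm$protocol_labels[dm$labels[i, j]],
                       protocol_label(act$protocol))
      expect_equal(dm$inb[i, j], act$inb, tolerance = 1e-12)
    } else {
      expect_identical(dm$labels[i, j], 0L)
    }
  }
  # every TEST cell has positive INB and beats random competitors
  test_cells <- which(dm$labels > 0L, arr.ind = TRUE)
  expect_true(all(dm$inb[test_cells] > 0))
  pick <- test_cells[seq(1, nrow(test_cells), length.out = 10), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    i <- pick[k, 1]; j <- pick[k, 2]
    competitors <- sample(length(protos), 20)
    for (c_idx in competitors) {
      expect_gte(dm$inb[i, j] + 1e-9,
                 inb(protos[[c_idx]], dm$p_grid[i], dm$rho_grid[j]))
    }
  }
  # along the rho = 0.26 row the TEST region stays within the global bounds
  j26 <- which.min(abs(dm$rho_grid - 0.26))
  rho26 <- dm$rho_grid[j26]
  bounds <- global_test_bounds(protos, rho26)
  tested <- dm$p_grid[dm$labels[, j26] > 0L]
  expect_true(all(tested >= bounds[1] - 1e-9 & tested <= bounds[2] + 1e-9))
  # and the tested region is a single contiguous run
  runs <- rle(dm$labels[, j26] > 0L)
  expect_identical(sum(runs$values), 1L)
})

test_that("with prohibitive losses the map is split by the diagonal only", {
  costly <- lapply(prostate$tests, function(t)
    dx(t$name, t$sensitivity, t$specificity, loss = 10))
  dm <- decision_map(costly, n = 21)
  df <- as.data.frame(dm)
  expect_setequal(unique(df$label), c("no test, no treat", "treat"))
  expect_identical(df$label == "treat", df$p >= df$rho)
})
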