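#' Expected utility of immediate treatment
#'
#' In units of the treatment benefit \eqn{b}, treating a patient with
#' disease probability \eqn{p} and trade-off \eqn{\rho} yields
#' \eqn{p - (1-p)\rho/(1-\rho)}. Treatment is preferred without testing iff
#' this is positive, giving the treatment thresholds \eqn{p_{Rx} = \rho}
#' and \eqn{\rho_{Rx} = p}.
#'
#' @param p Pre-test probability of disease, in [0, 1]. Vectorised.
#' @param rho Cost-benefit trade-off in (0, 1). Vectorised (recycled).
#' @return Expected utility in units of \eqn{b}.
#' @examples
#' expected_utility_treatment(0.5, 0.26)
#' @export
expected_utility_treatment <- function(p, rho) {
  check_prob(p, "p")
  check_rho(rho)
  p - (1 - p) * rho_to_r(rho)
}

#' Value of diagnostic information
#'
#' The expected-utility gain (in units of \eqn{b}) of deciding treatment on
#' the test result rather than taking the default action, which is no-treat
#' below the treatment threshold (\eqn{p < \rho}) and treat at or above it:
#' \deqn{VI = p\,Se - (1-p)(1-Sp)\,\rho/(1-\rho) \quad (p < \rho)}
#' \deqn{VI = -p(1-Se) + (1-p)\,Sp\,\rho/(1-\rho) \quad (p \ge \rho)}
#' The two branches agree at \eqn{p = \rho}, where both equal
#' \eqn{pJ} with \eqn{J} the Youden index.
#'
#' @param p,rho Patient state (vectorised, recycled).
#' @param sensitivity,specificity Operating point of the (possibly
#'   composite) test; alternatively pass a \code{\link{diagnostic_test}} or
#'   \code{\link{protocol}} as \code{sensitivity}.
#' @return Value of information in units of \eqn{b}.
#' @examples
#' value_of_information(0.2, 0.26, 0.91, 0.40)
#' @export
value_of_information <- function(p, rho, sensitivity, specificity = NULL) {
  if (inherits(sensitivity, "diagnostic_test") ||
      inherits(sensitivity, "protocol")) {
    op <- composite_operating_point(sensitivity)
    specificity <- op$specificity
    sensitivity <- op$sensitivity
  }
  check_prob(p, "p")
  check_rho(rho)
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  r <- rho_to_r(rho)
  ifelse(p < rho,
         p * sensitivity - (1 - p) * (1 - specificity) * r,
         -p * (1 - sensitivity) + (1 - p) * specificity * r)
}

#' Incremental net benefit of testing
#'
#' \code{inb()} is the generic for the incremental net benefit
#' \eqn{INB(p, \rho) = VI(p, \rho, Se, Sp) - E[\mathrm{testing\ loss}]}, in
#' units of \eqn{b}. For a single test the expected testing loss is its
#' \code{loss_over_b}; for a protocol it is the sequence-dependent expected
#' loss (\code{\link{expected_test_loss}}) at the composite operating point.
#' Testing is worthwhile only where \eqn{INB > 0}.
#'
#' @param x A \code{\link{diagnostic_test}} or \code{\link{protocol}}.
#' @param p,rho Patient state (vectorised, recycled).
#' @param ... Unused.
#' @return INB in units of \eqn{b}.
#' @examples
#' ft <- diagnostic_test("FT", 0.91, 0.40, loss_over_b = 0.01)
#' inb(ft, p = 0.26, rho = 0.26)
#' @export
inb <- function(x, p, rho, ...) UseMethod("inb")

#' @rdname inb
#' @export
inb.diagnostic_test <- function(x, p, rho, ...) {
  value_of_information(p, rho, x$sensitivity, x$specificity) - x$loss_over_b
}

#' @rdname inb
#' @export
inb.protocol <- function(x, p, rho, ...) {
  op <- composite_operating_point(x)
  value_of_information(p, rho, op$sensitivity, op$specificity) -
    expected_test_loss(x, p)
}

threshold_set <- function(p_test = NA_real_, p_test_treat = NA_real_,
                          rho_lower = NA_real_, rho_upper = NA_real_) {
  structure(list(p_test = p_test, p_test_treat = p_test_treat,
                 rho_lower = rho_lower, rho_upper = rho_upper),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.6g", v)
  cat(sprintf("Thresholds: p in [%s, %s], rho in [%s, %s]\n",
              fmt(x$p_test), fmt(x$p_test_treat),
              fmt(x$rho_lower), fmt(x$rho_upper)))
  invisible(x)
}

#' Test and test-treatment thresholds of a single test (in p)
#'
#' Closed-form zero crossings of the single-test INB in the pre-test
#' probability, at fixed trade-off \eqn{\rho}:
#' \deqn{\underline{p}_{Dx} = \frac{\rho(1-Sp) + (1-\rho)l_{Dx}/b}
#'                                 {\rho(1-Sp) + (1-\rho)Se}}
#' \deqn{\overline{p}_{Dx} = \frac{\rho\,Sp - (1-\rho)l_{Dx}/b}
#'                                {\rho\,Sp + (1-\rho)(1-Se)}}
#' Below \eqn{\underline{p}_{Dx}} neither testing nor treatment is
#' indicated; above \eqn{\overline{p}_{Dx}} treatment should be given
#' without testing. Components are \code{NA} when the testing interval is
#' empty (the test's maximum INB, at \eqn{p = \rho}, is negative) or a root
#' falls outside [0, 1].
#'
#' @param test A \code{\link{diagnostic_test}}.
#' @param rho Trade-off in (0, 1).
#' @return A \code{threshold_set} with the p components filled.
#' @examples
#' ett <- diagnostic_test("ETT", 0.68, 0.77, loss_over_b = 100 / 105000)
#' single_test_thresholds_p(ett, rho = 1 / 2.9)
#' @export
single_test_thresholds_p <- function(test, rho) {
  stopifnot(inherits(test, "diagnostic_test"))
  check_rho(rho)
  se <- test$sensitivity; sp <- test$specificity; l <- test$loss_over_b
  lo <- (rho * (1 - sp) + (1 - rho) * l) / (rho * (1 - sp) + (1 - rho) * se)
  hi <- (rho * sp - (1 - rho) * l) / (rho * sp + (1 - rho) * (1 - se))
  if (!is.finite(lo) || lo < 0 || lo > 1) lo <- NA_real_
  if (!is.finite(hi) || hi < 0 || hi > 1) hi <- NA_real_
  if (!is.na(lo) && !is.na(hi) && lo > hi) { lo <- NA_real_; hi <- NA_real_ }
  threshold_set(p_test = lo, p_test_treat = hi)
}

#' Trade-off thresholds of a single test (in rho)
#'
#' Zero crossings of the single-test INB in \eqn{\rho}, at fixed disease
#' probability \eqn{p}. Below \code{rho_lower} treatment is given without
#' testing; above \code{rho_upper} neither testing nor treatment is
#' indicated. For a free and harmless test (\eqn{l_{Dx} = 0}) the bounds
#' equal \eqn{1 - NPV} and the \eqn{PPV} of the test at prevalence \eqn{p}.
#'
#' @param test A \code{\link{diagnostic_test}}.
#' @param p Pre-test probability in (0, 1).
#' @return A \code{threshold_set} with the rho components filled; a
#'   component is \code{NA} when no root lies in (0, 1) on its branch.
#' @export
single_test_thresholds_rho <- function(test, p) {
  stopifnot(inherits(test, "diagnostic_test"))
  if (p <= 0 || p >= 1) stop("'p' must lie strictly inside (0, 1)")
  se <- test$sensitivity; sp <- test$specificity; l <- test$loss_over_b
  # treat-default branch (rho <= p): -p(1-Se) + (1-p) Sp r = l
  lo <- NA_real_
  if (sp > 0) {
    r_lo <- (l + p * (1 - se)) / ((1 - p) * sp)
    cand <- r_to_rho(r_lo)
    if (is.finite(cand) && cand > 0 && cand < 1 && cand <= p) lo <- cand
  }
  # no-treat-default branch (rho > p): p Se - (1-p)(1-Sp) r = l
  hi <- NA_real_
  if (sp < 1) {
    r_hi <- (p * se - l) / ((1 - p) * (1 - sp))
    cand <- r_to_rho(r_hi)
    if (is.finite(cand) && cand > 0 && cand < 1 && cand > p) hi <- cand
  }
  threshold_set(rho_lower = lo, rho_upper = hi)
}

#' Probability at which preference switches between two single tests
#'
#' The INB difference of two tests is linear in \eqn{p} (the default-action
#' term cancels between branches), so the crossing is
#' \deqn{p_{ij} = \frac{\rho\Delta Sp - (1-\rho)\Delta l_{Dx}/b}
#'                     {\rho\Delta Sp - (1-\rho)\Delta Se}}
#' with \eqn{\Delta x = x_i - x_j}.
#'
#' @param test_i,test_j \code{\link{diagnostic_test}} objects.
#' @param rho Trade-off in (0, 1).
#' @return The crossing probability in [0, 1], or \code{NA} when the two
#'   INB lines are parallel (or identical) or the crossing falls outside
#'   [0, 1].
#' @export
pairwise_transition_p <- function(test_i, test_j, rho) {
  stopifnot(inherits(test_i, "diagnostic_test"),
            inherits(test_j, "diagnostic_test"))
  check_rho(rho)
  dse <- test_i$sensitivity - test_j$sensitivity
  dsp <- test_i$specificity - test_j$specificity
  dl <- test_i$loss_over_b - test_j$loss_over_b
  den <- rho * dsp - (1 - rho) * dse
  if (abs(den) < 1e-300) return(NA_real_)
  p <- (rho * dsp - (1 - rho) * dl) / den
  if (!is.finite(p) || p < 0 || p > 1) NA_real_ else p
}

#' Trade-off at which preference switches between two single tests
#'
#' Solves \eqn{INB_i(\rho) = INB_j(\rho)} at fixed \eqn{p} in the odds
#' variable \eqn{r = \rho/(1-\rho)}, in which the INB difference is linear:
#' \deqn{\rho_{ij} = \frac{p\Delta Se - \Delta l_{Dx}/b}
#'                        {p\Delta Se - (1-p)\Delta Sp - \Delta l_{Dx}/b}}
#'
#' @param test_i,test_j \code{\link{diagnostic_test}} objects.
#' @param p Pre-test probability in (0, 1).
#' @return The crossing trade-off in (0, 1), or \code{NA}.
#' @export
pairwise_transition_rho <- function(test_i, test_j, p) {
  stopifnot(inherits(test_i, "diagnostic_test"),
            inherits(test_j, "diagnostic_test"))
  if (p <= 0 || p >= 1) stop("'p' must lie strictly inside (0, 1)")
  dse <- test_i$sensitivity - test_j$sensitivity
  dsp <- test_i$specificity - test_j$specificity
  dl <- test_i$loss_over_b - test_j$loss_over_b
  if (abs(dsp) < 1e-300) return(NA_real_)
  r <- (dl - p * dse) / ((1 - p) * dsp)
  rho <- r_to_rho(r)
  if (!is.finite(rho) || rho <= 0 || rho >= 1) NA_real_ else rho
}
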