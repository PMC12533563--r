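#' Construct a treatment frame
#'
#' A treatment frame holds the utility consequences of the treat/no-treat
#' decision: the benefit \eqn{b} of treating a diseased patient, the loss
#' \eqn{l} of treating a healthy one, and the cost-benefit trade-off
#' \eqn{\rho = l/(l+b)}, which equals the treatment-threshold probability.
#' The frame can be built either from \code{benefit}/\code{loss} directly,
#' from \code{benefit} and \code{rho}, or from health-economic components
#' via \eqn{b = \lambda q_g - c_{Rx}} and \eqn{l = \lambda q_l + c_{Rx}},
#' where \eqn{\lambda} is the willingness to pay per QALY, \eqn{q_g} and
#' \eqn{q_l} are the QALYs gained (diseased) and lost (healthy) under
#' treatment, and \eqn{c_{Rx}} is the treatment cost.
#'
#' All downstream computations work in units of \eqn{b}, so a frame with
#' only \code{benefit} set (loss and rho unknown) is permitted: it can still
#' normalise test losses, while threshold analyses then take \code{rho} as a
#' free parameter.
#'
#' @param benefit Utility gain \eqn{b > 0} of treating a diseased patient
#'   (monetary units).
#' @param loss Utility loss \eqn{l > 0} of treating a healthy patient.
#' @param rho Cost-benefit trade-off in the open interval (0, 1). Redundant
#'   with \code{loss} when both are given; consistency is checked.
#' @param lambda Willingness to pay per QALY (currency/QALY).
#' @param qaly_gain,qaly_loss QALYs gained by a treated diseased patient and
#'   lost by a treated healthy patient.
#' @param treatment_cost Treatment cost \eqn{c_{Rx} \ge 0}.
#' @return An object of class \code{"treatment_frame"}: a list with elements
#'   \code{benefit}, \code{loss}, \code{rho} (the latter two possibly
#'   \code{NA}) and any components supplied.
#' @examples
#' treatment_frame(lambda = 100000, qaly_gain = 1.5, treatment_cost = 75000)
#' treatment_frame(benefit = 105000, loss = 55000)
#' @export
treatment_frame <- function(benefit = NULL, loss = NULL, rho = NULL,
                            lambda = NULL, qaly_gain = NULL, qaly_loss = NULL,
                            treatment_cost = NULL) {
  if (!is.null(lambda)) {
    if (is.null(treatment_cost)) treatment_cost <- 0
    if (!is.null(qaly_gain)) {
      b_comp <- lambda * qaly_gain - treatment_cost
      if (b_comp <= 0)
        stop("non-positive treatment benefit: lambda*qaly_gain must exceed treatment_cost")
      if (!is.null(benefit) && !isTRUE(all.equal(benefit, b_comp)))
        stop("'benefit' inconsistent with lambda*qaly_gain - treatment_cost")
      benefit <- b_comp
    }
    if (!is.null(qaly_loss)) {
      if (qaly_loss < 0) stop("'qaly_loss' must be >= 0")
      l_comp <- lambda * qaly_loss + treatment_cost
      if (l_comp <= 0)
        stop("non-positive treatment loss")
      if (!is.null(loss) && !isTRUE(all.equal(loss, l_comp)))
        stop("'loss' inconsistent with lambda*qaly_loss + treatment_cost")
      loss <- l_comp
    }
  }
  if (is.null(benefit) && !is.null(loss) && !is.null(rho)) {
    # l/b = rho/(1-rho)  =>  b = l (1-rho)/rho
    benefit <- loss * (1 - rho) / rho
  }
  if (is.null(benefit))
    stop("a treatment frame needs at least 'benefit' (directly or via components)")
  if (!is.numeric(benefit) || length(benefit) != 1L || benefit <= 0)
    stop("'benefit' must be a single positive number")
  if (is.null(loss) && !is.null(rho)) {
    check_rho(rho)
    loss <- benefit * rho / (1 - rho)
  }
  if (!is.null(loss)) {
    if (!is.numeric(loss) || length(loss) != 1L || loss <= 0)
      stop("'loss' must be a single positive number")
    rho_comp <- loss / (loss + benefit)
    if (!is.null(rho) && abs(rho - rho_comp) > 1e-8)
      stop(sprintf("'rho' (%g) inconsistent with loss/(loss+benefit) = %g",
                   rho, rho_comp))
    rho <- rho_comp
  }
  structure(
    list(benefit = benefit,
         loss = if (is.null(loss)) NA_real_ else loss,
         rho = if (is.null(rho)) NA_real_ else rho,
         lambda = lambda, qaly_gain = qaly_gain, qaly_loss = qaly_loss,
         treatment_cost = treatment_cost),
    class = "treatment_frame")
}

#' @export
print.treatment_frame <- function(x, ...) {
  cat("Treatment frame\n")
  cat(sprintf("  benefit b: %g\n", x$benefit))
  if (!is.na(x$loss)) cat(sprintf("  loss l:    %g\n", x$loss))
  if (!is.na(x$rho))
    cat(sprintf("  trade-off rho = l/(l+b): %.6g (b/l = %.4g)\n",
                x$rho, (1 - x$rho) / x$rho))
  else
    cat("  trade-off rho: unspecified (free parameter)\n")
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be in [0, 1]", name))
  x
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1))
    stop("'rho' must lie strictly inside (0, 1): rho = 0 or 1 is a degenerate trade-off")
  rho
}

# odds transform used throughout: INB is linear in r within each branch
rho_to_r <- function(rho) rho / (1 - rho)
r_to_rho <- function(r) r / (1 + r)

#' Normalised utility loss of performing a test
#'
#' Combines the monetary cost and (for invasive tests) the QALY-valued harm
#' of a test into a single utility loss \eqn{l_{Dx} = \lambda q_h^{Dx} +
#' c_{Dx}}, expressed in units of the treatment benefit \eqn{b}.
#'
#' @param cost Test cost \eqn{c_{Dx} \ge 0} (currency).
#' @param harm Expected QALY loss \eqn{q_h^{Dx} \ge 0} caused by the test.
#' @param lambda Willingness to pay per QALY; required when \code{harm > 0}.
#' @param benefit Treatment benefit \eqn{b > 0} used for normalisation.
#' @return \eqn{(\lambda q_h^{Dx} + c_{Dx})/b}, dimensionless.
#' @examples
#' test_loss_over_b(cost = 1400, harm = 6e-4, lambda = 1e5, benefit = 75000)
#' @export
test_loss_over_b <- function(cost, harm = 0, lambda = 0, benefit) {
  if (any(c(cost, harm, lambda) < 0)) stop("cost, harm and lambda must be >= 0")
  if (!is.numeric(benefit) || length(benefit) != 1L || benefit <= 0)
    stop("'benefit' must be a single positive number")
  if (harm > 0 && lambda == 0)
    stop("a positive 'harm' needs a positive 'lambda' to be valued")
  (lambda * harm + cost) / benefit
}

#' Define a binary diagnostic test
#'
#' A diagnostic test is characterised by its operating point (sensitivity,
#' specificity) and the normalised utility loss of administering it,
#' \eqn{l_{Dx}/b}. The loss can be given directly via \code{loss_over_b}, or
#' derived from \code{cost}, \code{harm}, \code{lambda} and a treatment
#' \code{frame} (see \code{\link{test_loss_over_b}}).
#'
#' Tests with \eqn{Se + Sp \le 1} (no better than chance) are accepted with
#' a warning: the net-benefit framework remains well defined for them.
#'
#' @param name Short identifier, unique within a panel.
#' @param sensitivity,specificity Operating point, each in [0, 1].
#' @param loss_over_b Normalised testing loss \eqn{l_{Dx}/b \ge 0}.
#' @param cost,harm,lambda Components of the testing loss (used when
#'   \code{loss_over_b} is missing).
#' @param frame Optional \code{\link{treatment_frame}} supplying the benefit
#'   \eqn{b} for normalisation.
#' @return An object of class \code{"diagnostic_test"}.
#' @examples
#' diagnostic_test("FT", 0.91, 0.40, loss_over_b = 0.01)
#' @export
diagnostic_test <- function(name, sensitivity, specificity,
                            loss_over_b = NULL,
                            cost = 0, harm = 0, lambda = 0, frame = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  if (is.null(loss_over_b)) {
    if (cost == 0 && harm == 0) {
      loss_over_b <- 0
    } else {
      if (is.null(frame))
        stop("supply 'loss_over_b' directly, or a 'frame' to normalise cost/harm by")
      loss_over_b <- test_loss_over_b(cost, harm, lambda, frame$benefit)
    }
  }
  if (!is.numeric(loss_over_b) || length(loss_over_b) != 1L || loss_over_b < 0)
    stop("'loss_over_b' must be a single non-negative number")
  if (sensitivity + specificity <= 1)
    warning(sprintf("test '%s' is no better than chance (Se + Sp <= 1)", name))
  structure(
    list(name = name, sensitivity = sensitivity, specificity = specificity,
         loss_over_b = loss_over_b, cost = cost, harm = harm),
    class = "diagnostic_test")
}

#' @export
print.diagnostic_test <- function(x, ...) {
  cat(sprintf("Diagnostic test '%s': Se = %.4g, Sp = %.4g, lDx/b = %.4g\n",
              x$name, x$sensitivity, x$specificity, x$loss_over_b))
  invisible(x)
}

#' Summary indices of an operating point
#'
#' Youden index \eqn{J = Se - (1 - Sp)} and likelihood ratios
#' \eqn{LR^+ = Se/(1-Sp)}, \eqn{LR^- = (1-Se)/Sp}. \code{lr_plus} is
#' \code{Inf} when \eqn{Sp = 1}; \code{lr_minus} is \code{Inf} when
#' \eqn{Sp = 0} and the numerator is positive.
#'
#' @param sensitivity,specificity Operating point, or a
#'   \code{\link{diagnostic_test}}/\code{\link{protocol}} as first argument.
#' @return Named list with \code{youden}, \code{lr_plus}, \code{lr_minus}.
#' @examples
#' op_indices(0.91, 0.40)
#' @export
op_indices <- function(sensitivity, specificity = NULL) {
  if (inherits(sensitivity, "diagnostic_test")) {
    specificity <- sensitivity$specificity
    sensitivity <- sensitivity$sensitivity
  } else if (inherits(sensitivity, "protocol")) {
    op <- composite_operating_point(sensitivity)
    sensitivity <- op$sensitivity
    specificity <- op$specificity
  }
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  fpr <- 1 - specificity
  list(youden = sensitivity - fpr,
       lr_plus = if (fpr > 0) sensitivity / fpr else Inf,
       lr_minus = if (specificity > 0) (1 - sensitivity) / specificity
                  else if (sensitivity == 1) NaN else Inf)
}

#' Define a testing protocol
#'
#' A protocol is an ordered sequence of tests with a positivity rule:
#' \describe{
#'   \item{AND (conjunctive)}{treat only if all tests are positive; testing
#'     stops at the first negative result.}
#'   \item{OR (disjunctive)}{treat if any test is positive; testing stops at
#'     the first positive result.}
#'   \item{MAJORITY}{treat if a strict majority of an odd number of tests is
#'     positive; testing stops as soon as the majority is decided.}
#' }
#' Test results are assumed conditionally independent given disease status.
#' The order of tests never affects the protocol's composite operating
#' point, only the expected testing loss.
#'
#' @param tests A list of \code{\link{diagnostic_test}} objects (or a single
#'   test), in administration order, with distinct names.
#' @param rule One of \code{"AND"}, \code{"OR"}, \code{"MAJORITY"}. Ignored
#'   for a single test.
#' @return An object of class \code{"protocol"}.
#' @examples
#' ft  <- diagnostic_test("FT",  0.91, 0.40, loss_over_b = 0.01)
#' hk2 <- diagnostic_test("hK2", 0.51, 0.78, loss_over_b = 0.01)
#' protocol(list(hk2, ft), "AND")
#' @export
protocol <- function(tests, rule = c("AND", "OR", "MAJORITY")) {
  if (inherits(tests, "diagnostic_test")) tests <- list(tests)
  if (!is.list(tests) || length(tests) < 1L ||
      !all(vapply(tests, inherits, logical(1), "diagnostic_test")))
    stop("'tests' must be a non-empty list of diagnostic_test objects")
  rule <- match.arg(rule)
  n <- length(tests)
  nms <- vapply(tests, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("test names within a protocol must be distinct")
  if (rule == "MAJORITY" && n > 1L && (n %% 2L == 0L || n < 3L))
    stop("MAJORITY protocols need an odd number of tests, at least 3")
  if (n == 1L) rule <- "SINGLE"
  structure(list(rule = rule, tests = tests, names = nms),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  op <- composite_operating_point(x)
  cat(sprintf("Protocol %s: Se = %.4g, Sp = %.4g\n",
              protocol_label(x), op$sensitivity, op$specificity))
  invisible(x)
}

#' @export
length.protocol <- function(x) length(x$tests)

#' Human-readable protocol label
#'
#' \code{"A&B"} for conjunctive, \code{"A|B"} for disjunctive,
#' \code{"maj(A,B,C)"} for majority, and the test name for a single test.
#'
#' @param x A \code{\link{protocol}}.
#' @return A character scalar.
#' @export
protocol_label <- function(x) {
  stopifnot(inherits(x, "protocol"))
  switch(x$rule,
         SINGLE = x$names,
         AND = paste(x$names, collapse = "&"),
         OR = paste(x$names, collapse = "|"),
         MAJORITY = sprintf("maj(%s)", paste(x$names, collapse = ",")))
}

proto_se <- function(x) vapply(x$tests, `[[`, numeric(1), "sensitivity")
proto_sp <- function(x) vapply(x$tests, `[[`, numeric(1), "specificity")
proto_loss <- function(x) vapply(x$tests, `[[`, numeric(1), "loss_over_b")
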