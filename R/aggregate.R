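#' Composite operating point of a protocol
#'
#' Under conditional independence of test results given disease status, the
#' aggregated sensitivity and specificity are
#' \itemize{
#'   \item AND: \eqn{Se = \prod_i Se_i}, \eqn{Sp = 1 - \prod_i (1 - Sp_i)};
#'   \item OR: \eqn{Se = 1 - \prod_i (1 - Se_i)}, \eqn{Sp = \prod_i Sp_i};
#'   \item MAJORITY: the probability that a strict majority of the (odd
#'     number of) results is positive, given diseased (for \eqn{Se}) and
#'     given healthy (for \eqn{1 - Sp}), computed exactly from the
#'     Poisson-binomial distribution of the positive count.
#' }
#' The composite point is invariant under reordering of the tests.
#'
#' @param x A \code{\link{protocol}} (or a single
#'   \code{\link{diagnostic_test}}).
#' @return A list with \code{sensitivity} and \code{specificity}.
#' @examples
#' ft  <- diagnostic_test("FT",  0.91, 0.40, loss_over_b = 0.01)
#' hk2 <- diagnostic_test("hK2", 0.51, 0.78, loss_over_b = 0.01)
#' composite_operating_point(protocol(list(ft, hk2), "AND"))
#' @export
composite_operating_point <- function(x) {
  if (inherits(x, "diagnostic_test"))
    return(list(sensitivity = x$sensitivity, specificity = x$specificity))
  stopifnot(inherits(x, "protocol"))
  se <- proto_se(x); sp <- proto_sp(x)
  switch(x$rule,
    SINGLE = list(sensitivity = se, specificity = sp),
    AND = list(sensitivity = prod(se), specificity = 1 - prod(1 - sp)),
    OR = list(sensitivity = 1 - prod(1 - se), specificity = prod(sp)),
    MAJORITY = {
      k <- (length(se) + 1L) %/% 2L
      list(sensitivity = poisbin_tail(se, k),
           specificity = 1 - poisbin_tail(1 - sp, k))
    })
}

# P(sum of independent Bernoulli(prob) >= k), exact convolution
poisbin_tail <- function(prob, k) {
  dist <- 1
  for (q in prob) dist <- c(dist * (1 - q), 0) + c(0, dist * q)
  sum(dist[seq_len(length(dist) - k) + k])
}

# Per-status probabilities that each test in the sequence is administered.
# AND: test k runs iff all previous results were positive; OR: iff all were
# negative; MAJORITY: iff neither positives nor negatives have exceeded n/2
# among the first k-1 results.
administration_probs <- function(x) {
  stopifnot(inherits(x, "protocol"))
  se <- proto_se(x); sp <- proto_sp(x)
  n <- length(se)
  if (x$rule %in% c("SINGLE", "AND")) {
    list(diseased = c(1, cumprod(se))[seq_len(n)],
         healthy = c(1, cumprod(1 - sp))[seq_len(n)])
  } else if (x$rule == "OR") {
    list(diseased = c(1, cumprod(1 - se))[seq_len(n)],
         healthy = c(1, cumprod(sp))[seq_len(n)])
  } else {
    k <- (n + 1L) %/% 2L   # votes needed for a decided majority
    undecided <- function(prob) {
      out <- numeric(n)
      dist <- 1   # distribution of positive count over first m results
      for (m in seq_len(n)) {
        # administered iff undecided after m-1 results: positives < k and
        # negatives = (m-1) - positives < k
        pos <- seq_along(dist) - 1L
        out[m] <- sum(dist[pos < k & (m - 1L - pos) < k])
        dist <- c(dist * (1 - prob[m]), 0) + c(0, dist * prob[m])
      }
      out
    }
    list(diseased = undecided(se), healthy = undecided(1 - sp))
  }
}

#' Expected testing loss of a protocol
#'
#' The sum over sequence positions of each test's normalised loss
#' \eqn{l_{Dx}/b} times the probability that the test is actually
#' administered, given the stopping behaviour of the positivity rule.
#' Linear in \eqn{p}: it equals \eqn{p L_D + (1-p) L_H} with the per-status
#' expected losses \eqn{L_D, L_H}.
#'
#' @param x A \code{\link{protocol}}.
#' @param p Pre-test probability of disease, in [0, 1]. Vectorised.
#' @return Expected loss in units of \eqn{b}.
#' @examples
#' ft  <- diagnostic_test("FT",  0.91, 0.40, loss_over_b = 0.01)
#' hk2 <- diagnostic_test("hK2", 0.51, 0.78, loss_over_b = 0.01)
#' expected_test_loss(protocol(list(hk2, ft), "AND"), p = 0.26)
#' @export
expected_test_loss <- function(x, p) {
  check_prob(p, "p")
  loss <- proto_loss(x)
  ap <- administration_probs(x)
  p * sum(loss * ap$diseased) + (1 - p) * sum(loss * ap$healthy)
}

#' Probability that a given test in the sequence is administered
#'
#' @param x A \code{\link{protocol}}.
#' @param p Pre-test probability of disease (scalar).
#' @param position Sequence position (1-based); default returns the whole
#'   vector of administration probabilities.
#' @return Probability (or vector of probabilities over positions).
#' @examples
#' fit <- diagnostic_test("FIT", 0.733, 0.964, loss_over_b = 19 / 75000)
#' mt  <- diagnostic_test("MT",  0.933, 0.898, loss_over_b = 649 / 75000)
#' col <- diagnostic_test("COL", 0.887, 0.796, loss_over_b = 1460 / 75000)
#' administration_probability(protocol(list(fit, mt, col), "AND"), p = 0.02, 3)
#' @export
administration_probability <- function(x, p, position = NULL) {
  check_prob(p, "p")
  stopifnot(length(p) == 1L)
  ap <- administration_probs(x)
  probs <- p * ap$diseased + (1 - p) * ap$healthy
  if (is.null(position)) probs else probs[position]
}

#' Exhaustive outcome-enumeration oracle
#'
#' Independent reference computation of a protocol's composite operating
#' point and expected testing loss by enumerating all \eqn{2^n} result
#' vectors, replaying the sequential stopping rule on each, and summing
#' probabilities conditional on disease status. Used to validate the
#' closed-form composite points and administration probabilities; limited
#' to protocols of length 12.
#'
#' @param x A \code{\link{protocol}} with at most 12 tests.
#' @param p Pre-test probability of disease (scalar).
#' @return A list with \code{sensitivity}, \code{specificity} and
#'   \code{expected_loss}.
#' @export
outcome_enumeration_oracle <- function(x, p) {
  stopifnot(inherits(x, "protocol"))
  check_prob(p, "p")
  n <- length(x$tests)
  if (n > 12L) stop("oracle enumeration limited to 12 tests (2^n outcomes)")
  se <- proto_se(x); sp <- proto_sp(x); loss <- proto_loss(x)
  rule <- x$rule
  need <- (n + 1L) %/% 2L
  pos_d <- 0; neg_h <- 0; loss_d <- 0; loss_h <- 0
  for (code in 0:(2^n - 1L)) {
    res <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L))
    # replay the sequence with early stopping
    npos <- 0L; nneg <- 0L; run_loss <- 0; decided <- NA
    for (k in seq_len(n)) {
      stop_now <- switch(rule,
        SINGLE = FALSE,
        AND = nneg > 0L,
        OR = npos > 0L,
        MAJORITY = npos >= need || nneg >= need)
      if (stop_now) break
      run_loss <- run_loss + loss[k]
      if (res[k]) npos <- npos + 1L else nneg <- nneg + 1L
    }
    positive <- switch(rule,
      SINGLE = res[1L],
      AND = nneg == 0L,
      OR = npos > 0L,
      MAJORITY = npos >= need)
    prob_d <- prod(ifelse(res, se, 1 - se))
    prob_h <- prod(ifelse(res, 1 - sp, sp))
    if (positive) pos_d <- pos_d + prob_d else neg_h <- neg_h + prob_h
    loss_d <- loss_d + prob_d * run_loss
    loss_h <- loss_h + prob_h * run_loss
  }
  list(sensitivity = pos_d, specificity = neg_h,
       expected_loss = p * loss_d + (1 - p) * loss_h)
}
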