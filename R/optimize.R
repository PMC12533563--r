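# per-status expected-loss coefficients: L(p) = p*Ld + (1-p)*Lh
loss_components <- function(x) {
  if (inherits(x, "diagnostic_test"))
    return(c(diseased = x$loss_over_b, healthy = x$loss_over_b))
  loss <- proto_loss(x)
  ap <- administration_probs(x)
  c(diseased = sum(loss * ap$diseased), healthy = sum(loss * ap$healthy))
}

as_protocol <- function(x) {
  if (inherits(x, "diagnostic_test")) protocol(list(x)) else x
}

#' Test and test-treatment thresholds of a protocol (in p)
#'
#' The protocol INB is piecewise linear in \eqn{p}, with a kink at the
#' treatment threshold \eqn{p = \rho}: the value-of-information branch
#' changes there while the expected testing loss stays linear. Both ends
#' of the unit interval have non-positive INB, so the testing region, when
#' non-empty, is a single interval around \eqn{\rho} whose endpoints are
#' the exact roots of the two linear branches. Components are \code{NA}
#' when the INB is negative at \eqn{p = \rho} (no testing interval).
#'
#' For a single test this reduces to the closed forms of
#' \code{\link{single_test_thresholds_p}}.
#'
#' @param x A \code{\link{protocol}} or \code{\link{diagnostic_test}}.
#' @param rho Trade-off in (0, 1).
#' @return A \code{threshold_set} with the p components filled.
#' @export
protocol_thresholds_p <- function(x, rho) {
  check_rho(rho)
  x <- as_protocol(x)
  op <- composite_operating_point(x)
  se <- op$sensitivity; sp <- op$specificity
  lc <- loss_components(x)
  r <- rho_to_r(rho)
  inb_peak <- -rho * (1 - se) + (1 - rho) * sp * r -
    (rho * lc[["diseased"]] + (1 - rho) * lc[["healthy"]])
  if (inb_peak < 0) return(threshold_set())
  # no-treat branch: p(Se + (1-Sp) r - Ld + Lh) = (1-Sp) r + Lh
  den_lo <- se + (1 - sp) * r - lc[["diseased"]] + lc[["healthy"]]
  num_lo <- (1 - sp) * r + lc[["healthy"]]
  lo <- if (abs(den_lo) < 1e-300) {
    if (num_lo <= 1e-300) 0 else NA_real_
  } else min(max(num_lo / den_lo, 0), 1)
  # treat branch: p((1-Se) + Sp r + Ld - Lh) = Sp r - Lh
  den_hi <- (1 - se) + sp * r + lc[["diseased"]] - lc[["healthy"]]
  num_hi <- sp * r - lc[["healthy"]]
  hi <- if (abs(den_hi) < 1e-300) {
    if (num_hi >= -1e-300) 1 else NA_real_
  } else min(max(num_hi / den_hi, 0), 1)
  if (!is.na(lo) && !is.na(hi) && lo > hi) return(threshold_set())
  threshold_set(p_test = lo, p_test_treat = hi)
}

#' Trade-off thresholds of a protocol (in rho)
#'
#' Roots of the protocol INB in the odds variable \eqn{r = \rho/(1-\rho)},
#' in which each branch of the value of information is linear while the
#' expected testing loss does not depend on \eqn{\rho}. Roots violating
#' their branch condition (\eqn{\rho \le p} for the lower, \eqn{\rho > p}
#' for the upper threshold) or falling outside (0, 1) are reported as
#' \code{NA}.
#'
#' @param x A \code{\link{protocol}} or \code{\link{diagnostic_test}}.
#' @param p Pre-test probability in (0, 1).
#' @return A \code{threshold_set} with the rho components filled.
#' @export
protocol_thresholds_rho <- function(x, p) {
  if (p <= 0 || p >= 1) stop("'p' must lie strictly inside (0, 1)")
  x <- as_protocol(x)
  op <- composite_operating_point(x)
  se <- op$sensitivity; sp <- op$specificity
  lc <- loss_components(x)
  lp <- p * lc[["diseased"]] + (1 - p) * lc[["healthy"]]
  lo <- NA_real_
  if (sp > 0) {
    cand <- r_to_rho((lp + p * (1 - se)) / ((1 - p) * sp))
    if (is.finite(cand) && cand > 0 && cand < 1 && cand <= p) lo <- cand
  }
  hi <- NA_real_
  if (sp < 1) {
    cand <- r_to_rho((p * se - lp) / ((1 - p) * (1 - sp)))
    if (is.finite(cand) && cand > 0 && cand < 1 && cand > p) hi <- cand
  }
  threshold_set(rho_lower = lo, rho_upper = hi)
}

#' Probability at which preference switches between two protocols
#'
#' The INB difference of two protocols is globally linear in \eqn{p}: the
#' default-action utility cancels between the two branches of the value of
#' information, and expected testing losses are linear in \eqn{p}. The
#' crossing is the root of that line.
#'
#' @param x_i,x_j \code{\link{protocol}} or \code{\link{diagnostic_test}}
#'   objects.
#' @param rho Trade-off in (0, 1).
#' @return Crossing probability in [0, 1], or \code{NA} when the lines are
#'   parallel (e.g. identical protocols) or cross outside [0, 1].
#' @export
transition_threshold_p <- function(x_i, x_j, rho) {
  check_rho(rho)
  x_i <- as_protocol(x_i); x_j <- as_protocol(x_j)
  op_i <- composite_operating_point(x_i)
  op_j <- composite_operating_point(x_j)
  lc_i <- loss_components(x_i); lc_j <- loss_components(x_j)
  r <- rho_to_r(rho)
  dse <- op_i$sensitivity - op_j$sensitivity
  dsp <- op_i$specificity - op_j$specificity
  dld <- lc_i[["diseased"]] - lc_j[["diseased"]]
  dlh <- lc_i[["healthy"]] - lc_j[["healthy"]]
  slope <- dse - dsp * r - dld + dlh
  intercept <- dsp * r - dlh
  if (abs(slope) < 1e-12 && abs(intercept) < 1e-12) return(NA_real_)
  if (abs(slope) < 1e-300) return(NA_real_)
  p <- -intercept / slope
  if (!is.finite(p) || p < 0 || p > 1) NA_real_ else p
}

#' Trade-off at which preference switches between two protocols
#'
#' Analogue of \code{\link{transition_threshold_p}} solved in the odds
#' variable \eqn{r = \rho/(1-\rho)} at fixed \eqn{p}.
#'
#' @param x_i,x_j Protocols or tests.
#' @param p Pre-test probability in (0, 1).
#' @return Crossing trade-off in (0, 1), or \code{NA}.
#' @export
transition_threshold_rho <- function(x_i, x_j, p) {
  if (p <= 0 || p >= 1) stop("'p' must lie strictly inside (0, 1)")
  x_i <- as_protocol(x_i); x_j <- as_protocol(x_j)
  op_i <- composite_operating_point(x_i)
  op_j <- composite_operating_point(x_j)
  lc_i <- loss_components(x_i); lc_j <- loss_components(x_j)
  dse <- op_i$sensitivity - op_j$sensitivity
  dsp <- op_i$specificity - op_j$specificity
  dl <- p * (lc_i[["diseased"]] - lc_j[["diseased"]]) +
    (1 - p) * (lc_i[["healthy"]] - lc_j[["healthy"]])
  if (abs((1 - p) * dsp) < 1e-300) return(NA_real_)
  rho <- r_to_rho((dl - p * dse) / ((1 - p) * dsp))
  if (!is.finite(rho) || rho <= 0 || rho >= 1) NA_real_ else rho
}

permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n))
    out <- c(out, lapply(permutations(v[-i]), function(rest) c(v[i], rest)))
  out
}

#' Enumerate all protocols over a set of tests
#'
#' All single tests; every ordered sequence of two or more distinct tests
#' under the AND rule and under the OR rule; and every ordered sequence of
#' odd length at least three under the MAJORITY rule. For three tests this
#' yields 33 protocols.
#'
#' @param tests List of \code{\link{diagnostic_test}} objects (at most 6;
#'   the count grows factorially).
#' @param rules Subset of \code{c("AND", "OR", "MAJORITY")} to enumerate.
#' @return A list of \code{\link{protocol}} objects.
#' @examples
#' length(enumerate_protocols(case_study("prostate")$tests))  # 33
#' @export
enumerate_protocols <- function(tests, rules = c("AND", "OR", "MAJORITY")) {
  if (inherits(tests, "diagnostic_test")) tests <- list(tests)
  n <- length(tests)
  if (n < 1L) stop("'tests' must contain at least one test")
  if (n > 6L) {
    est <- sum(vapply(2:n, function(k) prod((n - k + 1):n), numeric(1)))
    stop(sprintf(
      "enumeration limited to 6 tests (%d tests imply > %d ordered sequences per rule)",
      n, est))
  }
  rules <- match.arg(rules, several.ok = TRUE)
  out <- lapply(tests, function(t) protocol(list(t)))
  idx <- seq_len(n)
  subsets <- function(k) {
    if (k > n) return(list())
    combs <- utils::combn(idx, k, simplify = FALSE)
    unlist(lapply(combs, permutations), recursive = FALSE)
  }
  for (rule in intersect(c("AND", "OR"), rules))
    for (k in 2:max(2L, n))
      for (ord in subsets(k))
        out <- c(out, list(protocol(tests[ord], rule)))
  if ("MAJORITY" %in% rules && n >= 3L)
    for (k in seq(3L, n, by = 2L))
      for (ord in subsets(k))
        out <- c(out, list(protocol(tests[ord], "MAJORITY")))
  out
}

#' Select the best action at a patient state
#'
#' Evaluates the INB of every candidate protocol at \eqn{(p, \rho)} and
#' applies the decision rule: if the maximal INB is positive, test with the
#' argmax protocol; otherwise fall back to the default action, no-treat
#' below the treatment threshold (\eqn{p < \rho}) and treat at or above it.
#' Exact INB ties are broken in favour of fewer tests, then lower expected
#' testing loss, then lexicographic protocol label.
#'
#' @param p,rho Patient state (scalars).
#' @param protocols Non-empty list of \code{\link{protocol}} objects (or
#'   tests).
#' @return An object of class \code{"inb_action"}: list with \code{kind}
#'   (one of \code{"NO_TEST_NO_TREAT"}, \code{"TREAT_WITHOUT_TESTING"},
#'   \code{"TEST"}), \code{protocol} (when testing), and \code{inb}.
#' @examples
#' pan <- case_study("prostate")
#' best_action(0.3, 0.26, enumerate_protocols(pan$tests))
#' @export
best_action <- function(p, rho, protocols) {
  check_prob(p, "p"); check_rho(rho)
  stopifnot(length(p) == 1L, length(rho) == 1L)
  if (inherits(protocols, "protocol") || inherits(protocols, "diagnostic_test"))
    protocols <- list(protocols)
  if (length(protocols) == 0L) stop("'protocols' must be non-empty")
  protocols <- lapply(protocols, as_protocol)
  inbs <- vapply(protocols, inb, numeric(1), p = p, rho = rho)
  best <- max(inbs)
  if (best <= 0) {
    kind <- if (p < rho) "NO_TEST_NO_TREAT" else "TREAT_WITHOUT_TESTING"
    return(structure(list(kind = kind, protocol = NULL, inb = best),
                     class = "inb_action"))
  }
  tied <- which(inbs >= best - 1e-12)
  if (length(tied) > 1L) {
    len <- vapply(protocols[tied], length, integer(1))
    elo <- vapply(protocols[tied], expected_test_loss, numeric(1), p = p)
    lab <- vapply(protocols[tied], protocol_label, character(1))
    tied <- tied[order(len, elo, lab)]
  }
  pick <- tied[1L]
  structure(list(kind = "TEST", protocol = protocols[[pick]],
                 inb = inbs[pick]),
            class = "inb_action")
}

#' @export
print.inb_action <- function(x, ...) {
  if (x$kind == "TEST")
    cat(sprintf("TEST with %s (INB = %.6g b)\n",
                protocol_label(x$protocol), x$inb))
  else
    cat(sprintf("%s (max INB = %.6g b)\n",
                gsub("_", " ", tolower(x$kind)), x$inb))
  invisible(x)
}

#' Global testing bounds over a protocol set
#'
#' The minimum of the lower test thresholds and the maximum of the upper
#' test-treatment thresholds over all protocols possessing a testing
#' interval at the given \eqn{\rho}. Outside these bounds no protocol has a
#' positive INB.
#'
#' @param protocols List of \code{\link{protocol}} objects (or tests).
#' @param rho Trade-off in (0, 1).
#' @return Numeric \code{c(p_min, p_max)}; both \code{NA} when no protocol
#'   has a testing interval.
#' @export
global_test_bounds <- function(protocols, rho) {
  if (inherits(protocols, "protocol") || inherits(protocols, "diagnostic_test"))
    protocols <- list(protocols)
  if (length(protocols) == 0L) stop("'protocols' must be non-empty")
  ths <- lapply(protocols, protocol_thresholds_p, rho = rho)
  lo <- vapply(ths, `[[`, numeric(1), "p_test")
  hi <- vapply(ths, `[[`, numeric(1), "p_test_treat")
  if (all(is.na(lo)) && all(is.na(hi))) return(c(p_min = NA_real_, p_max = NA_real_))
  c(p_min = min(lo, na.rm = TRUE), p_max = max(hi, na.rm = TRUE))
}

#' Decision-region map over the (p, rho) unit square
#'
#' Rasterises the argmax-INB decision over a grid of patient states: each
#' cell is labelled with the optimal testing protocol, or with the default
#' action (\code{"no test, no treat"} below the diagonal \eqn{p = \rho},
#' \code{"treat"} at or above it) where no protocol attains a positive INB.
#'
#' @param tests List of \code{\link{diagnostic_test}} objects; all
#'   protocols over them are enumerated unless \code{protocols} is given.
#' @param n Grid resolution per axis (default 501); grid points are
#'   \eqn{i/(n+1)}, uniform over (0, 1) excluding the endpoints.
#' @param protocols Optional explicit protocol list.
#' @return An object of class \code{"decision_map"}: list with
#'   \code{p_grid}, \code{rho_grid}, integer matrix \code{labels} (0 =
#'   default action, k = index into \code{protocol_labels}), matrix
#'   \code{inb} of the maximal INB, and \code{protocol_labels}.
#' @examples
#' pan <- case_study("prostate")
#' dm <- decision_map(pan$tests, n = 41)
#' table(as.data.frame(dm)$label)
#' @export
decision_map <- function(tests, n = 501, protocols = NULL) {
  if (n < 2) stop("grid resolution 'n' must be at least 2")
  if (is.null(protocols)) protocols <- enumerate_protocols(tests)
  protocols <- lapply(protocols, as_protocol)
  labs <- vapply(protocols, protocol_label, character(1))
  lens <- vapply(protocols, length, integer(1))
  ord <- order(lens, labs)   # tie-break preference order
  p <- seq_len(n) / (n + 1)
  rho <- seq_len(n) / (n + 1)
  r <- rho_to_r(rho)
  below <- outer(p, rho, `<`)
  best <- matrix(-Inf, n, n)
  pick <- matrix(0L, n, n)
  for (k in ord) {
    op <- composite_operating_point(protocols[[k]])
    lc <- loss_components(protocols[[k]])
    lower <- outer(p * op$sensitivity, rep(1, n)) -
      outer((1 - p) * (1 - op$specificity), r)
    upper <- outer(-p * (1 - op$sensitivity), rep(1, n)) +
      outer((1 - p) * op$specificity, r)
    vi <- ifelse(below, lower, upper)
    inb_k <- vi - (p * lc[["diseased"]] + (1 - p) * lc[["healthy"]])
    gain <- inb_k > best + 1e-12
    best[gain] <- inb_k[gain]
    pick[gain] <- k
  }
  pick[best <= 0] <- 0L
  structure(list(p_grid = p, rho_grid = rho, labels = pick, inb = best,
                 protocol_labels = labs, protocols = protocols),
            class = "decision_map")
}

#' @export
print.decision_map <- function(x, ...) {
  n_test <- sum(x$labels > 0L)
  cat(sprintf("Decision map: %d x %d grid over (0,1)^2, %d candidate protocols\n",
              length(x$p_grid), length(x$rho_grid), length(x$protocol_labels)))
  cat(sprintf("  testing optimal in %.1f%% of cells; %d protocols appear\n",
              100 * n_test / length(x$labels),
              length(unique(x$labels[x$labels > 0L]))))
  invisible(x)
}

#' @export
as.data.frame.decision_map <- function(x, ...) {
  lab <- c("no test", x$protocol_labels)[x$labels + 1L]
  default <- x$labels == 0L
  treat <- default & outer(x$p_grid, x$rho_grid, `>=`)
  lab[default] <- "no test, no treat"
  lab[treat] <- "treat"
  data.frame(p = rep(x$p_grid, times = length(x$rho_grid)),
             rho = rep(x$rho_grid, each = length(x$p_grid)),
             label = as.vector(lab),
             inb = as.vector(x$inb))
}

#' @export
plot.decision_map <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  z <- matrix(match(x$labels, labs), nrow = nrow(x$labels))
  cols <- grDevices::hcl.colors(length(labs), "Spectral")
  if (labs[1] == 0L) cols[1] <- "white"
  graphics::image(x$p_grid, x$rho_grid, z, col = cols,
                  xlab = "pre-test probability p",
                  ylab = expression(rho), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  legend_labs <- c("default action", x$protocol_labels)[labs + 1L]
  graphics::legend("topleft", legend = legend_labs, fill = cols,
                   bg = "white", cex = 0.7)
  invisible(x)
}
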