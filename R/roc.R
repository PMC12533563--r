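#' Distinct operating points of a protocol set
#'
#' Protocols that permute the same test set under the same rule share an
#' operating point exactly; this groups protocols whose composite
#' (sensitivity, specificity) coincide within an absolute tolerance of
#' 1e-9 on both coordinates.
#'
#' @param protocols Non-empty list of \code{\link{protocol}} objects (or
#'   tests).
#' @param tol Grouping tolerance (absolute, per coordinate).
#' @return A data frame with one row per distinct point: columns
#'   \code{sensitivity}, \code{specificity}, \code{n_protocols} and
#'   \code{protocols} (comma-separated labels of the members).
#' @examples
#' pan <- case_study("prostate")
#' nrow(distinct_points(enumerate_protocols(pan$tests)))  # 12
#' @export
distinct_points <- function(protocols, tol = 1e-9) {
  if (inherits(protocols, "protocol") || inherits(protocols, "diagnostic_test"))
    protocols <- list(protocols)
  if (length(protocols) == 0L) stop("'protocols' must be non-empty")
  protocols <- lapply(protocols, as_protocol)
  ops <- lapply(protocols, composite_operating_point)
  se <- vapply(ops, `[[`, numeric(1), "sensitivity")
  sp <- vapply(ops, `[[`, numeric(1), "specificity")
  labs <- vapply(protocols, protocol_label, character(1))
  # cluster each coordinate: points closer than tol merge into one bin
  bin <- function(v) {
    o <- order(v)
    g <- cumsum(c(1, diff(v[o]) > tol))
    out <- integer(length(v)); out[o] <- g
    out
  }
  key <- paste(bin(se), bin(sp))
  groups <- split(seq_along(key), key)
  df <- do.call(rbind, lapply(groups, function(i) {
    data.frame(sensitivity = mean(se[i]), specificity = mean(sp[i]),
               n_protocols = length(i),
               protocols = paste(labs[i], collapse = ", "))
  }))
  df <- df[order(1 - df$specificity, df$sensitivity), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' ROC-frontier (efficiency) flags
#'
#' Flags the operating points lying on the upper-left convex hull in
#' \eqn{(1 - Sp, Se)} space, anchored at the trivial points (0, 0) and
#' (1, 1). Points strictly below the hull are informationally inefficient:
#' some convex combination of efficient points dominates them. Collinear
#' points lying on a hull edge are retained as (weakly) efficient.
#'
#' @param sensitivity,specificity Numeric vectors of operating points, or a
#'   data frame from \code{\link{distinct_points}} as first argument.
#' @param tol Tolerance for lying on the hull.
#' @return Logical vector of efficiency flags (one per input point).
#' @examples
#' pts <- distinct_points(enumerate_protocols(case_study("colorectal")$tests))
#' sum(roc_frontier(pts))  # 5
#' @export
roc_frontier <- function(sensitivity, specificity = NULL, tol = 1e-9) {
  if (is.data.frame(sensitivity)) {
    specificity <- sensitivity$specificity
    sensitivity <- sensitivity$sensitivity
  }
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  fpr <- 1 - specificity
  hx <- c(0, fpr, 1); hy <- c(0, sensitivity, 1)
  o <- order(hx, -hy)
  hx <- hx[o]; hy <- hy[o]
  # strict upper hull, left to right (Andrew's monotone chain)
  sx <- numeric(0); sy <- numeric(0)
  for (i in seq_along(hx)) {
    while (length(sx) >= 2) {
      m <- length(sx)
      cross <- (sx[m] - sx[m - 1]) * (hy[i] - sy[m - 1]) -
               (sy[m] - sy[m - 1]) * (hx[i] - sx[m - 1])
      if (cross >= 0) { sx <- sx[-m]; sy <- sy[-m] } else break
    }
    sx <- c(sx, hx[i]); sy <- c(sy, hy[i])
  }
  hull_height <- stats::approx(sx, sy, xout = fpr, ties = max)$y
  sensitivity >= hull_height - tol
}
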