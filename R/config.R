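#' Read a test panel from a YAML configuration
#'
#' The configuration mirrors the package's domain types. Top level:
#' \code{name}, optional \code{description}, optional \code{frame},
#' optional \code{rho_default} (trade-off used as the panel's reference)
#' or \code{benefit_loss_ratio} (\eqn{b/l}, from which
#' \code{rho_default = 1/(1 + b/l)} is derived), and \code{tests}. Each
#' test entry has \code{name}, \code{sensitivity}, \code{specificity}, and
#' either \code{loss_over_b} directly or \code{cost} (and optionally
#' \code{harm}, valued via the frame's \code{lambda}) normalised by the
#' frame's \code{benefit}. Frame fields: \code{benefit}, \code{loss},
#' \code{rho}, \code{lambda}, \code{qaly_gain}, \code{qaly_loss},
#' \code{treatment_cost}.
#'
#' @param path Path to a YAML file.
#' @return A list with \code{name}, \code{description}, \code{tests},
#'   \code{frame}, \code{rho_default}, \code{benefit_loss_ratio}.
#' @seealso \code{\link{write_panel}}, \code{\link{case_study}}
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$tests) || length(y$tests) == 0L)
    stop("malformed config: field 'tests' is missing or empty")
  frame <- NULL
  if (!is.null(y$frame)) {
    allowed <- c("benefit", "loss", "rho", "lambda", "qaly_gain",
                 "qaly_loss", "treatment_cost")
    bad <- setdiff(names(y$frame), allowed)
    if (length(bad))
      stop("malformed config: unknown frame field '", bad[1], "'")
    frame <- do.call(treatment_frame, y$frame)
  }
  tests <- lapply(y$tests, function(entry) {
    if (is.null(entry$name))
      stop("malformed config: field 'name' missing in a test entry")
    for (f in c("sensitivity", "specificity"))
      if (is.null(entry[[f]]))
        stop("malformed config: field '", f, "' missing for test '",
             entry$name, "'")
    if (!is.null(entry$loss_over_b)) {
      diagnostic_test(entry$name, entry$sensitivity, entry$specificity,
                      loss_over_b = entry$loss_over_b)
    } else {
      cost <- if (is.null(entry$cost)) 0 else entry$cost
      harm <- if (is.null(entry$harm)) 0 else entry$harm
      if ((cost > 0 || harm > 0) && is.null(frame))
        stop("malformed config: test '", entry$name,
             "' has 'cost'/'harm' but no 'frame' provides a benefit")
      lambda <- if (!is.null(frame) && !is.null(frame$lambda))
        frame$lambda else 0
      diagnostic_test(entry$name, entry$sensitivity, entry$specificity,
                      cost = cost, harm = harm, lambda = lambda,
                      frame = frame)
    }
  })
  nms <- vapply(tests, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("malformed config: duplicated test name '", nms[anyDuplicated(nms)], "'")
  rho_default <- NA_real_
  if (!is.null(y$rho_default)) rho_default <- check_rho(y$rho_default)
  else if (!is.null(y$benefit_loss_ratio))
    rho_default <- 1 / (1 + y$benefit_loss_ratio)
  else if (!is.null(frame) && !is.na(frame$rho)) rho_default <- frame$rho
  list(name = if (is.null(y$name)) basename(path) else y$name,
       description = y$description,
       tests = tests, frame = frame, rho_default = rho_default,
       benefit_loss_ratio = y$benefit_loss_ratio)
}

#' Write a test panel to a YAML configuration
#'
#' Inverse of \code{\link{read_panel}}: a written panel reads back with
#' identical test parameters and frame.
#'
#' @param panel A list as returned by \code{\link{read_panel}} or
#'   \code{\link{case_study}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  y <- list(name = panel$name)
  if (!is.null(panel$description)) y$description <- panel$description
  if (!is.null(panel$frame)) {
    fr <- panel$frame
    keep <- c("lambda", "qaly_gain", "qaly_loss", "treatment_cost")
    comp <- Filter(Negate(is.null), fr[keep])
    y$frame <- if (length(comp)) comp else
      Filter(function(v) !is.na(v), list(benefit = fr$benefit, loss = fr$loss))
  }
  if (!is.null(panel$benefit_loss_ratio))
    y$benefit_loss_ratio <- panel$benefit_loss_ratio
  else if (!is.na(panel$rho_default)) y$rho_default <- panel$rho_default
  y$tests <- lapply(panel$tests, function(t) {
    entry <- list(name = t$name, sensitivity = t$sensitivity,
                  specificity = t$specificity)
    if (!is.null(t$cost) && (t$cost > 0 || t$harm > 0)) {
      entry$cost <- t$cost
      if (t$harm > 0) entry$harm <- t$harm
    } else entry$loss_over_b <- t$loss_over_b
    entry
  })
  writeLines(yaml::as.yaml(y), path)
  invisible(path)
}

#' Parse a protocol specification string
#'
#' Accepted forms, with test names taken from the panel: a single name
#' (\code{"FT"}), a pure conjunction (\code{"hK2&FT"}), a pure disjunction
#' (\code{"FT|hK2"}), or a majority (\code{"maj(FT,hK2,TRUS)"}). Mixing
#' \code{&} and \code{|} within one protocol is not supported.
#'
#' @param spec Protocol string.
#' @param tests List of available \code{\link{diagnostic_test}} objects (or
#'   a panel/case study list with a \code{tests} element).
#' @return A \code{\link{protocol}}.
#' @examples
#' parse_protocol("hK2&FT", case_study("prostate"))
#' @export
parse_protocol <- function(spec, tests) {
  if (is.list(tests) && !is.null(tests$tests)) tests <- tests$tests
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub("[[:space:]]", "", spec)
  available <- vapply(tests, `[[`, character(1), "name")
  lookup <- function(nms) {
    missing <- setdiff(nms, available)
    if (length(missing))
      stop("unknown test name '", missing[1], "'; available: ",
           paste(available, collapse = ", "))
    tests[match(nms, available)]
  }
  if (grepl("^maj\\(.*\\)$", spec)) {
    nms <- strsplit(sub("^maj\\((.*)\\)$", "\\1", spec), ",", fixed = TRUE)[[1]]
    return(protocol(lookup(nms), "MAJORITY"))
  }
  has_and <- grepl("&", spec, fixed = TRUE)
  has_or <- grepl("|", spec, fixed = TRUE)
  if (has_and && has_or)
    stop("mixed '&' and '|' protocols are not supported: ", spec)
  if (has_and) return(protocol(lookup(strsplit(spec, "&", fixed = TRUE)[[1]]), "AND"))
  if (has_or) return(protocol(lookup(strsplit(spec, "|", fixed = TRUE)[[1]]), "OR"))
  protocol(lookup(spec))
}

#' Tabulate thresholds for a set of protocols
#'
#' @param protocols List of \code{\link{protocol}} objects (or tests).
#' @param rho Trade-off at which to solve the p thresholds (or \code{NULL}
#'   to skip them).
#' @param p Disease probability at which to solve the rho thresholds (or
#'   \code{NULL}).
#' @param round_digits Optional rounding applied to the numeric columns
#'   (presentation only; computation is full precision).
#' @return Data frame with columns \code{protocol}, \code{rho},
#'   \code{p_test}, \code{p_test_treat}, \code{rho_lower},
#'   \code{rho_upper}.
#' @export
threshold_table <- function(protocols, rho = NULL, p = NULL,
                            round_digits = NULL) {
  if (inherits(protocols, "protocol") || inherits(protocols, "diagnostic_test"))
    protocols <- list(protocols)
  protocols <- lapply(protocols, as_protocol)
  rows <- lapply(protocols, function(pr) {
    tp <- if (is.null(rho)) threshold_set() else protocol_thresholds_p(pr, rho)
    tr <- if (is.null(p)) threshold_set() else protocol_thresholds_rho(pr, p)
    data.frame(protocol = protocol_label(pr),
               rho = if (is.null(rho)) NA_real_ else rho,
               p_test = tp$p_test, p_test_treat = tp$p_test_treat,
               rho_lower = tr$rho_lower, rho_upper = tr$rho_upper)
  })
  out <- do.call(rbind, rows)
  if (!is.null(round_digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, digits = round_digits)
  }
  out
}

#' Operating-point and efficiency table for a set of protocols
#'
#' One row per protocol with its composite operating point, Youden index,
#' likelihood ratios, and an efficiency flag marking membership of the ROC
#' frontier of the whole set.
#'
#' @param protocols List of \code{\link{protocol}} objects (or tests).
#' @param round_digits Optional presentation rounding.
#' @return Data frame with columns \code{protocol}, \code{sensitivity},
#'   \code{specificity}, \code{youden}, \code{lr_plus}, \code{lr_minus},
#'   \code{efficient}.
#' @export
roc_table <- function(protocols, round_digits = NULL) {
  if (inherits(protocols, "protocol") || inherits(protocols, "diagnostic_test"))
    protocols <- list(protocols)
  protocols <- lapply(protocols, as_protocol)
  ops <- lapply(protocols, composite_operating_point)
  se <- vapply(ops, `[[`, numeric(1), "sensitivity")
  sp <- vapply(ops, `[[`, numeric(1), "specificity")
  eff <- roc_frontier(se, sp)
  idx <- lapply(seq_along(se), function(i) op_indices(se[i], sp[i]))
  out <- data.frame(
    protocol = vapply(protocols, protocol_label, character(1)),
    sensitivity = se, specificity = sp,
    youden = vapply(idx, `[[`, numeric(1), "youden"),
    lr_plus = vapply(idx, `[[`, numeric(1), "lr_plus"),
    lr_minus = vapply(idx, `[[`, numeric(1), "lr_minus"),
    efficient = eff)
  if (!is.null(round_digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, digits = round_digits)
  }
  out
}
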