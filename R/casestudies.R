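#' Load a packaged case study
#'
#' Three worked test panels ship with the package as YAML fixtures (see
#' \code{system.file("extdata", package = "inbdx")}), in the same format
#' \code{\link{read_panel}} accepts:
#' \describe{
#'   \item{\code{"prostate"}}{free-to-total PSA (FT), human kallikrein 2
#'     (hK2) and transrectal ultrasound (TRUS), with testing losses given
#'     directly as ratios to the treatment benefit (0.01, 0.01, 0.1);
#'     operating points from Vickers et al. (2013).}
#'   \item{\code{"colorectal"}}{fecal immunochemical test (FIT),
#'     multitarget stool DNA (MT) and colonoscopy (COL), with monetary
#'     costs, a QALY-valued perforation harm for colonoscopy, and a
#'     treatment frame built from a willingness to pay of USD 100000/QALY,
#'     a 1.5 QALY treatment gain and USD 75000 treatment cost (benefit
#'     b = USD 75000); data after Pickhardt et al. (2003) and Ladabaum &
#'     Mannalithara (2016).}
#'   \item{\code{"cad"}}{exercise treadmill testing (ETT), stress
#'     echocardiography (SE), myocardial perfusion scintigraphy (MPS) and
#'     coronary CT angiography (CCTA) for stable coronary artery disease,
#'     with costs after Min et al. (2017), benefit USD 105000 and loss
#'     USD 55000; threshold reproductions use the calibration ratio
#'     b/l = 1.9 (\code{rho_calibration}).}
#' }
#'
#' @param name One of \code{"prostate"}, \code{"colorectal"}, \code{"cad"}.
#' @return A list of class \code{"case_study"}: \code{name}, \code{tests}
#'   (list of \code{\link{diagnostic_test}}), \code{frame} (a
#'   \code{\link{treatment_frame}} or \code{NULL}), \code{rho_default}
#'   (trade-off used in the panel's reference analyses, or \code{NA}) and
#'   \code{notes}.
#' @examples
#' case_study("prostate")
#' @export
case_study <- function(name = c("prostate", "colorectal", "cad")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("prostate", "colorectal", "cad"))
    stop("unknown case study '", paste(name, collapse = ","),
         "'; available: prostate, colorectal, cad")
  path <- system.file("extdata", paste0(name, ".yaml"), package = "inbdx")
  if (!nzchar(path)) stop("fixture file for '", name, "' not found")
  panel <- read_panel(path)
  class(panel) <- c("case_study", class(panel))
  panel
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("Case study '%s' (%d tests)\n", x$name, length(x$tests)))
  for (t in x$tests)
    cat(sprintf("  %-5s Se = %.3g, Sp = %.3g, lDx/b = %.3g\n",
                t$name, t$sensitivity, t$specificity, t$loss_over_b))
  if (!is.null(x$frame)) { cat("  "); print(x$frame) }
  if (!is.na(x$rho_default))
    cat(sprintf("  reference trade-off rho = %.4g\n", x$rho_default))
  invisible(x)
}

#' Generate a random test panel
#'
#' Deterministic pseudo-random panels for property testing: sensitivities
#' and specificities uniform on (0.5, 1), normalised testing losses uniform
#' on (0, 0.05). The global RNG state is saved and restored.
#'
#' @param n_tests Number of tests (>= 1).
#' @param seed Integer seed; the same seed always yields the same panel.
#' @return List of \code{\link{diagnostic_test}} objects named
#'   \code{T1 ... Tn}.
#' @examples
#' random_panel(3, seed = 7)
#' @export
random_panel <- function(n_tests, seed) {
  stopifnot(n_tests >= 1L, is.numeric(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lapply(seq_len(n_tests), function(i)
    diagnostic_test(paste0("T", i),
                    sensitivity = stats::runif(1, 0.5, 1),
                    specificity = stats::runif(1, 0.5, 1),
                    loss_over_b = stats::runif(1, 0, 0.05)))
}
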