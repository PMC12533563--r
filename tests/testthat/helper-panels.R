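# Shared fixtures: the three packaged panels plus shorthand test builders.

prostate <- case_study("prostate")
colorectal <- case_study("colorectal")
cad <- case_study("cad")

pick_test <- function(panel, name) {
  nms <- vapply(panel$tests, `[[`, character(1), "name")
  panel$tests[[match(name, nms)]]
}

dx <- function(name, se, sp, loss = 0)
  diagnostic_test(name, se, sp, loss_over_b = loss)

# bisection root of f on [lo, hi]; independent of the closed-form solvers
bisect <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
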