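# Shared fixtures. find_minima is deterministic but takes a few seconds per
# surface, so the well sets are computed once per test run.
MULLER <- muller_surface()
MODIFIED <- modified_muller_surface()
MULLER_WELLS <- find_minima(MULLER)
MODIFIED_WELLS <- find_minima(MODIFIED)

# central finite-difference gradient oracle
fd_gradient <- function(f, p, h = 1e-5) {
  c((f(p + c(h, 0)) - f(p - c(h, 0))) / (2 * h),
    (f(p + c(0, h)) - f(p - c(0, h))) / (2 * h))
}

rel_err <- function(got, want) {
  denom <- pmax(abs(want), 1e-10)
  max(abs(got - want) / denom)
}
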