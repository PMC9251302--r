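# Local maxima with topographic prominence.
#
# A sample i is a peak when x[i-1] < x[i] >= x[i+1] (flat tops keep their
# first sample). Prominence is the drop from the peak to the higher of the
# two valley minima separating it from the nearest strictly higher ground
# (or the series end) on each side.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(tibble(idx = integer(), value = numeric(),
                            prominence = numeric()))
  d <- diff(x)
  # strictly rising then non-rising
  cand <- which(d[-(n - 1L)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(tibble(idx = integer(), value = numeric(),
                                   prominence = numeric()))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1L) rev(x[1:(i - 1L)]) else numeric()
    hi <- which(left > h)
    vl <- if (length(hi)) min(left[1:hi[1L]]) else min(left)
    right <- if (i < n) x[(i + 1L):n] else numeric()
    hi <- which(right > h)
    vr <- if (length(hi)) min(right[1:hi[1L]]) else min(right)
    h - max(vl, vr)
  }, numeric(1))
  keep <- prom >= min_prominence
  tibble(idx = cand[keep], value = x[cand[keep]], prominence = prom[keep])
}

# quadratic (parabolic) refinement of a discrete argmax position:
# offset in bins of the vertex of the parabola through (k-1, k, k+1)
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (denom == 0) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(min(off, 0.5), -0.5)
}

# deterministic child-seed derivation; keeps seeds in 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 10007 + i) %% 2147483647)
}

# a random admissible state: used for multistability and chaos-seed draws
random_initial_state <- function(seed, params = nfkb_params()) {
  set.seed(seed)
  ikk <- runif(2)
  ikk <- ikk / max(1, sum(ikk) / params$IKK_tot * 1.01)
  c(N_n = runif(1, 0.01, 0.9 * params$N_tot),
    I_m = runif(1, 0.001, 0.05),
    I = runif(1, 0.05, 1),
    IKK_a = ikk[1], IKK_i = ikk[2])
}
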