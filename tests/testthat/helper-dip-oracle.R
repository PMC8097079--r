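# Independent definition-based dip oracle (hull-feasibility + bisection),
# used to cross-check the compiled implementation on small samples: dip = min eps such that a unimodal cdf U
# (convex below its mode, concave above, possibly with an atom AT the mode)
# stays within [Fn - eps, Fn + eps]. Mode scanned over data points.
# At mode t_m: left limit v = U(t_m^-) produced by the convex half over
# points 1..m-1 extended to t_m (v <= F_{m-1} + eps); after the atom
# U(t_m) = u in [F_m - eps, F_m + eps], u >= v; concave half through
# (t_m, u) and points m+1..K.
lower_hull_vals <- function(t, y) {
  n <- length(t)
  if (n == 1) return(y)
  idx <- 1L
  for (j in 2:n) {
    while (length(idx) >= 2) {
      a <- idx[length(idx) - 1]; b <- idx[length(idx)]
      if ((y[j] - y[a]) * (t[b] - t[a]) <= (y[b] - y[a]) * (t[j] - t[a])) {
        idx <- idx[-length(idx)]
      } else break
    }
    idx <- c(idx, j)
  }
  approx(t[idx], y[idx], xout = t)$y
}
# min feasible value at t_end of a convex nondecreasing function with
# v(t_j) in [lo_j, hi_j] (virtual end has upper bound hi_end, no lower)
conv_min_end <- function(t, hi, lo, t_end, hi_end) {
  K <- length(t)
  if (K == 0) return(0)
  lo_u <- max(lo[K], 0); hi_u <- hi_end   # end >= v(t_K) >= lo_K
  f <- function(u) {
    y <- c(hi, u)
    all(lower_hull_vals(c(t, t_end), y) >= c(lo, -Inf) - 1e-9)
  }
  if (!f(hi_u)) return(Inf)
  if (f(lo_u)) return(lo_u)
  for (it in 1:50) {
    mid <- (lo_u + hi_u) / 2
    if (f(mid)) hi_u <- mid else lo_u <- mid
  }
  hi_u
}
dip_oracle <- function(x, tol = 1e-7) {
  x <- sort(x); n <- length(x)
  t <- unique(x)
  F <- cumsum(as.numeric(table(factor(x, levels = t)))) / n
  Fm <- c(0, F[-length(F)])
  K <- length(t)
  feasible <- function(eps) {
    hi <- Fm + eps; lo <- F - eps
    for (m in 1:K) {
      v <- if (m == 1) 0 else
        conv_min_end(t[1:(m - 1)], hi[1:(m - 1)], lo[1:(m - 1)],
                     t[m], Fm[m] + eps)
      if (!is.finite(v)) next
      # largest feasible concave start value at t_m over points m+1..K
      u_hi <- F[m] + eps
      u_lo <- max(v, F[m] - eps)
      if (u_lo > u_hi + 1e-12) next
      if (m == K) return(TRUE)
      # concave side mirrored into a convex problem
      tc <- c(t[m], t[(m + 1):K])
      hic <- c(Inf, hi[(m + 1):K])
      loc <- c(-Inf, lo[(m + 1):K])
      g <- function(u) {
        # concave func through (t_m, u), within [loc, hic], nondecreasing,
        # extended right to 1: mirror x -> -x, y -> 1 - y gives convex
        tm <- rev(-tc); yhi <- rev(1 - loc); ylo <- rev(1 - hic)
        yhi[length(yhi)] <- 1 - u; ylo[length(ylo)] <- 1 - u
        hull <- lower_hull_vals(tm, yhi)
        all(hull >= ylo - 1e-9) && all(hull <= yhi + 1e-9)
      }
      if (g(u_hi)) return(TRUE)
      ok <- FALSE
      lo_u <- u_lo; hi_u <- u_hi
      if (g(u_lo)) ok <- TRUE else {
        # g monotone decreasing in u is not guaranteed both ways; scan coarse
        for (uu in seq(u_lo, u_hi, length.out = 12)) if (g(uu)) { ok <- TRUE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  lo_e <- 0; hi_e <- 0.25
  while (hi_e - lo_e > tol) {
    mid <- (lo_e + hi_e) / 2
    if (feasible(mid)) hi_e <- mid else lo_e <- mid
  }
  (lo_e + hi_e) / 2
}
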