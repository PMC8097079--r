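# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (no kd-trees, no envelopes): plain O(n^2)
# loops and quadrature.

# brute-force neighbor counts within radius (excluding self)
ref_neighbor_counts <- function(x, y, radius) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  as.integer(colSums(d <= radius) - 1L)
}

# exhaustive re-implementation of the detection pipeline, no spatial index
ref_detect <- function(locs, n_frames, radius = 10, window = c(0.2, 0.8),
                       min_members = 2) {
  o <- order(locs$x, locs$y, locs$frame)
  locs <- locs[o, ]
  n <- nrow(locs)
  d <- as.matrix(stats::dist(cbind(locs$x, locs$y)))
  counts <- as.integer(colSums(d <= radius) - 1L)
  nxt <- integer(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= radius)
    key <- counts[nb] * (n + 1) + (n - nb)
    best <- nb[which.max(key)]
    nxt[i] <- if (counts[best] * (n + 1) + (n - best) >
                  counts[i] * (n + 1) + (n - i)) best else 0L
  }
  root <- vapply(seq_len(n), function(i) {
    while (nxt[i] != 0L) i <- nxt[i]
    i
  }, integer(1))
  term <- sort(unique(root))
  # single-linkage merge of terminals within radius/2
  merge_sl <- function(cx, cy) {
    k <- length(cx)
    comp <- seq_len(k)
    repeat {
      changed <- FALSE
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (comp[i] != comp[j] &&
            sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2) < radius / 2) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    match(comp, unique(comp))
  }
  cx <- locs$x[term]
  cy <- locs$y[term]
  comp <- merge_sl(cx, cy)
  cx <- as.numeric(tapply(cx, comp, mean))
  cy <- as.numeric(tapply(cy, comp, mean))
  assign_once <- function(cx, cy) {
    sid <- integer(n)
    for (i in seq_len(n)) {
      dd <- sqrt((locs$x[i] - cx)^2 + (locs$y[i] - cy)^2)
      ok <- which(dd <= radius)
      if (length(ok) > 0) {
        dmin <- min(dd[ok])
        sid[i] <- min(ok[dd[ok] <= dmin + 1e-9])
      }
    }
    # drop empty centers, relabel compactly
    occ <- sort(unique(sid[sid != 0L]))
    list(sid = match(sid, occ, nomatch = 0L), occ = occ)
  }
  prev <- NULL
  sid <- NULL
  for (pass in 1:20) {
    a <- assign_once(cx, cy)
    sid <- a$sid
    if (identical(sid, prev)) break
    prev <- sid
    keep <- sid != 0L
    f <- factor(sid[keep], levels = seq_along(a$occ))
    cx <- as.numeric(tapply(locs$x[keep], f, mean))
    cy <- as.numeric(tapply(locs$y[keep], f, mean))
    comp <- merge_sl(cx, cy)
    if (length(unique(comp)) < length(cx)) {
      cx <- as.numeric(tapply(cx, comp, mean))
      cy <- as.numeric(tapply(cy, comp, mean))
      prev <- NULL
    }
  }
  keep <- sid != 0L
  f <- factor(sid[keep], levels = seq_along(cx))
  small <- as.integer(names(table(f)))[table(f) < min_members]
  if (length(small) > 0) {
    keep <- keep & !(sid %in% small)
    f <- factor(sid[keep], levels = setdiff(seq_along(cx), small))
  }
  mf <- as.numeric(tapply(locs$frame[keep], f, mean)) / n_frames
  mem <- as.integer(table(f))
  ok <- !is.na(mf) & mf >= window[1] & mf <= window[2]
  out <- data.frame(x = as.numeric(tapply(locs$x[keep], f, mean))[ok],
                    y = as.numeric(tapply(locs$y[keep], f, mean))[ok],
                    members = mem[ok])
  out[order(out$x, out$y), ]
}

# numerical quadrature of the Marko-Siggia force-extension relation
ref_wlc_energy <- function(x, L0, Lp, temperature) {
  kB <- 0.01380649
  force <- function(xx) {
    r <- xx / L0
    kB * temperature / Lp * (r + 1 / (4 * (1 - r)^2) - 1 / 4)
  }
  stats::integrate(force, 0, x, rel.tol = 1e-10)$value
}

# winding-number point-in-polygon (independent formulation: angle sum)
ref_in_polygon <- function(px, py, vx, vy) {
  vapply(seq_along(px), function(i) {
    ang <- atan2(vy - py[i], vx - px[i])
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > 1e-6
  }, logical(1))
}

# small synthetic acquisition: well-separated sites with guaranteed events
sim_isolated_sites <- function(n_side = 5, spacing = 80, sigma = 4,
                               locs_per_site = 25, n_frames = 1000,
                               seed = 1) {
  withr::with_seed(seed, {
    g <- expand.grid(x = seq(50, by = spacing, length.out = n_side),
                     y = seq(50, by = spacing, length.out = n_side))
    n_sites <- nrow(g)
    site <- rep(seq_len(n_sites), each = locs_per_site)
    frame <- as.integer(round(seq(0.25, 0.75, length.out = locs_per_site) *
                                n_frames))
    meta <- acquisition_meta(n_frames, 0.1,
                             field_width = max(g$x) + 50,
                             field_height = max(g$y) + 50)
    locs <- data.frame(
      x = g$x[site] + rnorm(length(site), 0, sigma),
      y = g$y[site] + rnorm(length(site), 0, sigma),
      frame = rep(frame, n_sites)
    )
    list(truth = g, locs = loc_table(locs, meta), meta = meta)
  })
}
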