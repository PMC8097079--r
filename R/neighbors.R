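# Fixed-radius and k-nearest neighbor queries, backed by RANN kd-trees.
# Radius queries use an adaptive neighbor cap (doubled until no query is
# saturated) and are chunked so the idx/dist matrices stay small.

.radius_idx <- function(data, query, radius, k0 = 32L, chunk = 50000L) {
  nd <- nrow(data)
  nq <- nrow(query)
  blocks <- split(seq_len(nq), ceiling(seq_len(nq) / chunk))
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    k <- min(k0, nd)
    repeat {
      res <- RANN::nn2(data, query[rows, , drop = FALSE], k = k,
                       searchtype = "radius", radius = radius)
      if (k == nd || !any(res$nn.idx[, k] != 0L)) break
      k <- min(2L * k, nd)
    }
    out[[b]] <- res$nn.idx
  }
  out
}

# neighbor counts within radius, excluding the point itself
.radius_counts <- function(m, radius, chunk = 50000L) {
  idx <- .radius_idx(m, m, radius, chunk = chunk)
  unlist(lapply(idx, function(mat) {
    as.integer(rowSums(mat != 0L) - 1L)
  }), use.names = FALSE)
}

# For each point, the neighbor within `radius` maximizing (count, -index)
# lexicographically, or 0 if no neighbor beats the point's own (count, -index).
.best_neighbor <- function(m, counts, radius, chunk = 50000L) {
  n <- nrow(m)
  idxs <- .radius_idx(m, m, radius, chunk = chunk)
  offset <- 0L
  nxt <- integer(n)
  for (mat in idxs) {
    nb <- nrow(mat)
    cm <- matrix(counts[pmax(mat, 1L)], nrow = nb)
    score <- cm * (n + 1) + (n - mat)
    score[mat == 0L] <- -Inf
    best <- max.col(score, ties.method = "first")
    sel <- cbind(seq_len(nb), best)
    rows <- offset + seq_len(nb)
    own <- counts[rows] * (n + 1) + (n - rows)
    cand <- mat[sel]
    cand[score[sel] <= own] <- 0L
    nxt[rows] <- cand
    offset <- offset + nb
  }
  nxt
}

# kth nearest neighbor distances among points (self excluded)
.knn_dists <- function(data, query, k) {
  res <- RANN::nn2(data, query, k = k)
  res$nn.dists
}

# single-linkage components with linking distance `radius`
.link_components <- function(m, radius) {
  n <- nrow(m)
  if (n <= 1) return(rep(1L, n))
  idx <- .radius_idx(m, m, radius)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offset <- 0L
  for (mat in idx) {
    for (i in seq_len(nrow(mat))) {
      for (j in mat[i, ]) {
        if (j > 0L && j != offset + i) {
          ri <- find(offset + i)
          rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    offset <- offset + nrow(mat)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, sort(unique(comp)))
}

# nearest center within `radius` for each point; ties (within 1e-9) broken
# toward the lower center index; 0 when no center is in range
.nearest_center <- function(centers, points, radius) {
  nc <- nrow(centers)
  k <- min(2L, nc)
  res <- RANN::nn2(centers, points, k = k, searchtype = "radius",
                   radius = radius)
  sid <- res$nn.idx[, 1]
  if (k == 2L) {
    tie <- res$nn.idx[, 2] != 0L &
      res$nn.dists[, 2] - res$nn.dists[, 1] < 1e-9
    sid[tie] <- pmin(res$nn.idx[tie, 1], res$nn.idx[tie, 2])
  }
  sid
}
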