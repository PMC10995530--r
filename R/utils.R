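# Internal array helpers shared by filtering, morphology and feature code.

# result[x] = a[x + offset], out-of-grid handled per pad mode.
# pad: "zero" (fill), "reflect" (edge-inclusive mirror), "replicate" (clamp)
take_shifted <- function(a, offset, pad = c("zero", "reflect", "replicate"),
                         fill = 0) {
  pad <- match.arg(pad)
  dm <- dim(a)
  idx <- vector("list", 3L)
  oob <- vector("list", 3L)
  for (ax in 1:3) {
    i <- seq_len(dm[ax]) + offset[ax]
    if (pad == "reflect") i <- reflect_index(i, dm[ax])
    else if (pad == "replicate") i <- pmin(pmax(i, 1L), dm[ax])
    else {
      oob[[ax]] <- i < 1L | i > dm[ax]
      i[oob[[ax]]] <- 1L
    }
    idx[[ax]] <- i
  }
  out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (pad == "zero") {
    if (any(oob[[1]])) out[oob[[1]], , ] <- fill
    if (any(oob[[2]])) out[, oob[[2]], ] <- fill
    if (any(oob[[3]])) out[, , oob[[3]]] <- fill
  }
  out
}

# mirror indices into 1..n, edge repeated (d c b a | a b c d | d c b a)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  p[p < 0L] <- p[p < 0L] + 2L * n
  ifelse(p < n, p + 1L, 2L * n - p)
}

# integer voxel offsets whose centers lie within radius_mm (Euclidean, mm)
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(0L, floor(radius_mm / spacing))
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# 26- or 6-neighborhood integer offsets
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

# label connected components of a logical 3D array (vectorized BFS);
# returns integer array, 0 = background, components numbered from 1
label_components <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  labels <- array(0L, dim = dm)
  nb <- neighbor_offsets(connectivity)
  todo <- which(mask)
  seen <- array(FALSE, dim = dm)
  lab <- 0L
  for (seed in todo) {
    if (seen[seed]) next
    lab <- lab + 1L
    frontier <- arr_ind(seed, dm)
    seen[seed] <- TRUE
    labels[seed] <- lab
    while (nrow(frontier) > 0L) {
      cand <- expand_neighbors(frontier, nb, dm)
      if (nrow(cand) == 0L) break
      lin <- cand[, 1] + dm[1] * (cand[, 2] - 1L) + dm[1] * dm[2] * (cand[, 3] - 1L)
      keep <- mask[lin] & !seen[lin]
      lin <- unique(lin[keep])
      if (length(lin) == 0L) break
      seen[lin] <- TRUE
      labels[lin] <- lab
      frontier <- arr_ind(lin, dm)
    }
  }
  labels
}

arr_ind <- function(lin, dm) {
  lin0 <- lin - 1L
  i <- lin0 %% dm[1]
  j <- (lin0 %/% dm[1]) %% dm[2]
  k <- lin0 %/% (dm[1] * dm[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

expand_neighbors <- function(frontier, nb, dm) {
  n <- nrow(frontier); m <- nrow(nb)
  pts <- frontier[rep(seq_len(n), each = m), , drop = FALSE] +
    nb[rep(seq_len(m), times = n), , drop = FALSE]
  keep <- pts[, 1] >= 1L & pts[, 1] <= dm[1] &
    pts[, 2] >= 1L & pts[, 2] <= dm[2] &
    pts[, 3] >= 1L & pts[, 3] <= dm[3]
  pts[keep, , drop = FALSE]
}

# sum over ball offsets of shifted copies (zero pad); used for SUVpeak
ball_sum <- function(a, offsets) {
  out <- array(0, dim = dim(a))
  for (r in seq_len(nrow(offsets)))
    out <- out + take_shifted(a, offsets[r, ], pad = "zero")
  out
}
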