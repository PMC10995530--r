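# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops and from-the-definition formulas.

# mean SUV over all voxels within r_mm of each in-mask center; returns
# the best center (0-based index) and value by exhaustive scan
oracle_peak <- function(vol, mask, sphere_volume_cm3 = 1.0) {
  r <- (3 * sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  dm <- dim(vol$values)
  sp <- vol$spacing
  all_idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                                   k = 0:(dm[3] - 1)))
  all_w <- all_idx * matrix(sp, nrow(all_idx), 3, byrow = TRUE)
  vals <- as.vector(vol$values)  # column-major == expand.grid order
  centers <- which(mask$values, arr.ind = TRUE) - 1L
  best <- -Inf; best_center <- NULL
  for (c in seq_len(nrow(centers))) {
    cw <- centers[c, ] * sp
    d <- sqrt(rowSums((all_w - matrix(cw, nrow(all_w), 3, byrow = TRUE))^2))
    m <- mean(vals[d <= r + 1e-9])
    if (m > best + 1e-12) { best <- m; best_center <- centers[c, ] }
  }
  list(value = best, index = best_center)
}

# GLCM by explicit enumeration of every ordered in-mask voxel pair at
# Chebyshev distance 1
oracle_glcm <- function(dvol) {
  lev <- dvol$levels
  dm <- dim(lev)
  g <- dvol$params$levels
  counts <- matrix(0, g, g)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(lev[i, j, k])) next
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]) next
      if (is.na(lev[ii, jj, kk])) next
      counts[lev[i, j, k], lev[ii, jj, kk]] <-
        counts[lev[i, j, k], lev[ii, jj, kk]] + 1
    }
  }
  counts / sum(counts)
}

# run-length counts by explicit per-direction line scanning
oracle_glrlm <- function(dvol) {
  lev <- dvol$levels
  dm <- dim(lev)
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
               c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= dm)
  for (d in dirs) {
    for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
      p <- c(i, j, k)
      if (is.na(lev[i, j, k])) next
      prev <- p - d
      pv <- if (inb(prev)) lev[prev[1], prev[2], prev[3]] else NA
      if (!is.na(pv) && pv == lev[i, j, k]) next  # not a run start
      len <- 1L
      q <- p + d
      while (inb(q) && !is.na(lev[q[1], q[2], q[3]]) &&
             lev[q[1], q[2], q[3]] == lev[i, j, k]) {
        len <- len + 1L
        q <- q + d
      }
      runs[[length(runs) + 1L]] <- c(lev[i, j, k], len)
    }
  }
  do.call(rbind, runs)
}

# zone (level, size) list via igraph connected components - a
# 26-connected labeling independent of the package's own
oracle_glszm <- function(dvol) {
  lev <- dvol$levels
  vox <- which(!is.na(lev), arr.ind = TRUE)
  n <- nrow(vox)
  edges <- c()
  for (r in seq_len(n)) for (s in seq_len(n)) {
    if (s <= r) next
    if (max(abs(vox[r, ] - vox[s, ])) > 1) next  # not 26-adjacent
    if (lev[vox[r, , drop = FALSE]] != lev[vox[s, , drop = FALSE]]) next
    edges <- c(edges, r, s)
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)
  zl <- tapply(as.vector(lev[vox]), comp$membership, function(x) x[1])
  zs <- as.vector(table(comp$membership))
  cbind(level = as.vector(zl), size = zs)
}

# Spearman matrix from the definition: average ranks, then Pearson
oracle_spearman <- function(x) {
  rk <- apply(x, 2, rank)
  p <- ncol(x)
  out <- matrix(NA_real_, p, p)
  for (i in 1:p) for (j in 1:p) {
    a <- rk[, i]; b <- rk[, j]
    out[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  out
}

# Harrell C by explicit pair enumeration
oracle_cindex <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# per-cutoff standardized log-rank score statistic, from the definition
oracle_maxstat <- function(time, event, x, minprop = 0.10) {
  n <- length(time)
  # Nelson-Aalen scores computed independently
  a <- numeric(n)
  for (i in 1:n) {
    ch <- 0
    for (tu in sort(unique(time[time <= time[i]]))) {
      d <- sum(time == tu & event == 1)
      r <- sum(time >= tu)
      ch <- ch + d / r
    }
    a[i] <- event[i] - ch
  }
  cuts <- sort(unique(x))
  cuts <- (cuts[-length(cuts)] + cuts[-1]) / 2
  kmin <- max(1, ceiling(minprop * n))
  best <- -Inf; best_cut <- NA
  abar <- mean(a)
  ss <- sum((a - abar)^2)
  for (cc in cuts) {
    k <- sum(x <= cc)
    if (k < kmin || k > n - kmin) next
    s <- sum(a[x <= cc])
    v <- k * (n - k) / (n * (n - 1)) * ss
    t <- abs(s - k * abar) / sqrt(v)
    if (t > best) { best <- t; best_cut <- cc }
  }
  list(statistic = best, cutoff = best_cut)
}

# product-limit estimate by hand
oracle_km <- function(time, event) {
  tu <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tu))
  for (i in seq_along(tu)) {
    d <- sum(time == tu[i] & event == 1)
    r <- sum(time >= tu[i])
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  data.frame(time = tu, surv = surv)
}

# random discretized VOI on a small grid for texture oracle tests
random_dvol <- function(dim = c(4, 4, 4), g = 4, p_mask = 0.8) {
  vals <- array(runif(prod(dim), 0, g), dim = dim)
  m <- array(runif(prod(dim)) < p_mask, dim = dim)
  if (!any(m)) m[1] <- TRUE
  discretize(suv_volume(vals), lesion_mask(m),
             discretization_params(0, g, g))
}

# digital ball mask
ball_mask <- function(radius_mm, spacing = 1, dim = NULL, center = NULL) {
  spacing <- rep(spacing, length.out = 3)
  if (is.null(dim)) dim <- rep(2L * ceiling(radius_mm / spacing) + 5L, 3)[1:3]
  dim <- as.integer(rep(dim, length.out = 3))
  cx <- (seq_len(dim[1]) - 1) * spacing[1]
  cy <- (seq_len(dim[2]) - 1) * spacing[2]
  cz <- (seq_len(dim[3]) - 1) * spacing[3]
  if (is.null(center)) center <- (dim - 1) * spacing / 2
  d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
              (cz - center[3])^2, `+`)
  lesion_mask(d2 <= radius_mm^2, spacing = spacing)
}
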