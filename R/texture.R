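# 13 unique 3D directions (26-neighborhood up to sign)
texture_directions <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- g[, 3] > 0L | (g[, 3] == 0L & (g[, 2] > 0L |
                                           (g[, 2] == 0L & g[, 1] > 0L)))
  g[keep, , drop = FALSE]
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Distance-1 co-occurrence probabilities over the 13 unique 3D
#' directions (Chebyshev distance 1), merged into a single matrix: both
#' orderings of each in-mask voxel pair are counted, so the matrix is
#' symmetric, then normalized to sum to 1. Gray levels are the 1-based
#' levels of the [discretize()]d VOI.
#'
#' @param dvol a `discretized_volume` from [discretize()].
#' @return A `cooccurrence_matrix`: `$p` (G x G probabilities), `$counts`,
#'   `$n_pairs`.
#' @export
glcm <- function(dvol) {
  stopifnot(inherits(dvol, "discretized_volume"))
  lev <- dvol$levels
  g <- dvol$params$levels
  counts <- matrix(0, g, g)
  dirs <- texture_directions()
  for (d in seq_len(nrow(dirs))) {
    dir <- dirs[d, ]
    nb <- take_shifted(lev, dir, pad = "zero", fill = NA_integer_)
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    i <- lev[ok]; j <- nb[ok]
    tab <- tabulate(i + g * (j - 1L), nbins = g * g)
    counts <- counts + matrix(tab, g, g)
  }
  counts <- counts + t(counts)  # both orderings
  n <- sum(counts)
  if (n == 0) stop("no in-mask voxel pair; VOI too small for GLCM")
  structure(list(p = counts / n, counts = counts, n_pairs = n),
            class = "cooccurrence_matrix")
}

#' GLCM texture features
#'
#' Joint entropy (log base 10), `-sum p log10 p` over positive cells,
#' and the inverse difference moment `sum p / (1 + (i - j)^2)`.
#'
#' @param m a `cooccurrence_matrix` from [glcm()].
#' @return Named numeric vector `joint_entropy_log10`,
#'   `inverse_difference_moment`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "cooccurrence_matrix"))
  p <- m$p
  pos <- p > 0
  ent <- -sum(p[pos] * log10(p[pos]))
  g <- nrow(p)
  ij <- outer(seq_len(g), seq_len(g), `-`)
  idm <- sum(p / (1 + ij^2))
  c(joint_entropy_log10 = ent, inverse_difference_moment = idm)
}

#' Gray-level run-length matrix (GLRLM)
#'
#' Counts maximal runs of consecutive in-mask voxels with equal gray
#' level along each of the 13 unique 3D directions, merged into one
#' counts matrix `r(i, j)` (level i, run length j). Runs break at mask
#' gaps and at level changes.
#'
#' @inheritParams glcm
#' @return A `runlength_matrix`: `$counts` (G x Jmax), `$n_runs`.
#' @export
glrlm <- function(dvol) {
  stopifnot(inherits(dvol, "discretized_volume"))
  lev <- dvol$levels
  dm <- dim(lev)
  g <- dvol$params$levels
  dirs <- texture_directions()
  run_lev <- integer(0)
  run_len <- integer(0)
  for (d in seq_len(nrow(dirs))) {
    dir <- dirs[d, ]
    prev <- take_shifted(lev, -dir, pad = "zero", fill = NA_integer_)
    start <- !is.na(lev) & (is.na(prev) | prev != lev)
    pos <- which(start, arr.ind = TRUE)
    if (nrow(pos) == 0L) next
    vals <- lev[start]
    len <- rep(1L, nrow(pos))
    active <- seq_len(nrow(pos))
    cur <- pos
    while (length(active) > 0L) {
      nxt <- cur + matrix(dir, length(active), 3, byrow = TRUE)
      inb <- nxt[, 1] >= 1L & nxt[, 1] <= dm[1] &
        nxt[, 2] >= 1L & nxt[, 2] <= dm[2] &
        nxt[, 3] >= 1L & nxt[, 3] <= dm[3]
      same <- rep(FALSE, length(active))
      if (any(inb)) {
        nl <- lev[nxt[inb, , drop = FALSE]]
        same[inb] <- !is.na(nl) & nl == vals[active][inb]
      }
      len[active[same]] <- len[active[same]] + 1L
      cur <- nxt[same, , drop = FALSE]
      active <- active[same]
    }
    run_lev <- c(run_lev, vals)
    run_len <- c(run_len, len)
  }
  if (length(run_lev) == 0L) stop("empty VOI")
  jmax <- max(run_len)
  counts <- matrix(0, g, jmax)
  tab <- tabulate(run_lev + g * (run_len - 1L), nbins = g * jmax)
  counts <- matrix(tab, g, jmax)
  structure(list(counts = counts, n_runs = sum(counts)),
            class = "runlength_matrix")
}

#' GLRLM texture features
#'
#' Short run emphasis `(1/Nr) sum r(i,j)/j^2` and long run emphasis
#' `(1/Nr) sum r(i,j) j^2` from the merged-direction run-length matrix.
#'
#' @inheritParams glcm
#' @return Named numeric vector `short_run_emphasis`,
#'   `long_run_emphasis`.
#' @export
glrlm_features <- function(dvol) {
  m <- if (inherits(dvol, "runlength_matrix")) dvol else glrlm(dvol)
  j2 <- matrix(seq_len(ncol(m$counts))^2, nrow(m$counts), ncol(m$counts),
               byrow = TRUE)
  c(short_run_emphasis = sum(m$counts / j2) / m$n_runs,
    long_run_emphasis = sum(m$counts * j2) / m$n_runs)
}

#' Gray-level size-zone matrix (GLSZM)
#'
#' Counts 26-connected zones of equal gray level: `s(i, j)` is the
#' number of zones of level i and size j voxels. Unlike the run-length
#' matrix there is no direction to merge.
#'
#' @inheritParams glcm
#' @return A `sizezone_matrix`: `$counts` (G x Jmax), `$n_zones`.
#' @export
glszm <- function(dvol) {
  stopifnot(inherits(dvol, "discretized_volume"))
  lev <- dvol$levels
  g <- dvol$params$levels
  zone_lev <- integer(0)
  zone_size <- integer(0)
  for (gl in sort(unique(lev[!is.na(lev)]))) {
    labs <- label_components(!is.na(lev) & lev == gl, connectivity = 26L)
    if (max(labs) == 0L) next
    sz <- tabulate(labs[labs > 0L])
    zone_lev <- c(zone_lev, rep(gl, length(sz)))
    zone_size <- c(zone_size, sz)
  }
  if (length(zone_lev) == 0L) stop("empty VOI")
  jmax <- max(zone_size)
  tab <- tabulate(zone_lev + g * (zone_size - 1L), nbins = g * jmax)
  counts <- matrix(tab, g, jmax)
  structure(list(counts = counts, n_zones = sum(counts)),
            class = "sizezone_matrix")
}

#' GLSZM texture features
#'
#' Low gray-level zone emphasis `(1/Nz) sum s(i,j)/i^2` and high
#' gray-level zone emphasis `(1/Nz) sum s(i,j) i^2`, with i the 1-based
#' gray level.
#'
#' @inheritParams glcm
#' @return Named numeric vector `low_gray_zone_emphasis`,
#'   `high_gray_zone_emphasis`.
#' @export
glszm_features <- function(dvol) {
  m <- if (inherits(dvol, "sizezone_matrix")) dvol else glszm(dvol)
  i2 <- matrix(seq_len(nrow(m$counts))^2, nrow(m$counts), ncol(m$counts))
  c(low_gray_zone_emphasis = sum(m$counts / i2) / m$n_zones,
    high_gray_zone_emphasis = sum(m$counts * i2) / m$n_zones)
}
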