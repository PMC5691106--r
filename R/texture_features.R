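# Three-dimensional textural heterogeneity features.
#
# Two matrix families are computed on a 16-level discretized VOI:
#  - co-occurrence matrix (CM): gray-level pairs over the 26 neighbours of
#    each voxel (the 13 distance-1 directions and their opposites),
#    normalized to probabilities — local texture;
#  - run-length matrix (RLM): maximal collinear same-level runs in the 13
#    directions — regional texture.
# The gradient energies (SE, TE) are computed on the raw SUV field, not
# the discretized one.

crop_to_mask <- function(arr, mask) {
  w <- which(mask, arr.ind = TRUE)
  xs <- min(w[, 1L]):max(w[, 1L])
  ys <- min(w[, 2L]):max(w[, 2L])
  zs <- min(w[, 3L]):max(w[, 3L])
  list(arr = arr[xs, ys, zs, drop = FALSE],
       mask = mask[xs, ys, zs, drop = FALSE])
}

#' Discretize the VOI into gray-level classes
#'
#' Equal-width binning of the masked SUVs between the VOI minimum and
#' maximum into `n_levels` classes:
#' `level = min(N, floor(N * (s - min) / (max - min)) + 1)`.
#' A constant VOI (max = min) maps every voxel to level 1. Binning is
#' per-lesion (relative) by default; fixed bounds can be supplied for
#' cross-lesion comparability.
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask`.
#' @param n_levels Number of gray classes N, default 16.
#' @param bounds Optional fixed `(min, max)` replacing the VOI range.
#' @return An object of class `discretized_voi`: `levels` (integer array
#'   cropped to the mask's bounding region, 0 outside the mask),
#'   `n_levels`, `histogram` (counts per level), `n_voxels`.
#' @export
discretize_voi <- function(volume, mask, n_levels = 16, bounds = NULL) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "tumor_mask"))
  if (!any(mask$mask)) stop("empty mask", call. = FALSE)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  cr <- crop_to_mask(volume$suv, mask$mask)
  s <- cr$arr[cr$mask]
  lo <- if (is.null(bounds)) min(s) else bounds[1L]
  hi <- if (is.null(bounds)) max(s) else bounds[2L]
  lev <- array(0L, dim = dim(cr$arr))
  if (hi > lo) {
    lev[cr$mask] <- pmin(as.integer(n_levels),
                         as.integer(floor(n_levels * (s - lo) / (hi - lo))) + 1L)
  } else {
    lev[cr$mask] <- 1L
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 histogram = tabulate(lev[cr$mask], nbins = n_levels),
                 n_voxels = sum(cr$mask)),
            class = "discretized_voi")
}

#' Build the 3D co-occurrence matrix
#'
#' Counts every ordered pair of 26-adjacent in-mask voxels (all 13
#' distance-1 directions and their opposites), increments
#' `CM(level(a), level(b))`, and normalizes by the total pair count. The
#' matrix is symmetric by construction; pairs with either voxel outside
#' the mask are ignored.
#'
#' @param d A [discretize_voi()] result.
#' @return An object of class `cooccurrence_matrix`: `p` (N x N
#'   probability matrix summing to 1), `counts` (raw ordered-pair counts)
#'   and `pairs` (their total).
#' @export
build_cm <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  n <- d$n_levels
  lev <- d$levels
  dm <- dim(lev)
  counts <- matrix(0, n, n)
  dirs <- directions13()
  for (k in seq_len(13L)) {
    p <- offset_pairs(dm, dirs[k, ])
    li <- lev[p[, 1L]]
    lj <- lev[p[, 2L]]
    keep <- li > 0L & lj > 0L
    if (!any(keep)) next
    li <- li[keep]; lj <- lj[keep]
    t1 <- tabulate((lj - 1L) * n + li, nbins = n * n)
    counts <- counts + matrix(t1, n, n)
    counts <- counts + t(matrix(t1, n, n))   # the opposite direction
  }
  total <- sum(counts)
  if (total == 0)
    stop("texture undefined: no adjacent in-mask voxel pairs", call. = FALSE)
  structure(list(p = counts / total, counts = counts,
                 pairs = as.integer(total)),
            class = "cooccurrence_matrix")
}

#' Co-occurrence features
#'
#' The five local texture measures evaluated on a normalized CM with
#' natural logarithms and the convention 0 * ln 0 = 0:
#' entropy `ENT = -sum CM(i,j) ln CM(i,j)`;
#' homogeneity `HOM = sum CM(i,j) / (1 + (i-j)^2)`;
#' contrast `CON = sum CM(i,j) (i-j)^2`;
#' dissimilarity `DIS = sum CM(i,j) |i-j|`;
#' uniformity `UNI = sum CM(i,j)^2`.
#'
#' @param cm A `cooccurrence_matrix` (or a plain normalized matrix).
#' @return Named numeric vector `ENT, HOM, CON, DIS, UNI`.
#' @export
cm_features <- function(cm) {
  p <- if (inherits(cm, "cooccurrence_matrix")) cm$p else as.matrix(cm)
  if (abs(sum(p) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalized to sum 1", call. = FALSE)
  n <- nrow(p)
  i <- row(p); j <- col(p)
  pl <- p
  pl[p > 0] <- p[p > 0] * log(p[p > 0])
  c(ENT = -sum(pl),
    HOM = sum(p / (1 + (i - j)^2)),
    CON = sum(p * (i - j)^2),
    DIS = sum(p * abs(i - j)),
    UNI = sum(p^2))
}

#' Build the 3D run-length matrix
#'
#' For each of the 13 directions, maximal runs of collinear in-mask voxels
#' sharing a gray level are counted; a voxel outside the mask terminates
#' the run (no bridging). Every masked voxel belongs to exactly one run
#' per direction — an isolated voxel yields a run of length 1 — so
#' `sum_ij RLM(i,j) * j = 13 * |mask|` always.
#'
#' @param d A [discretize_voi()] result.
#' @return An object of class `run_length_matrix`: `counts` (N x M integer
#'   matrix, M = longest run observed), `n_runs`, `n_directions` (13),
#'   `n_voxels`.
#' @export
build_rlm <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  n <- d$n_levels
  lev <- d$levels
  dm <- dim(lev)
  nx <- dm[1L]; ny <- dm[2L]; nz <- dm[3L]
  co <- which(array(TRUE, dm), arr.ind = TRUE)   # all voxels of the crop
  x <- co[, 1L]; y <- co[, 2L]; z <- co[, 3L]
  v <- as.vector(lev)
  runs_i <- integer(0)
  runs_j <- integer(0)
  dirs <- directions13()
  for (k in seq_len(13L)) {
    dvec <- dirs[k, ]
    axis <- which(dvec == 1L)[1L]                # parameter along the line
    t <- co[, axis]
    a1 <- x - t * dvec[1L]; a2 <- y - t * dvec[2L]; a3 <- z - t * dvec[3L]
    s <- nx + ny + nz                            # anchors lie in [-s, s]
    key <- (a1 + s) + (2 * s + 1) *
      ((a2 + s) + (2 * s + 1) * (a3 + s))        # line anchor, collision-free
    ord <- order(key, t)
    kk <- key[ord]
    vv <- v[ord]
    m <- length(vv)
    new_run <- c(TRUE, kk[-1L] != kk[-m] | vv[-1L] != vv[-m])
    id <- cumsum(new_run)
    len <- tabulate(id)
    lvl <- vv[new_run]
    keep <- lvl > 0L
    runs_i <- c(runs_i, lvl[keep])
    runs_j <- c(runs_j, len[keep])
  }
  if (length(runs_i) == 0L) stop("empty mask", call. = FALSE)
  mmax <- max(runs_j)
  counts <- matrix(0L, n, mmax)
  t2 <- tabulate((runs_j - 1L) * n + runs_i, nbins = n * mmax)
  counts[] <- t2
  structure(list(counts = counts, n_runs = length(runs_i),
                 n_directions = 13L, n_voxels = d$n_voxels),
            class = "run_length_matrix")
}

#' Run-length features
#'
#' The eleven regional texture measures, with `n_r` the total number of
#' runs, i the gray level and j the run length:
#' SRE `(1/n_r) sum RLM/j^2`, LRE `(1/n_r) sum RLM j^2`,
#' LGRE `(1/n_r) sum RLM/i^2`, HGRE `(1/n_r) sum RLM i^2`,
#' SRLGE `(1/n_r) sum RLM/(i^2 j^2)`, SRHGE `(1/n_r) sum RLM i^2/j^2`,
#' LRLGE `(1/n_r) sum RLM j^2/i^2`, LRHGE `(1/n_r) sum RLM i^2 j^2`,
#' GLNU `(1/n_r) sum_i (sum_j RLM)^2`, RLNU `(1/n_r) sum_j (sum_i RLM)^2`,
#' RPC `n_r / sum RLM j` (the denominator equals 13 x voxel count).
#'
#' @param r A `run_length_matrix`.
#' @return Named numeric vector of the eleven features.
#' @export
rlm_features <- function(r) {
  stopifnot(inherits(r, "run_length_matrix"))
  cnt <- r$counts
  nr <- r$n_runs
  if (nr <= 0L) stop("empty run-length matrix", call. = FALSE)
  i <- row(cnt); j <- col(cnt)
  c(SRE   = sum(cnt / j^2) / nr,
    LRE   = sum(cnt * j^2) / nr,
    LGRE  = sum(cnt / i^2) / nr,
    HGRE  = sum(cnt * i^2) / nr,
    SRLGE = sum(cnt / (i^2 * j^2)) / nr,
    SRHGE = sum(cnt * i^2 / j^2) / nr,
    LRLGE = sum(cnt * j^2 / i^2) / nr,
    LRHGE = sum(cnt * i^2 * j^2) / nr,
    GLNU  = sum(rowSums(cnt)^2) / nr,
    RLNU  = sum(colSums(cnt)^2) / nr,
    RPC   = nr / sum(cnt * j))
}

#' Gradient energies
#'
#' Gradient-based heterogeneity measures evaluated on the raw
#' (undiscretized) SUV field u restricted to the VOI:
#' specific energy `SE = sqrt(int |grad u|^2 dV) / sqrt(int |u|^2 dV)`
#' (intensive: SUV variation per unit volume and unit SUV) and total
#' energy `TE = sqrt(int |grad u|^2 dV) / SUVmax` (extensive: grows with
#' the domain). The gradient is computed per masked voxel by central
#' differences in physical units (mm), falling back to a one-sided
#' difference where one axis neighbour leaves the mask; an axis
#' contributes 0 where both neighbours are outside. Integrals are voxel
#' sums times the voxel volume (mm^3).
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask`.
#' @return Named numeric vector `c(SE, TE)`.
#' @export
energy_features <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "tumor_mask"))
  if (!any(mask$mask)) stop("empty mask", call. = FALSE)
  cr <- crop_to_mask(volume$suv, mask$mask)
  u <- cr$arr
  m <- cr$mask
  dm <- dim(u)
  grad2 <- array(0, dim = dm)
  for (axis in 1:3) {
    h <- volume$spacing[axis]
    dvec <- c(0L, 0L, 0L); dvec[axis] <- 1L
    up <- shift_arr(u, dvec); mp <- shift_arr(m, dvec, fill = FALSE)
    un <- shift_arr(u, -dvec); mn <- shift_arr(m, -dvec, fill = FALSE)
    g <- array(0, dim = dm)
    both <- mp & mn
    g[both] <- (up[both] - un[both]) / (2 * h)
    ponly <- mp & !mn
    g[ponly] <- (up[ponly] - u[ponly]) / h
    nonly <- mn & !mp
    g[nonly] <- (u[nonly] - un[nonly]) / h
    grad2 <- grad2 + g^2
  }
  dv <- prod(volume$spacing)
  num <- sqrt(sum(grad2[m]) * dv)
  umax <- max(u[m])
  if (umax <= 0) stop("SUVmax is zero: energies undefined", call. = FALSE)
  c(SE = num / sqrt(sum(u[m]^2) * dv), TE = num / umax)
}

# Shift an array by +dvec, padding with `fill`. shift_arr(u, c(1,0,0))[x]
# holds u[x+1].
shift_arr <- function(a, dvec, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dim = dm)
  if (any(abs(dvec) >= dm)) return(out)
  sx <- max(1L, 1L - dvec[1L]):min(dm[1L], dm[1L] - dvec[1L])
  sy <- max(1L, 1L - dvec[2L]):min(dm[2L], dm[2L] - dvec[2L])
  sz <- max(1L, 1L - dvec[3L]):min(dm[3L], dm[3L] - dvec[3L])
  out[sx, sy, sz] <- a[sx + dvec[1L], sy + dvec[2L], sz + dvec[3L],
                       drop = FALSE]
  out
}

#' Extract all features for one scan
#'
#' Runs the full per-scan pipeline on a segmented VOI: the five SUV/volume
#' metrics, then 16-level discretization feeding the CM and RLM feature
#' families, and the gradient energies on the raw SUV field. Deterministic:
#' identical inputs give identical outputs.
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask` (e.g. from [segment_lesion()]).
#' @param n_levels Gray classes for discretization, default 16.
#' @param peak_masked_only Passed to [suv_peak()].
#' @return Named numeric vector of the 23 [feature_columns()].
#' @export
extract_features <- function(volume, mask, n_levels = 16,
                             peak_masked_only = FALSE) {
  met <- metabolic_metrics(volume, mask, peak_masked_only = peak_masked_only)
  d <- discretize_voi(volume, mask, n_levels = n_levels)
  out <- c(met,
           cm_features(build_cm(d)),
           rlm_features(build_rlm(d)),
           energy_features(volume, mask))
  out[feature_columns()]
}

#' Segment a lesion inside a manual box
#'
#' Convenience wrapper for the delineation chain: fixed-fraction threshold
#' ([threshold_voi()]), necrosis accounting ([exclude_necrotic_core()]),
#' and hottest-component selection ([pick_hottest_component()], optional).
#'
#' @param volume A [pet_volume()].
#' @param box A [bounding_box()].
#' @param fraction Threshold fraction, default 0.40.
#' @param hottest_only Keep only the hottest 26-connected component
#'   (default TRUE).
#' @return A `tumor_mask`.
#' @export
segment_lesion <- function(volume, box, fraction = 0.40, hottest_only = TRUE) {
  m <- threshold_voi(volume, box, fraction)
  m <- exclude_necrotic_core(m, volume)
  if (hottest_only) m <- pick_hottest_component(m, volume)
  m
}
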