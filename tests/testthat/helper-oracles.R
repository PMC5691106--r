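# Independent brute-force oracles: plain loops, no shared code with the
# package internals beyond exported constructors.

all_offsets26 <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

canonical_dirs13 <- local({
  keep <- apply(all_offsets26, 1L, function(v) {
    nz <- v[v != 0]
    nz[1L] > 0
  })
  all_offsets26[keep, , drop = FALSE]
})

in_bounds <- function(p, dm) all(p >= 1L) && all(p <= dm)

# Ordered-pair co-occurrence counts by triple loop over voxels and all 26
# offsets. `lev` is an integer array, 0 = outside mask.
oracle_cm_counts <- function(lev, n) {
  dm <- dim(lev)
  cm <- matrix(0, n, n)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    i <- lev[x, y, z]
    if (i == 0L) next
    for (o in seq_len(nrow(all_offsets26))) {
      q <- c(x, y, z) + all_offsets26[o, ]
      if (!in_bounds(q, dm)) next
      j <- lev[q[1], q[2], q[3]]
      if (j == 0L) next
      cm[i, j] <- cm[i, j] + 1
    }
  }
  cm
}

# Run-length counts by walking each of the 13 directions voxel by voxel.
oracle_rlm_counts <- function(lev, n) {
  dm <- dim(lev)
  runs <- list()
  for (k in seq_len(nrow(canonical_dirs13))) {
    d <- canonical_dirs13[k, ]
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      v <- lev[x, y, z]
      if (v == 0L) next
      prev <- c(x, y, z) - d
      if (in_bounds(prev, dm) && lev[prev[1], prev[2], prev[3]] == v)
        next                        # not the start of a run
      len <- 0L
      p <- c(x, y, z)
      while (in_bounds(p, dm) && lev[p[1], p[2], p[3]] == v) {
        len <- len + 1L
        p <- p + d
      }
      runs[[length(runs) + 1L]] <- c(as.integer(v), len)
    }
  }
  m <- max(vapply(runs, `[`, integer(1L), 2L))
  out <- matrix(0L, n, m)
  for (r in runs) out[r[1], r[2]] <- out[r[1], r[2]] + 1L
  out
}

# 26-connected components by breadth-first search.
oracle_label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dim = dm)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      pos <- arrayInd(v, dm)
      for (o in seq_len(nrow(all_offsets26))) {
        q <- pos + all_offsets26[o, ]
        if (!in_bounds(q, dm)) next
        li <- q[1] + dm[1] * (q[2] - 1L) + dm[1] * dm[2] * (q[3] - 1L)
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# Voxels of `cold` reachable from a box face through cold voxels
# (26-connectivity); the enclosed remainder is necrosis.
oracle_enclosed_count <- function(cold) {
  dm <- dim(cold)
  lab <- oracle_label_components(cold)
  open <- integer(0)
  for (v in which(cold)) {
    p <- arrayInd(v, dm)
    if (any(p == 1L) || any(p == dm)) open <- c(open, lab[v])
  }
  sum(cold & !(lab %in% unique(open)))
}

# SUVpeak by exhaustive sliding 3x3x3 cube over masked centres.
oracle_suv_peak <- function(u, mask) {
  dm <- dim(u)
  best <- -Inf
  for (v in which(mask)) {
    p <- arrayInd(v, dm)
    vals <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      q <- p + c(dx, dy, dz)
      if (in_bounds(q, dm)) vals <- c(vals, u[q[1], q[2], q[3]])
    }
    best <- max(best, mean(vals))
  }
  best
}

# Spearman r as Pearson on midranks, p from the t approximation.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  list(r = r, p = p)
}

# A pet_volume with unit metadata-free construction.
vol_of <- function(arr, spacing = c(1, 1, 1)) pet_volume(arr, spacing)

# A tumor_mask over a whole small volume without running segmentation
# (for metric/texture unit tests).
mask_of <- function(maskarr, box = NULL) {
  dm <- dim(maskarr)
  if (is.null(box)) box <- bounding_box(0, dm[1], 0, dm[2], 0, dm[3])
  m <- threshold_stub(maskarr, box)
  m
}

# Build a tumor_mask object directly; mirrors the exported structure.
threshold_stub <- function(maskarr, box) {
  structure(list(mask = maskarr, box = box, fraction = NA_real_,
                 threshold = NA_real_, necrotic_voxels = NA_integer_),
            class = "tumor_mask")
}

# Random small discretized VOI for oracle comparisons.
random_voi <- function(dm = c(5, 5, 5), n_levels = 4, p_mask = 0.7) {
  maskarr <- array(stats::runif(prod(dm)) < p_mask, dim = dm)
  if (!any(maskarr)) maskarr[1] <- TRUE
  u <- array(0, dim = dm)
  u[maskarr] <- stats::runif(sum(maskarr), 1, 10)
  list(u = u, mask = maskarr)
}
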