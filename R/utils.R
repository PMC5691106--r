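# Internal geometry and RNG helpers shared across modules.

# The 13 canonical 3D directions: every distance-1 neighbour offset up to
# sign, first nonzero component positive. Together with their opposites they
# enumerate the 26 neighbours of a voxel.
directions13 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    d <- as.matrix(d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ])
    keep <- apply(d, 1L, function(v) {
      nz <- v[v != 0]
      nz[1L] > 0
    })
    d <- d[keep, , drop = FALSE]
    dimnames(d) <- NULL
    stopifnot(nrow(d) == 13L)
    cache <<- d
    d
  }
})

# Linear-index pairs (src, dst) of voxels separated by offset d inside an
# array of dimension `dm`. Returns a 2-column integer matrix.
offset_pairs <- function(dm, d) {
  if (any(abs(d) >= dm))
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("src", "dst"))))
  xs <- max(1L, 1L - d[1L]):min(dm[1L], dm[1L] - d[1L])
  ys <- max(1L, 1L - d[2L]):min(dm[2L], dm[2L] - d[2L])
  zs <- max(1L, 1L - d[3L]):min(dm[3L], dm[3L] - d[3L])
  idx <- array(seq_len(prod(dm)), dim = dm)
  src <- as.vector(idx[xs, ys, zs])
  dst <- as.vector(idx[xs + d[1L], ys + d[2L], zs + d[3L]])
  cbind(src, dst)
}

# Label 26-connected components of a logical 3D array. Returns an integer
# array: 0 outside `mask`, component id (1..k) inside. Deterministic: ids
# are assigned in order of each component's lowest linear index.
label_components26 <- function(mask) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  n <- sum(mask)
  lab <- array(0L, dim = dm)
  if (n == 0L) return(lab)
  vox <- which(mask)                       # linear indices, ascending
  rank <- integer(prod(dm))
  rank[vox] <- seq_len(n)
  edges <- NULL
  for (k in seq_len(13L)) {
    p <- offset_pairs(dm, directions13()[k, ])
    keep <- mask[p[, 1L]] & mask[p[, 2L]]
    if (any(keep)) edges <- rbind(edges, p[keep, , drop = FALSE])
  }
  if (is.null(edges)) {
    lab[vox] <- seq_len(n)                 # all isolated voxels
    return(lab)
  }
  g <- igraph::graph_from_edgelist(
    cbind(rank[edges[, 1L]], rank[edges[, 2L]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber so component ids follow the lowest linear index they contain
  first <- vapply(split(seq_len(n), memb), min, integer(1L))
  ord <- order(first)
  remap <- integer(length(ord))
  remap[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[vox] <- remap[memb]
  lab
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
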