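# Independent oracles used to validate the compiled implementations.

# Brute-force BFS flood fill connected components. Returns a labeled array
# with components numbered by first-voxel scan order (z fastest, then y,
# then x), matching the implementation's deterministic order.
bfs_cc_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  nn <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[(connectivity == 26) | (connectivity == 18 & nn <= 2) |
                 (connectivity == 6 & nn <= 1), ]
  labels <- array(0L, dim = d)
  nxt <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (mask[z, y, x] == 0 || labels[z, y, x] != 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(z, y, x), ncol = 3)
    labels[z, y, x] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nz <- cur[1] + offs$dz[k]; ny <- cur[2] + offs$dy[k]
        nx <- cur[3] + offs$dx[k]
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] ||
            nx < 1 || nx > d[3]) next
        if (mask[nz, ny, nx] == 1 && labels[nz, ny, nx] == 0) {
          labels[nz, ny, nx] <- nxt
          queue <- rbind(queue, c(nz, ny, nx))
        }
      }
    }
  }
  labels
}

# From-scratch Benjamini-Hochberg: sort, multiply by m/rank, enforce
# monotonicity from the largest p downwards.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# walk parent links to find the ancestor at a level (independent of the
# package's implementation)
ancestor_oracle <- function(ont, id, level) {
  nodes <- ont$nodes
  cur <- id
  repeat {
    row <- match(cur, nodes$id)
    if (nodes$level[row] <= level) return(cur)
    cur <- nodes$parent_id[row]
  }
}

# tiny shared fixtures (memoized; cheap enough to build once per run)
.fix <- new.env()

tiny_atlas <- function() {
  if (is.null(.fix$atlas))
    .fix$atlas <- generate_toy_atlas(c(16, 16, 16), levels = 3,
                                     regions_per_split = 2, seed = 7,
                                     spacing_um = 40)
  .fix$atlas
}

tiny_scene <- function() {
  if (is.null(.fix$scene))
    .fix$scene <- generate_scene(tiny_atlas(), upscale = 4,
                                 cells_per_mm3 = 800,
                                 cell_radius_um = c(20, 4), snr = 6,
                                 seed = 11)
  .fix$scene
}
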