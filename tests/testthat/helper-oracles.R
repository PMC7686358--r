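# Naive enumeration oracles, written as plain triple loops, independent of
# the package's counting kernels. Levels use 0 for out-of-mask voxels.

all_offsets13 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- apply(g, 1, function(o) {
    o[3] > 0 || (o[3] == 0 && o[2] > 0) || (o[3] == 0 && o[2] == 0 && o[1] > 0)
  })
  g[keep, , drop = FALSE]
}

inside <- function(v, d) all(v >= 1) && all(v <= d)

oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  m <- matrix(0, ng, ng)
  offs <- all_offsets13()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    a <- lev[z, y, x]
    if (a == 0) next
    for (r in seq_len(nrow(offs))) {
      w <- c(z, y, x) + offs[r, ]
      if (!inside(w, d)) next
      b <- lev[w[1], w[2], w[3]]
      if (b == 0) next
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  m
}

oracle_glrlm <- function(lev, ng, directions = all_offsets13()) {
  d <- dim(lev)
  m <- matrix(0, ng, max(d))
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    seen <- array(FALSE, d)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      v <- c(z, y, x)
      g <- lev[z, y, x]
      if (g == 0 || seen[z, y, x]) next
      # walk back to the start of this run
      while (TRUE) {
        u <- v - o
        if (!inside(u, d) || lev[u[1], u[2], u[3]] != g) break
        v <- u
      }
      if (seen[v[1], v[2], v[3]]) next
      len <- 0
      w <- v
      while (inside(w, d) && lev[w[1], w[2], w[3]] == g) {
        seen[w[1], w[2], w[3]] <- TRUE
        len <- len + 1
        w <- w + o
      }
      m[g, len] <- m[g, len] + 1
      # un-mark so other directions rescan: use fresh `seen` per direction
    }
    seen[] <- FALSE
  }
  m
}

# BFS flood fill over 26-connected equal-level components
oracle_zones <- function(lev) {
  d <- dim(lev)
  lab <- array(0L, d)
  zones <- list()
  nid <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  coords <- which(lev > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(coords))) {
    v <- coords[i, ]
    if (lab[v[1], v[2], v[3]] > 0) next
    nid <- nid + 1L
    g <- lev[v[1], v[2], v[3]]
    queue <- list(v)
    size <- 0L
    lab[v[1], v[2], v[3]] <- nid
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        w <- u + offs[r, ]
        if (!inside(w, d)) next
        if (lev[w[1], w[2], w[3]] == g && lab[w[1], w[2], w[3]] == 0) {
          lab[w[1], w[2], w[3]] <- nid
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[nid]] <- c(level = g, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(lev, ng) {
  zs <- oracle_zones(lev)
  m <- matrix(0, ng, max(zs[, "size"]))
  for (i in seq_len(nrow(zs))) {
    m[zs[i, "level"], zs[i, "size"]] <- m[zs[i, "level"], zs[i, "size"]] + 1
  }
  m
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng)
  n <- integer(ng)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    g <- lev[z, y, x]
    if (g == 0) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      w <- c(z + dz, y + dy, x + dx)
      if (!inside(w, d)) next
      h <- lev[w[1], w[2], w[3]]
      if (h > 0) nb <- c(nb, h)
    }
    if (length(nb) > 0) {
      s[g] <- s[g] + abs(g - mean(nb))
      n[g] <- n[g] + 1L
    }
  }
  list(s = s, n = n)
}

# AUC as the mean pairwise Mann-Whitney score over all (positive, negative)
# score pairs
oracle_auc <- function(probs, labels) {
  p <- probs[labels == 1]
  q <- probs[labels == 0]
  tot <- 0
  for (a in p) for (b in q) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(q))
}
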