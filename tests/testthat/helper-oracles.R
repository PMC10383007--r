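# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized implementations: plain loops and
# enumerations only.

# digital disc: all pixels with (x-cx)^2 + (y-cy)^2 <= r^2, as a label mask
# matrix [H, W] (0-based pixel convention)
oracle_disc_mask <- function(r, cx, cy, W, H, label = 1L) {
  L <- matrix(0L, H, W)
  for (yy in 0:(H - 1L)) for (xx in 0:(W - 1L)) {
    if ((xx - cx)^2 + (yy - cy)^2 <= r^2) L[yy + 1L, xx + 1L] <- label
  }
  L
}

oracle_disc_area <- function(r) {
  n <- 0L
  for (xx in (-ceiling(r)):ceiling(r)) for (yy in (-ceiling(r)):ceiling(r)) {
    if (xx^2 + yy^2 <= r^2) n <- n + 1L
  }
  n
}

# border-pixel count by direct 4-neighbour enumeration
oracle_perimeter <- function(L, label) {
  h <- nrow(L); w <- ncol(L)
  n <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (L[i, j] != label) next
    nb <- c(if (i > 1) L[i - 1, j] else -1L,
            if (i < h) L[i + 1, j] else -1L,
            if (j > 1) L[i, j - 1] else -1L,
            if (j < w) L[i, j + 1] else -1L)
    if (any(nb != label)) n <- n + 1L
  }
  n
}

oracle_area <- function(L, label) {
  n <- 0L
  for (v in L) if (v == label) n <- n + 1L
  n
}

# per-pixel nearest-centre labelling by direct loop (ties: lowest index)
oracle_nearest <- function(x, y, W, H) {
  out <- matrix(0L, H, W)
  for (yy in 0:(H - 1L)) for (xx in 0:(W - 1L)) {
    d2 <- (x - xx)^2 + (y - yy)^2
    out[yy + 1L, xx + 1L] <- which.min(d2)
  }
  out
}

# even-odd ray-casting point-in-polygon
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# classical balanced two-way ANOVA from cell means (equal n per cell)
oracle_balanced_anova <- function(df) {
  # df: group, ecc, value; balanced
  gm <- mean(df$value)
  groups <- unique(df$group); eccs <- unique(df$ecc)
  nrep <- nrow(df) / (length(groups) * length(eccs))
  ssa <- 0; ssb <- 0; ssab <- 0; sse <- 0
  mg <- sapply(groups, function(g) mean(df$value[df$group == g]))
  me <- sapply(eccs, function(e) mean(df$value[df$ecc == e]))
  for (g in seq_along(groups)) {
    ssa <- ssa + length(eccs) * nrep * (mg[g] - gm)^2
  }
  for (e in seq_along(eccs)) {
    ssb <- ssb + length(groups) * nrep * (me[e] - gm)^2
  }
  for (g in seq_along(groups)) for (e in seq_along(eccs)) {
    v <- df$value[df$group == groups[g] & df$ecc == eccs[e]]
    mc <- mean(v)
    ssab <- ssab + nrep * (mc - mg[g] - me[e] + gm)^2
    sse <- sse + sum((v - mc)^2)
  }
  list(group = as.numeric(ssa), eccentricity = as.numeric(ssb),
       interaction = as.numeric(ssab), error = as.numeric(sse),
       total = as.numeric(sum((df$value - gm)^2)))
}

# independent 4-connectivity check: is the set of pixels with this label
# one connected component?
oracle_connected4 <- function(L, label) {
  idx <- which(L == label)
  if (!length(idx)) return(FALSE)
  h <- nrow(L)
  seen <- rep(FALSE, length(idx))
  names(seen) <- idx
  stack <- idx[1]
  seen[1] <- TRUE
  set <- as.integer(idx)
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    r <- ((cur - 1) %% h) + 1
    nbrs <- c(if (r > 1) cur - 1L, if (r < h) cur + 1L, cur - h, cur + h)
    for (nb in nbrs) {
      pos <- match(nb, set)
      if (!is.na(pos) && !seen[pos]) {
        seen[pos] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  all(seen)
}

# grow a random 4-connected blob of n pixels (for shape-metric oracles)
oracle_random_blob <- function(n, W, H, seed) {
  set.seed(seed)
  L <- matrix(0L, H, W)
  cx <- sample(5:(W - 5), 1); cy <- sample(5:(H - 5), 1)
  cells <- matrix(c(cy, cx), 1)
  L[cy, cx] <- 1L
  while (nrow(cells) < n) {
    i <- sample(nrow(cells), 1)
    d <- sample(4, 1)
    ny <- cells[i, 1] + c(-1, 1, 0, 0)[d]
    nx <- cells[i, 2] + c(0, 0, -1, 1)[d]
    if (ny >= 1 && ny <= H && nx >= 1 && nx <= W && L[ny, nx] == 0L) {
      L[ny, nx] <- 1L
      cells <- rbind(cells, c(ny, nx))
    }
  }
  L
}

# small ROI helper used in several suites
tiny_roi <- function(w = 64, h = 64, upp = 0.5, ecc = 1) {
  roi_spec(w, h, eccentricity_deg = ecc, microns_per_pixel = upp)
}
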