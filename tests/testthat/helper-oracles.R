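# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and shares no code with the package internals it checks.

# Build a segmented-object structure from a logical mask.
obj_from <- function(mask, cell_id = "test") {
  ij <- which(mask, arr.ind = TRUE)
  list(label = 1L, coords = cbind(row = ij[, 1L], col = ij[, 2L]),
       dim = dim(mask), cell_id = cell_id)
}

rect_mask <- function(nr, nc, pad = 1L) {
  m <- matrix(FALSE, nr + 2L * pad, nc + 2L * pad)
  m[(pad + 1L):(pad + nr), (pad + 1L):(pad + nc)] <- TRUE
  m
}

# Random edge-connected polyomino of n pixels grown by rook-adjacent accretion.
random_polyomino <- function(n, size = 64L) {
  m <- matrix(FALSE, size, size)
  r <- size %/% 2L; c <- size %/% 2L
  m[r, c] <- TRUE
  cells <- matrix(c(r, c), ncol = 2L)
  while (nrow(cells) < n) {
    k <- sample.int(nrow(cells), 1L)
    d <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))[sample.int(4L, 1L), ]
    nr <- cells[k, 1L] + d[1L]; nc <- cells[k, 2L] + d[2L]
    if (nr < 2L || nc < 2L || nr > size - 1L || nc > size - 1L) next
    if (m[nr, nc]) next
    m[nr, nc] <- TRUE
    cells <- rbind(cells, c(nr, nc))
  }
  m
}

# Rotation-sweep oracle for the minimum projection width of a pixel set:
# projects all pixel corner points on a grid of directions.
min_width_sweep <- function(coords, step_deg = 0.25) {
  x <- coords[, 2L]; y <- coords[, 1L]
  px <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  w <- vapply(th, function(a) {
    p <- px * cos(a) + py * sin(a)
    max(p) - min(p)
  }, numeric(1L))
  min(w)
}

# Grow a random tree of pixels: each new pixel 8-touches exactly one
# existing pixel, so the 8-adjacency graph is a tree by construction.
random_tree_pixels <- function(n, size = 48L) {
  m <- matrix(FALSE, size, size)
  m[size %/% 2L, size %/% 2L] <- TRUE
  cells <- matrix(c(size %/% 2L, size %/% 2L), ncol = 2L)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), ]
  tries <- 0L
  while (nrow(cells) < n && tries < 50L * n) {
    tries <- tries + 1L
    k <- sample.int(nrow(cells), 1L)
    d <- offs[sample.int(8L, 1L), ]
    r <- cells[k, 1L] + d[1L]; c <- cells[k, 2L] + d[2L]
    if (r < 2L || c < 2L || r > size - 1L || c > size - 1L) next
    if (m[r, c]) next
    # count existing 8-neighbours of the candidate
    nb <- sum(m[(r - 1L):(r + 1L), (c - 1L):(c + 1L)])
    if (nb != 1L) next
    m[r, c] <- TRUE
    cells <- rbind(cells, c(r, c))
  }
  m
}

# Floyd-Warshall longest-shortest-path oracle on the 8-adjacency graph of a
# pixel set (weights 1 axial, sqrt(2) diagonal), replicating the endpoint
# rule: maximum over degree-1 vertex pairs, else over all pairs.
floyd_longest_path <- function(mask, pixel_size = 1) {
  ij <- which(mask, arr.ind = TRUE)
  n <- nrow(ij)
  if (n <= 1L) return(0)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dr <- abs(ij[i, 1L] - ij[j, 1L]); dc <- abs(ij[i, 2L] - ij[j, 2L])
    if (dr <= 1L && dc <= 1L) {
      w <- if (dr + dc == 1L) 1 else sqrt(2)
      D[i, j] <- w; D[j, i] <- w
    }
  }
  deg <- rowSums(is.finite(D) & D > 0)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  ep <- which(deg == 1L)
  pool <- if (length(ep) >= 2L) D[ep, ep] else D
  pool[!is.finite(pool)] <- 0
  max(pool) * pixel_size
}

# Explicit-loop Yen criterion maximization over every histogram cut.
yen_oracle <- function(px, n_bins = 256L) {
  rng <- range(px)
  u <- (px - rng[1L]) / (rng[2L] - rng[1L])
  counts <- tabulate(pmin(floor(u * n_bins) + 1L, n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(n_bins - 1L)) {
    p1 <- sum(p[1:t]); s1 <- sum(p[1:t]^2); s2 <- sum(p[(t + 1L):n_bins]^2)
    if (p1 <= 0 || p1 >= 1 || s1 <= 0 || s2 <= 0) next
    crit <- 2 * log(p1 * (1 - p1)) - log(s1 * s2)
    if (crit > best) { best <- crit; best_t <- t }
  }
  rng[1L] + (best_t - 0.5) / n_bins * (rng[2L] - rng[1L])
}

# Brute-force grayscale opening with a spherical-cap structuring function,
# double loop over pixels and offsets, replicate padding.
brute_open_ball <- function(m, radius_px, aspect) {
  r <- floor(radius_px)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius_px^2, ]
  offs$h <- aspect * (sqrt(radius_px^2 - offs$dy^2 - offs$dx^2) - radius_px)
  nr <- nrow(m); nc <- ncol(m)
  at <- function(i, j) m[min(max(i, 1L), nr), min(max(j, 1L), nc)]
  ero <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    ero[i, j] <- min(vapply(seq_len(nrow(offs)), function(k)
      at(i + offs$dy[k], j + offs$dx[k]) - offs$h[k], numeric(1L)))
  ate <- function(i, j) ero[min(max(i, 1L), nr), min(max(j, 1L), nc)]
  opn <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    opn[i, j] <- max(vapply(seq_len(nrow(offs)), function(k)
      ate(i + offs$dy[k], j + offs$dx[k]) + offs$h[k], numeric(1L)))
  opn
}

# Minimal ImageJ .roi writer (big-endian), enough for parser round-trips.
write_ij_roi <- function(path, type, top, left, bottom, right,
                         x = NULL, y = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(c(228L), con, size = 2L, endian = "big")          # version
  writeBin(as.raw(c(type, 0L)), con)                          # type byte + pad
  writeBin(as.integer(c(top, left, bottom, right)), con, size = 2L,
           endian = "big")
  n <- length(x)
  writeBin(n, con, size = 2L, endian = "big")
  writeBin(raw(64L - 18L), con)                               # pad to byte 64
  if (n > 0L) {
    writeBin(as.integer(x - left), con, size = 2L, endian = "big")
    writeBin(as.integer(y - top), con, size = 2L, endian = "big")
  }
  invisible(path)
}

default_rules <- classification_rules()

# Feature row builder with sensible fillers for classifier tests.
feat_row <- function(C = 0.5, AR = 3, S = 0.8, E = 1, r_eq = 0.5,
                     MLE = 2 * r_eq, A = pi * r_eq^2) {
  data.frame(A = A, C = C, AR = AR, S = S, E = E, r_eq = r_eq, MLE = MLE)
}

small_scene_spec <- function(seed = 3L, ...) {
  scene_spec(shape = c(384L, 384L),
             counts = c(filament = 1L, rod = 3L, punctum = 3L, swollen = 2L),
             seed = seed, ...)
}
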