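# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive n child seeds (< 2^31) from one parent seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary <- function(x) all(x == 0 | x == 1)

# ---- separable resampling -------------------------------------------------

# Linear interpolation weight matrix mapping n_in samples to n_out samples.
# Endpoints map to endpoints ("align corners"), so a ramp keeps its range.
interp_matrix <- function(n_in, n_out, method = c("linear", "nearest")) {
  method <- match.arg(method)
  W <- matrix(0, n_out, n_in)
  pos <- if (n_out == 1L) (n_in - 1) / 2 else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos) + 1, 1), n_in)
    W[cbind(seq_len(n_out), idx)] <- 1
  } else {
    lo <- pmin(floor(pos), n_in - 1)
    frac <- pos - lo
    W[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    W[cbind(seq_len(n_out), pmin(lo + 2, n_in))] <-
      W[cbind(seq_len(n_out), pmin(lo + 2, n_in))] + frac
    if (n_out == 1L) W[1, ] <- W[1, ] / sum(W[1, ])
  }
  W
}

# Apply a weight matrix along one axis of a 3D array.
apply_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- W %*% matrix(a, nrow = d[axis])
  out <- array(m, c(nrow(W), d[perm][2:3]))
  aperm(out, order(perm))
}

# Resize a 3D array to `target` dims, trilinear or nearest-neighbour.
resize_array <- function(arr, target, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  stopifnot(length(d) == 3, length(target) == 3)
  for (ax in 1:3) {
    if (d[ax] != target[ax]) {
      arr <- apply_axis(arr, interp_matrix(dim(arr)[ax], target[ax], method), ax)
    }
  }
  arr
}

# ---- Gaussian blur --------------------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolution weight matrix with reflected edges for one axis.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    # reflect out-of-range indices back into 1..n
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + kernel[j]
  }
  W
}

# Separable Gaussian blur of a 3D array; sigma_vox is per-axis (z, y, x), in
# voxel units. A zero entry skips that axis.
gauss_blur <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0 && dim(arr)[ax] > 1) {
      k <- gaussian_kernel_1d(sigma_vox[ax])
      if (length(k) > 1) arr <- apply_axis(arr, conv_matrix(dim(arr)[ax], k), ax)
    }
  }
  arr
}

# ---- Euclidean distance transform ----------------------------------------

# 1D squared distance transform (lower envelope of parabolas), sample step h.
dt1d <- function(f, h = 1) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (!length(idx)) return(rep(Inf, n))
  if (length(idx) == n && all(f == 0)) return(f)  # fast path: all sites
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- idx[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(idx) > 1L) {
    for (q in idx[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + (q * h)^2) - (f[p] + (p * h)^2)) / (2 * h * (q - p))
        if (k > 1L && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q * h) k <- k + 1L
    d[q] <- (h * (q - v[k]))^2 + f[v[k]]
  }
  d
}

# Squared Euclidean distance from every voxel to the nearest TRUE voxel of a
# 3D logical array; spacing gives the physical step per axis (z, y, x).
edt_sq <- function(sites, spacing = c(1, 1, 1)) {
  d <- dim(sites)
  f <- array(ifelse(sites, 0, Inf), d)
  for (ax in 1:3) {
    if (d[ax] > 1) {
      perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
      a <- aperm(f, perm)
      m <- matrix(a, nrow = d[ax])
      m <- apply(m, 2, dt1d, h = spacing[ax])
      f <- aperm(array(m, dim(a)), order(perm))
    }
  }
  f
}

# ---- binary morphology (separable box structuring element) ---------------

# Running min/max along one axis with radius 1, edge-replicated.
shift_axis <- function(arr, axis, by, fill) {
  d <- dim(arr)
  idx <- seq_len(d[axis]) - by
  idx[idx < 1 | idx > d[axis]] <- NA
  out <- switch(axis, `1` = arr[idx, , , drop = FALSE],
                `2` = arr[, idx, , drop = FALSE],
                `3` = arr[, , idx, drop = FALSE])
  out[is.na(out)] <- fill
  out
}

erode_box <- function(mask, radius) {
  m <- mask
  for (i in seq_len(radius)) {
    for (ax in 1:3) {
      if (dim(m)[ax] > 1) {
        m <- m & shift_axis(m, ax, 1L, TRUE) & shift_axis(m, ax, -1L, TRUE)
      }
    }
  }
  m
}

dilate_box <- function(mask, radius) {
  m <- mask
  for (i in seq_len(radius)) {
    for (ax in 1:3) {
      if (dim(m)[ax] > 1) {
        m <- m | shift_axis(m, ax, 1L, FALSE) | shift_axis(m, ax, -1L, FALSE)
      }
    }
  }
  m
}

# ---- 3D connected components (6-connectivity) ----------------------------

label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  remaining <- which(mask)
  if (!length(remaining)) return(lab)
  n <- prod(d)
  current <- 0L
  # neighbour offsets in linear index space, validity checked via coordinates
  while (length(remaining)) {
    current <- current + 1L
    frontier <- remaining[1L]
    lab[frontier] <- current
    while (length(frontier)) {
      coords <- arrayInd(frontier, d)
      nb <- integer(0)
      for (ax in 1:3) {
        for (s in c(-1L, 1L)) {
          cc <- coords
          cc[, ax] <- cc[, ax] + s
          ok <- cc[, ax] >= 1L & cc[, ax] <= d[ax]
          if (any(ok)) {
            lin <- cc[ok, 1L] + (cc[ok, 2L] - 1L) * d[1L] + (cc[ok, 3L] - 1L) * d[1L] * d[2L]
            nb <- c(nb, lin)
          }
        }
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- current
      frontier <- nb
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

# ---- in-plane warping -----------------------------------------------------

# Sample every z-slice of a (z, y, x) array at input-plane coordinates
# (src_y, src_x) (matrices of dim (ny, nx), 1-based, possibly fractional).
# interp: "linear" (bilinear) or "nearest". Out-of-range samples get `fill`.
warp_inplane <- function(arr, src_y, src_x, interp = c("linear", "nearest"),
                         fill = 0) {
  interp <- match.arg(interp)
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  m <- matrix(aperm(arr, c(2, 3, 1)), nrow = ny * nx)  # (y*x, z)
  gather <- function(iy, ix) {
    ok <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
    lin <- (pmin(pmax(ix, 1), nx) - 1) * ny + pmin(pmax(iy, 1), ny)
    g <- m[lin, , drop = FALSE]
    g[!ok, ] <- fill
    g
  }
  if (interp == "nearest") {
    out <- gather(round(src_y), round(src_x))
  } else {
    y0 <- floor(src_y); x0 <- floor(src_x)
    wy <- as.vector(src_y - y0); wx <- as.vector(src_x - x0)
    out <- gather(y0, x0) * ((1 - wy) * (1 - wx)) +
      gather(y0 + 1, x0) * (wy * (1 - wx)) +
      gather(y0, x0 + 1) * ((1 - wy) * wx) +
      gather(y0 + 1, x0 + 1) * (wy * wx)
  }
  aperm(array(out, c(ny, nx, nz)), c(3, 1, 2))
}
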