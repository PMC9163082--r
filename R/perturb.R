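#' MRI noise specification
#'
#' Defines a noise-injection scenario at a target signal-to-noise ratio. SNR
#' is the mean foreground signal divided by the noise standard deviation (the
#' usual magnitude-MRI convention). The study scenarios are the three single
#' distributions at SNR 30 and the mixed scenario at SNR 20, where one of the
#' three distributions is drawn at random per image.
#'
#' @param distribution `"gaussian"`, `"rician"`, `"rayleigh"` or `"mixed"`.
#' @param snr Target signal-to-noise ratio (> 0); default 30 for single
#'   distributions, 20 for `"mixed"`.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(distribution = c("gaussian", "rician", "rayleigh", "mixed"),
                       snr = NULL, seed = 0L) {
  distribution <- match.arg(distribution)
  if (is.null(snr)) snr <- if (distribution == "mixed") 20 else 30
  if (snr <= 0) stopf("snr must be positive")
  structure(list(distribution = distribution, snr = snr, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add calibrated MRI noise to an image
#'
#' The noise sd is `sigma = mean(image[fg_mask]) / snr` (whole-image mean when
#' no mask is given). Models:
#' \itemize{
#'   \item gaussian: `I + N(0, sigma)`;
#'   \item rician: `sqrt((I + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` iid,
#'     the magnitude reconstruction of complex Gaussian channel noise;
#'   \item rayleigh: mean-centred additive Rayleigh noise,
#'     `I + (R - E[R])` with the Rayleigh scale chosen so `sd(R) = sigma`,
#'     keeping the mean intensity comparable across scenarios;
#'   \item mixed: one of the three, drawn uniformly per image.
#' }
#'
#' @param image 3D intensity array (non-negative for rician).
#' @param fg_mask Optional [mask_stack()] (or binary array) defining the
#'   signal region for the SNR calibration.
#' @param spec A [noise_spec()].
#' @param sigma Optional explicit noise sd, bypassing the SNR calibration
#'   (useful for validating the noise models directly, e.g. on a zero image).
#' @return Noisy image, same shape.
#' @export
add_noise <- function(image, fg_mask = NULL, spec = noise_spec(), sigma = NULL) {
  if (is.null(sigma)) {
    fg <- if (is.null(fg_mask)) NULL
          else if (inherits(fg_mask, "mask_stack")) fg_mask$voxels else fg_mask
    mu <- if (is.null(fg) || sum(fg) == 0) mean(image) else mean(image[fg == 1])
    sigma <- mu / spec$snr
    if (sigma <= 0) stopf("non-positive noise sd: mean signal is %.3g", mu)
  }
  if (sigma <= 0) stopf("noise sd must be positive")
  with_seed(spec$seed, {
    dist <- spec$distribution
    if (dist == "mixed") dist <- sample(c("gaussian", "rician", "rayleigh"), 1)
    n <- length(image)
    out <- switch(dist,
      gaussian = image + stats::rnorm(n, 0, sigma),
      rician = {
        if (any(image < 0)) stopf("rician noise requires non-negative intensities")
        sqrt((image + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
      },
      rayleigh = {
        scale <- sigma / sqrt(2 - pi / 2)  # sd(Rayleigh(s)) = s sqrt(2 - pi/2)
        r <- scale * sqrt(-2 * log(stats::runif(n)))
        image + (r - scale * sqrt(pi / 2))
      })
    array(out, dim(image))
  })
}

#' Augmentation specification
#'
#' Parameter ranges of the six-transform augmentation suite: elastic
#' deformation, in-plane shifts, rotation, scaling, Gaussian blurring and
#' gamma correction, plus the dataset inflation factor. Geometric transforms
#' are in-plane (x, y) and are applied identically to image (trilinear) and
#' mask (nearest-neighbour, re-binarised); blur and gamma touch the image
#' only.
#'
#' @param rotation_deg Rotation range, degrees.
#' @param shift_frac In-plane shift range as a fraction of the extent.
#' @param scale Scaling range about 1 (contraction / expansion).
#' @param blur_sigma Gaussian blur sigma range, voxels.
#' @param gamma_mean,gamma_sd Gamma correction factor `~ N(mean, sd)`.
#' @param elastic_amplitude_vox,elastic_smooth_vox Elastic displacement
#'   amplitude and smoothing, voxels.
#' @param inflation_factor Dataset inflation factor (default 10).
#' @param seed Integer seed.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_deg = c(-20, 20),
                              shift_frac = c(-0.1, 0.1),
                              scale = c(0.9, 1.1),
                              blur_sigma = c(0.5, 1.5),
                              gamma_mean = 1, gamma_sd = 0.1,
                              elastic_amplitude_vox = 8,
                              elastic_smooth_vox = 4,
                              inflation_factor = 10L, seed = 0L) {
  if (inflation_factor < 1) stopf("inflation_factor must be >= 1")
  if (any(blur_sigma <= 0)) stopf("blur_sigma range must be positive")
  structure(list(rotation_deg = rotation_deg, shift_frac = shift_frac,
                 scale = scale, blur_sigma = blur_sigma,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 elastic_amplitude_vox = elastic_amplitude_vox,
                 elastic_smooth_vox = elastic_smooth_vox,
                 inflation_factor = as.integer(inflation_factor),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

# In-plane source coordinates for an affine (scale about centre, rotate,
# shift) of a (ny, nx) grid; returns matrices of source y and x.
affine_coords <- function(ny, nx, rot_deg = 0, shift_y = 0, shift_x = 0, scale = 1) {
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  th <- rot_deg * pi / 180
  # inverse map: undo shift, then rotate by -theta, then unscale
  yy <- g$y - cy - shift_y; xx <- g$x - cx - shift_x
  ys <- (cos(th) * yy + sin(th) * xx) / scale + cy
  xs <- (-sin(th) * yy + cos(th) * xx) / scale + cx
  list(y = matrix(ys, ny, nx), x = matrix(xs, ny, nx))
}

# Draw one transform set from the spec (which transforms fire + parameters).
draw_augmentation <- function(spec, shape) {
  repeat {
    use <- stats::runif(6) < 0.5
    if (any(use)) break
  }
  names(use) <- c("elastic", "shift", "rotation", "scaling", "blur", "gamma")
  ny <- shape[2]; nx <- shape[3]
  par <- list(
    use = use,
    rot = stats::runif(1, spec$rotation_deg[1], spec$rotation_deg[2]),
    shift_y = stats::runif(1, spec$shift_frac[1], spec$shift_frac[2]) * ny,
    shift_x = stats::runif(1, spec$shift_frac[1], spec$shift_frac[2]) * nx,
    scale = stats::runif(1, spec$scale[1], spec$scale[2]),
    blur = stats::runif(1, spec$blur_sigma[1], spec$blur_sigma[2]),
    gamma = stats::rnorm(1, spec$gamma_mean, spec$gamma_sd))
  if (use["elastic"]) {
    dy <- gauss_blur(array(stats::rnorm(ny * nx), c(1, ny, nx)),
                     c(0, spec$elastic_smooth_vox, spec$elastic_smooth_vox))
    dx <- gauss_blur(array(stats::rnorm(ny * nx), c(1, ny, nx)),
                     c(0, spec$elastic_smooth_vox, spec$elastic_smooth_vox))
    norm <- max(max(abs(dy)), max(abs(dx)), 1e-12)
    par$elastic_dy <- matrix(dy[1, , ] / norm * spec$elastic_amplitude_vox, ny, nx)
    par$elastic_dx <- matrix(dx[1, , ] / norm * spec$elastic_amplitude_vox, ny, nx)
  }
  par
}

apply_augmentation <- function(image, mask_vox, par) {
  shape <- dim(image)
  ny <- shape[2]; nx <- shape[3]
  use <- par$use
  geom <- use["shift"] || use["rotation"] || use["scaling"] || use["elastic"]
  if (geom) {
    co <- affine_coords(ny, nx,
                        rot_deg = if (use["rotation"]) par$rot else 0,
                        shift_y = if (use["shift"]) par$shift_y else 0,
                        shift_x = if (use["shift"]) par$shift_x else 0,
                        scale = if (use["scaling"]) par$scale else 1)
    if (use["elastic"]) {
      co$y <- co$y + par$elastic_dy
      co$x <- co$x + par$elastic_dx
    }
    image <- warp_inplane(image, co$y, co$x, "linear", fill = 0)
    if (!is.null(mask_vox)) {
      mask_vox <- warp_inplane(mask_vox, co$y, co$x, "nearest", fill = 0)
      mask_vox <- array(as.integer(mask_vox > 0.5), shape)
    }
  }
  if (use["blur"]) image <- gauss_blur(image, c(0, par$blur, par$blur))
  if (use["gamma"]) {
    rng <- range(image)
    if (rng[2] > rng[1]) {
      norm <- (image - rng[1]) / (rng[2] - rng[1])
      image <- rng[1] + (rng[2] - rng[1]) * norm^par$gamma
    }
  }
  list(image = image, mask = mask_vox)
}

#' Augment one image/mask pair
#'
#' Samples a non-empty random subset of the six augmentation transforms and
#' applies it: geometric transforms identically to image and mask, blur and
#' gamma to the image only. Gamma correction is applied on the `[0, 1]`
#' normalised intensities and mapped back to the original range.
#'
#' @param image 3D intensity array (z, y, x).
#' @param mask A [mask_stack()] (or binary 3D array), or NULL.
#' @param spec An [augmentation_spec()].
#' @param seed Seed for this draw (defaults to `spec$seed`).
#' @return List with `image` and `mask` (same types as the inputs).
#' @export
augment_one <- function(image, mask = NULL, spec = augmentation_spec(),
                        seed = spec$seed) {
  mv <- if (inherits(mask, "mask_stack")) mask$voxels else mask
  if (!is.null(mv) && !identical(dim(image), dim(mv)))
    stopf("image and mask must share one shape")
  out <- with_seed(seed, {
    par <- draw_augmentation(spec, dim(image))
    apply_augmentation(image, mv, par)
  })
  if (inherits(mask, "mask_stack") && !is.null(out$mask))
    out$mask <- mask_stack(out$mask, mask$spacing_mm, mask$label)
  out
}

#' Inflate a dataset by seeded augmentation
#'
#' Returns `inflation_factor` times the input: the originals plus
#' `inflation_factor - 1` independent augmentations of each pair,
#' deterministically derived from the spec seed.
#'
#' @param pairs Non-empty list of `list(image =, mask =)` pairs.
#' @param spec An [augmentation_spec()].
#' @return List of `inflation_factor * length(pairs)` pairs.
#' @export
inflate_dataset <- function(pairs, spec = augmentation_spec()) {
  if (!length(pairs)) stopf("empty input")
  k <- spec$inflation_factor
  if (k == 1L) return(pairs)
  seeds <- derive_seeds(spec$seed, (k - 1L) * length(pairs))
  out <- vector("list", k * length(pairs))
  j <- 0L
  for (i in seq_along(pairs)) {
    j <- j + 1L
    out[[j]] <- pairs[[i]]
    for (r in seq_len(k - 1L)) {
      j <- j + 1L
      s <- seeds[(i - 1L) * (k - 1L) + r]
      out[[j]] <- augment_one(pairs[[i]]$image, pairs[[i]]$mask, spec, seed = s)
    }
  }
  out
}
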