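#' Loss configuration
#'
#' Constants of the Dice-family training objectives: the smoothing term
#' epsilon of the soft Dice loss, and the border-map constants w0 and sigma.
#'
#' @param epsilon Smoothing constant added to numerators and denominators
#'   (default 1).
#' @param w0 Border emphasis amplitude (default 2).
#' @param sigma Border emphasis decay, in voxels (default 1).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(epsilon = 1, w0 = 2, sigma = 1) {
  if (epsilon <= 0) stopf("epsilon must be positive")
  if (sigma <= 0) stopf("sigma must be positive")
  structure(list(epsilon = epsilon, w0 = w0, sigma = sigma),
            class = "loss_config")
}

check_loss_inputs <- function(t, p) {
  if (!identical(dim(t) %||% length(t), dim(p) %||% length(p)))
    stopf("target and prediction must share one shape")
  if (!is_binary(t)) stopf("target must be binary")
  if (any(p < 0 | p > 1)) stopf("predictions must lie in [0, 1]")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft Dice loss
#'
#' Two-sided soft Dice objective over foreground and background:
#' \deqn{1 - \frac{\sum t_i p_i + \epsilon}{\sum (t_i + p_i) + \epsilon}
#'         - \frac{\sum (1-t_i)(1-p_i) + \epsilon}{\sum (2 - t_i - p_i) + \epsilon}}
#' Perfect prediction gives a loss near 0 from below; on small arrays the
#' epsilon smoothing makes the minimum slightly negative (e.g. -1/9 for a
#' perfect 8-voxel half-foreground fixture).
#'
#' @param t Binary target array (any shape).
#' @param p Predicted probabilities in `[0, 1]`, same shape.
#' @param cfg A [loss_config()].
#' @param weights Optional per-voxel non-negative weights applied to every
#'   term inside the four sums (used by [weighted_soft_dice_loss()]).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(t, p, cfg = loss_config(), weights = NULL) {
  check_loss_inputs(t, p)
  w <- if (is.null(weights)) 1 else weights
  e <- cfg$epsilon
  1 - (sum(w * t * p) + e) / (sum(w * (t + p)) + e) -
    (sum(w * (1 - t) * (1 - p)) + e) / (sum(w * (2 - t - p)) + e)
}

#' Border-emphasising weight map
#'
#' Per-voxel weights `w_c + w0 * exp(-(d1 + d2)^2 / (2 sigma^2))` in the
#' construction of Ronneberger et al.: `w_c` balances class frequencies
#' (each class weighted by its inverse frequency, normalised so the mean
#' weight is 1), and the border term emphasises background voxels close to
#' foreground-component borders. `d1` is the Euclidean distance (voxels) from
#' a background voxel to the border of the nearest foreground component and
#' `d2` to the border of the second-nearest component; with a single
#' component (the usual LV case) `d2 = d1`. A background voxel touching a
#' component is on its border (`d = 0`). The border term is 0 on foreground
#' voxels.
#'
#' @param t Binary target 3D array.
#' @param cfg A [loss_config()] (uses `w0`, `sigma`).
#' @return An object of class `weight_map`: list with `weights`
#'   (= `w_c + border`), `w_c` and `border` arrays.
#' @export
weight_map <- function(t, cfg = loss_config()) {
  if (length(dim(t)) != 3) stopf("target must be a 3D array")
  if (!is_binary(t)) stopf("target must be binary")
  n <- length(t)
  n1 <- sum(t)
  if (n1 == 0 || n1 == n) {
    warnf("single-class target: returning uniform weights")
    one <- array(1, dim(t))
    return(structure(list(weights = one, w_c = one, border = array(0, dim(t))),
                     class = "weight_map"))
  }
  # inverse class frequency, normalised to mean 1 over the array
  wc_fg <- n / (2 * n1); wc_bg <- n / (2 * (n - n1))
  w_c <- array(ifelse(t == 1, wc_fg, wc_bg), dim(t))
  lab <- label_components(t == 1)
  ncomp <- max(lab)
  dists <- lapply(seq_len(ncomp), function(k) {
    pmax(sqrt(edt_sq(lab == k)) - 1, 0)  # border sits at adjacent bg voxels
  })
  if (ncomp == 1) {
    d1 <- dists[[1]]; d2 <- d1
  } else {
    ds <- array(unlist(dists), c(dim(t), ncomp))
    srt <- apply(ds, 1:3, function(v) sort(v)[1:2])
    d1 <- array(srt[1, , , ], dim(t)); d2 <- array(srt[2, , , ], dim(t))
  }
  border <- cfg$w0 * exp(-(d1 + d2)^2 / (2 * cfg$sigma^2))
  border[t == 1] <- 0
  structure(list(weights = w_c + border, w_c = w_c, border = border),
            class = "weight_map")
}

#' Weighted soft Dice loss
#'
#' Soft Dice loss with every voxel's contribution to the four sums scaled by
#' the border-emphasising [weight_map()], penalising misclassification at the
#' borders of the region of interest. With unit weights it reduces exactly to
#' [soft_dice_loss()].
#'
#' @inheritParams soft_dice_loss
#' @param weights Per-voxel weights; by default computed as
#'   `weight_map(t, cfg)$weights`.
#' @return Scalar loss.
#' @export
weighted_soft_dice_loss <- function(t, p, cfg = loss_config(), weights = NULL) {
  if (is.null(weights)) weights <- weight_map(t, cfg)$weights
  if (any(weights < 0)) stopf("weights must be non-negative")
  soft_dice_loss(t, p, cfg, weights = weights)
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-[t log(p) + (1-t) log(1-p)]`, with predictions
#' clipped to `[clip, 1-clip]` so the loss stays finite.
#'
#' @inheritParams soft_dice_loss
#' @param clip Clipping bound (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(t, p, clip = 1e-7) {
  check_loss_inputs(t, p)
  ph <- pmin(pmax(p, clip), 1 - clip)
  -mean(t * log(ph) + (1 - t) * log(1 - ph))
}

#' Hybrid loss
#'
#' Binary cross-entropy plus the (unit-weight) soft Dice loss.
#'
#' @inheritParams soft_dice_loss
#' @param clip Clipping bound for the cross-entropy term.
#' @return Scalar loss.
#' @export
hybrid_loss <- function(t, p, cfg = loss_config(), clip = 1e-7) {
  bce_loss(t, p, clip) + soft_dice_loss(t, p, cfg)
}
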