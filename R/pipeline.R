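#' Segmentation backends
#'
#' The pipeline treats segmentation as a plug-in: a backend is any function
#' `f(image, info)` returning a 3D probability map for one phase, where
#' `image` is the intensity array and `info` is a list with `label` (series
#' label), `phase_index` and `spacing_mm`.
#'
#' `oracle_backend(series_list)` returns the ground-truth mask of the matching
#' series/phase -- the upper bound of what any backend can achieve, used to
#' validate the pipeline itself.
#'
#' `threshold_backend` is a bundled reference backend: it separates tissue
#' from background with an Otsu threshold, then separates the bright cavity
#' from the myocardium with a second Otsu pass restricted to tissue voxels.
#'
#' @param series_list List of [cine_series()] (with masks) the oracle can
#'   answer for.
#' @return `oracle_backend`: a backend function. `threshold_backend` is
#'   itself a backend function.
#' @export
oracle_backend <- function(series_list) {
  truth <- new.env(parent = emptyenv())
  for (s in series_list) {
    for (p in s$phases) {
      if (!is.null(p$mask))
        assign(paste(s$label, p$phase_index), p$mask$voxels, envir = truth)
    }
  }
  function(image, info) {
    key <- paste(info$label, info$phase_index)
    if (!exists(key, envir = truth)) stopf("oracle has no mask for %s", key)
    get(key, envir = truth) * 1.0
  }
}

#' @rdname oracle_backend
#' @param image 3D intensity array.
#' @param info Phase info list (see above).
#' @export
threshold_backend <- function(image, info) {
  rng <- range(image)
  if (rng[1] == rng[2]) return(array(0, dim(image)))
  v <- (image - rng[1]) / (rng[2] - rng[1])
  t1 <- EBImage::otsu(matrix(v, nrow = dim(image)[2]), range = c(0, 1))
  tissue <- v[v > t1]
  t2 <- if (length(unique(tissue)) < 2) t1
        else EBImage::otsu(matrix(tissue, nrow = 1), range = c(0, 1))
  array(as.numeric(v > t2), dim(image))
}

#' Benchmark phase-selection metrics and fitting methods
#'
#' Runs the full automated-EF pipeline over a set of reference series for
#' every combination of cycle metric and fitting method, and scores each
#' combination against the reference EF values: mean absolute difference
#' (MD +/- sd), Bland-Altman bias and limits, and the fraction of series
#' whose systole and diastole phases were both selected correctly. By default
#' the reference set is synthetic (known truth), spanning 11-13 phases and
#' EF drawn uniformly from the study range 41-67%, alternating cosine and
#' skewed cycle shapes.
#'
#' @param n_series Number of synthetic series (ignored when `series_list`
#'   is supplied).
#' @param metrics,methods Combinations to benchmark.
#' @param ef_range EF sampling range, percent.
#' @param n_phases_choices Phase counts to sample from.
#' @param shape,edv_ul Passed to [synthetic_cine_spec()].
#' @param seed Master seed; every per-series spec and fit derives from it.
#' @param series_list Optional list of [cine_series()] to use instead of
#'   synthetic data; requires `reference`.
#' @param reference Optional data.frame with columns `label`, `ef_pct`,
#'   `diastole_phase`, `systole_phase` giving the reference values.
#' @return An object of class `benchmark_result`: list with `table` (one row
#'   per metric x method) and `per_series` (one row per series x metric x
#'   method). Series failing phase selection are excluded and counted in
#'   `n_failed`.
#' @export
run_benchmark <- function(n_series = 50L,
                          metrics = c("volume", "surface_area", "slice_area"),
                          methods = c("poly4", "gp"),
                          ef_range = c(41, 67),
                          n_phases_choices = 11:13,
                          shape = c(12L, 86L, 98L),
                          edv_ul = 500,
                          seed = 0L,
                          series_list = NULL,
                          reference = NULL) {
  if (is.null(series_list)) {
    if (n_series < 1) stopf("empty input: n_series must be >= 1")
    seeds <- derive_seeds(seed, n_series)
    draws <- with_seed(seed, list(ef = stats::runif(n_series, ef_range[1], ef_range[2]),
                                  np = sample(n_phases_choices, n_series, replace = TRUE)))
    series_list <- vector("list", n_series)
    reference <- data.frame(label = character(n_series), ef_pct = NA_real_,
                            diastole_phase = NA_integer_, systole_phase = NA_integer_)
    for (i in seq_len(n_series)) {
      res <- generate_synthetic_cine(synthetic_cine_spec(
        n_phases = draws$np[i], shape = shape, edv_ul = edv_ul,
        ef_pct = draws$ef[i],
        cycle_shape = if (i %% 2 == 0) "skewed" else "cosine",
        seed = seeds[i]))
      res$series$label <- sprintf("series%03d", i)
      series_list[[i]] <- res$series
      reference[i, ] <- list(res$series$label, res$truth$ef_pct,
                             res$truth$diastole_phase, res$truth$systole_phase)
    }
  }
  if (!length(series_list)) stopf("empty input: no series to benchmark")
  if (is.null(reference)) stopf("reference EF values are required")
  fit_seeds <- derive_seeds(seed + 1L, length(series_list))
  rows <- list()
  for (si in seq_along(series_list)) {
    s <- series_list[[si]]
    ref <- reference[reference$label == s$label, ]
    if (!nrow(ref)) stopf("no reference row for series '%s'", s$label)
    curves <- lapply(stats::setNames(metrics, metrics), function(m)
      tryCatch(cycle_metric_curve(s, m), error = function(e) e))
    for (m in metrics) {
      for (meth in methods) {
        row <- data.frame(label = s$label, metric = m, method = meth,
                          ef_est = NA_real_, ef_ref = ref$ef_pct,
                          diastole_ok = NA, systole_ok = NA,
                          failed = FALSE, stringsAsFactors = FALSE)
        out <- tryCatch({
          if (inherits(curves[[m]], "error")) stop(curves[[m]])
          sel <- select_phases(curves[[m]],
                               fit_spec(method = meth, seed = fit_seeds[si]))
          ef <- estimate_ef(s, sel)
          list(sel = sel, ef = ef)
        }, error = function(e) e)
        if (inherits(out, "error")) {
          row$failed <- TRUE
        } else {
          row$ef_est <- out$ef$ef_pct
          row$diastole_ok <- out$sel$diastole_phase == ref$diastole_phase
          row$systole_ok <- out$sel$systole_phase == ref$systole_phase
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  per_series <- do.call(rbind, rows)
  table <- do.call(rbind, lapply(split(per_series,
                                       list(per_series$metric, per_series$method)),
    function(g) {
      ok <- g[!g$failed, ]
      if (!nrow(ok)) {
        return(data.frame(metric = g$metric[1], method = g$method[1],
                          n = 0L, n_failed = sum(g$failed), md = NA_real_,
                          md_sd = NA_real_, bias = NA_real_, sd_diff = NA_real_,
                          loa_lower = NA_real_, loa_upper = NA_real_,
                          phase_accuracy_pct = NA_real_))
      }
      pe <- paired_ef(ok$label, ok$ef_est, ok$ef_ref)
      ba <- suppressWarnings(if (nrow(pe) >= 3) bland_altman(pe) else NULL)
      mdv <- suppressWarnings(mean_abs_diff(pe))
      data.frame(metric = g$metric[1], method = g$method[1],
                 n = nrow(ok), n_failed = sum(g$failed),
                 md = unname(mdv["md"]), md_sd = unname(mdv["sd"]),
                 bias = if (is.null(ba)) NA_real_ else ba$bias,
                 sd_diff = if (is.null(ba)) NA_real_ else ba$sd_diff,
                 loa_lower = if (is.null(ba)) NA_real_ else ba$loa_lower,
                 loa_upper = if (is.null(ba)) NA_real_ else ba$loa_upper,
                 phase_accuracy_pct = 100 * mean(ok$diastole_ok & ok$systole_ok))
    }))
  rownames(table) <- NULL
  structure(list(table = table, per_series = per_series),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Noise-robustness sweep of a segmentation backend
#'
#' For each scenario (clean, the three single distributions at SNR 30, mixed
#' at SNR 20) the intensity images are corrupted, the backend segments every
#' phase, maps are postprocessed, and two endpoints are scored against the
#' ground truth: mean Dice over all phases, and the absolute EF error with
#' EDV/ESV read at the reference diastole/systole phases (phase selection is
#' benchmarked separately by [run_benchmark()]). The default postprocessing
#' is threshold + per-slice hole filling without opening, an identity for a
#' perfect binary map.
#'
#' @param results List of `synthetic_cine_result` objects (series + truth),
#'   e.g. from [generate_synthetic_cine()].
#' @param backend A backend function (see [oracle_backend()]).
#' @param scenarios Named list of [noise_spec()] or NULL entries (NULL =
#'   clean).
#' @param post A [postprocess_spec()].
#' @param seed Master seed for the noise draws.
#' @return An object of class `noise_robustness_result`: list with `table`
#'   (scenario, mean_dsc, sd_dsc, ef_md, ef_md_sd, n_failed) and `per_series`.
#' @export
run_noise_robustness <- function(results, backend,
                                 scenarios = default_noise_scenarios(),
                                 post = postprocess_spec(opening_radius_vox = 0L),
                                 seed = 0L) {
  if (!length(results)) stopf("empty input")
  rows <- list()
  sc_seeds <- derive_seeds(seed, length(scenarios) * length(results))
  k <- 0L
  for (sc in names(scenarios)) {
    for (ri in seq_along(results)) {
      k <- k + 1L
      res <- results[[ri]]
      s <- res$series
      row <- data.frame(scenario = sc, label = s$label, mean_dsc = NA_real_,
                        ef_abs_err = NA_real_, failed = FALSE,
                        stringsAsFactors = FALSE)
      out <- tryCatch({
        nspec <- scenarios[[sc]]
        dscs <- numeric(n_phases(s))
        vols <- numeric(n_phases(s))
        for (pi in seq_len(n_phases(s))) {
          p <- s$phases[[pi]]
          img <- p$image
          if (!is.null(nspec)) {
            ns <- nspec
            ns$seed <- sc_seeds[k] + pi
            img <- add_noise(img, p$mask, ns)
          }
          prob <- backend(img, list(label = s$label,
                                    phase_index = p$phase_index,
                                    spacing_mm = s$spacing_mm))
          mask <- suppressWarnings(postprocess(prob, post, s$spacing_mm))
          dscs[pi] <- dice_score(mask, p$mask)
          vols[pi] <- lv_volume(mask)
        }
        edv <- vols[res$truth$diastole_phase + 1L]
        esv <- vols[res$truth$systole_phase + 1L]
        if (edv == 0) stop("estimated EDV is zero")
        ef <- 100 * (edv - esv) / edv
        list(dsc = mean(dscs), err = abs(ef - res$truth$ef_pct))
      }, error = function(e) e)
      if (inherits(out, "error")) row$failed <- TRUE
      else { row$mean_dsc <- out$dsc; row$ef_abs_err <- out$err }
      rows[[length(rows) + 1]] <- row
    }
  }
  per_series <- do.call(rbind, rows)
  table <- do.call(rbind, lapply(names(scenarios), function(sc) {
    g <- per_series[per_series$scenario == sc, ]
    ok <- g[!g$failed, ]
    data.frame(scenario = sc, n = nrow(ok), n_failed = sum(g$failed),
               mean_dsc = mean(ok$mean_dsc), sd_dsc = stats::sd(ok$mean_dsc),
               ef_md = mean(ok$ef_abs_err), ef_md_sd = stats::sd(ok$ef_abs_err))
  }))
  structure(list(table = table, per_series = per_series),
            class = "noise_robustness_result")
}

#' @rdname run_noise_robustness
#' @export
default_noise_scenarios <- function() {
  list(clean = NULL,
       gaussian30 = noise_spec("gaussian", 30),
       rician30 = noise_spec("rician", 30),
       rayleigh30 = noise_spec("rayleigh", 30),
       mixed20 = noise_spec("mixed", 20))
}

#' @export
print.noise_robustness_result <- function(x, ...) {
  cat("<noise_robustness_result>\n")
  print(x$table, digits = 3)
  invisible(x)
}
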