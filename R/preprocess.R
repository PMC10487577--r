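#' Fixed m/z grid specification
#'
#' The working representation of a fingerprint is an intensity vector on a
#' fixed m/z grid covering the detection window, by default 2-20 kDa at
#' 1 Da spacing (18001 points).
#'
#' @param start,stop grid bounds in Da
#' @param step grid spacing in Da; `(stop - start)` must be divisible by
#'   `step`
#' @return object of class `grid_spec`
#' @export
grid_spec <- function(start = 2000, stop = 20000, step = 1) {
  if (start >= stop) stop("start must be < stop")
  if (step <= 0) stop("step must be > 0")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9) stop("(stop - start) must be divisible by step")
  structure(list(start = start, stop = stop, step = step),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`
#' @return `grid_length`: number of grid points
#' @export
grid_length <- function(grid) {
  as.integer(round((grid$stop - grid$start) / grid$step)) + 1L
}

#' @rdname grid_spec
#' @return `grid_mz`: the m/z value at each grid point
#' @export
grid_mz <- function(grid) {
  grid$start + (seq_len(grid_length(grid)) - 1) * grid$step
}

new_grid_spectrum <- function(intensity, grid, strain_id, replicate_id,
                              flags) {
  structure(list(grid = grid, intensity = intensity,
                 strain_id = strain_id, replicate_id = replicate_id,
                 flags = flags),
            class = "grid_spectrum")
}

#' @export
print.grid_spectrum <- function(x, ...) {
  on <- names(x$flags)[unlist(x$flags)]
  cat(sprintf("grid_spectrum: %s/%s, %d/%d nonzero points [%s]\n",
              x$strain_id, x$replicate_id, sum(x$intensity != 0),
              length(x$intensity),
              if (length(on)) paste(on, collapse = ",") else "raw"))
  invisible(x)
}

#' Resample a peak list onto the fixed grid
#'
#' Each grid point receives the maximum intensity of the raw peaks whose
#' m/z, rounded half-up to the grid step, maps to it; grid points with no
#' peak are zero. Taking the maximum (rather than the sum) within a bin
#' preserves the apex height of a peak whose centroid jitters around a bin
#' boundary.
#'
#' @param raw a [raw_spectrum()] whose peaks lie within the grid
#' @param grid a [grid_spec()]
#' @return a `grid_spectrum` with the `resampled` flag set
#' @export
resample_to_grid <- function(raw, grid = grid_spec()) {
  if (!inherits(raw, "raw_spectrum")) stop("raw must be a raw_spectrum")
  if (length(raw$mz) == 0) {
    stop("empty spectrum for strain ", raw$strain_id)
  }
  mz_r <- round_half_up((raw$mz - grid$start) / grid$step) * grid$step +
    grid$start
  if (any(mz_r < grid$start | mz_r > grid$stop)) {
    stop("peak outside grid for strain ", raw$strain_id)
  }
  idx <- as.integer(round((mz_r - grid$start) / grid$step)) + 1L
  intensity <- numeric(grid_length(grid))
  # max per bin; peaks are sorted so pmax via tapply is fine at this scale
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    if (raw$intensity[[k]] > intensity[[i]]) intensity[[i]] <- raw$intensity[[k]]
  }
  new_grid_spectrum(intensity, grid, raw$strain_id, raw$replicate_id,
                    list(resampled = TRUE, log_transformed = FALSE,
                         denoised = FALSE))
}

#' Log10 intensity conversion
#'
#' Applies `log10(1 + I)` point-wise. The +1 offset maps the empty
#' baseline (zero intensity) to exactly zero while compressing the
#' dynamic range of real peaks, so large intensity differences are
#' narrowed and small ones retained.
#'
#' @param s a `grid_spectrum`
#' @return the spectrum with transformed intensities and the
#'   `log_transformed` flag set
#' @export
log_transform <- function(s) {
  if (!inherits(s, "grid_spectrum")) stop("s must be a grid_spectrum")
  if (isTRUE(s$flags$log_transformed)) stop("spectrum already log-transformed")
  if (any(s$intensity < 0)) stop("negative intensity")
  s$intensity <- log10(1 + s$intensity)
  s$flags$log_transformed <- TRUE
  s
}

#' Sliding-window denoiser parameters
#'
#' The noise filter slides a window of `window_width` Da across the grid
#' in steps of `step` Da; within each window the top
#' `ceiling(keep_fraction * w)` intensities (w = window width in grid
#' points) are marked as signal and the rest as noise. With the defaults
#' (100 Da window, keep 20%, 1 Da step) each window marks its 20 largest
#' of 100 consecutive grid intensities.
#'
#' @param window_width window width in Da
#' @param keep_fraction fraction of window points kept as signal, in (0, 1]
#' @param step window advance in Da
#' @param combine_rule how overlapping windows combine: `"union"` keeps a
#'   point if any covering window marks it as signal; `"per_window"`
#'   applies each window's zeroing in sequence so the last window covering
#'   a point decides
#' @return object of class `denoise_params`
#' @export
denoise_params <- function(window_width = 100, keep_fraction = 0.2,
                           step = 1, combine_rule = c("union", "per_window")) {
  combine_rule <- match.arg(combine_rule)
  if (!(keep_fraction > 0 && keep_fraction <= 1)) {
    stop("keep_fraction must be in (0, 1]")
  }
  if (window_width < step) stop("window_width must be >= step")
  structure(list(window_width = window_width, keep_fraction = keep_fraction,
                 step = step, combine_rule = combine_rule),
            class = "denoise_params")
}

#' Sliding-window top-fraction noise filter
#'
#' Slides a window across the grid; each fully-enclosed window ranks its
#' intensities (ties broken by higher intensity first, then lower m/z) and
#' marks the top `ceiling(keep_fraction * w)` points as signal. Under the
#' default `union` rule a grid point keeps its intensity if at least one
#' covering window marks it; otherwise it is set to zero. The final window
#' start is clamped so every grid point lies in at least one window.
#'
#' @param s a `grid_spectrum`
#' @param p a [denoise_params()]
#' @return the filtered spectrum with the `denoised` flag set
#' @export
denoise <- function(s, p = denoise_params()) {
  if (!inherits(s, "grid_spectrum")) stop("s must be a grid_spectrum")
  if (isTRUE(s$flags$denoised)) stop("spectrum already denoised")
  n <- length(s$intensity)
  w <- p$window_width / s$grid$step
  if (abs(w - round(w)) > 1e-9) stop("window_width must be a multiple of the grid step")
  w <- as.integer(round(w))
  step_pts <- p$step / s$grid$step
  if (abs(step_pts - round(step_pts)) > 1e-9) {
    stop("denoise step must be a multiple of the grid step")
  }
  step_pts <- as.integer(round(step_pts))
  if (w > n) stop("denoise window larger than the grid")
  s$intensity <- denoise_cpp(s$intensity, w, p$keep_fraction, step_pts,
                             p$combine_rule == "per_window")
  s$flags$denoised <- TRUE
  s
}

#' Preprocessing pipeline
#'
#' Resamples a raw peak list onto the grid, then applies the log10
#' conversion and the sliding-window noise filter. The default order is
#' log first, then denoise; because the log is strictly increasing the
#' within-window intensity ranking is unchanged, so the retained support
#' is identical under either order — only the surviving values differ
#' (log-scale vs raw-scale).
#'
#' @param raw a [raw_spectrum()]
#' @param grid a [grid_spec()]
#' @param p a [denoise_params()]
#' @param order `"log_then_denoise"` (default) or `"denoise_then_log"`
#' @return a fully processed `grid_spectrum` (all flags set); the
#'   configuration used is stored in attribute `provenance`
#' @export
preprocess_pipeline <- function(raw, grid = grid_spec(),
                                p = denoise_params(),
                                order = c("log_then_denoise",
                                          "denoise_then_log")) {
  order <- match.arg(order)
  s <- resample_to_grid(raw, grid)
  if (order == "log_then_denoise") {
    s <- denoise(log_transform(s), p)
  } else {
    s <- log_transform(denoise(s, p))
  }
  attr(s, "provenance") <- list(grid = unclass(grid), denoise = unclass(p),
                                order = order)
  s
}
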