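#' Maximum-intensity projection of an image stack
#'
#' Per-pixel maximum across z planes; single images pass through unchanged.
#'
#' @param stack Numeric array `[ny, nx, nz]`, a matrix, or a list of
#'   matrices.
#' @return Numeric matrix `[ny, nx]`.
#' @export
project_max <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) stop("empty stack")
    stack <- simplify2array(stack)
  }
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    stop("empty stack")
  }
  apply(stack, c(1, 2), max)
}

#' Background subtraction for spot images
#'
#' Removes smooth background before spot detection.  `"log"` subtracts a
#' wide Gaussian blur of the image (a difference-of-Gaussians high-pass, the
#' discrete analogue of Laplacian-of-Gaussian background removal), `"rolling
#' ball"` subtracts a grayscale morphological opening with a disc of the
#' given radius.  Both clamp at zero, map flat images to ~0, and are
#' invariant to a constant offset.
#'
#' @param image Numeric matrix.
#' @param method `"log"` or `"rolling_ball"`.
#' @param radius_px Background length scale in pixels (blur sigma / ball
#'   radius); must be much larger than the spot width.
#' @return Non-negative numeric matrix.
#' @export
subtract_background <- function(image, method = c("log", "rolling_ball"),
                                radius_px = 10) {
  method <- match.arg(method)
  if (radius_px <= 0) stop("'radius_px' must be positive")
  bg <- switch(method,
    log = as.matrix(EBImage::gblur(image, sigma = radius_px)),
    rolling_ball = {
      r <- floor(radius_px)
      brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
      # replicate-pad so border pixels see a full neighborhood
      ny <- nrow(image); nx <- ncol(image)
      padded <- image[c(rep(1, r), 1:ny, rep(ny, r)),
                      c(rep(1, r), 1:nx, rep(nx, r))]
      # EBImage grayscale morphology operates on [0, 1]; min/max filters
      # commute with positive scaling, so rescale around the opening
      lo <- min(padded); hi <- max(padded)
      if (hi > lo) {
        op <- as.matrix(EBImage::opening((padded - lo) / (hi - lo), brush))
        op <- op * (hi - lo) + lo
      } else {
        op <- padded
      }
      op[r + (1:ny), r + (1:nx)]
    })
  pmax(image - bg, 0)
}

#' Detect candidate spots as filtered local maxima
#'
#' Applies a small Gaussian blur to improve signal-to-noise, then keeps
#' local maxima (8-neighborhood) above a threshold, enforcing a minimum
#' separation by keeping the brighter of any two close maxima.
#'
#' @param image Background-subtracted numeric matrix.
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables).
#' @param min_peak Peak threshold on the filtered image; default
#'   `median + 5 * MAD` of the filtered image.
#' @param min_separation_px Minimum distance between candidates, pixels.
#' @return Data frame with `x_px`, `y_px` (continuous pixel coordinates of
#'   the peak pixel center) and `value` (filtered peak height), ordered by
#'   decreasing value.
#' @export
detect_candidates <- function(image, blur_sigma_px = 1, min_peak = NULL,
                              min_separation_px = 2) {
  if (min_separation_px < 0) stop("thresholds must be non-negative")
  f <- if (blur_sigma_px > 0) {
    as.matrix(EBImage::gblur(image, sigma = blur_sigma_px))
  } else image
  if (is.null(min_peak)) {
    min_peak <- stats::median(f) + 5 * stats::mad(f)
  }
  ny <- nrow(f); nx <- ncol(f)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- f
  is_max <- f > min_peak
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    is_max <- is_max & (f >= nb)
  }
  idx <- which(is_max)
  if (length(idx) == 0L) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0), value = numeric(0)))
  }
  row <- ((idx - 1L) %% ny) + 1L
  col <- ((idx - 1L) %/% ny) + 1L
  val <- f[idx]
  ord <- order(-val)
  row <- row[ord]; col <- col[ord]; val <- val[ord]
  # greedy separation: brighter peak wins
  keep <- rep(TRUE, length(val))
  if (min_separation_px > 0 && length(val) > 1) {
    for (i in 2:length(val)) {
      prev <- which(keep[seq_len(i - 1)])
      if (length(prev)) {
        d2 <- (col[prev] - col[i])^2 + (row[prev] - row[i])^2
        if (any(d2 < min_separation_px^2)) keep[i] <- FALSE
      }
    }
  }
  data.frame(x_px = col[keep] - 0.5, y_px = row[keep] - 0.5,
             value = val[keep])
}

# 2D Gaussian least-squares fit in one window; returns coefs or NULL.
fit_one_spot <- function(image, cx, cy, half, sigma0) {
  ny <- nrow(image); nx <- ncol(image)
  ci <- round(cx + 0.5); ri <- round(cy + 0.5)
  xr <- max(1L, ci - half):min(nx, ci + half)
  yr <- max(1L, ri - half):min(ny, ri + half)
  w <- image[yr, xr, drop = FALSE]
  d <- data.frame(
    x = rep(xr - 0.5, each = length(yr)),
    y = rep(yr - 0.5, times = length(xr)),
    v = as.vector(w)
  )
  b0 <- min(d$v); a0 <- max(d$v) - b0
  if (a0 <= 0) return(NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = d,
      start = list(b = b0, A = a0, x0 = cx, y0 = cy, s = sigma0),
      lower = c(b = -Inf, A = 0, x0 = min(d$x), y0 = min(d$y), s = 0.2),
      upper = c(b = Inf, A = Inf, x0 = max(d$x), y0 = max(d$y), s = 10),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  stats::coef(fit)
}

#' Gaussian localization of candidate spots
#'
#' Least-squares fit of an isotropic 2D Gaussian plus local background in a
#' window around each candidate.  The background-corrected total intensity
#' is `2 * pi * sigma^2 * amplitude`.  Candidates whose fitted width or
#' intensity falls outside the thresholds (or whose fit fails) are moved to
#' a rejects table with `fit_ok = FALSE`; positions are converted to nm.
#' When a stack is supplied the lateral fit runs on the maximum projection
#' and an axial Gaussian is fitted to the through-focus profile at the spot
#' to yield `z_nm` and `sigma_z_nm`.
#'
#' @param image Numeric matrix (or `[ny, nx, nz]` array for the 3D option).
#' @param candidates Data frame from [detect_candidates()].
#' @param geometry [make_cell_geometry()] (pixel size, z step).
#' @param window_px Odd fit-window width in pixels.
#' @param sigma_bounds_px Retained fitted widths, pixels (`[0.7, 2.5]`
#'   default).
#' @param intensity_bounds Retained total intensities.
#' @param sigma0_px Width initialization, pixels.
#' @param cell_id,channel Labels written into the table.
#' @return List with `spots` (retained spot table) and `rejects` (failed or
#'   thresholded candidates, `fit_ok = FALSE`).
#' @export
fit_spots <- function(image, candidates, geometry,
                      window_px = 9,
                      sigma_bounds_px = c(0.7, 2.5),
                      intensity_bounds = c(0, Inf),
                      sigma0_px = 1.3,
                      cell_id = "cell_1", channel = "channel_1") {
  stopifnot(inherits(geometry, "cell_geometry"))
  px <- geometry$pixel_size_nm
  stack <- NULL
  if (length(dim(image)) == 3L) { stack <- image; image <- project_max(stack) }
  half <- max(2L, floor(window_px / 2))

  n <- nrow(candidates)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- fit_one_spot(image, candidates$x_px[i], candidates$y_px[i],
                       half, sigma0_px)
    if (is.null(cf)) {
      rows[[i]] <- data.frame(
        cell_id = cell_id, channel = channel,
        x_nm = candidates$x_px[i] * px, y_nm = candidates$y_px[i] * px,
        z_nm = NA_real_, intensity = NA_real_, sigma_nm = NA_real_,
        copies = NA_integer_, fit_ok = FALSE, stringsAsFactors = FALSE)
      next
    }
    total <- 2 * pi * cf[["s"]]^2 * cf[["A"]]
    z_nm <- 0; sigma_z_nm <- NA_real_
    if (!is.null(stack)) {
      zprof <- stack[round(cf[["y0"]] + 0.5), round(cf[["x0"]] + 0.5), ]
      zf <- fit_z_profile(zprof, geometry$z_step_nm)
      if (!is.null(zf)) { z_nm <- zf[1]; sigma_z_nm <- zf[2] }
    }
    ok <- cf[["s"]] >= sigma_bounds_px[1] && cf[["s"]] <= sigma_bounds_px[2] &&
      total >= intensity_bounds[1] && total <= intensity_bounds[2]
    rows[[i]] <- data.frame(
      cell_id = cell_id, channel = channel,
      x_nm = cf[["x0"]] * px, y_nm = cf[["y0"]] * px, z_nm = z_nm,
      intensity = total, sigma_nm = cf[["s"]] * px,
      copies = NA_integer_, fit_ok = ok,
      sigma_z_nm = sigma_z_nm, stringsAsFactors = FALSE)
  }
  all <- if (n > 0) do.call(rbind, rows) else {
    data.frame(cell_id = character(0), channel = character(0),
               x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
               intensity = numeric(0), sigma_nm = numeric(0),
               copies = integer(0), fit_ok = logical(0))
  }
  spots <- all[which(all$fit_ok), , drop = FALSE]
  if (nrow(spots)) spots$spot_id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  list(spots = spots, rejects = all[which(!all$fit_ok), , drop = FALSE])
}

# 1D Gaussian fit along z; returns c(center_nm, sigma_nm) or NULL.
fit_z_profile <- function(profile, z_step_nm) {
  nz <- length(profile)
  if (nz < 3) return(NULL)
  d <- data.frame(z = (seq_len(nz) - 0.5) * z_step_nm, v = profile)
  b0 <- min(d$v); a0 <- max(d$v) - b0
  z0 <- d$z[which.max(d$v)]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ b + A * exp(-(z - z0)^2 / (2 * s^2)), data = d,
                      start = list(b = b0, A = a0, z0 = z0, s = z_step_nm),
                      lower = c(-Inf, 0, min(d$z), z_step_nm / 4),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  c(cf[["z0"]], cf[["s"]])
}

#' Full spot-detection pipeline on one image or stack
#'
#' Convenience chain: maximum projection, background subtraction, candidate
#' detection, Gaussian localization.
#'
#' @inheritParams fit_spots
#' @param stack Image matrix or stack.
#' @param background_method,background_radius_px See [subtract_background()].
#' @param blur_sigma_px,min_peak,min_separation_px See [detect_candidates()].
#' @param ... Passed to [fit_spots()].
#' @return As [fit_spots()].
#' @export
detect_spots <- function(stack, geometry,
                         background_method = "log",
                         background_radius_px = 10,
                         blur_sigma_px = 1, min_peak = NULL,
                         min_separation_px = 2, ...) {
  img <- project_max(stack)
  bg <- subtract_background(img, background_method, background_radius_px)
  if (is.null(min_peak)) {
    # noise level estimated on the filtered *raw* projection: the clamped
    # background-subtracted image underestimates it
    fb <- as.matrix(EBImage::gblur(bg, sigma = max(blur_sigma_px, 0.5)))
    noise_sd <- stats::mad(as.matrix(
      EBImage::gblur(img, sigma = max(blur_sigma_px, 0.5))))
    min_peak <- stats::median(fb) + 5 * noise_sd
  }
  cand <- detect_candidates(bg, blur_sigma_px, min_peak, min_separation_px)
  out <- fit_spots(if (length(dim(stack)) == 3L) stack else img,
                   cand, geometry, ...)
  dedupe_spots(out, min_separation_px * geometry$pixel_size_nm)
}

# Merge fitted spots whose centers ended up closer than min_sep_nm
# (shoulder maxima relocalizing onto the same molecule); brighter one wins.
dedupe_spots <- function(fitres, min_sep_nm) {
  sp <- fitres$spots
  if (nrow(sp) < 2) return(fitres)
  ord <- order(-sp$intensity)
  sp <- sp[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(sp))
  for (i in 2:nrow(sp)) {
    prev <- which(keep[seq_len(i - 1)])
    d2 <- (sp$x_nm[prev] - sp$x_nm[i])^2 + (sp$y_nm[prev] - sp$y_nm[i])^2
    if (any(d2 < min_sep_nm^2)) keep[i] <- FALSE
  }
  dropped <- sp[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$fit_ok <- FALSE
    fitres$rejects <- rbind(fitres$rejects, dropped)
  }
  sp <- sp[keep, , drop = FALSE]
  sp <- sp[order(-sp$intensity), , drop = FALSE]
  sp$spot_id <- seq_len(nrow(sp))
  rownames(sp) <- NULL
  fitres$spots <- sp
  fitres
}

#' Mean spot radius from fitted widths
#'
#' The average visible spot radius used by the chance-correction model:
#' mean fitted FWHM/2 across retained spots, in nm
#' (`FWHM = 2 sqrt(2 ln 2) * sigma`).
#'
#' @param spots Spot table with `sigma_nm`.
#' @return Radius in nm.
#' @export
mean_spot_radius_nm <- function(spots) {
  s <- spots$sigma_nm
  s <- s[is.finite(s)]
  if (!length(s)) stop("no finite 'sigma_nm' values")
  mean(2 * sqrt(2 * log(2)) * s / 2)
}
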