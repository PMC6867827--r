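#' Single-mRNA intensity from the pooled intensity histogram
#'
#' Fits the binned histogram of pooled spot intensities with a sum of
#' Gaussian components sharing one baseline,
#' \deqn{y(x) = y_0 + \sum_k \frac{A_k}{w_k\sqrt{\pi/2}}
#'   e^{-2 (x - x_{c,k})^2 / w_k^2},}
#' and extracts the typical single-molecule intensity as the center of the
#' lowest-center component whose peak amplitude exceeds 10% of the largest
#' component's.  The number of components is chosen by BIC over 1..
#' `max_components` when `n_components = "auto"`.  Bins follow
#' Freedman-Diaconis by default; the least-squares fit is weighted by
#' 1/sqrt(count) per bin (Poisson weighting).
#'
#' Component centers are fitted freely (not pinned at integer multiples);
#' multi-start initialization seeds them at k times the histogram mode.
#'
#' @param intensities Numeric vector of spot intensities (>= 100 values,
#'   all positive).
#' @param n_components `"auto"` (BIC) or a fixed integer.
#' @param bin_width Histogram bin width; `NULL` for Freedman-Diaconis.
#' @param max_components Largest K tried under `"auto"`.
#' @return Object of class `calibration_result`: `components` (data frame
#'   `A`, `center`, `width`, `peak_height`), `y0`, `single_intensity`,
#'   `n_components`, `n_spots_fit`, `bin_width`, `bic` (per-K table).
#' @export
fit_intensity_histogram <- function(intensities, n_components = "auto",
                                    bin_width = NULL, max_components = 6L) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 100) stop("need at least 100 intensities for calibration")
  if (any(x <= 0)) stop("intensities must be positive")

  if (stats::sd(x) == 0 || diff(range(x)) < 1e-12 * mean(x)) {
    # degenerate single-valued pool: the single-molecule intensity is the value
    comp <- data.frame(A = length(x), center = x[1], width = 0, peak_height = Inf)
    return(structure(list(components = comp, y0 = 0,
                          single_intensity = x[1], n_components = 1L,
                          n_spots_fit = length(x), bin_width = 0,
                          bic = data.frame(K = 1L, bic = -Inf)),
                     class = "calibration_result"))
  }

  if (is.null(bin_width)) {
    bin_width <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    if (bin_width <= 0) bin_width <- diff(range(x)) / 50
  }
  breaks <- seq(0, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  # empty bins below the first peak are kept: they anchor the left flank
  d <- data.frame(x = h$mids, y = h$counts)
  wts <- 1 / pmax(d$y, 1)  # residuals scaled by sqrt(count)

  mode_x <- d$x[which.max(d$y)]

  sum_of_gaussians <- function(K) {
    terms <- vapply(seq_len(K), function(k) {
      sprintf("(A%d / (w%d * sqrt(pi/2))) * exp(-2 * (x - c%d)^2 / w%d^2)",
              k, k, k, k)
    }, character(1))
    stats::as.formula(paste("y ~ y0 +", paste(terms, collapse = " + ")))
  }

  make_start <- function(K, base) {
    st <- list(y0 = 0)
    for (k in seq_len(K)) {
      ck <- k * base
      wk <- max(2 * bin_width, 0.3 * base)
      i_near <- which.min(abs(d$x - ck))
      hk <- max(d$y[i_near], 1)
      st[[paste0("A", k)]] <- hk * wk * sqrt(pi / 2)
      st[[paste0("c", k)]] <- ck
      st[[paste0("w", k)]] <- wk
    }
    st
  }

  fit_K <- function(K) {
    lo <- c(0, rep(c(0, 0, bin_width / 4), K))
    names(lo) <- c("y0", paste0(rep(c("A", "c", "w"), K),
                                rep(seq_len(K), each = 3)))
    best <- NULL; best_rss <- Inf
    for (base in unique(c(mode_x, mode_x / 2))) {
      st <- make_start(K, base)
      fit <- tryCatch(
        minpack.lm::nlsLM(sum_of_gaussians(K), data = d, start = st,
                          weights = wts, lower = lo[names(unlist(st))],
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        rss <- sum(wts * stats::residuals(fit)^2)
        if (rss < best_rss) { best <- fit; best_rss <- rss }
      }
    }
    if (is.null(best)) return(NULL)
    nb <- nrow(d); p <- 3 * K + 1
    list(fit = best, rss = best_rss,
         bic = nb * log(best_rss / nb) + p * log(nb), K = K)
  }

  Ks <- if (identical(n_components, "auto")) seq_len(max_components)
        else as.integer(n_components)
  fits <- Filter(Negate(is.null), lapply(Ks, fit_K))
  if (!length(fits)) stop("calibration failed: no mixture fit converged")
  bic_tab <- data.frame(K = vapply(fits, `[[`, 1L, "K"),
                        bic = vapply(fits, `[[`, 1, "bic"))
  chosen <- fits[[which.min(bic_tab$bic)]]
  cf <- stats::coef(chosen$fit)
  K <- chosen$K
  comp <- data.frame(
    A = cf[paste0("A", seq_len(K))],
    center = cf[paste0("c", seq_len(K))],
    width = cf[paste0("w", seq_len(K))]
  )
  comp$peak_height <- comp$A / (comp$width * sqrt(pi / 2))
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL

  qual <- comp$peak_height >= 0.1 * max(comp$peak_height)
  single <- comp$center[qual][1]
  structure(list(components = comp, y0 = unname(cf["y0"]),
                 single_intensity = single, n_components = K,
                 n_spots_fit = length(x), bin_width = bin_width,
                 bic = bic_tab),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> K =", x$n_components, "components,",
      x$n_spots_fit, "spots\n")
  cat("  single-mRNA intensity:", format(x$single_intensity, digits = 5), "\n")
  invisible(x)
}

#' Convert spot intensities to mRNA copy numbers
#'
#' `copies = max(1, round(intensity / single_intensity))` per spot.
#'
#' @param spots Spot table with `intensity`.
#' @param calibration A [fit_intensity_histogram()] result or a single
#'   positive number (the single-mRNA intensity).
#' @return The spot table with `copies` filled in.
#' @export
assign_copy_number <- function(spots, calibration) {
  single <- if (inherits(calibration, "calibration_result")) {
    calibration$single_intensity
  } else as.numeric(calibration)
  if (!is.finite(single) || single <= 0) {
    stop("single-molecule intensity must be positive")
  }
  spots$copies <- pmax(1L, as.integer(round(spots$intensity / single)))
  spots
}

#' Cluster-size distribution of transcripts
#'
#' Fraction of detected particles carrying 1, 2, ..., `max_class - 1`, or
#' `>= max_class` mRNA copies.
#'
#' @param spots Spot table with `copies` assigned.
#' @param max_class Top class; larger clusters are pooled into
#'   `">=max_class"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
cluster_size_distribution <- function(spots, max_class = 6L) {
  if (is.null(spots$copies) || all(is.na(spots$copies))) {
    stop("'copies' must be assigned first (see assign_copy_number)")
  }
  cp <- pmin(spots$copies, max_class)
  lev <- seq_len(max_class)
  fr <- tabulate(cp, nbins = max_class) / length(cp)
  names(fr) <- c(head(lev, -1), paste0(">=", max_class))
  fr
}

#' Per-cell transcript counts
#'
#' Number of detected particles (`mode = "spots"`) or total mRNA copies
#' (`mode = "copies"`) per cell and species.
#'
#' @param spots Spot table with `cell_id` and `channel` (and `copies` for
#'   `mode = "copies"`).
#' @param mode `"spots"` or `"copies"`.
#' @return Data frame `cell_id`, `channel`, `count`.
#' @export
count_mrna_per_cell <- function(spots, mode = c("spots", "copies")) {
  mode <- match.arg(mode)
  if (is.null(spots$cell_id)) stop("'cell_id' column required")
  v <- if (mode == "spots") rep(1L, nrow(spots)) else spots$copies
  agg <- stats::aggregate(list(count = v),
                          by = list(cell_id = spots$cell_id,
                                    channel = spots$channel), FUN = sum)
  agg[order(agg$cell_id, agg$channel), , drop = FALSE]
}
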