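#' Aggregate elemental abundance across channels
#'
#' Per-pixel sum or mean over a channel subset. Missing entries contribute
#' nothing: `sum` treats them as zero, `mean` divides by the count of
#' non-missing channels. A pixel missing in every selected channel is missing
#' in the output.
#'
#' @param map An [elemental_map()].
#' @param channels Channel names to aggregate; `NULL` = all.
#' @param method `"sum"` (default) or `"mean"`.
#' @return Numeric matrix (`NA` = missing).
#' @export
aggregate_channels <- function(map, channels = NULL, method = c("sum", "mean")) {
  method <- match.arg(method)
  avail <- channel_names(map)
  if (is.null(channels)) channels <- avail
  if (length(channels) == 0L) {
    abort_elemap("channels must be non-empty", "elemap_bad_channels")
  }
  unknown <- setdiff(channels, avail)
  if (length(unknown)) {
    abort_elemap(sprintf("unknown channel(s) %s; available: %s",
                         paste(unknown, collapse = ", "), paste(avail, collapse = ", ")),
                 "elemap_unknown_channel")
  }
  d <- dim(map$data)
  sub <- map$data[, , channels, drop = FALSE]
  miss <- map$missing[, , channels, drop = FALSE]
  v <- matrix(sub, d[1] * d[2], length(channels))
  m <- matrix(miss, d[1] * d[2], length(channels))
  v[m] <- 0
  total <- rowSums(v)
  n_ok <- rowSums(!m)
  out <- if (method == "sum") total else total / n_ok
  out[n_ok == 0L] <- NA_real_
  matrix(out, d[1], d[2])
}

#' Pseudo-log intensity transform
#'
#' `log(1 + x)`: compresses the heavy right tail of elemental intensities
#' while keeping zero at zero. Missing stays missing.
#'
#' @param img Non-negative numeric matrix (`NA` = missing).
#' @return Transformed matrix.
#' @export
pseudo_log <- function(img) {
  if (any(img < 0, na.rm = TRUE)) {
    abort_elemap("pseudo_log needs non-negative input", "elemap_domain_error")
  }
  log1p(img)
}

#' Gaussian smoothing with missing-data handling
#'
#' Separable Gaussian blur by normalized convolution: the mask-weighted image
#' and the mask itself are blurred with the same kernel and divided, so
#' missing pixels (and out-of-frame positions) contribute nothing and
#' constants are preserved everywhere including the border. Positions missing
#' on input remain missing on output.
#'
#' @param img Numeric matrix (`NA` = missing).
#' @param sigma Positive kernel standard deviation, pixels.
#' @return Smoothed matrix.
#' @export
gaussian_smooth <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort_elemap("sigma must be a positive scalar", "elemap_domain_error")
  }
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  miss <- is.na(img)
  w <- matrix(1, nrow(img), ncol(img)); w[miss] <- 0
  v <- img; v[miss] <- 0
  num <- conv_sep(v, k)
  den <- conv_sep(w, k)
  out <- num / den
  out[den <= 0 | miss] <- NA_real_
  out
}

# zero-padded separable convolution (columns then rows)
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_rc <- function(x) rbind(matrix(0, r, ncol(x)), x, matrix(0, r, ncol(x)))
  conv_cols <- function(x) {
    p <- pad_rc(x)
    f <- stats::filter(p, k, method = "convolution", sides = 2)
    matrix(f[(r + 1):(r + nrow(x)), ], nrow(x), ncol(x))
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Threshold an intensity image
#'
#' `method = "fixed"` uses the supplied value; `method = "otsu"` picks the
#' threshold maximizing between-class variance over the histogram of
#' non-missing values (256 bins). The mask is `img > threshold`; missing
#' pixels are always `FALSE`. A constant (degenerate) image yields an
#' all-`FALSE` mask with a warning.
#'
#' @param img Numeric matrix (`NA` = missing).
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @return Logical matrix; the chosen threshold is attached as attribute
#'   `"threshold"`.
#' @export
threshold_image <- function(img, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  ok <- !is.na(img)
  if (!any(ok)) abort_elemap("image is entirely missing", "elemap_domain_error")
  if (method == "fixed") {
    if (is.null(value)) {
      abort_elemap("method = 'fixed' requires a threshold value", "elemap_domain_error")
    }
    thr <- value
  } else {
    thr <- otsu_threshold(img[ok])
    if (is.na(thr)) {
      warn("degenerate histogram (constant image); returning all-FALSE mask")
      out <- matrix(FALSE, nrow(img), ncol(img))
      attr(out, "threshold") <- NA_real_
      return(out)
    }
  }
  out <- !is.na(img) & img > thr
  attr(out, "threshold") <- as.numeric(thr)
  out
}

# Otsu on a 256-bin histogram of the given values; returns the bin edge
# maximizing between-class variance, NA if the histogram is degenerate.
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)          # classes: bins <= k vs > k
  edges[k + 1L]
}

#' Remove small objects, then fill small holes
#'
#' Deletes 8-connected foreground components with area `< min_object_px`,
#' then fills 4-connected background components that do not touch the raster
#' border and have area `<= fill_hole_px`. Idempotent.
#'
#' @param mask Logical matrix.
#' @param min_object_px,fill_hole_px Non-negative integer area limits.
#' @return Cleaned logical matrix.
#' @export
morphological_clean <- function(mask, min_object_px = 64L, fill_hole_px = 64L) {
  stopifnot(is.logical(mask), min_object_px >= 0, fill_hole_px >= 0)
  lab <- label_components(mask, connectivity = 8L)
  if (min_object_px > 0 && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0L])
    kill <- which(areas < min_object_px)
    mask <- mask & !(lab %in% kill & lab > 0L)
    dim(mask) <- dim(lab)
  }
  if (fill_hole_px > 0) {
    holes <- label_components(!mask, connectivity = 4L)
    if (max(holes) > 0) {
      areas <- tabulate(holes[holes > 0L])
      border <- unique(c(holes[1, ], holes[nrow(holes), ], holes[, 1], holes[, ncol(holes)]))
      fill <- setdiff(which(areas <= fill_hole_px), border)
      mask <- mask | (holes %in% fill & holes > 0L)
      dim(mask) <- dim(holes)
    }
  }
  mask
}

#' Label connected components
#'
#' Deterministic labelling by iterative minimum-index propagation; labels are
#' renumbered 1..k in raster order of each component's first pixel.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(0L, nr, nc))
  lab[idx] <- idx
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- shift_matrix(lab, s[1], s[2])
      new <- pmin(new, sh)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  ids <- lab[idx]
  first_seen <- !duplicated(ids[order(idx)])
  uniq <- sort(unique(ids))
  # renumber by component minimum index (raster order of first pixel)
  out <- matrix(0L, nr, nc)
  out[idx] <- match(ids, uniq)
  out
}

shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(Inf, nr, nc)
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

#' Detect tissue on an elemental map
#'
#' The preprocessing chain: aggregate selected channels, pseudo-log
#' transform, Gaussian smoothing, thresholding, then morphological cleanup
#' (remove specks, fill holes). Fully deterministic; the returned `params`
#' reproduce the mask from the same map.
#'
#' @param map An [elemental_map()].
#' @param channels Channels to aggregate (`NULL` = all).
#' @param agg_method `"sum"` or `"mean"`.
#' @param sigma Gaussian sigma in pixels (default 2).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value Threshold for `"fixed"`.
#' @param min_object_px,fill_hole_px Morphology area limits (default 64).
#' @return A `tissue_mask`: list with logical `mask` and `params`.
#' @export
detect_tissue <- function(map, channels = NULL, agg_method = "sum", sigma = 2,
                          threshold_method = "otsu", threshold_value = NULL,
                          min_object_px = 64L, fill_hole_px = 64L) {
  agg <- aggregate_channels(map, channels, agg_method)
  sm <- gaussian_smooth(pseudo_log(agg), sigma)
  bin <- threshold_image(sm, threshold_method, threshold_value)
  thr <- attr(bin, "threshold")
  mask <- morphological_clean(bin, min_object_px, fill_hole_px)
  attr(mask, "threshold") <- NULL
  structure(list(
    mask = mask,
    params = list(channels_used = if (is.null(channels)) channel_names(map) else channels,
                  agg_method = agg_method, sigma = sigma,
                  threshold_method = threshold_method,
                  threshold_value = if (threshold_method == "fixed") threshold_value else thr,
                  min_object_px = as.integer(min_object_px),
                  fill_hole_px = as.integer(fill_hole_px))),
    class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d px, %d (%.1f%%) tissue, threshold %s (%s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask),
              format(x$params$threshold_value, digits = 4), x$params$threshold_method))
  invisible(x)
}

#' Write a tissue mask as a 0/255 PNG
#' @param tm A `tissue_mask` (or plain logical matrix).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(tm, path) {
  mask <- if (inherits(tm, "tissue_mask")) tm$mask else tm
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Intersection-over-union of two masks
#' @param a,b Logical matrices of equal shape.
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Plot a tissue mask
#' @param object A `tissue_mask`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tissue_mask
#' @export
autoplot.tissue_mask <- function(object, ...) {
  m <- object$mask
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)) - 1L, ncol(m)),
    col = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    tissue = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$tissue)) +
    ggplot2::geom_raster() + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "grey25")) +
    ggplot2::labs(x = "col", y = "row")
}
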