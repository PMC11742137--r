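# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the package implementation: plain loops, queue-based
# flood fill, exhaustive searches.

# BFS flood-fill connected-component labelling
oracle_label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  next_lab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    next_lab <- next_lab + 1L
    queue <- list(c(i, j)); lab[i, j] <- next_lab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc && mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- next_lab
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# two labelings agree up to renaming
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  key <- paste(a[a > 0L], b[b > 0L])
  length(unique(key)) == length(unique(a[a > 0L])) &&
    length(unique(key)) == length(unique(b[b > 0L]))
}

# exhaustive Otsu: try every distinct value as cut, maximize between-class
# variance of (values <= t) vs (values > t)
oracle_otsu_classes <- function(values) {
  cand <- sort(unique(values))
  best <- -Inf; best_t <- NA_real_
  for (t in cand[-length(cand)]) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t }
  }
  values > best_t
}

# scalar-loop even-odd point-in-polygon over a full grid
oracle_rasterize <- function(set, shape, pixel_size_um) {
  labels <- matrix(0L, shape[1], shape[2])
  ids <- stats::setNames(set$label_table$id, set$label_table$label)
  point_in <- function(x, y, rings) {
    crossings <- 0L
    for (ring in rings) {
      n <- nrow(ring)
      for (e in seq_len(n)) {
        x1 <- ring[e, 1]; y1 <- ring[e, 2]
        f <- if (e == n) 1L else e + 1L
        x2 <- ring[f, 1]; y2 <- ring[f, 2]
        if ((y1 > y) != (y2 > y)) {
          xi <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
          if (x < xi) crossings <- crossings + 1L
        }
      }
    }
    crossings %% 2L == 1L
  }
  for (a in set$annotations) {
    rings <- c(list(a$exterior), a$holes)
    for (r in seq_len(shape[1])) for (cc in seq_len(shape[2])) {
      if (point_in((cc - 1) * pixel_size_um, (r - 1) * pixel_size_um, rings)) {
        labels[r, cc] <- ids[[a$label]]
      }
    }
  }
  labels
}

# per-pixel loop version of summarize_regions
oracle_summarize <- function(map, labels, zero_eps = 0) {
  rows <- list()
  for (el in channel_names(map)) {
    for (id in sort(unique(labels$labels[labels$labels > 0L]))) {
      x <- c()
      for (r in seq_len(nrow(labels$labels))) for (cc in seq_len(ncol(labels$labels))) {
        if (labels$labels[r, cc] == id && !map$missing[r, cc, el]) {
          x <- c(x, map$data[r, cc, el])
        }
      }
      if (length(x) == 0L) next
      pos <- x[x > zero_eps]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region_label = unname(labels$label_table[[as.character(id)]]),
        element = el, n_pixels = length(x), n_nonzero = length(pos),
        detect_frac = length(pos) / length(x), mean = mean(x),
        mean_positive = if (length(pos)) mean(pos) else NA_real_,
        median = stats::median(x), sd = stats::sd(x),
        q05 = unname(stats::quantile(x, 0.05)),
        q95 = unname(stats::quantile(x, 0.95)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$element, out$region_label), ]
}

# direct hurdle-gamma log density sum at given parameters
oracle_hurdle_loglik <- function(values, p_detect, mu, shape) {
  ll <- 0
  for (i in seq_along(values)) {
    y <- values[i]
    ll <- ll + if (y <= 0) log(1 - p_detect[i]) else {
      log(p_detect[i]) + stats::dgamma(y, shape = shape, rate = shape / mu[i], log = TRUE)
    }
  }
  ll
}

# small random elemental map + label raster for oracle comparisons
random_map_and_labels <- function(seed, nr = 9, nc = 11, n_ch = 3, n_regions = 3,
                                  p_missing = 0.1, p_zero = 0.3) {
  set.seed(seed)
  data <- array(stats::rgamma(nr * nc * n_ch, 2, 0.5), c(nr, nc, n_ch))
  data[stats::runif(length(data)) < p_zero] <- 0
  miss <- array(stats::runif(nr * nc * n_ch) < p_missing, dim(data))
  data[miss] <- NA_real_
  map <- elemental_map(data, channel_names = paste0("E", seq_len(n_ch)),
                       pixel_size_um = 5, frame_id = "elemental", missing = miss)
  labels <- matrix(sample(0:n_regions, nr * nc, replace = TRUE), nr, nc)
  lt <- stats::setNames(paste0("R", seq_len(n_regions)), as.character(seq_len(n_regions)))
  lmap <- region_label_map(labels, lt, 5, "elemental")
  list(map = map, labels = lmap)
}

# random simple convex-ish polygon (star-shaped around a center)
random_polygon <- function(center, r_min, r_max, n = 7L) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  rr <- stats::runif(n, r_min, r_max)
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

expect_map_equal <- function(a, b) {
  expect_identical(dim(a$data), dim(b$data))
  expect_identical(channel_names(a), channel_names(b))
  expect_identical(a$pixel_size_um, b$pixel_size_um)
  expect_identical(a$frame_id, b$frame_id)
  expect_identical(a$missing, b$missing)
  expect_identical(a$data, b$data)
}
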