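#' Per-region, per-element abundance summaries
#'
#' One row per (region, element) with at least one non-missing pixel.
#' Missing pixels are excluded entirely; a value `<= zero_eps` counts as a
#' non-detect (zero), distinct from missing.
#'
#' @param map An [elemental_map()].
#' @param labels A [region_label_map()] with the map's spatial shape and
#'   frame.
#' @param zero_eps Non-detect threshold (default 0).
#' @return Tibble with columns `region_label`, `element`, `n_pixels`,
#'   `n_nonzero`, `detect_frac`, `mean`, `mean_positive`, `median`, `sd`,
#'   `q05`, `q95`.
#' @export
summarize_regions <- function(map, labels, zero_eps = 0) {
  stopifnot(inherits(map, "elemental_map"), inherits(labels, "region_label_map"))
  if (!identical(dim(map$data)[1:2], dim(labels$labels))) {
    abort_elemap(sprintf("map is %dx%d but labels are %dx%d",
                         dim(map$data)[1], dim(map$data)[2],
                         nrow(labels$labels), ncol(labels$labels)),
                 "elemap_shape_mismatch")
  }
  if (!identical(map$frame_id, labels$frame_id)) {
    abort_elemap(sprintf("map frame '%s' vs label frame '%s'",
                         map$frame_id, labels$frame_id),
                 "elemap_frame_mismatch")
  }
  if (zero_eps < 0) abort_elemap("zero_eps must be >= 0", "elemap_domain_error")
  lab_vec <- as.vector(labels$labels)
  rows <- purrr::map_dfr(channel_names(map), function(el) {
    v <- as.vector(map$data[, , el])
    keep <- !is.na(v) & lab_vec > 0L
    if (!any(keep)) return(tibble::tibble())
    vv <- v[keep]; ll <- lab_vec[keep]
    purrr::map_dfr(sort(unique(ll)), function(id) {
      x <- vv[ll == id]
      pos <- x[x > zero_eps]
      tibble::tibble(
        region_label = unname(labels$label_table[[as.character(id)]]),
        element = el,
        n_pixels = length(x),
        n_nonzero = length(pos),
        detect_frac = length(pos) / length(x),
        mean = mean(x),
        mean_positive = if (length(pos)) mean(pos) else NA_real_,
        median = stats::median(x),
        sd = stats::sd(x),
        q05 = unname(stats::quantile(x, 0.05)),
        q95 = unname(stats::quantile(x, 0.95)))
    })
  })
  rows
}

#' Fit a two-part hurdle-gamma model
#'
#' Part one is a logistic regression of the detection indicator
#' `1{y > zero_eps}` on the design; part two a log-link gamma regression of
#' the positive values on the same design, with the gamma shape estimated by
#' maximum likelihood (Newton iteration on the profile log-likelihood). The
#' two parts factorize the hurdle likelihood, so the total log-likelihood is
#' their sum. When the data carry no zeros (or no positives) the
#' corresponding part is flagged degenerate rather than fitted.
#'
#' @param values Non-negative observations.
#' @param design Model matrix with an intercept column; default
#'   intercept-only.
#' @param zero_eps Non-detect threshold (default 0).
#' @return A `hurdle_gamma_fit` with coefficient vectors `logit_coef` and
#'   `gamma_coef`, standard errors, `shape`, `shape_se`, `loglik`,
#'   `converged`, counts, and a `degenerate` character vector naming any
#'   unfittable part.
#' @export
fit_hurdle_gamma <- function(values, design = NULL, zero_eps = 0) {
  values <- as.numeric(values)
  if (any(is.na(values))) {
    abort_elemap("values must not contain NA (drop missing pixels upstream)",
                 "elemap_domain_error")
  }
  if (any(values < 0)) {
    abort_elemap("hurdle-gamma values must be non-negative", "elemap_domain_error")
  }
  n <- length(values)
  if (n < 10L) {
    abort_elemap(sprintf("need >= 10 observations, got %d", n), "elemap_domain_error")
  }
  if (is.null(design)) {
    design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  design <- as.matrix(design)
  stopifnot(nrow(design) == n)
  if (is.null(colnames(design))) {
    colnames(design) <- c("(Intercept)", paste0("x", seq_len(ncol(design) - 1L)))
  }
  z <- as.numeric(values > zero_eps)
  degenerate <- character(0)
  p_terms <- ncol(design)
  logit_coef <- logit_se <- stats::setNames(rep(NA_real_, p_terms), colnames(design))
  gamma_coef <- gamma_se <- stats::setNames(rep(NA_real_, p_terms), colnames(design))
  ll_logit <- 0; converged <- TRUE

  if (all(z == 1) || all(z == 0)) {
    degenerate <- c(degenerate, "logit")
  } else {
    fit1 <- suppressWarnings(stats::glm.fit(design, z, family = stats::binomial()))
    logit_coef[] <- fit1$coefficients
    mu1 <- fit1$fitted.values
    w1 <- mu1 * (1 - mu1)
    info <- crossprod(design * sqrt(w1))
    logit_se[] <- sqrt(diag(solve(info)))
    ll_logit <- sum(z * log(mu1) + (1 - z) * log(1 - mu1))
    converged <- converged && fit1$converged
  }

  shape <- NA_real_; shape_se <- NA_real_; ll_gamma <- 0
  pos <- values > zero_eps
  if (!any(pos)) {
    degenerate <- c(degenerate, "gamma")
  } else {
    ypos <- values[pos]
    Xpos <- design[pos, , drop = FALSE]
    if (qr(Xpos)$rank < p_terms) {
      degenerate <- c(degenerate, "gamma")
    } else {
      fit2 <- suppressWarnings(stats::glm.fit(Xpos, ypos,
                                              family = stats::Gamma(link = "log")))
      gamma_coef[] <- fit2$coefficients
      mu2 <- fit2$fitted.values
      ns <- gamma_shape_ml(ypos, mu2)
      shape <- ns$shape
      shape_se <- ns$se
      converged <- converged && fit2$converged && ns$converged
      if (is.finite(shape)) {
        # Fisher information for log-link gamma coefficients: shape * X'X
        gamma_se[] <- sqrt(diag(solve(crossprod(Xpos))) / shape)
        ll_gamma <- sum(stats::dgamma(ypos, shape = shape, rate = shape / mu2, log = TRUE))
      } else {
        # positives fit exactly (e.g. all equal): dispersion is zero and the
        # likelihood degenerates; keep the mean coefficients, flag the shape
        degenerate <- c(degenerate, "shape")
      }
    }
  }

  structure(list(
    logit_coef = logit_coef, logit_se = logit_se,
    gamma_coef = gamma_coef, gamma_se = gamma_se,
    shape = shape, shape_se = shape_se,
    loglik = ll_logit + ll_gamma,
    converged = converged && length(degenerate) == 0L,
    degenerate = degenerate,
    n = n, n_zero = sum(!pos), n_pos = sum(pos),
    zero_eps = zero_eps, terms = colnames(design)),
    class = "hurdle_gamma_fit")
}

# ML gamma shape given fitted means: Newton on
#   g(k) = log k - digamma(k) - c,  c = -1 - mean(log(y/mu) - y/mu) >= 0
gamma_shape_ml <- function(y, mu, tol = 1e-10, max_iter = 50L) {
  n <- length(y)
  cc <- -1 - mean(log(y / mu) - y / mu)
  if (cc <= 0) {                     # numerically exact fit (e.g. constant y)
    return(list(shape = Inf, se = NA_real_, converged = TRUE))
  }
  k <- (1 + sqrt(1 + 4 * cc / 3)) / (4 * cc)   # standard log-moment init
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    g <- log(k) - digamma(k) - cc
    gp <- 1 / k - trigamma(k)
    k_new <- k - g / gp
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * (1 + k)) { k <- k_new; converged <- TRUE; break }
    k <- k_new
  }
  se <- 1 / sqrt(n * (trigamma(k) - 1 / k))
  list(shape = k, se = se, converged = converged)
}

#' @export
print.hurdle_gamma_fit <- function(x, ...) {
  cat(sprintf("<hurdle_gamma_fit> n = %d (%d zero, %d positive)\n",
              x$n, x$n_zero, x$n_pos))
  if (!"logit" %in% x$degenerate) {
    cat("  detection (logit):", paste(sprintf("%s = %.4g (se %.3g)", x$terms,
                                              x$logit_coef, x$logit_se), collapse = ", "), "\n")
  }
  if (!"gamma" %in% x$degenerate) {
    cat("  abundance (log):  ", paste(sprintf("%s = %.4g (se %.3g)", x$terms,
                                              x$gamma_coef, x$gamma_se), collapse = ", "), "\n")
    cat(sprintf("  shape = %.4g (se %.3g)\n", x$shape, x$shape_se))
  }
  cat(sprintf("  loglik = %.4f, converged = %s%s\n", x$loglik, x$converged,
              if (length(x$degenerate)) paste0(" [degenerate: ",
                                               paste(x$degenerate, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Tidy a hurdle-gamma fit
#' @param x A `hurdle_gamma_fit`.
#' @param ... Unused.
#' @return Tibble with `component` (detection / abundance / shape), `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy hurdle_gamma_fit
#' @export
tidy.hurdle_gamma_fit <- function(x, ...) {
  rows <- list()
  if (!"logit" %in% x$degenerate) {
    rows$det <- tibble::tibble(component = "detection", term = x$terms,
                               estimate = unname(x$logit_coef),
                               std.error = unname(x$logit_se))
  }
  if (!"gamma" %in% x$degenerate) {
    rows$ab <- tibble::tibble(component = "abundance", term = x$terms,
                              estimate = unname(x$gamma_coef),
                              std.error = unname(x$gamma_se))
    rows$sh <- tibble::tibble(component = "shape", term = "shape",
                              estimate = x$shape, std.error = x$shape_se)
  }
  out <- dplyr::bind_rows(rows)
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  out
}

#' One-line fit summary
#' @param x A `hurdle_gamma_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_zero`, `n_pos`, `shape`, `logLik`,
#'   `converged`.
#' @method glance hurdle_gamma_fit
#' @export
glance.hurdle_gamma_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_zero = x$n_zero, n_pos = x$n_pos,
                 shape = x$shape, logLik = x$loglik, converged = x$converged)
}

#' Compare elemental abundance between two region groups
#'
#' Pools the non-missing pixels of regions mapped to two groups, fits a
#' hurdle-gamma model with a group indicator per element, and reports the
#' abundance log mean ratio (gamma part), the detection odds ratio (logistic
#' part), a Wald p-value on the gamma group coefficient, and
#' Benjamini-Hochberg q-values across the elements of the call.
#'
#' @param map An [elemental_map()].
#' @param labels A [region_label_map()].
#' @param grouping Named character vector `region_label -> group name`;
#'   exactly two distinct groups. The alphabetically first group is the
#'   reference.
#' @param elements Elements to test (`NULL` = all channels).
#' @param zero_eps Non-detect threshold.
#' @return Tibble with `element`, `contrast`, `log_mean_ratio`,
#'   `log_mean_ratio_se`, `detect_odds_ratio`, `p_value`, `q_value`,
#'   `degenerate`.
#' @export
compare_groups <- function(map, labels, grouping, elements = NULL, zero_eps = 0) {
  stopifnot(inherits(map, "elemental_map"), inherits(labels, "region_label_map"))
  groups <- sort(unique(unname(grouping)))
  if (length(groups) != 2L) {
    abort_elemap(sprintf("grouping must define exactly 2 groups, got %d", length(groups)),
                 "elemap_domain_error")
  }
  if (is.null(elements)) elements <- channel_names(map)
  lab_vec <- as.vector(labels$labels)
  region_of <- labels$label_table[as.character(lab_vec)]
  group_of <- unname(grouping[region_of])        # NA where region not mapped
  contrast <- sprintf("%s vs %s", groups[2], groups[1])
  rows <- purrr::map_dfr(elements, function(el) {
    v <- as.vector(map$data[, , el])
    keep <- !is.na(v) & !is.na(group_of) & lab_vec > 0L
    vv <- v[keep]; gg <- factor(group_of[keep], levels = groups)
    n_by <- table(gg)
    if (any(n_by < 10L)) {
      abort_elemap(sprintf("element %s: groups need >= 10 non-missing pixels (have %s)",
                           el, paste(n_by, collapse = "/")),
                   "elemap_domain_error")
    }
    design <- cbind("(Intercept)" = 1, group = as.numeric(gg == groups[2]))
    fit <- fit_hurdle_gamma(vv, design, zero_eps = zero_eps)
    flags <- fit$degenerate
    # a group with no detections (or no non-detections) separates the
    # logistic part perfectly: its odds ratio is not identifiable
    det_by <- tapply(vv > zero_eps, gg, mean)
    dor <- exp(unname(fit$logit_coef["group"]))
    if (!"logit" %in% flags && any(det_by %in% c(0, 1))) {
      flags <- unique(c(flags, "separation"))
      dor <- NA_real_
    }
    lmr <- unname(fit$gamma_coef["group"])
    lmr_se <- unname(fit$gamma_se["group"])
    tibble::tibble(
      element = el, contrast = contrast,
      log_mean_ratio = lmr, log_mean_ratio_se = lmr_se,
      detect_odds_ratio = dor,
      p_value = if (is.na(lmr)) NA_real_ else 2 * stats::pnorm(-abs(lmr / lmr_se)),
      degenerate = paste(flags, collapse = ","))
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  dplyr::relocate(rows, "q_value", .after = "p_value")
}

#' Export a summary or comparison table
#'
#' CSV output has a stable column order (the tibble's own) and quotes
#' strings; JSON output is an array of records. Both round-trip losslessly.
#'
#' @param table A data frame (e.g. from [summarize_regions()] or
#'   [compare_groups()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(as.data.frame(table), path, dataframe = "rows",
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}
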