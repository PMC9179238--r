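#' Robust outlier flagging for a longitudinal series
#'
#' Robust-fit-then-flag in the spirit of FDR-controlled outlier removal:
#' a cubic is fitted by iteratively reweighted least squares (Tukey
#' bisquare), residuals are standardised by the robust scale estimate, and
#' points are flagged by a Benjamini-Hochberg rule at rate `Q` on two-sided
#' t-tail probabilities.
#'
#' @param data Data frame with columns `dim` and `value`.
#' @param Q False-discovery rate in percent (default 1); `Q = 0` never
#'   flags.
#' @return The input tibble with a logical `.outlier` column.
#' @export
rout_outliers <- function(data, Q = 1) {
  assert_cols(data, c("dim", "value"), "series")
  if (Q < 0 || Q >= 50) abort("Q must be in [0, 50) percent")
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 10) {
    warn("series too short for outlier flagging; no points flagged")
    data$.outlier <- FALSE
    return(data)
  }
  if (length(unique(data$dim)) < 4) {
    abort("rank-deficient design: need at least 4 distinct DIMs")
  }
  if (Q == 0) {
    data$.outlier <- FALSE
    return(data)
  }
  fit <- suppressWarnings(
    MASS::rlm(value ~ poly(dim, 3), data = data,
              psi = MASS::psi.bisquare, maxit = 100))
  res <- residuals(fit)
  s <- fit$s
  if (!is.finite(s) || s <= 0) s <- mad(res)
  if (s <= 0) {
    data$.outlier <- FALSE
    return(data)
  }
  tt <- res / s
  p <- 2 * pt(-abs(tt), df = n - 4)
  data$.outlier <- p.adjust(p, "BH") < Q / 100
  data
}

new_trend <- function(kind, data, model, knots = NULL) {
  fitted_all <- unname(predict(model, newdata = data))
  res <- data$value[!data$.outlier] - fitted_all[!data$.outlier]
  structure(list(kind = kind, data = data, model = model, knots = knots,
                 fitted = fitted_all,
                 residual_sd = sd(res),
                 coefficients = coef(model)),
            class = "hrdcc_trend")
}

#' Third-order polynomial trend
#'
#' Least-squares cubic on the unflagged points of a series.
#'
#' @param data Data frame with `dim`, `value` and optionally `.outlier`
#'   (as from [rout_outliers()]).
#' @return An object of class `hrdcc_trend` with exactly four coefficients.
#' @export
fit_poly3 <- function(data) {
  assert_cols(data, c("dim", "value"), "series")
  data <- tibble::as_tibble(data)
  if (!".outlier" %in% names(data)) data$.outlier <- FALSE
  keep <- data[!data$.outlier, ]
  if (nrow(keep) < 5) abort("need at least 5 unflagged points for a cubic")
  if (length(unique(keep$dim)) < 4) {
    abort("rank-deficient design: need at least 4 distinct DIMs")
  }
  model <- lm(value ~ poly(dim, 3, raw = TRUE), data = keep)
  new_trend("poly3", data, model)
}

#' Four-knot cubic regression spline trend
#'
#' Cubic B-spline with four interior knots at the 20/40/60/80% DIM
#' quantiles, fitted to the unflagged points.
#'
#' @inheritParams fit_poly3
#' @return An `hrdcc_trend` object.
#' @export
fit_spline4 <- function(data) {
  assert_cols(data, c("dim", "value"), "series")
  data <- tibble::as_tibble(data)
  if (!".outlier" %in% names(data)) data$.outlier <- FALSE
  keep <- data[!data$.outlier, ]
  if (nrow(keep) < 8) {
    abort("need at least 8 unflagged points for a 4-knot cubic spline")
  }
  knots <- unname(quantile(keep$dim, c(0.2, 0.4, 0.6, 0.8)))
  model <- lm(value ~ splines::bs(dim, knots = knots, degree = 3),
              data = keep)
  new_trend("spline4", data, model, knots = knots)
}

#' Linear trend
#' @inheritParams fit_poly3
#' @return An `hrdcc_trend` object.
#' @export
fit_linear <- function(data) {
  assert_cols(data, c("dim", "value"), "series")
  data <- tibble::as_tibble(data)
  if (!".outlier" %in% names(data)) data$.outlier <- FALSE
  keep <- data[!data$.outlier, ]
  if (nrow(keep) < 3) abort("need at least 3 unflagged points")
  model <- lm(value ~ dim, data = keep)
  new_trend("linear", data, model)
}

#' Flag outliers then fit a trend
#'
#' The standard description pipeline: outliers are eliminated (rate `Q`)
#' before any trend is fitted.
#'
#' @param data Data frame with `dim` and `value`.
#' @param kind `"poly3"`, `"spline4"` or `"linear"`.
#' @param Q Outlier FDR in percent passed to [rout_outliers()].
#' @return An `hrdcc_trend` object.
#' @export
fit_trend <- function(data, kind = c("spline4", "poly3", "linear"), Q = 1) {
  kind <- match.arg(kind)
  flagged <- rout_outliers(data, Q = Q)
  switch(kind,
         poly3 = fit_poly3(flagged),
         spline4 = fit_spline4(flagged),
         linear = fit_linear(flagged))
}

#' @export
print.hrdcc_trend <- function(x, ...) {
  cat(sprintf("<hrdcc_trend> %s: n = %d (%d flagged), residual SD = %.3g\n",
              x$kind, nrow(x$data), sum(x$data$.outlier), x$residual_sd))
  invisible(x)
}

#' @export
tidy.hrdcc_trend <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.hrdcc_trend <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = nrow(x$data),
                 n_flagged = sum(x$data$.outlier),
                 residual_sd = x$residual_sd)
}

#' @export
augment.hrdcc_trend <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted)
}

#' @importFrom generics augment
#' @export
generics::augment

#' @export
autoplot.hrdcc_trend <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.outlier), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 name = "outlier") +
    ggplot2::labs(x = "DIM", y = "value",
                  title = sprintf("%s trend", object$kind)) +
    ggplot2::theme_minimal()
}

#' Per-series summary statistics
#'
#' Arithmetic mean and sample SD of the raw (unflagged) values, the
#' cow-level description used for stationary blood populations.
#'
#' @param data Data frame with a `value` column (and optional `.outlier`),
#'   or a bare numeric vector.
#' @return One-row tibble `mean`, `sd`, `n`.
#' @export
per_animal_summary <- function(data) {
  v <- if (is.data.frame(data)) {
    keep <- if (".outlier" %in% names(data)) !data$.outlier else TRUE
    data$value[keep]
  } else as.numeric(data)
  v <- v[is.finite(v)]
  if (length(v) == 0) abort("empty series")
  if (length(v) < 2) abort("need at least 2 values for a sample SD")
  tibble::tibble(mean = mean(v), sd = sd(v), n = length(v))
}

#' Summaries for every (animal, matrix, population) series of a study
#'
#' @param results Long `hrdcc_result` tibble from [run_study_hrdcc()]
#'   (reference mode rows are used if both modes are present).
#' @return Tibble `animal_id`, `matrix`, `node`, `mean`, `sd`, `n`.
#' @export
animal_summaries <- function(results) {
  res <- tibble::as_tibble(results)
  res <- dplyr::filter(res, .data$mode == res$mode[1])
  res |>
    dplyr::filter(is.finite(.data$percent)) |>
    dplyr::group_by(.data$animal_id, .data$matrix, .data$node) |>
    dplyr::summarise(mean = mean(.data$percent), sd = sd(.data$percent),
                     n = dplyr::n(), .groups = "drop")
}
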