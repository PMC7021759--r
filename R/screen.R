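#' Concentrations of a plate dilution series
#'
#' The first concentration is the stock after the pin-tool transfer
#' (`stock / dilution_factor`, 890-fold by default); each subsequent
#' column is diluted by `ratio` (1:3 by default), for `steps` columns.
#'
#' @param stock_molar stock concentration (molar, > 0).
#' @param dilution_factor fold dilution into the first well.
#' @param steps number of concentrations.
#' @param ratio serial dilution ratio.
#' @return Numeric vector of molar concentrations, strictly decreasing for
#'   `ratio > 1`.
#' @examples
#' make_dilution_series(10e-3)[1]  # 11.236 uM
#' @export
make_dilution_series <- function(stock_molar, dilution_factor = 890,
                                 steps = 10, ratio = 3) {
  if (stock_molar <= 0) stop("stock concentration must be positive")
  (stock_molar / dilution_factor) / ratio^(seq_len(steps) - 1)
}

#' Normalize plate luminescence for cytotoxic or protective analysis
#'
#' Cytotoxic mode: log2 RLU rescaled to the plate controls, so the vehicle
#' mean maps to 1 and the positive-control mean to 0:
#' `v = (log2 rlu - mean log2 pos) / (mean log2 veh - mean log2 pos)`.
#' Protective mode: `v = log2 rlu - mean log2 veh`, so the vehicle mean
#' maps to 0 and doubling a well's RLU adds exactly 1.
#'
#' @param rlu 8x12 matrix of raw luminescence (positive where occupied).
#' @param layout tibble with `row`, `col`, `role` as produced by
#'   [simulate_plate()].
#' @param mode `"cytotoxic"` or `"protective"`.
#' @return A matrix of normalized values, same shape as `rlu`.
#' @export
normalize_plate <- function(rlu, layout, mode = c("cytotoxic", "protective")) {
  mode <- match.arg(mode)
  role_at <- matrix(NA_character_, nrow(rlu), ncol(rlu))
  role_at[cbind(layout$row, layout$col)] <- layout$role
  veh <- rlu[role_at == "vehicle" & !is.na(rlu)]
  if (!length(veh)) stop("no vehicle wells on the plate")
  mean_veh <- mean(log2(veh))
  if (mode == "protective")
    return(log2(rlu) - mean_veh)
  pos <- rlu[role_at == "positive_control" & !is.na(rlu)]
  if (!length(pos)) stop("no positive_control wells on the plate")
  mean_pos <- mean(log2(pos))
  (log2(rlu) - mean_pos) / (mean_veh - mean_pos)
}

#' Assemble a dose-response series for one compound
#'
#' @param normalized matrix from [normalize_plate()], or a list of such
#'   matrices (replicate plates are pooled).
#' @param layout plate layout tibble.
#' @param compound compound id.
#' @return A tibble with `x` (log10 molar concentration, ascending within
#'   each replicate), `y` (normalized response), `replicate`.
#' @export
dose_response_series <- function(normalized, layout, compound) {
  if (is.matrix(normalized)) normalized <- list(normalized)
  sel <- layout$role == "drug" & !is.na(layout$compound) &
    layout$compound == compound
  if (!any(sel)) stop("compound not on plate: ", compound)
  rows <- layout[sel, ]
  out <- do.call(rbind, lapply(seq_along(normalized), function(p) {
    y <- normalized[[p]][cbind(rows$row, rows$col)]
    tibble::tibble(x = log10(rows$concentration), y = y, replicate = p)
  }))
  out[order(out$replicate, out$x), ]
}

#' Fit a smoothing spline to a dose-response series
#'
#' Cubic smoothing spline of the normalized response on log10
#' concentration, with the penalty chosen by generalized cross-validation;
#' all replicate points enter one pooled fit.  A response with no
#' variability returns the constant function.
#'
#' @param series tibble with `x` and `y` (e.g. from
#'   [dose_response_series()]).
#' @param spar optional fixed smoothing parameter overriding GCV.
#' @return A `dose_spline` object: call `predict_dose_spline()` or treat
#'   `$fun` as a function of log10 concentration; `$range` is the fitted
#'   x-range.
#' @export
fit_dose_spline <- function(series, spar = NULL) {
  x <- series$x; y <- series$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct concentrations for spline fitting")
  if (stats::var(y) == 0) {
    const <- y[1]
    fun <- function(newx) rep(const, length(newx))
  } else {
    fit <- if (is.null(spar))
      stats::smooth.spline(x, y, cv = FALSE)
    else
      stats::smooth.spline(x, y, spar = spar)
    fun <- function(newx) stats::predict(fit, newx)$y
  }
  structure(list(fun = fun, range = range(x)), class = "dose_spline")
}

#' Evaluate a fitted dose-response spline
#'
#' @param curve a `dose_spline` from [fit_dose_spline()].
#' @param x log10 concentrations.
#' @return Fitted values.
#' @export
predict_dose_spline <- function(curve, x) curve$fun(x)

#' Protective AUC of a fitted dose-response curve
#'
#' The baseline is the fitted value at the lowest tested concentration;
#' the curve is evaluated on a uniform grid over the fitted concentration
#' range and the area where it exceeds the baseline is integrated by the
#' trapezoid rule.  Curves that never rise above their low-concentration
#' value (monotone non-increasing or flat) score exactly 0.  Units are
#' (log10 concentration) x (log2 RLU).  Higher values indicate greater
#' protection.
#'
#' @param curve a `dose_spline` fitted on protective-mode values.
#' @param grid_n number of grid points.
#' @return Non-negative AUC.
#' @export
protective_auc <- function(curve, grid_n = 256) {
  xr <- curve$range
  grid <- seq(xr[1], xr[2], length.out = grid_n)
  y <- predict_dose_spline(curve, grid)
  baseline <- predict_dose_spline(curve, xr[1])
  excess <- pmax(y - baseline, 0)
  sum((excess[-1] + excess[-grid_n]) / 2 * diff(grid))
}

#' Score every compound of a simulated or measured plate set
#'
#' Normalizes each replicate plate in protective mode, pools replicates,
#' fits the smoothing spline per compound and returns the protective AUC.
#'
#' @param plates list with `rlu` (list of matrices) and `layout`, as from
#'   [simulate_plate()].
#' @param mode normalization mode passed to [normalize_plate()].
#' @return A tibble: `compound`, `auc`.
#' @export
score_plate <- function(plates, mode = "protective") {
  norm <- lapply(plates$rlu, normalize_plate, layout = plates$layout,
                 mode = mode)
  compounds <- unique(stats::na.omit(plates$layout$compound))
  auc <- vapply(compounds, function(cmp) {
    series <- dose_response_series(norm, plates$layout, cmp)
    protective_auc(fit_dose_spline(series))
  }, numeric(1))
  tibble::tibble(compound = compounds, auc = unname(auc))
}
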