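#' A single well's A340 time series
#'
#' @param sample_id Sample identifier.
#' @param cabp_conc CABP concentration in the well (nM).
#' @param dilution Lysate dilution factor (>= 1).
#' @param times Read times (s), strictly increasing, >= 10 points.
#' @param a340 Absorbance values, same length as `times`.
#' @return An object of class `absorbance_trace`.
#' @export
absorbance_trace <- function(sample_id, cabp_conc, dilution, times, a340) {
  if (length(times) != length(a340))
    stop("times and a340 must have equal length", call. = FALSE)
  if (length(times) < 10L)
    stop("a trace needs at least 10 points", call. = FALSE)
  if (anyNA(times) || anyNA(a340))
    stop("missing values in trace", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.finite(cabp_conc) || cabp_conc < 0)
    stop("cabp_conc must be >= 0 (nM)", call. = FALSE)
  if (!is.finite(dilution) || dilution < 1)
    stop("dilution must be >= 1", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 cabp_conc = cabp_conc, dilution = dilution,
                 times = as.numeric(times), a340 = as.numeric(a340)),
            class = "absorbance_trace")
}

# OLS slope/intercept/R2 on a window; handles zero-variance response
ols_window <- function(t, y) {
  n <- length(t)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * tm
  fitted <- intercept + slope * t
  sse <- sum((y - fitted)^2)
  sst <- sum((y - ym)^2)
  r2 <- if (sst <= .Machine$double.eps * n) 1 else 1 - sse / sst
  resid_sd <- if (n > 2) sqrt(sse / (n - 2)) else 0
  slope_se <- if (sxx > 0) resid_sd / sqrt(sxx) else Inf
  list(slope = slope, intercept = intercept, r2 = r2,
       resid_sd = resid_sd, slope_se = slope_se)
}

#' Fit the initial linear slope of an absorbance trace
#'
#' Scans candidate windows within the first `search_frac` of the trace.
#' Window widths run from the whole search region down (halving) to the
#' minimum span `window_min`; starts advance in steps of half the minimum
#' window. Candidates are visited earliest start first, and at each start
#' widest first, and the first window whose local R-squared reaches
#' `r2_min` wins: the initial-rate convention (earliest linear stretch),
#' with as many points as linearity allows for precision under read noise.
#' If no window is linear enough, the best-R-squared window is used and the
#' `nonlinear` flag set. A flat trace (slope indistinguishable from zero at
#' 3 standard errors) gets the `flat` flag; a trace whose tail has lost
#' nearly all of its initial slope and dropped well below the early signal
#' gets the `depleted` flag (NADH or RuBP exhaustion).
#'
#' @param trace An [absorbance_trace()].
#' @param window_min Minimum fit-window span (s).
#' @param r2_min Local linearity threshold on R-squared.
#' @param search_frac Fraction of the trace span in which windows must end.
#' @return A list of class `slope_fit`: `slope` (A/s), `intercept`,
#'   `fit_window` (start_s, end_s), `r_squared`, `resid_sd`, `slope_se`,
#'   `qc_flags` (character subset of nonlinear/depleted/flat/short),
#'   `ok` (logical).
#' @export
fit_initial_slope <- function(trace, window_min = 60, r2_min = 0.98,
                              search_frac = 0.5) {
  stopifnot(inherits(trace, "absorbance_trace"))
  t <- trace$times; y <- trace$a340
  n <- length(t)
  span <- t[n] - t[1]

  # points per minimum window (whole trace if it spans less than window_min)
  w_min <- if (span <= window_min) n else which(t - t[1] >= window_min)[1]
  if (is.na(w_min) || w_min < 5L) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          fit_window = c(NA_real_, NA_real_),
                          r_squared = NA_real_, resid_sd = NA_real_,
                          slope_se = NA_real_, qc_flags = "short",
                          ok = FALSE), class = "slope_fit"))
  }

  # search region: windows must end within the first search_frac of the
  # trace (but always at least one minimum window)
  region <- max(w_min, sum(t <= t[1] + search_frac * span))

  widths <- region
  while (widths[length(widths)] %/% 2L >= w_min)
    widths <- c(widths, widths[length(widths)] %/% 2L)
  if (widths[length(widths)] != w_min) widths <- c(widths, w_min)
  stride <- max(1L, w_min %/% 2L)

  # a window is accepted when it is locally linear (R^2) AND its two
  # halves agree on the slope -- R^2 alone can stay high across the NADH
  # depletion breakpoint, which silently flattens the fitted slope
  # slope standard error of a segment given an externally estimated read
  # noise (a bend inside the segment must not inflate its own allowance)
  seg_se <- function(ix, noise) {
    sxx <- sum((t[ix] - mean(t[ix]))^2)
    if (sxx > 0) noise / sqrt(sxx) else Inf
  }
  halves_consistent <- function(s, w, fit) {
    h <- w %/% 2L
    if (h < 3L) return(TRUE)
    # read noise from the earliest minimum window at this start
    noise <- ols_window(t[s:(s + w_min - 1L)],
                        y[s:(s + w_min - 1L)])$resid_sd
    i1 <- s:(s + h - 1L); i2 <- (s + h):(s + w - 1L)
    f1 <- ols_window(t[i1], y[i1])
    f2 <- ols_window(t[i2], y[i2])
    se <- sqrt(seg_se(i1, noise)^2 + seg_se(i2, noise)^2)
    if (is.finite(se) &&
        abs(f1$slope - f2$slope) > 0.05 * abs(fit$slope) + 4 * se + 1e-15)
      return(FALSE)
    # a breakpoint near the window end barely moves the half slopes:
    # compare the final third against the whole window as well
    if (w %/% 3L >= 3L) {
      i3 <- (s + w - w %/% 3L):(s + w - 1L)
      f3 <- ols_window(t[i3], y[i3])
      se3 <- sqrt(seg_se(i3, noise)^2 + seg_se(s:(s + w - 1L), noise)^2)
      if (is.finite(se3) &&
          abs(f3$slope - fit$slope) >
            0.05 * abs(fit$slope) + 4 * se3 + 1e-15)
        return(FALSE)
    }
    TRUE
  }

  best <- NULL; best_r2 <- -Inf; best_start <- NA_integer_
  chosen <- NULL; chosen_start <- NA_integer_
  starts <- seq(1L, max(1L, region - w_min + 1L), by = stride)
  for (s in starts) {
    for (w in widths) {
      if (s + w - 1L > region) next
      fit <- ols_window(t[s:(s + w - 1L)], y[s:(s + w - 1L)])
      if (fit$r2 > best_r2) {
        best <- fit; best_r2 <- fit$r2; best_start <- s
        best$width <- w
      }
      if (fit$r2 >= r2_min && halves_consistent(s, w, fit)) {
        chosen <- fit; chosen$width <- w; chosen_start <- s
        break
      }
    }
    if (!is.null(chosen)) break
  }

  flags <- character(0)
  if (is.null(chosen)) {
    chosen <- best; chosen_start <- best_start
    flags <- c(flags, "nonlinear")
  }
  s0 <- chosen_start; w <- chosen$width
  window <- c(t[s0], t[s0 + w - 1L])

  # flat: no significant downward trend. Judged on the whole search
  # region, not the selected window -- best-of-many window selection
  # biases the local slope away from zero on pure noise
  full <- ols_window(t[1:region], y[1:region])
  if (abs(chosen$slope) < 1e-12 ||
      (is.finite(full$slope_se) && full$slope_se > 0 &&
       abs(full$slope) < 3 * full$slope_se))
    flags <- c(flags, "flat")

  # depleted: tail slope has collapsed relative to a real initial slope and
  # the signal has actually fallen
  if (!("flat" %in% flags) && chosen$slope < 0 && n >= 2L * w_min) {
    tail_fit <- ols_window(t[(n - w_min + 1L):n], y[(n - w_min + 1L):n])
    drop <- mean(y[s0:(s0 + w - 1L)]) - mean(y[(n - w_min + 1L):n])
    if (abs(tail_fit$slope) < 0.1 * abs(chosen$slope) &&
        drop > max(5 * chosen$resid_sd, 1e-12))
      flags <- c(flags, "depleted")
  }

  structure(list(slope = chosen$slope, intercept = chosen$intercept,
                 fit_window = window, r_squared = chosen$r2,
                 resid_sd = chosen$resid_sd, slope_se = chosen$slope_se,
                 qc_flags = flags, ok = TRUE),
            class = "slope_fit")
}

#' Convert an A340 slope to a carboxylation flux
#'
#' Beer-Lambert inversion: an A340 slope of `s` A/s corresponds to an NADH
#' consumption rate of `|s| / (epsilon340 * path_length)` M/s, and each
#' carboxylation consumes `nadh_per_carboxylation` NADH, so
#' `flux = max(0, -s) / (epsilon340 * l) / nadh_per_carboxylation * 1e9`
#' nM/s. Positive (rising) slopes cannot mean catalysis and clamp to zero.
#'
#' @param slope A340 slope (A/s; catalysis gives negative slopes).
#' @param constants An [assay_constants()].
#' @return Carboxylation flux in nM/s, with attribute `clamped` TRUE when a
#'   positive slope was clamped to zero flux.
#' @examples
#' slope_to_flux(-3.2344e-3, assay_constants()) # 1000 nM/s
#' @export
slope_to_flux <- function(slope, constants = assay_constants()) {
  constants <- validate_assay_constants(constants)
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  clamped <- slope > 0
  nadh_m_per_s <- max(0, -slope) / (constants$epsilon340 *
                                      constants$path_length)
  flux <- nadh_m_per_s / constants$nadh_per_carboxylation * 1e9
  attr(flux, "clamped") <- clamped
  flux
}
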