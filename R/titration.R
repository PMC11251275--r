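#' Assemble a titration series from traces
#'
#' @param sample_id Sample identifier.
#' @param traces List of [absorbance_trace()] for this sample, one per CABP
#'   ladder entry. Must contain at least two distinct CABP concentrations
#'   and at least one zero-CABP trace.
#' @param constants Shared [assay_constants()].
#' @param dilution Lysate dilution factor.
#' @param batch_id Measurement batch (assay day/plate).
#' @param is_reference TRUE for the internal-standard sample.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(sample_id, traces,
                             constants = assay_constants(), dilution = 1,
                             batch_id = "batch1", is_reference = FALSE) {
  if (!length(traces) || !all(vapply(traces, inherits, logical(1),
                                     "absorbance_trace")))
    stop("traces must be a non-empty list of absorbance_trace",
         call. = FALSE)
  cabp <- vapply(traces, `[[`, numeric(1), "cabp_conc")
  if (length(unique(cabp)) < 2L)
    stop("titration needs >= 2 distinct CABP concentrations", call. = FALSE)
  if (!any(cabp == 0))
    stop("titration needs >= 1 zero-CABP trace", call. = FALSE)
  structure(list(sample_id = as.character(sample_id), traces = traces,
                 constants = validate_assay_constants(constants),
                 dilution = dilution, batch_id = batch_id,
                 is_reference = is_reference),
            class = "titration_series")
}

#' Reaction rate at each CABP concentration of a titration series
#'
#' Fits each trace's initial slope and converts it to a carboxylation flux.
#' Trace order is preserved and both zero-CABP replicates are retained.
#' Traces failing hard QC (`short`) are dropped and recorded.
#'
#' @param series A [titration_series()].
#' @param ... Passed to [fit_initial_slope()].
#' @return A data.frame with columns `cabp_nM`, `flux_nM_s`, `slope_A_s`,
#'   `r_squared`, `qc_flags` (comma-separated), plus attribute
#'   `dropped` (indices of traces dropped by hard QC).
#' @export
titration_points <- function(series, ...) {
  stopifnot(inherits(series, "titration_series"))
  fits <- lapply(series$traces, fit_initial_slope, ...)
  keep <- vapply(fits, `[[`, logical(1), "ok")
  pts <- data.frame(
    cabp_nM = vapply(series$traces, `[[`, numeric(1), "cabp_conc"),
    flux_nM_s = NA_real_, slope_A_s = NA_real_, r_squared = NA_real_,
    qc_flags = vapply(fits, function(f) paste(f$qc_flags, collapse = ","),
                      character(1)),
    stringsAsFactors = FALSE
  )
  for (i in which(keep)) {
    pts$slope_A_s[i] <- fits[[i]]$slope
    # a flat flag means the slope is indistinguishable from zero at the
    # read-noise floor: report no activity rather than a noise slope
    pts$flux_nM_s[i] <- if ("flat" %in% fits[[i]]$qc_flags) 0
      else as.numeric(slope_to_flux(fits[[i]]$slope, series$constants))
    pts$r_squared[i] <- fits[[i]]$r_squared
  }
  out <- pts[keep, , drop = FALSE]
  attr(out, "dropped") <- which(!keep)
  out
}

#' Active-site concentration from a CABP titration
#'
#' Fits an ordinary least-squares line `v = a + b * c` to reaction rate
#' versus CABP concentration; with tight stoichiometric binding the rate
#' reaches zero where CABP equals the active-site concentration, so
#' `site_conc = -a / b` (the x-intercept). Points past the equivalence
#' point violate the linear model (the rate is pinned at zero there), so
#' the fit iteratively excludes the largest-CABP point whenever its
#' predicted rate is <= 0, refitting until at most 3 points remain.
#'
#' @param points Data.frame with columns `cabp_nM` and `flux_nM_s` (as from
#'   [titration_points()]), or a two-column matrix.
#' @return A list of class `site_fit`: `site_conc` (nM or NA), `intercept`
#'   (`a`, nM/s), `slope` (`b`, per s), `r_squared`, `excluded` (original
#'   row indices excluded), `qc_flags`, `ok`.
#' @export
fit_active_sites <- function(points) {
  if (is.matrix(points))
    points <- data.frame(cabp_nM = points[, 1], flux_nM_s = points[, 2])
  stopifnot(all(c("cabp_nM", "flux_nM_s") %in% names(points)))
  pts <- points[is.finite(points$cabp_nM) & is.finite(points$flux_nM_s), ,
                drop = FALSE]
  fail <- function(flag) structure(
    list(site_conc = NA_real_, intercept = NA_real_, slope = NA_real_,
         r_squared = NA_real_, excluded = integer(0), qc_flags = flag,
         ok = FALSE), class = "site_fit")

  if (nrow(pts) < 3L || length(unique(pts$cabp_nM)) < 2L)
    return(fail("poor_fit"))

  use <- seq_len(nrow(pts))
  excluded <- integer(0)
  repeat {
    f <- ols_window(pts$cabp_nM[use], pts$flux_nM_s[use])
    if (!is.finite(f$slope) || f$slope >= 0)
      return(fail("saturated_needs_dilution"))
    i_max <- use[which.max(pts$cabp_nM[use])]
    pred <- f$intercept + f$slope * pts$cabp_nM[i_max]
    if (pred <= 0 && length(use) > 3L) {
      excluded <- c(excluded, i_max)
      use <- setdiff(use, i_max)
    } else break
  }
  if (length(unique(pts$cabp_nM[use])) < 2L) return(fail("poor_fit"))
  site <- -f$intercept / f$slope
  if (!is.finite(site) || site <= 0) return(fail("poor_fit"))
  structure(list(site_conc = site, intercept = f$intercept,
                 slope = f$slope, r_squared = f$r2, excluded = excluded,
                 qc_flags = character(0), ok = TRUE),
            class = "site_fit")
}

#' Carboxylation rate per active site from a titration series
#'
#' The uninhibited activity `v0` is the mean flux of the zero-CABP
#' replicates; the active-site concentration comes from
#' [fit_active_sites()]; the rate per active site is `kcat = v0 /
#' site_conc` (s^-1, since nM/s over nM). `kcat` is invariant to lysate
#' dilution because `v0` and `site_conc` scale together. A sample is
#' called active when `kcat > activity_threshold` (default 0.5 s^-1).
#' When the flux at the highest CABP concentration still exceeds
#' `saturation_frac` of `v0`, the ladder did not titrate the sites and the
#' sample is flagged `saturated_needs_dilution` (re-assay more dilute).
#'
#' @param series A [titration_series()].
#' @param activity_threshold Rate defining "active" (s^-1).
#' @param saturation_frac Fraction of `v0` above which residual flux at the
#'   top CABP concentration flags saturation.
#' @param ... Passed to [fit_initial_slope()].
#' @return An object of class `kinetic_result`: list with `sample_id`,
#'   `v0` (nM/s), `site_conc` (nM), `kcat` (s^-1), `active`, `qc_flags`,
#'   `fit` (the `site_fit`), `points`, `batch_id`, `is_reference`,
#'   `dilution`.
#' @examples
#' ts <- simulate_titration_series(
#'   truth_record("v1", kcat_true = 0.2, site_conc_true = 50),
#'   assay_constants(), seed = 1
#' )
#' compute_kcat(ts)$kcat # ~0.2, inactive
#' @export
compute_kcat <- function(series, activity_threshold = 0.5,
                         saturation_frac = 0.8, ...) {
  stopifnot(inherits(series, "titration_series"))
  pts <- titration_points(series, ...)
  flags <- character(0)
  zero <- pts$cabp_nM == 0
  v0 <- if (any(zero)) mean(pts$flux_nM_s[zero]) else NA_real_

  fit <- fit_active_sites(pts)
  site <- fit$site_conc
  kcat <- NA_real_
  if (!fit$ok) {
    flags <- c(flags, fit$qc_flags)
  } else if (is.finite(v0)) {
    kcat <- v0 / site
  }
  if (is.finite(v0) && v0 > 0 && any(!zero)) {
    top <- which.max(pts$cabp_nM)
    if (pts$flux_nM_s[top] > saturation_frac * v0)
      flags <- unique(c(flags, "saturated_needs_dilution"))
  }
  if (is.finite(v0) && v0 == 0) kcat <- 0
  active <- is.finite(kcat) && kcat > activity_threshold
  if (!active) flags <- c(flags, "inactive")
  if (length(fit$excluded))
    flags <- c(flags, paste0("excluded_points:",
                             paste(fit$excluded, collapse = "+")))
  structure(list(sample_id = series$sample_id, v0 = v0, site_conc = site,
                 kcat = kcat, active = active, qc_flags = unique(flags),
                 fit = fit, points = pts, batch_id = series$batch_id,
                 is_reference = series$is_reference,
                 dilution = series$dilution),
            class = "kinetic_result")
}

#' @export
print.kinetic_result <- function(x, ...) {
  cat(sprintf("kinetic_result %s: v0 = %.3g nM/s, sites = %.3g nM, ",
              x$sample_id, x$v0, x$site_conc))
  cat(sprintf("kcat = %.3g s^-1 (%s)\n", x$kcat,
              if (isTRUE(x$active)) "active" else "inactive"))
  if (length(x$qc_flags))
    cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Batch QC against the internal reference standard
#'
#' Every measurement batch carries the same reference rubisco; systematic
#' drift shows up as that sample's kcat wandering across batches. Reports
#' each batch's reference kcat and its relative deviation from the grand
#' median across batches, flagging batches beyond `max_deviation`.
#' Measurements are never rescaled.
#'
#' @param results Data.frame with columns `sample_id`, `batch_id`, `kcat`
#'   (e.g. from [kinetics_table()]).
#' @param reference_id `sample_id` of the internal standard.
#' @param max_deviation Tolerated relative deviation (default 0.2).
#' @return Data.frame, one row per batch: `batch_id`, `reference_kcat`,
#'   `deviation`, `flagged` (missing reference gives NA kcat and
#'   `flagged = TRUE`).
#' @export
batch_reference_check <- function(results, reference_id,
                                  max_deviation = 0.2) {
  stopifnot(all(c("sample_id", "batch_id", "kcat") %in% names(results)))
  batches <- unique(results$batch_id)
  ref <- vapply(batches, function(b) {
    k <- results$kcat[results$batch_id == b &
                        results$sample_id == reference_id]
    if (length(k)) k[1] else NA_real_
  }, numeric(1))
  grand <- median(ref, na.rm = TRUE)
  dev <- abs(ref - grand) / grand
  data.frame(batch_id = batches, reference_kcat = ref, deviation = dev,
             flagged = is.na(ref) | dev > max_deviation,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate kinetic results
#'
#' @param results List of `kinetic_result` objects.
#' @return Data.frame with columns sample_id, batch_id, v0_nM_s,
#'   site_conc_nM, kcat_s, active, qc_flags.
#' @export
kinetics_table <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1), "kinetic_result")))
  data.frame(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    batch_id = vapply(results, `[[`, character(1), "batch_id"),
    v0_nM_s = vapply(results, `[[`, numeric(1), "v0"),
    site_conc_nM = vapply(results, `[[`, numeric(1), "site_conc"),
    kcat_s = vapply(results, `[[`, numeric(1), "kcat"),
    active = vapply(results, `[[`, logical(1), "active"),
    qc_flags = vapply(results, function(r)
      paste(r$qc_flags, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}
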