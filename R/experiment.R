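# In-silico scan-rescan experiment: run all correction methods with and
# without induced drift and compare the resulting MTR-asymmetry.

STATIC_METHODS <- c("minz", "wassr", "gre2te")
DYNAMIC_METHODS <- c("cestgre2te", "cestgre1te", "nav2te")

#' Default ROI: object interior
#'
#' All voxels whose combined unsaturated magnitude exceeds 20% of its
#' maximum (the phantom/brain interior).
#'
#' @param acq A [cest_acquisition()].
#' @param frac Threshold fraction.
#' @return Logical matrix.
#' @export
default_roi <- function(acq, frac = 0.2) {
  s0 <- sos_magnitude(acq$s0_image)
  s0 > frac * max(s0)
}

#' Erode a logical mask
#'
#' Shrinks a mask by `r` voxels (box erosion). Used to keep ROI statistics
#' of smoothed field maps away from the object boundary, where an unmasked
#' smoothing window mixes in background voxels.
#'
#' @param mask Logical matrix.
#' @param r Erosion radius in voxels.
#' @return Eroded logical matrix.
#' @export
erode_mask <- function(mask, r = 4) {
  stopifnot(is.logical(mask), is.matrix(mask), r >= 0)
  out <- mask
  for (s in seq_len(r)) {
    m <- out
    out <- m &
      shift_mat(m, 1, 1, FALSE) > 0 & shift_mat(m, -1, 1, FALSE) > 0 &
      shift_mat(m, 1, 2, FALSE) > 0 & shift_mat(m, -1, 2, FALSE) > 0
  }
  out
}

#' Estimate a static water-referencing field map
#'
#' Dispatches to the requested static method: `"minz"` (Z-spectrum minimum
#' after smoothing-spline interpolation), `"wassr"` (Lorentzian fit of the
#' WASSR prescan) or `"gre2te"` (dual-echo prescan phase map). The
#' magnitude-based methods return their ppm centre converted to Hz through
#' the scanner profile.
#'
#' @param acq A [cest_acquisition()].
#' @param method One of `"minz"`, `"wassr"`, `"gre2te"`, `"truth"`.
#' @param z Optional precomputed [build_zstack()] result (minz only).
#' @param ... Passed to [dual_echo_map()] for `"gre2te"`.
#' @return A single-map [field_map_series()].
#' @export
static_map <- function(acq, method = c("gre2te", "minz", "wassr", "truth"),
                       z = NULL, ...) {
  method <- match.arg(method)
  sc <- acq$scanner
  switch(method,
    gre2te = dual_echo_map(acq$gre_prescan, sc, ...),
    minz = {
      if (is.null(z)) z <- build_zstack(acq)
      ctr <- minz_center(z)
      field_map_series(ctr * sc$hz_per_ppm, 0, "minz")
    },
    wassr = {
      wc <- wassr_center(wassr_zstack(acq))
      field_map_series(wc$center * sc$hz_per_ppm,
                       max(acq$wassr$schedule$timestamp_s), "wassr")
    },
    truth = {
      if (is.null(acq$truth)) stop("no ground truth available", call. = FALSE)
      field_map_series(acq$truth$b0_map, 0, "truth")
    })
}

#' Correct an acquisition with any of the six methods
#'
#' Builds the Z-stack and applies either a static correction (one field map
#' shifting the whole spectrum) or a dynamic correction (one map per
#' Z-spectral point). `method = "truth"` corrects dynamically with the
#' simulator's exact per-offset field (spatial map plus drift), available
#' only on simulated data.
#'
#' @param acq A [cest_acquisition()].
#' @param method One of `"minz"`, `"wassr"`, `"gre2te"`, `"cestgre2te"`,
#'   `"cestgre1te"`, `"nav2te"`, `"truth"`.
#' @param z Optional precomputed [build_zstack()] result.
#' @param ... Passed to [dynamic_series()] / [static_map()].
#' @return A corrected [z_stack()].
#' @export
correct_acquisition <- function(acq, method, z = NULL, ...) {
  stopifnot(inherits(acq, "cest_acquisition"))
  method <- match.arg(method, c(STATIC_METHODS, DYNAMIC_METHODS, "truth"))
  if (is.null(z)) z <- build_zstack(acq)
  sc <- acq$scanner
  if (method %in% STATIC_METHODS)
    return(correct_static(z, static_map(acq, method, z = z, ...), sc))
  if (method == "truth") {
    if (is.null(acq$truth)) stop("no ground truth available", call. = FALSE)
    n <- nrow(acq$schedule)
    dr <- truth_drift(acq$truth, acq$schedule$timestamp_s)
    maps <- lapply(seq_len(n), function(k) acq$truth$b0_map + dr[k])
    series <- field_map_series(maps, acq$schedule$timestamp_s, "nav2te",
                               source_offsets = acq$schedule$offset_ppm)
    return(correct_dynamic(z, series, sc))
  }
  correct_dynamic(z, dynamic_series(acq, method, ...), sc)
}

#' Least-squares drift fit to a dynamic field-map series
#'
#' Fits an ordinary least-squares line to the ROI-mean field value of each
#' map against its timestamp.
#'
#' @param series A [field_map_series()] with at least 3 maps.
#' @param roi Logical ROI matrix.
#' @param exclude_low_confidence Drop maps flagged low-confidence (near-water
#'   intrinsic maps replaced by temporal interpolation carry no independent
#'   field information and would flatten the fitted ramp).
#' @return List with `rate_hz_min` (slope in Hz/min), `total_hz`
#'   (slope times the timestamp span), `r2`, and the per-map `roi_mean` and
#'   `timestamp` vectors.
#' @export
fit_drift <- function(series, roi, exclude_low_confidence = TRUE) {
  stopifnot(inherits(series, "field_map_series"))
  keep <- seq_len(n_maps(series))
  if (exclude_low_confidence && length(series$low_confidence))
    keep <- setdiff(keep, series$low_confidence)
  if (length(keep) < 3L)
    stop("drift fitting needs at least 3 maps", call. = FALSE)
  y <- vapply(series$values[keep], function(m) mean(m[roi], na.rm = TRUE),
              numeric(1))
  t <- series$timestamps[keep]
  fit <- stats::lm(y ~ t)
  rate_s <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(rate_hz_min = rate_s * 60, total_hz = rate_s * diff(range(t)),
       r2 = r2, roi_mean = y, timestamp = t)
}

#' In-silico scan-rescan drift experiment
#'
#' Generates two acquisitions from the same seed that differ only in the
#' induced drift (zero versus the configured rate), applies the requested
#' correction methods to both, and summarises the ROI-mean MTR-asymmetry
#' discrepancy per Hz of induced drift for each method:
#' `drift_error_rate = |mean(drift) - mean(no drift)| / total drift`.
#' Dynamic per-offset corrections should keep this rate more than an order
#' of magnitude below the static corrections.
#'
#' @param cfg A [sim_config()] with a nonzero configured drift.
#' @param methods Character vector of methods, or `"all"`.
#' @param ranges List of positive integration ranges; the first is the
#'   primary range of the report.
#' @param roi Optional ROI matrix. The default is the object interior eroded
#'   by a few voxels: the field maps are smoothed without masking, so a thin
#'   boundary ring mixes background phase and is excluded from the summary
#'   statistics (the same reason an ROI is drawn just inside the object
#'   boundary in practice).
#' @param out Optional output directory for [render_report()].
#' @return A `comparison_report`: list with `table` (one row per method and
#'   range), `drift_total_hz`, `primary_range`, `seed`, drift fits for the
#'   dynamic methods, and the per-method MTR-asymmetry maps.
#' @export
run_scan_rescan <- function(cfg,
                            methods = "all",
                            ranges = list(c(0.3, 1.0), c(1, 2), c(3, 4)),
                            roi = NULL, out = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (identical(methods, "all")) methods <- c(STATIC_METHODS, DYNAMIC_METHODS)
  methods <- match.arg(methods, c(STATIC_METHODS, DYNAMIC_METHODS, "truth"),
                       several.ok = TRUE)
  ranges <- Filter(function(r) max(abs(cfg$offsets_ppm)) > r[1], ranges)
  cfg0 <- cfg
  cfg0$drift_total <- 0
  cfg0$drift_rate <- NULL
  acq0 <- generate_acquisition(cfg0)
  acq1 <- generate_acquisition(cfg)
  if (is.null(roi)) roi <- erode_mask(default_roi(acq0), 4)
  drift_total <- truth_drift(acq1$truth, max(acq1$schedule$timestamp_s))
  if (drift_total == 0)
    message("configured drift is zero: drift_error_rate will be NA")
  z0 <- build_zstack(acq0)
  z1 <- build_zstack(acq1)
  rows <- list()
  maps <- list()
  drift_fits <- list()
  for (m in methods) {
    c0 <- correct_acquisition(acq0, m, z = z0)
    c1 <- correct_acquisition(acq1, m, z = z1)
    if (m %in% DYNAMIC_METHODS)
      drift_fits[[m]] <- fit_drift(dynamic_series(acq1, m), roi)
    for (ri in seq_along(ranges)) {
      rg <- ranges[[ri]]
      a0 <- mtr_asym(c0, rg, roi = roi, method_tag = m)
      a1 <- mtr_asym(c1, rg, roi = roi, method_tag = m)
      if (ri == 1L) maps[[m]] <- list(nodrift = a0, drift = a1)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m,
        class = if (m %in% STATIC_METHODS) "static" else "dynamic",
        range_lo = rg[1], range_hi = rg[2],
        mean_nodrift = a0$roi_mean, sd_nodrift = a0$roi_sd,
        mean_drift = a1$roi_mean, sd_drift = a1$roi_sd,
        drift_error_rate = if (drift_total > 0)
          abs(a1$roi_mean - a0$roi_mean) / drift_total else NA_real_)
    }
  }
  report <- structure(
    list(table = do.call(rbind, rows),
         drift_total_hz = drift_total,
         primary_range = ranges[[1]],
         seed = cfg$seed,
         methods = methods,
         drift_fits = drift_fits,
         maps = maps,
         roi = roi),
    class = "comparison_report")
  if (!is.null(out)) render_report(report, out)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> seed %d, induced drift %.1f Hz, range %.2f-%.2f ppm\n",
              x$seed, x$drift_total_hz, x$primary_range[1], x$primary_range[2]))
  tb <- x$table[x$table$range_lo == x$primary_range[1] &
                x$table$range_hi == x$primary_range[2], ]
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s (%s): %+.3f%% -> %+.3f%%  error %.5f %%/Hz\n",
                tb$method[i], tb$class[i], tb$mean_nodrift[i],
                tb$mean_drift[i], tb$drift_error_rate[i]))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `report.csv` (one row per method, primary range),
#' `report_all_ranges.csv`, `report.json` (round-trippable through
#' [read_report()]), the per-method MTR-asymmetry maps as NIfTI, and PNG
#' panels of the maps and of the dynamic drift curves. Filenames are
#' deterministic.
#'
#' @param report A `comparison_report`.
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
render_report <- function(report, out) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tb <- report$table
  prim <- tb[tb$range_lo == report$primary_range[1] &
             tb$range_hi == report$primary_range[2], ]
  utils::write.csv(prim, file.path(out, "report.csv"), row.names = FALSE)
  utils::write.csv(tb, file.path(out, "report_all_ranges.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(table = tb, drift_total_hz = report$drift_total_hz,
         primary_range = report$primary_range, seed = report$seed,
         methods = report$methods),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = I(17),
    na = "null", dataframe = "columns")
  for (m in names(report$maps)) {
    write_map(report$maps[[m]]$nodrift,
              file.path(out, sprintf("mtrasym_%s_nodrift", m)))
    write_map(report$maps[[m]]$drift,
              file.path(out, sprintf("mtrasym_%s_drift", m)))
    grDevices::png(file.path(out, sprintf("mtrasym_%s.png", m)),
                   width = 900, height = 480)
    graphics::par(mfrow = c(1, 2), mar = c(2, 2, 3, 1))
    for (cond in c("nodrift", "drift")) {
      v <- report$maps[[m]][[cond]]$values
      graphics::image(v, main = sprintf("%s (%s)", m, cond), axes = FALSE,
                      zlim = range(v, na.rm = TRUE))
    }
    grDevices::dev.off()
  }
  if (length(report$drift_fits)) {
    grDevices::png(file.path(out, "drift_curves.png"), width = 700,
                   height = 480)
    cols <- seq_along(report$drift_fits)
    ylim <- range(unlist(lapply(report$drift_fits, `[[`, "roi_mean")))
    graphics::plot(NA, xlim = range(report$drift_fits[[1]]$timestamp),
                   ylim = ylim, xlab = "time [s]",
                   ylab = "ROI-mean field [Hz]",
                   main = "Dynamic field tracking")
    for (i in cols) {
      f <- report$drift_fits[[i]]
      graphics::lines(f$timestamp, f$roi_mean, col = i, lwd = 2)
    }
    graphics::legend("topleft", legend = names(report$drift_fits),
                     col = cols, lwd = 2, bty = "n")
    grDevices::dev.off()
  }
  invisible(out)
}

#' Read back the JSON part of a rendered report
#'
#' @param out Directory written by [render_report()].
#' @return A `comparison_report` (table and scalars; maps are on disk).
#' @export
read_report <- function(out) {
  x <- jsonlite::read_json(file.path(out, "report.json"),
                           simplifyVector = TRUE)
  structure(list(table = x$table, drift_total_hz = x$drift_total_hz,
                 primary_range = x$primary_range, seed = x$seed,
                 methods = x$methods, drift_fits = list(), maps = list()),
            class = "comparison_report")
}
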