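test_that("drift fitting recovers exact lines and constants", {
  maps <- lapply(0:5, function(k) matrix(2 * k + 1, 8, 8))
  ser <- field_map_series(maps, (0:5) * 30, "cestgre2te",
                          source_offsets = seq(-2.5, 0, 0.5))
  roi <- matrix(TRUE, 8, 8)
  fd <- fit_drift(ser, roi)
  expect_equal(fd$rate_hz_min, 4)       # 2 Hz / 30 s
  expect_equal(fd$total_hz, 10)
  expect_equal(fd$r2, 1)
  const <- field_map_series(rep(list(matrix(5, 8, 8)), 4), (0:3) * 10,
                            "nav2te", source_offsets = 1:4)
  fc <- fit_drift(const, roi)
  expect_equal(fc$rate_hz_min, 0)
  expect_error(fit_drift(field_map_series(maps[1:2], c(0, 1), "nav2te",
                                          source_offsets = 1:2), roi),
               "at least 3")
})

test_that("mask erosion shrinks from the boundary only", {
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE
  e <- erode_mask(m, 2)
  expect_true(all(which(e) %in% which(m)))
  expect_equal(sum(e), 16)   # 4x4 core
})

test_that("scan-rescan with zero drift yields NA error rates and identical runs", {
  cfg <- tiny_cfg(snr = 100, drift_total = 0, with_wassr = FALSE)
  expect_message(rep0 <- run_scan_rescan(cfg, methods = c("gre2te")), "zero")
  tb <- rep0$table
  expect_true(all(is.na(tb$drift_error_rate)))
  expect_equal(tb$mean_nodrift, tb$mean_drift)
})

# duration of the saturation schedule implied by a configuration
cfg_schedule_duration <- function(cfg) {
  block <- cfg$nav_duration + cestb0:::train_duration(cfg$train) +
    cfg$grid[1] * cfg$tr_s + cfg$recovery_delay
  length(cfg$offsets_ppm) * block
}

test_that("the scan-rescan report is deterministic and dynamic beats static", {
  cfg <- tiny_cfg(snr = 100, drift_total = 20,
                  offsets_ppm = alternating_offsets(3, 0.15),
                  with_wassr = FALSE)
  rep1 <- run_scan_rescan(cfg, methods = c("gre2te", "cestgre2te"),
                          ranges = list(c(0.3, 1.0)))
  rep2 <- run_scan_rescan(cfg, methods = c("gre2te", "cestgre2te"),
                          ranges = list(c(0.3, 1.0)))
  expect_identical(rep1$table, rep2$table)
  tb <- rep1$table
  expect_gt(tb$drift_error_rate[tb$method == "gre2te"],
            tb$drift_error_rate[tb$method == "cestgre2te"])
  expect_equal(rep1$drift_total_hz, 20, tolerance = 1e-9)
  f <- rep1$drift_fits$cestgre2te
  expect_equal(f$rate_hz_min * max(cfg_schedule_duration(cfg)) / 60, 20,
               tolerance = 0.05 * 20)
})

test_that("dynamic corrections stay below static ones across drift rates and seeds", {
  rates <- c(1.5, 4, 9)
  for (i in seq_along(rates)) {
    cfg <- tiny_cfg(snr = 100, drift_rate = rates[i],
                    offsets_ppm = alternating_offsets(3, 0.15),
                    with_wassr = FALSE, seed = i)
    rep <- run_scan_rescan(cfg, methods = c("minz", "gre2te", "cestgre2te",
                                            "nav2te"),
                           ranges = list(c(0.3, 1.0)))
    tb <- rep$table
    expect_gt(min(tb$drift_error_rate[tb$class == "static"]),
              max(tb$drift_error_rate[tb$class == "dynamic"]))
  }
})

test_that("rendered reports round trip and have one CSV row per method", {
  cfg <- tiny_cfg(snr = 100, drift_total = 20, with_wassr = FALSE)
  out <- file.path(withr::local_tempdir(), "rep")
  rep <- run_scan_rescan(cfg, methods = c("gre2te", "nav2te"), out = out)
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "mtrasym_gre2te_nodrift.nii.gz")))
  expect_true(file.exists(file.path(out, "drift_curves.png")))
  csv <- utils::read.csv(file.path(out, "report.csv"))
  expect_equal(nrow(csv), 2)
  expect_setequal(csv$method, c("gre2te", "nav2te"))
  back <- read_report(out)
  expect_equal(back$table$drift_error_rate, rep$table$drift_error_rate,
               tolerance = 1e-12)
  expect_equal(back$drift_total_hz, rep$drift_total_hz)
  expect_equal(back$primary_range, rep$primary_range)
  # regeneration is byte-identical for the CSV table
  out2 <- file.path(withr::local_tempdir(), "rep2")
  render_report(rep, out2)
  expect_identical(readLines(file.path(out, "report.csv")),
                   readLines(file.path(out2, "report.csv")))
})
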