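# Dataset input/output: NIfTI volumes with a JSON sidecar. Complex data are
# stored losslessly as separate real/imaginary float64 volumes; offsets are
# stored in ppm, field maps in Hz, times in seconds.

SIDECAR_VERSION <- "1.0"

sidecar_required <- c("format_version", "te_s", "offsets_ppm", "timestamps_s",
                      "n_channels", "b0_tesla", "method_tag")

check_sidecar <- function(sc) {
  for (k in sidecar_required)
    if (is.null(sc[[k]]))
      stop(sprintf("sidecar missing required key: %s", k), call. = FALSE)
  if (!is.character(sc$format_version))
    stop("sidecar key format_version must be a string", call. = FALSE)
  for (k in c("te_s", "offsets_ppm", "timestamps_s", "b0_tesla"))
    if (!is.numeric(sc[[k]]))
      stop(sprintf("sidecar key %s must be numeric", k), call. = FALSE)
  if (length(sc$te_s) < 1L || length(sc$te_s) > 2L)
    stop("sidecar key te_s must list 1 or 2 echo times", call. = FALSE)
  if (any(diff(sc$te_s) <= 0) || any(sc$te_s <= 0))
    stop("sidecar key te_s must be positive and increasing", call. = FALSE)
  if (length(sc$offsets_ppm) != length(sc$timestamps_s))
    stop("sidecar offsets_ppm and timestamps_s lengths differ", call. = FALSE)
  if (sc$n_channels < 1)
    stop("sidecar key n_channels must be >= 1", call. = FALSE)
  invisible(sc)
}

write_complex_volume <- function(data, path_base) {
  # data: [channel, echo, row, col] -> stored spatial-first [row, col, ch, echo]
  arr <- aperm(data, c(3, 4, 1, 2))
  RNifti::writeNifti(Re(arr), paste0(path_base, "_real.nii.gz"),
                     datatype = "double")
  RNifti::writeNifti(Im(arr), paste0(path_base, "_imag.nii.gz"),
                     datatype = "double")
}

# plain array from a NIfTI file, with image attributes stripped
read_nifti_array <- function(path) {
  x <- as.array(RNifti::readNifti(path))
  array(as.vector(x), dim(x))
}

read_complex_volume <- function(path_base) {
  re <- read_nifti_array(paste0(path_base, "_real.nii.gz"))
  im <- read_nifti_array(paste0(path_base, "_imag.nii.gz"))
  if (length(dim(re)) == 3L) dim(re) <- c(dim(re), 1L)
  if (length(dim(im)) == 3L) dim(im) <- c(dim(im), 1L)
  arr <- array(complex(real = re, imaginary = im), dim(re))
  aperm(arr, c(3, 4, 1, 2))
}

img_finite <- function(img) all(is.finite(Re(img$data))) &&
  all(is.finite(Im(img$data)))

#' Save a CEST acquisition to a directory
#'
#' Writes one pair of real/imaginary float64 NIfTI volumes per image (layout
#' `[row, col, channel, echo]`) and a JSON sidecar holding echo times (s),
#' offsets (ppm), timestamps (s), channel count and scanner profile. The
#' round trip through [load_acquisition()] is lossless.
#'
#' @param acq A [cest_acquisition()].
#' @param path Output directory.
#' @param force Overwrite an existing dataset.
#' @return `path`, invisibly.
#' @export
save_acquisition <- function(acq, path, force = FALSE) {
  stopifnot(inherits(acq, "cest_acquisition"))
  sidecar_file <- file.path(path, "sidecar.json")
  if (file.exists(sidecar_file) && !force)
    stop("dataset already exists at this path; use force = TRUE to overwrite",
         call. = FALSE)
  imgs <- c(acq$sat_images, list(acq$s0_image, acq$gre_prescan),
            if (!is.null(acq$nav_images)) acq$nav_images)
  if (!all(vapply(imgs, img_finite, TRUE)))
    stop("refusing to write non-finite image data", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(acq$schedule)
  for (k in seq_len(n))
    write_complex_volume(acq$sat_images[[k]]$data,
                         file.path(path, sprintf("sat_%03d", k)))
  write_complex_volume(acq$s0_image$data, file.path(path, "s0"))
  write_complex_volume(acq$gre_prescan$data, file.path(path, "prescan"))
  if (!is.null(acq$nav_images))
    for (k in seq_len(n))
      write_complex_volume(acq$nav_images[[k]]$data,
                           file.path(path, sprintf("nav_%03d", k)))
  sc <- list(
    format_version = SIDECAR_VERSION,
    method_tag = "cest",
    b0_tesla = acq$scanner$static_field,
    gamma_mhz_t = acq$scanner$gyromagnetic_ratio,
    n_channels = n_channels(acq$s0_image),
    grid = grid_dim(acq$s0_image),
    te_s = acq$s0_image$echo_times,
    offsets_ppm = acq$schedule$offset_ppm,
    timestamps_s = acq$schedule$timestamp_s,
    s0_timestamp_s = acq$s0_image$timestamp,
    prescan_te_s = acq$gre_prescan$echo_times,
    prescan_timestamp_s = acq$gre_prescan$timestamp,
    has_nav = !is.null(acq$nav_images))
  if (!is.null(acq$nav_images)) {
    sc$nav_te_s <- acq$nav_images[[1]]$echo_times
    sc$nav_timestamps_s <- vapply(acq$nav_images, `[[`, 0, "timestamp")
  }
  if (!is.null(acq$wassr)) {
    if (!all(is.finite(acq$wassr$magnitude)) || !all(is.finite(acq$wassr$s0)))
      stop("refusing to write non-finite WASSR data", call. = FALSE)
    RNifti::writeNifti(acq$wassr$magnitude, file.path(path, "wassr_mag.nii.gz"),
                       datatype = "double")
    RNifti::writeNifti(acq$wassr$s0, file.path(path, "wassr_s0.nii.gz"),
                       datatype = "double")
    sc$wassr <- list(offsets_ppm = acq$wassr$schedule$offset_ppm,
                     timestamps_s = acq$wassr$schedule$timestamp_s)
  }
  if (!is.null(acq$truth)) {
    tr <- acq$truth
    RNifti::writeNifti(tr$b0_map, file.path(path, "truth_b0.nii.gz"),
                       datatype = "double")
    RNifti::writeNifti(aperm(tr$coil_phase, c(2, 3, 1)),
                       file.path(path, "truth_coil_phase.nii.gz"),
                       datatype = "double")
    RNifti::writeNifti(aperm(tr$coil_mag, c(2, 3, 1)),
                       file.path(path, "truth_coil_mag.nii.gz"),
                       datatype = "double")
    sc$truth <- list(drift_rate_hz_min = tr$drift_rate_hz_min,
                     noise_sd = tr$noise_sd)
    if (!is.null(tr$clean_zstack)) {
      RNifti::writeNifti(tr$clean_zstack$values,
                         file.path(path, "truth_clean_z.nii.gz"),
                         datatype = "double")
      RNifti::writeNifti(tr$clean_zstack$s0,
                         file.path(path, "truth_clean_s0.nii.gz"),
                         datatype = "double")
    }
    if (!is.null(tr$support))
      RNifti::writeNifti(tr$support * 1,
                         file.path(path, "truth_support.nii.gz"),
                         datatype = "double")
  }
  jsonlite::write_json(sc, sidecar_file, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a CEST acquisition from a directory
#'
#' Reads a dataset written by [save_acquisition()], validating the sidecar
#' schema (missing keys are reported by name) and the consistency between
#' sidecar and volumes (offset counts, echo counts, channel counts).
#'
#' @param path Dataset directory.
#' @return A [cest_acquisition()].
#' @export
load_acquisition <- function(path) {
  sidecar_file <- file.path(path, "sidecar.json")
  if (!file.exists(sidecar_file))
    stop("no sidecar.json found at this path", call. = FALSE)
  sc <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
  check_sidecar(sc)
  scanner <- scanner_profile(sc$b0_tesla,
                             if (!is.null(sc$gamma_mhz_t)) sc$gamma_mhz_t
                             else 42.577)
  n <- length(sc$offsets_ppm)
  read_img <- function(base, te, ts) {
    arr <- read_complex_volume(file.path(path, base))
    if (dim(arr)[2] != length(te))
      stop(sprintf("echo count of %s does not match sidecar", base),
           call. = FALSE)
    if (dim(arr)[1] != sc$n_channels)
      stop(sprintf("channel count of %s does not match sidecar", base),
           call. = FALSE)
    multi_coil_image(arr, te, ts)
  }
  sat_files <- list.files(path, pattern = "^sat_[0-9]+_real\\.nii\\.gz$")
  if (length(sat_files) != n)
    stop(sprintf("sidecar lists %d offsets but %d saturated volumes found",
                 n, length(sat_files)), call. = FALSE)
  sat <- lapply(seq_len(n), function(k)
    read_img(sprintf("sat_%03d", k), sc$te_s, sc$timestamps_s[k]))
  s0_ts <- if (!is.null(sc$s0_timestamp_s)) sc$s0_timestamp_s else 0
  s0 <- read_img("s0", sc$te_s, s0_ts)
  pre_te <- if (!is.null(sc$prescan_te_s)) sc$prescan_te_s else sc$te_s
  pre_ts <- if (!is.null(sc$prescan_timestamp_s)) sc$prescan_timestamp_s else 0
  prescan <- read_img("prescan", pre_te, pre_ts)
  nav <- NULL
  if (isTRUE(sc$has_nav)) {
    nav <- lapply(seq_len(n), function(k)
      read_img(sprintf("nav_%03d", k), sc$nav_te_s, sc$nav_timestamps_s[k]))
  }
  wassr <- NULL
  if (!is.null(sc$wassr)) {
    wm <- read_nifti_array(file.path(path, "wassr_mag.nii.gz"))
    ws <- read_nifti_array(file.path(path, "wassr_s0.nii.gz"))
    if (dim(wm)[3] != length(sc$wassr$offsets_ppm))
      stop("WASSR volume count does not match sidecar", call. = FALSE)
    wassr <- list(
      schedule = saturation_schedule(sc$wassr$offsets_ppm,
                                     sc$wassr$timestamps_s),
      magnitude = wm, s0 = matrix(ws, dim(wm)[1], dim(wm)[2]))
  }
  truth <- NULL
  if (!is.null(sc$truth)) {
    b0 <- read_nifti_array(file.path(path, "truth_b0.nii.gz"))
    b0 <- matrix(b0, dim(b0)[1], dim(b0)[2])
    cp <- aperm(as.array(RNifti::readNifti(
      file.path(path, "truth_coil_phase.nii.gz"))), c(3, 1, 2))
    cm <- aperm(as.array(RNifti::readNifti(
      file.path(path, "truth_coil_mag.nii.gz"))), c(3, 1, 2))
    supp_file <- file.path(path, "truth_support.nii.gz")
    supp <- if (file.exists(supp_file))
      as.array(RNifti::readNifti(supp_file)) > 0.5 else NULL
    if (!is.null(supp)) supp <- matrix(supp, nrow(b0), ncol(b0))
    cz <- NULL
    cz_file <- file.path(path, "truth_clean_z.nii.gz")
    if (file.exists(cz_file)) {
      czv <- read_nifti_array(cz_file)
      czs <- read_nifti_array(file.path(path, "truth_clean_s0.nii.gz"))
      cz <- z_stack(czv, sc$offsets_ppm,
                    matrix(czs, dim(czv)[1], dim(czv)[2]),
                    mask = supp, timestamps_s = sc$timestamps_s)
    }
    truth <- ground_truth(b0, sc$truth$drift_rate_hz_min, cp, cm,
                          clean_zstack = cz, support = supp,
                          noise_sd = sc$truth$noise_sd)
  }
  schedule <- saturation_schedule(sc$offsets_ppm, sc$timestamps_s)
  cest_acquisition(schedule, sat, s0, prescan, scanner,
                   nav_images = nav, wassr = wassr, truth = truth)
}

#' Write a field map or MTR-asymmetry map to NIfTI plus JSON metadata
#'
#' A [field_map_series()] is written as one NIfTI volume per map (stacked
#' along the third dimension) with units `"Hz"`; an [mtr_asym_map()] with
#' units `"%"`. A plain matrix requires an explicit `units` argument —
#' writing without units is refused.
#'
#' @param map A [field_map_series()], [mtr_asym_map()] or plain matrix.
#' @param path_base Output path without extension; `.nii.gz` and `.json`
#'   are appended.
#' @param units Units string, mandatory for plain matrices.
#' @return `path_base`, invisibly.
#' @export
write_map <- function(map, path_base, units = NULL) {
  meta <- list(format_version = SIDECAR_VERSION)
  if (inherits(map, "field_map_series")) {
    units <- if (is.null(units)) "Hz" else units
    arr <- array(unlist(map$values),
                 c(dim(map$values[[1]]), length(map$values)))
    meta$method_tag <- map$method_tag
    meta$timestamps_s <- map$timestamps
    meta$source_offsets_ppm <- map$source_offsets
    meta$low_confidence <- map$low_confidence
  } else if (inherits(map, "mtr_asym_map")) {
    units <- if (is.null(units)) "%" else units
    arr <- map$values
    meta$method_tag <- map$method_tag
    meta$range_ppm <- map$range
    meta$roi_mean <- map$roi_mean
    meta$roi_sd <- map$roi_sd
    meta$roi_n <- map$roi_n
  } else if (is.matrix(map)) {
    if (is.null(units))
      stop("units must be provided when writing a plain matrix", call. = FALSE)
    arr <- map
  } else stop("unsupported map object", call. = FALSE)
  if (any(is.infinite(arr)))
    stop("refusing to write infinite map values", call. = FALSE)
  meta$units <- units
  RNifti::writeNifti(arr, paste0(path_base, ".nii.gz"), datatype = "double")
  jsonlite::write_json(meta, paste0(path_base, ".json"), auto_unbox = TRUE,
                       digits = I(17), na = "null", pretty = TRUE)
  invisible(path_base)
}

#' Read a map written by [write_map()]
#'
#' @param path_base Path without extension.
#' @return A [field_map_series()], [mtr_asym_map()] or matrix, according to
#'   the stored metadata.
#' @export
read_map <- function(path_base) {
  meta <- jsonlite::read_json(paste0(path_base, ".json"),
                              simplifyVector = TRUE)
  if (is.null(meta$units)) stop("map metadata lacks units", call. = FALSE)
  arr <- as.array(RNifti::readNifti(paste0(path_base, ".nii.gz")))
  if (identical(meta$units, "Hz") && !is.null(meta$method_tag)) {
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    maps <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    field_map_series(maps, meta$timestamps_s, meta$method_tag,
                     source_offsets = if (is.null(meta$source_offsets_ppm))
                       NA_real_ else meta$source_offsets_ppm,
                     low_confidence = if (is.null(meta$low_confidence))
                       integer(0) else meta$low_confidence)
  } else if (identical(meta$units, "%") && !is.null(meta$range_ppm)) {
    mtr_asym_map(matrix(arr, dim(arr)[1], dim(arr)[2]), meta$range_ppm,
                 meta$method_tag,
                 roi_mean = meta$roi_mean %||% NA_real_,
                 roi_sd = meta$roi_sd %||% NA_real_,
                 roi_n = meta$roi_n %||% NA_integer_)
  } else {
    matrix(arr, dim(arr)[1], dim(arr)[2])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the arguments of [sim_config()]; nested blocks `scanner`,
#' `pools`, `train` and `wassr_train` map onto the corresponding
#' constructors. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$scanner)) args$scanner <- do.call(scanner_profile, cfg$scanner)
  if (!is.null(cfg$pools))
    args$pools <- pool_model(water = cfg$pools$water, solute = cfg$pools$solute)
  if (!is.null(cfg$train)) args$train <- do.call(pulse_train, cfg$train)
  if (!is.null(cfg$wassr_train))
    args$wassr_train <- do.call(pulse_train, cfg$wassr_train)
  plain <- setdiff(names(cfg), c("scanner", "pools", "train", "wassr_train"))
  allowed <- names(formals(sim_config))
  bad <- setdiff(plain, allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  args[plain] <- cfg[plain]
  if (!is.null(args$b0_coef)) args$b0_coef <- unlist(args$b0_coef)
  do.call(sim_config, args)
}
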