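#' Read an RGB micrograph from TIFF or PNG
#'
#' Reads an 8- or 16-bit RGB image into an [rgb_field()] with intensities
#' rescaled to `[0, 1]` (16-bit samples are scaled by 1/65535). The physical
#' pixel size is taken from a JSON sidecar `<path>.json` (key `pixel_size`)
#' when present, otherwise from the `pixel_size` argument.
#'
#' @param path image file path (TIFF or PNG).
#' @param pixel_size default um/px when no sidecar is found.
#' @param field_id identifier; defaults to the file name.
#' @return An [rgb_field()].
#' @export
read_rgb_image <- function(path, pixel_size = 1, field_id = NULL) {
  if (!file.exists(path)) stop_ihc(sprintf("file not found: %s", path), "ihcquant_io_error")
  img <- tryCatch(EBImage::readImage(path), error = function(e) {
    stop_ihc(sprintf("unreadable image %s: %s", path, conditionMessage(e)),
             "ihcquant_io_error")
  })
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) != 3 || dim(dat)[3] != 3) {
    stop_ihc(sprintf(
      "%s is not an RGB image: a 3-channel (RGB) TIFF or PNG is required", path
    ), "ihcquant_io_error")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$pixel_size)) pixel_size <- as.numeric(meta$pixel_size)
  }
  # EBImage stores images x-major; rgb_field is row (H) x column (W) x channel
  rgb_field(clip01(aperm(dat, c(2, 1, 3))), pixel_size = pixel_size,
            field_id = field_id %||% basename(path))
}

#' Write an RGB micrograph to TIFF or PNG
#'
#' @param field an [rgb_field()].
#' @param path output path; format follows the extension (`.tif`/`.tiff` or
#'   `.png`).
#' @param bits bits per sample for TIFF output (8 or 16; PNG is 8-bit).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(field, path, bits = 8) {
  assert_rgb_field(field, "field")
  if (!bits %in% c(8, 16)) stop_ihc("`bits` must be 8 or 16", "ihcquant_io_error")
  img <- EBImage::Image(aperm(field$pixels, c(2, 1, 3)), colormode = "Color")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(img, path, type = "tiff", bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    EBImage::writeImage(img, path, type = "png")
  } else {
    stop_ihc("unsupported image format: use .tif/.tiff or .png", "ihcquant_io_error")
  }
  invisible(path)
}

#' Write a ground-truth mask with its JSON sidecar
#'
#' The mask is written as a single-channel 0/255 PNG; the sidecar
#' `<path>.json` records the realized fraction, object count and (optionally)
#' the generating seed and config echo.
#'
#' @param truth a [ground_truth()].
#' @param path output PNG path.
#' @param config optional [synth_ihc_config()] echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, config = NULL) {
  if (!inherits(truth, "ground_truth")) {
    stop_ihc("`truth` must be a ground_truth object", "ihcquant_bad_input")
  }
  img <- EBImage::Image(t(matrix(as.numeric(truth$mask),
                                 nrow(truth$mask), ncol(truth$mask))))
  EBImage::writeImage(img, path, type = "png")
  meta <- list(
    realized_fraction = truth$realized_fraction,
    object_count = truth$object_count
  )
  if (!is.null(config)) {
    meta$seed <- config$seed
    meta$config <- unclass(config)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# CSV schemas shared by the generators and readers; every quantity carries its
# unit in the column name -- no silent unit coercion.
.table_schemas <- list(
  dose_response = list(
    cols = c("cell_line", "dose_uM", "replicate", "count"),
    nonneg = c("dose_uM", "count")
  ),
  ldh = list(
    cols = c("condition", "time_h", "released", "total"),
    nonneg = c("time_h", "released"),
    positive = "total"
  ),
  tumor = list(
    cols = c("group", "mouse", "day", "R1_mm", "R2_mm"),
    positive = c("R1_mm", "R2_mm")
  ),
  colonies = list(
    cols = c("dose_uM", "well", "count"),
    nonneg = c("dose_uM", "count")
  )
)

#' Read and validate an assay CSV table
#'
#' Reads one of the package's CSV schemas (`dose_response`, `ldh`, `tumor`,
#' `colonies`), checks that the expected unit-suffixed columns are present and
#' that doses/radii/signals are in range, reports the row count, and -- for
#' caliper tables -- warns about rows with `R1_mm > R2_mm` (accepted;
#' [tumor_volume()] canonicalizes by sorting).
#'
#' @param path CSV file path.
#' @param schema one of `"dose_response"`, `"ldh"`, `"tumor"`, `"colonies"`.
#' @return A validated tibble.
#' @export
read_assay_table <- function(path, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  spec <- .table_schemas[[schema]]
  if (!file.exists(path)) stop_ihc(sprintf("file not found: %s", path), "ihcquant_io_error")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(spec$cols, names(tab))
  if (length(miss)) {
    stop_ihc(sprintf("%s is missing required column(s): %s",
                     basename(path), paste(miss, collapse = ", ")),
             "ihcquant_io_error")
  }
  for (col in spec$nonneg %||% character()) {
    if (any(tab[[col]] < 0, na.rm = TRUE)) {
      stop_ihc(sprintf("negative values in column `%s`", col), "ihcquant_io_error")
    }
  }
  for (col in spec$positive %||% character()) {
    if (any(tab[[col]] <= 0, na.rm = TRUE)) {
      stop_ihc(sprintf("non-positive values in column `%s`", col), "ihcquant_io_error")
    }
  }
  if (schema == "tumor" && any(tab$R1_mm > tab$R2_mm)) {
    rlang::warn(sprintf(
      "%d caliper row(s) have R1_mm > R2_mm; accepted, radii are canonicalized downstream",
      sum(tab$R1_mm > tab$R2_mm)
    ), class = "ihcquant_canonicalized")
  }
  rlang::inform(sprintf("read %d row(s) from %s [%s]", nrow(tab), basename(path), schema))
  tab
}

#' Run configuration
#'
#' Serializable configuration of an end-to-end [run_pipeline()] run: master
#' seed, per-assay generator settings, segmentation tunables and statistics
#' options. All fields are plain values so that `load_run_config(save_run_config(x))`
#' reproduces `x` exactly.
#'
#' @param seed master seed; per-stage seeds are derived deterministically so
#'   stages can be rerun independently.
#' @param ihc,dose_response,ldh,tumor,colonies per-stage settings; partial
#'   lists are merged over the defaults.
#' @param segmentation overrides for [segmentation_config()] fields.
#' @param stats statistics options (`welch`).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1,
                       ihc = list(), dose_response = list(), ldh = list(),
                       tumor = list(), colonies = list(),
                       segmentation = list(), stats = list(),
                       log_level = "info") {
  defaults <- list(
    ihc = list(preset = "ki67-fig3c", n_fields_per_group = 3L,
               width = 256L, height = 256L, write_images = FALSE),
    dose_response = list(cell_line = "PC3", bottom = 0, top = 1000,
                         ec50 = 1.24, hill = -1.5,
                         doses = c(0, 0.1, 0.3, 1, 3, 10, 15),
                         cv = 0.05, n_reps = 3L),
    ldh = list(preset = "ldh-fig4a", timepoints = c(0.5, 3, 24, 48)),
    tumor = list(preset = "tumor-fig3a", n_mice_per_group = 8L,
                 n_timepoints = 10L),
    colonies = list(preset = "colony-fig1b", n_wells = 6L),
    segmentation = list(),
    stats = list(welch = FALSE)
  )
  merge1 <- function(base, user) utils::modifyList(base, as.list(user))
  structure(
    list(
      seed = as.integer(seed),
      ihc = merge1(defaults$ihc, ihc),
      dose_response = merge1(defaults$dose_response, dose_response),
      ldh = merge1(defaults$ldh, ldh),
      tumor = merge1(defaults$tumor, tumor),
      colonies = merge1(defaults$colonies, colonies),
      segmentation = as.list(segmentation),
      stats = merge1(defaults$stats, stats),
      log_level = log_level
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) {
    stop_ihc("`config` must be a run_config", "ihcquant_bad_input")
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_ihc(sprintf("file not found: %s", path), "ihcquant_io_error")
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}
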