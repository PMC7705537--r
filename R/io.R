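TRACE_SCHEMA_VERSION <- 1L

#' Read a grayscale video
#'
#' Accepts a multi-page TIFF file or a directory of numbered PNG/TIFF
#' frames (sorted by file name). Pixels are returned in `[0, 1]`; 16-bit
#' TIFFs keep their native quantization (values are n / 65535). Color input
#' is averaged to grayscale. AVI is not supported; convert to an image
#' sequence first.
#'
#' @param path file or directory path
#' @return list of intensity matrices
#' @export
read_video <- function(path) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    a
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    return(lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) to_gray(png::readPNG(f))
      else to_gray(tiff::readTIFF(f))
    }))
  }
  if (!file.exists(path)) stop("video source not found: ", path)
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("AVI input is not supported; export the video as a multi-page ",
         "TIFF or a PNG/TIFF frame directory")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, to_gray)
}

#' Write frames as a multi-page TIFF
#'
#' @param frames list of intensity matrices in `[0, 1]`
#' @param path output file
#' @param bits 8 or 16
#' @export
write_video <- function(frames, path, bits = 8) {
  stopifnot(bits %in% c(8, 16))
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f, 0), 1)),
                  path, bits.per.sample = bits)
  invisible(path)
}

#' Write a trace table
#'
#' Flat CSV with a versioned header; lossless round-trip via
#' [read_traces()]. Angles are stored in radians.
#'
#' @param trace a trace table (data frame `frame`, `identity`, `rho`,
#'   `theta`, `b`, `L`, `rss`, `status`, `valid`)
#' @param path output file
#' @param fps frames per second recorded in the header
#' @param provenance free-text provenance string
#' @export
write_traces <- function(trace, path, fps = NA_real_,
                         provenance = "whisktrace") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#whisktrace-trace v%d", TRACE_SCHEMA_VERSION),
               sprintf("#fps=%s", format(fps, digits = 17)),
               sprintf("#provenance=%s", provenance)), con)
  write.csv(trace, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace table
#'
#' Rejects files with an unknown schema version.
#'
#' @param path file written by [write_traces()] (or any CSV with the
#'   documented columns preceded by the version header)
#' @return the trace table; attributes `fps` and `provenance` carry the
#'   header fields
#' @export
read_traces <- function(path) {
  hdr <- readLines(path, n = 3)
  m <- regmatches(hdr[1], regexec("^#whisktrace-trace v(\\d+)$", hdr[1]))[[1]]
  if (length(m) < 2) stop("not a trace file: ", path)
  ver <- as.integer(m[2])
  if (ver != TRACE_SCHEMA_VERSION)
    stop("unsupported trace schema version: ", ver)
  out <- read.csv(path, skip = 3)
  attr(out, "fps") <- as.numeric(sub("^#fps=", "", hdr[2]))
  attr(out, "provenance") <- sub("^#provenance=", "", hdr[3])
  out
}

#' Default run configuration
#'
#' Nested list mirroring the YAML run-configuration schema; every module's
#' tunables with their defaults. [load_run_config()] merges a user file over
#' these values and rejects unknown keys.
#'
#' @return nested configuration list
#' @export
default_run_config <- function() {
  list(
    source = list(path = NULL, invert = FALSE),
    snout = list(p0 = c(80, 1), p1 = c(80, 480), side = c(300, 240)),
    background = list(n_samples = 20),
    silhouette = list(threshold = NULL, open_radius = 2, dilate_radius = 3,
                      max_fraction = 0.5),
    centerline = list(sigma = 1.5, min_strength = NULL,
                      threshold_method = "fraction", quantile = NULL),
    cluster = list(method = "dbscan", dbscan_eps = 2.5, dbscan_min_pts = 3,
                   steger_angle_tol_deg = 45, stitch_fit_len = 20,
                   stitch_max_dist = 3, stitch_max_gap = 30,
                   stitch_max_angle_deg = 30, min_whisker_len = 40,
                   snout_attach_dist = 10),
    fit = list(max_iter = 100, tol = 1e-8, max_rms = 1),
    track = list(bootstrap_len = 50, s = 25, W = 2000,
                 max_train_per_class = 200, min_train_samples = 20,
                 assign_max_cost = 3, max_dtheta_deg = 10, max_drho = 15,
                 max_coast = 100, svm_cost = 1),
    output = list(dir = NULL),
    fps = 1000,
    seed = 1
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".", key)))
    if (is.list(base[[key]]) && is.list(user[[key]]) &&
        !is.null(names(base[[key]])))
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(path, ".", key))
    else base[key] <- user[key]
  }
  base
}

#' Load and validate a YAML run configuration
#'
#' @param path YAML file; keys must exist in [default_run_config()]
#' @return validated configuration list
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user)
}
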