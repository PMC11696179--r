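## Plain-format readers and writers: 16-bit grayscale TIFF for images, CSV
## for FRAP traces and sensorgrams, JSON/YAML for experiment configs.

#' Write a nucleus image as 16-bit grayscale TIFF
#'
#' Intensities are stored as 16-bit counts (values are clipped to
#' `[0, 65535]`); the pixel size is not stored in the file and must be
#' supplied again on reading.
#'
#' @param image a [NucleusImage-class] or numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNucleusTiff <- function(image, path) {
  im <- if (is(image, "NucleusImage")) intensities(image) else as.matrix(image)
  im <- pmin(pmax(im, 0), 65535) / 65535
  tiff::writeTIFF(im, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a (possibly multi-page) grayscale TIFF
#'
#' @param path TIFF file; multi-page files yield one image per page.
#' @param pixelSize micrometres per pixel to attach.
#' @param channel channel label to attach.
#' @return A [NucleusImage-class], or a list of them for a multi-page file.
#' @export
readNucleusTiff <- function(path, pixelSize = 0.1, channel = "GFP") {
  pages <- tiff::readTIFF(path, all = TRUE)
  imgs <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    NucleusImage(p * 65535, pixelSize = pixelSize, channel = channel)
  })
  if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' Write / read a FRAP trace as CSV
#'
#' Columns: `time`, `bleach_roi`, `reference_roi`, `prebleach` (0/1 flag).
#'
#' @param trace a [FrapTrace-class].
#' @param path CSV file.
#' @return `path` invisibly (write) or a [FrapTrace-class] (read).
#' @export
writeFrapCsv <- function(trace, path) {
  stopifnot(is(trace, "FrapTrace"))
  df <- data.frame(time = trace@times,
                   bleach_roi = trace@bleachRoi,
                   reference_roi = trace@referenceRoi,
                   prebleach = as.integer(seq_along(trace@times) <=
                                            trace@prebleachFrames))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrapCsv
#' @export
readFrapCsv <- function(path) {
  df <- read.csv(path)
  need <- c("time", "bleach_roi", "reference_roi")
  if (!all(need %in% names(df))) {
    stop("FRAP CSV must have columns: ", paste(need, collapse = ", "))
  }
  pre <- if ("prebleach" %in% names(df)) sum(df$prebleach == 1L) else 1L
  FrapTrace(df$time, df$bleach_roi, df$reference_roi,
            prebleachFrames = max(pre, 1L))
}

#' Write / read a sensorgram set as CSV
#'
#' Long format with columns `time`, `response`, `concentration` (molar) and
#' `phase` (`association` / `dissociation`).
#'
#' @param sensorgrams a list of [Sensorgram-class] objects.
#' @param path CSV file.
#' @return `path` invisibly (write) or a list of [Sensorgram-class] (read).
#' @export
writeSensorgramCsv <- function(sensorgrams, path) {
  if (is(sensorgrams, "Sensorgram")) sensorgrams <- list(sensorgrams)
  df <- do.call(rbind, lapply(sensorgrams, function(sg) {
    data.frame(time = sg@times, response = sg@response,
               concentration = sg@analyteConcentration,
               phase = ifelse(sg@times <= sg@phaseBoundary,
                              "association", "dissociation"))
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSensorgramCsv
#' @export
readSensorgramCsv <- function(path) {
  df <- read.csv(path)
  need <- c("time", "response", "concentration")
  if (!all(need %in% names(df))) {
    stop("sensorgram CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$concentration), function(d) {
    pb <- if ("phase" %in% names(d) && any(d$phase == "association")) {
      max(d$time[d$phase == "association"])
    } else 60
    Sensorgram(d$time, d$response, d$concentration[1], phaseBoundary = pb)
  })
}

#' Read an experiment configuration (JSON or YAML)
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
readExperimentConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext)
  }
}

#' Write an experiment report
#'
#' Serialises a report list (as returned by the `run*Experiment()`
#' functions) as `report.json`, plus a CSV for any data-frame element.
#'
#' @param report a report list.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dfs <- names(report)[vapply(report, is.data.frame, logical(1))]
  for (nm in dfs) {
    write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  scalarish <- report[setdiff(names(report), dfs)]
  jsonlite::write_json(scalarish, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read line-ROI definitions
#'
#' Loads line ROIs for profile extraction from CSV or JSON with fields
#' `x0, y0, x1, y1` (0-based pixel coordinates) and optional `width_um`
#' (default 3).
#'
#' @param path `.csv` or `.json` file.
#' @return A data frame with columns `x0, y0, x1, y1, width_um`.
#' @export
readLineRois <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    read.csv(path)
  } else if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    stop("unsupported ROI format: .", ext)
  }
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(df))) {
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$width_um)) df$width_um <- 3
  df[, c(need, "width_um")]
}
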