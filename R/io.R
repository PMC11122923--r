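## Delimited-text readers/writers. All tables are TAB-separated with an exact
## header; curve files carry the device area in commented metadata lines.

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "File %s is missing required column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
}

#' Read and write filtration-curve files
#'
#' One file per device run: `# area_mm2:` and `# label:` metadata lines
#' followed by a tab-separated table with columns `time_s`, `volume_uL`.
#'
#' @param path File path.
#' @return `read_filtration_curve()` returns a [filtration_curve()].
#' @export
read_filtration_curve <- function(path) {
  if (!file.exists(path)) abort(sprintf("Curve file not found: %s", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  area_line <- grep("^#\\s*area_mm2:", meta, value = TRUE)
  if (length(area_line) != 1) {
    abort(sprintf("File %s must contain exactly one '# area_mm2:' header line.", path))
  }
  area <- as.numeric(sub("^#\\s*area_mm2:\\s*", "", area_line))
  if (is.na(area)) abort(sprintf("File %s: unparseable area in '%s'.", path, area_line))
  label_line <- grep("^#\\s*label:", meta, value = TRUE)
  label <- if (length(label_line) == 1) sub("^#\\s*label:\\s*", "", label_line) else ""
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], check.names = FALSE)
  .check_columns(df, c("time_s", "volume_uL"), path)
  filtration_curve(df$time_s, df$volume_uL, area_mm2 = area, label = label)
}

#' @rdname read_filtration_curve
#' @param curve A [filtration_curve()] to write.
#' @export
write_filtration_curve <- function(curve, path) {
  area <- curve_area(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# area_mm2: %.10g", area), con)
  writeLines(sprintf("# label: %s", attr(curve, "label") %||% ""), con)
  utils::write.table(curve[, c("time_s", "volume_uL")], con,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write calibration tables
#'
#' Tab-separated, columns `area_mm2`, `vq_uL`, optional `replicate`.
#'
#' @param path File path.
#' @return `read_calibration()` returns a [calibration_set()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("Calibration file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE)
  .check_columns(df, c("area_mm2", "vq_uL"), path)
  calibration_set(df$area_mm2, df$vq_uL, replicate = df$replicate)
}

#' @rdname read_calibration
#' @param cal A [calibration_set()] to write.
#' @export
write_calibration <- function(cal, path) {
  utils::write.table(as.data.frame(cal), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cell-count tables
#'
#' Tab-separated, columns `replicate`, `sample_point`, `cells`, `volume_uL`.
#'
#' @param path File path.
#' @return `read_counts()` returns a tibble.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("Count file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE)
  .check_columns(df, c("replicate", "sample_point", "cells", "volume_uL"), path)
  tibble::as_tibble(df)
}

#' @rdname read_counts
#' @param counts A count table to write.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a fitted filtration model as a small YAML file
#'
#' Stores k, ve and q_th together with their units and (when written from a
#' `filtration_fit`) the fit metadata, so that design runs are reproducible
#' without refitting.
#'
#' @param x A [filtration_model()] or `filtration_fit`.
#' @param path File path.
#' @return `read_model()` returns a [filtration_model()] with any stored fit
#'   metadata in the `"fit_meta"` attribute.
#' @export
write_model <- function(x, path) {
  if (inherits(x, "filtration_fit")) {
    meta <- list(
      type = x$type, rms_error = x$rms_error,
      converged = x$converged, n_iter = x$n_iter, nobs = nrow(x$data)
    )
    x <- x$model
  } else {
    meta <- NULL
  }
  stopifnot(inherits(x, "filtration_model"))
  yaml::write_yaml(list(
    k = x$k, ve = x$ve, q_th = x$q_th,
    units = list(k = "uL^2 mm^-4 min^-1", ve = "uL", q_th = "1/min"),
    fit = meta
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  y <- yaml::read_yaml(path)
  for (fld in c("k", "ve", "q_th")) {
    if (is.null(y[[fld]])) abort(sprintf("Model file %s is missing field `%s`.", path, fld))
  }
  m <- filtration_model(k = y$k, ve = y$ve, q_th = y$q_th)
  attr(m, "fit_meta") <- y$fit
  m
}

#' Write a design report table
#'
#' Tab-separated table with columns `target_uL`, `area_mm2`, `predicted_uL`,
#' `rel_error`, `feasible`, `reason`.
#'
#' @param report A tibble from [design_report()].
#' @param path File path.
#' @export
write_design_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", row.names = FALSE, quote = TRUE)
  invisible(path)
}
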