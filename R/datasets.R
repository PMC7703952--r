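#' Plate-reader time-series dataset
#'
#' A light container for one well's time course: observation times,
#' values in either raw relative fluorescence units (`"RFU"`) or reporter
#' concentration (`"uM"`, after conversion through a standard curve), the
#' exposure concentration applied at `t = 0`, and a free-text label.
#'
#' @param times Observation times, seconds, strictly increasing.
#' @param values Measurements, same length as `times`, finite.
#' @param unit `"RFU"` or `"uM"`.
#' @param c_tot Exposure concentration, uM (non-negative).
#' @param label Free-text description.
#' @return An object of class `rsw_timeseries`: a data frame with columns
#'   `time_s` and `value`, plus `unit`, `c_tot` and `label` attributes.
#' @export
riboswitch_timeseries <- function(times, values, unit = c("uM", "RFU"),
                                  c_tot = 0, label = "") {
  unit <- match.arg(unit)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  if (!is.numeric(c_tot) || length(c_tot) != 1L || c_tot < 0)
    stop("'c_tot' must be a single non-negative concentration",
         call. = FALSE)
  structure(data.frame(time_s = as.numeric(times),
                       value = as.numeric(values)),
            class = c("rsw_timeseries", "data.frame"),
            unit = unit, c_tot = c_tot, label = as.character(label)[1])
}

#' @export
print.rsw_timeseries <- function(x, ...) {
  cat("Riboswitch time series '", attr(x, "label"), "': ", nrow(x),
      " points, unit = ", attr(x, "unit"), ", exposure = ",
      format(attr(x, "c_tot")), " uM\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more rows\n")
  invisible(x)
}

#' Read / write a time-series CSV
#'
#' Files carry the data as `time_s,rfu` or `time_s,p_uM` (the column name
#' encodes the unit) preceded by `#`-prefixed metadata lines, e.g.
#' `# exposure_c_tot_uM=44` and `# label=exposed well`.
#'
#' @param path File path.
#' @param x An [rsw_timeseries][riboswitch_timeseries].
#' @return `read_timeseries_csv` returns an `rsw_timeseries`;
#'   `write_timeseries_csv` returns `path` invisibly.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(c_tot = 0, label = "")
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "exposure_c_tot_uM") meta$c_tot <- as.numeric(val)
      if (key == "label") meta$label <- val
    }
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  if (!"time_s" %in% names(df))
    stop("missing 'time_s' column in ", path, call. = FALSE)
  vcol <- intersect(c("rfu", "p_uM"), names(df))
  if (length(vcol) != 1L)
    stop("expected exactly one of 'rfu' or 'p_uM' in ", path, call. = FALSE)
  riboswitch_timeseries(df$time_s, df[[vcol]],
                        unit = if (vcol == "rfu") "RFU" else "uM",
                        c_tot = meta$c_tot, label = meta$label)
}

#' @rdname read_timeseries_csv
#' @export
write_timeseries_csv <- function(x, path) {
  stopifnot(inherits(x, "rsw_timeseries"))
  vcol <- if (attr(x, "unit") == "RFU") "rfu" else "p_uM"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# exposure_c_tot_uM=", attr(x, "c_tot")),
               paste0("# label=", attr(x, "label")),
               paste0("time_s,", vcol)), con)
  utils::write.table(as.data.frame(x), con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: fitters work in concentration units only
require_uM <- function(data, caller) {
  stopifnot(inherits(data, "rsw_timeseries"))
  if (attr(data, "unit") != "uM")
    stop(caller, "() needs concentrations in uM; convert RFU data first ",
         "with rfu_to_concentration()", call. = FALSE)
  invisible(data)
}
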