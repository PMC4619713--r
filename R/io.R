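#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text ESRI ASCII grid export for depth, backscatter, slope, p-hard
#' or class-code layers (row 1 of the matrix is written last, as the format
#' stores the top row first).
#'
#' @param m numeric matrix (row 1 = southernmost row).
#' @param file output path.
#' @param cell_size cell edge in metres.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_esri_ascii <- function(m, file, cell_size, xll = 0, yll = 0,
                             nodata = -9999) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", xll),
               paste("yllcorner", yll),
               paste("cellsize", cell_size),
               paste("NODATA_value", nodata)), con)
  m[is.na(m)] <- nodata
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(file)
}

#' Read an ESRI ASCII raster
#'
#' @param file path to an ESRI ASCII grid.
#' @return List with `values` (matrix, row 1 = southernmost row),
#'   `cell_size`, `xll`, `yll`.
#' @export
read_esri_ascii <- function(file) {
  hdr <- readLines(file, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1])
  val <- as.numeric(kv[, 2])
  ncols <- val[key == "ncols"]; nrows <- val[key == "nrows"]
  cs <- val[key == "cellsize"]
  nodata <- if (any(key == "nodata_value")) val[key == "nodata_value"] else NA
  body <- scan(file, skip = 6, quiet = TRUE)
  m <- matrix(body, nrows, ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]
  if (!is.na(nodata)) m[m == nodata] <- NA
  list(values = m, cell_size = cs,
       xll = val[key == "xllcorner"], yll = val[key == "yllcorner"])
}

#' Read a sampling frame from CSV
#'
#' Expects columns `unit_id`, `x`, `y` and optionally `pi` and `class`.
#'
#' @param file CSV path.
#' @return A [sampling_frame()].
#' @export
read_frame_csv <- function(file) {
  d <- utils::read.csv(file, comment.char = "#")
  sampling_frame(d$x, d$y, pi = d$pi, unit_id = d$unit_id, class = d$class)
}

# short deterministic hash of a configuration, for output provenance headers
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) h <- (bitwXor(as.integer(h %% 2^31), x) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

# CSV writer with provenance comment lines
write_result_csv <- function(d, file, cfg = NULL, seed = NA) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# benthoscape output; config_hash=%s; seed=%s",
                     if (is.null(cfg)) "none" else config_hash(cfg),
                     as.character(seed)), con)
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
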