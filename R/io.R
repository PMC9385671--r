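#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled to [0, 1]; the
#' scaling factor, the physical metadata and an optional ground-truth
#' manifest go into `<path>.json`, so [readMovieTIFF] restores the movie in
#' original intensity units.
#'
#' @param movie an [FtsZMovie-class].
#' @param path output TIFF path.
#' @param truth optional ground-truth manifest (e.g. from [makeRingMovie]).
#' @return invisibly, the sidecar path.
#' @export
writeMovieTIFF <- function(movie, path, truth = NULL) {
  scale <- max(movie@stack, 1e-12)
  pages <- lapply(seq_len(nFrames(movie)),
                  function(t) movie@stack[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- paste0(path, ".json")
  meta <- list(pixel_size_nm = movie@pixelSizeNm,
               frame_interval_s = movie@frameIntervalS,
               intensity_scale = scale)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a movie from multi-page TIFF (+ JSON sidecar)
#'
#' Reads 8/16-bit integer or 32-bit float multi-page TIFF. When a
#' `<path>.json` sidecar exists its pixel size, frame interval and
#' intensity scale are applied; otherwise they must be supplied.
#'
#' @param path TIFF path.
#' @param pixelSizeNm,frameIntervalS metadata fallbacks when no sidecar is
#'   present.
#' @return list with `movie` ([FtsZMovie-class]) and `truth` (manifest or
#'   NULL).
#' @export
readMovieTIFF <- function(path, pixelSizeNm = NULL, frameIntervalS = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  truth <- NULL; scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixelSizeNm <- meta$pixel_size_nm
    frameIntervalS <- meta$frame_interval_s
    scale <- meta$intensity_scale
    truth <- meta$truth
  }
  if (is.null(pixelSizeNm) || is.null(frameIntervalS))
    stop("no sidecar found: supply pixelSizeNm and frameIntervalS")
  stack <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) stack[t, , ] <- pages[[t]] * scale
  list(movie = FtsZMovie(stack, pixelSizeNm, frameIntervalS), truth = truth)
}

#' Write / read a kymograph as CSV
#'
#' Plain-text round trip: metadata in `#`-prefixed header lines, then the
#' time x arclength matrix (rows = frames).
#'
#' @param kymo a [Kymograph-class].
#' @param path CSV path.
#' @return invisibly `path` (write); a [Kymograph-class] (read).
#' @export
writeKymographCSV <- function(kymo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arcStepPx=%.10g frameIntervalS=%.10g radiusPx=%.10g pixelSizeNm=%.10g",
                     kymo@arcStepPx, kymo@frameIntervalS, kymo@radiusPx,
                     kymo@pixelSizeNm), con)
  utils::write.table(kymoData(kymo), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeKymographCSV
#' @export
readKymographCSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[A-Za-z]+=[-0-9.eE+]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  K <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(K) <- NULL
  Kymograph(K, arcStepPx = meta[["arcStepPx"]],
            frameIntervalS = meta[["frameIntervalS"]],
            radiusPx = meta[["radiusPx"]], pixelSizeNm = meta[["pixelSizeNm"]])
}

#' Read / write FRAP traces as CSV
#'
#' Columns `time`, `bleached`, `reference`; rows with `time < 0` are
#' pre-bleach samples used for the normalization anchors.
#'
#' @param path CSV path.
#' @param trace a [FRAPTrace-class] (write).
#' @return a [FRAPTrace-class] (read); invisibly `path` (write).
#' @export
readFrapTraceCSV <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time", "bleached", "reference") %in% names(d)))
  FRAPTrace(d$time, d$bleached, d$reference)
}

#' @rdname readFrapTraceCSV
#' @export
writeFrapTraceCSV <- function(trace, path) {
  utils::write.csv(data.frame(time = trace@time, bleached = trace@bleached,
                              reference = trace@reference),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an NMR titration table
#'
#' CSV with columns `pH` and `delta` (chemical shift, ppm).
#'
#' @param path CSV path.
#' @return data.frame with `pH`, `delta`.
#' @export
readTitrationCSV <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("pH", "delta") %in% names(d)))
  d[, c("pH", "delta")]
}

#' Read filament centerline traces
#'
#' Two plain-text formats: (1) CSV with columns `filament`, `x_nm`, `y_nm`
#' (point order = row order within each filament); (2) SOAX-style snake
#' export (`format = "soax"`): whitespace-separated numeric rows whose
#' first column is the snake id and whose 3rd/4th columns are x/y in
#' pixels, converted to nm via `pixelSizeNm`; non-numeric lines are
#' skipped.
#'
#' @param path input path.
#' @param format `"csv"` or `"soax"`.
#' @param pixelSizeNm pixel size for SOAX pixel coordinates.
#' @return list of n x 2 matrices (columns x, y in nm), one per filament.
#' @export
readFilamentTraces <- function(path, format = c("csv", "soax"),
                               pixelSizeNm = 65) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- utils::read.csv(path)
    stopifnot(all(c("filament", "x_nm", "y_nm") %in% names(d)))
    lapply(split(d, d$filament),
           function(g) cbind(x = g$x_nm, y = g$y_nm))
  } else {
    lines <- readLines(path)
    rows <- lapply(strsplit(trimws(lines), "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f))
      if (length(v) >= 4 && !anyNA(v[1:4])) v else NULL
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(rows)) return(list())
    lapply(split(seq_len(nrow(rows)), rows[, 1]), function(i)
      cbind(x = rows[i, 3] * pixelSizeNm, y = rows[i, 4] * pixelSizeNm))
  }
}
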