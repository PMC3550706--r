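#' Polar IVOCT pullback container
#'
#' A pullback is an ordered stack of polar frames acquired while the imaging
#' catheter is withdrawn. Frames are stored as a 3D integer array indexed
#' `[aline, depth, frame]`: rows are A-lines (the angular axis, wrapping so
#' that row 1 neighbours row `n_alines`), columns are depth samples with the
#' catheter at column 1.
#'
#' @param data 3D numeric array `[n_alines, n_depth, n_frames]` of
#'   non-negative intensities representable in 16 bits, or a list of
#'   identically shaped matrices.
#' @param pixel_size_mm Optional physical depth-pixel size in mm.
#' @return An object of class `"oct_pullback"` with elements `data`,
#'   `n_alines`, `n_depth`, `n_frames`, `pixel_size_mm`.
#' @export
oct_pullback <- function(data, pixel_size_mm = 0.005) {
  if (is.list(data)) {
    shapes <- unique(lapply(data, dim))
    if (length(shapes) != 1L)
      stop("all frames must share an identical (n_alines, n_depth) shape")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(shapes[[1]], length(data)))
  }
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array or list of matrices")
  if (anyNA(data) || min(data) < 0 || max(data) > 65535)
    stop("intensities must be non-negative and representable in 16 bits")
  storage.mode(data) <- "integer"
  structure(
    list(data = data,
         n_alines = dim(data)[1], n_depth = dim(data)[2],
         n_frames = dim(data)[3], pixel_size_mm = pixel_size_mm),
    class = "oct_pullback"
  )
}

#' @export
print.oct_pullback <- function(x, ...) {
  cat(sprintf(
    "IVOCT polar pullback: %d frame(s) of %d A-lines x %d depth samples\n",
    x$n_frames, x$n_alines, x$n_depth))
  cat(sprintf("  intensity range [%d, %d]; depth pixel %s mm\n",
              min(x$data), max(x$data),
              format(x$pixel_size_mm)))
  invisible(x)
}

#' Extract one frame of a pullback
#'
#' @param pullback An `"oct_pullback"`.
#' @param i Frame index (1-based).
#' @return An integer matrix `[aline, depth]`.
#' @export
get_frame <- function(pullback, i) {
  stopifnot(inherits(pullback, "oct_pullback"),
            i >= 1, i <= pullback$n_frames)
  pullback$data[, , i, drop = TRUE]
}

#' Read a polar pullback from disk
#'
#' Two on-disk layouts are supported: a multipage 16-bit grayscale TIFF
#' stack (one page per frame, rows = A-lines), or headerless raw binary
#' with a YAML sidecar describing the shape. The sidecar (default
#' `<path>.yaml`) must define `n_frames`, `n_alines`, `n_depth` and may set
#' `dtype` (`uint16`/`uint8`) and `byte_order` (`little`/`big`). Raw frames
#' are stored depth-fastest (row-major within a frame).
#'
#' @param path File path.
#' @param format `"tiff_stack"` or `"raw_binary"`; `"auto"` picks by file
#'   extension (`.tif`/`.tiff` vs anything else).
#' @param sidecar Sidecar path for raw binary input.
#' @param pixel_size_mm Physical depth pixel size recorded on the result.
#' @return An `"oct_pullback"`; pixel values are preserved bit-exactly.
#' @export
read_pullback <- function(path, format = c("auto", "tiff_stack", "raw_binary"),
                          sidecar = paste0(path, ".yaml"),
                          pixel_size_mm = 0.005) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "raw_binary"
  }
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(m) {
      if (length(dim(m)) == 3L) {
        if (dim(m)[3] != 1L)
          stop("multi-channel TIFF is not a grayscale polar stack")
        m <- m[, , 1]
      }
      m
    })
    return(oct_pullback(pages, pixel_size_mm = pixel_size_mm))
  }
  if (!file.exists(sidecar))
    stop("raw binary input requires a YAML sidecar: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  need <- c("n_frames", "n_alines", "n_depth")
  if (!all(need %in% names(meta)))
    stop("sidecar must define n_frames, n_alines and n_depth")
  dtype <- if (is.null(meta$dtype)) "uint16" else meta$dtype
  if (!dtype %in% c("uint16", "uint8"))
    stop("non-16-bit input requires dtype 'uint16' or 'uint8', got: ", dtype)
  endian <- if (is.null(meta$byte_order)) "little" else meta$byte_order
  if (!endian %in% c("little", "big")) stop("byte_order must be little or big")
  bytes_per <- if (dtype == "uint16") 2L else 1L
  n <- meta$n_frames * meta$n_alines * meta$n_depth
  expected <- n * bytes_per
  actual <- file.info(path)$size
  if (actual != expected)
    stop(sprintf("shape mismatch: sidecar implies %d bytes, file has %d",
                 expected, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "integer", n = n, size = bytes_per,
               signed = FALSE, endian = endian)
  # depth-fastest on disk -> fill a [depth, aline, frame] array and flip
  arr <- array(v, dim = c(meta$n_depth, meta$n_alines, meta$n_frames))
  arr <- aperm(arr, c(2, 1, 3))
  oct_pullback(arr, pixel_size_mm = pixel_size_mm)
}

#' Write a polar pullback to disk
#'
#' @param pullback An `"oct_pullback"`.
#' @param path Output path; `.tif`/`.tiff` writes a 16-bit multipage TIFF,
#'   anything else raw binary (uint16, little endian, depth-fastest) plus a
#'   YAML sidecar at `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_pullback <- function(pullback, path) {
  stopifnot(inherits(pullback, "oct_pullback"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(pullback$n_frames), function(i)
      get_frame(pullback, i) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    arr <- aperm(pullback$data, c(2, 1, 3))  # depth-fastest
    con <- file(path, "wb")
    writeBin(as.integer(arr), con, size = 2L, endian = "little")
    close(con)
    yaml::write_yaml(list(n_frames = pullback$n_frames,
                          n_alines = pullback$n_alines,
                          n_depth = pullback$n_depth,
                          dtype = "uint16", byte_order = "little"),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Build a table of strut records
#'
#' @param frame,aline,depth Integer coordinate vectors (1-based).
#' @param kind Provenance flag per record: `"bright"`, `"non_bright"`,
#'   `"guide_wire_removed"` or `"outside_segment_removed"`.
#' @return A `data.frame` with columns `frame`, `aline`, `depth`, `kind`.
#' @export
strut_records <- function(frame = integer(0), aline = integer(0),
                          depth = integer(0), kind = "bright") {
  n <- max(length(frame), length(aline), length(depth))
  if (length(frame) == 0L || length(aline) == 0L || length(depth) == 0L)
    n <- 0L
  frame <- rep_len(frame, n)
  aline <- rep_len(aline, n)
  depth <- rep_len(depth, n)
  kinds <- c("bright", "non_bright", "guide_wire_removed",
             "outside_segment_removed")
  kind <- rep_len(as.character(kind), n)
  if (n && !all(kind %in% kinds))
    stop("unknown strut kind; expected one of: ", paste(kinds, collapse = ", "))
  data.frame(frame = as.integer(frame), aline = as.integer(aline),
             depth = as.integer(depth), kind = kind,
             stringsAsFactors = FALSE)
}

#' Read strut annotations or detections from CSV
#'
#' Expects a header `frame,aline,depth[,kind]`; coordinates are 1-based. A
#' missing `kind` column defaults to `"bright"`.
#'
#' @param path CSV file path.
#' @param n_alines,n_depth Optional declared frame shape; when given,
#'   out-of-range coordinates raise an error.
#' @return A strut record `data.frame` (possibly 0-row).
#' @export
read_annotations <- function(path, n_alines = NULL, n_depth = NULL) {
  if (!file.exists(path)) stop("annotation file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "aline", "depth")
  if (ncol(df) > 0L && !all(need %in% names(df)))
    stop("annotation CSV must have columns frame, aline, depth")
  if (nrow(df) == 0L) return(empty_strut_df())
  for (cn in need) {
    if (!is.numeric(df[[cn]]) || anyNA(df[[cn]]) || any(df[[cn]] != round(df[[cn]])))
      stop("malformed (non-integer) value in column ", cn)
  }
  if (any(df$frame < 1) || any(df$aline < 1) || any(df$depth < 1))
    stop("coordinates are 1-based and must be >= 1")
  if (!is.null(n_alines) && any(df$aline > n_alines))
    stop("aline coordinate exceeds declared n_alines")
  if (!is.null(n_depth) && any(df$depth > n_depth))
    stop("depth coordinate exceeds declared n_depth")
  if (is.null(df$kind)) df$kind <- "bright"
  strut_records(df$frame, df$aline, df$depth, df$kind)
}

#' Write strut detections to CSV (and optionally a JSON mirror)
#'
#' Rows are sorted by frame, then A-line, then depth, so identical record
#' sets always serialize identically.
#'
#' @param records A strut record `data.frame` ([strut_records()] layout).
#' @param path Output CSV path.
#' @param json Optional path for a JSON mirror of the same records.
#' @return `path`, invisibly.
#' @export
write_detections <- function(records, path, json = NULL) {
  records <- strut_records(records$frame, records$aline, records$depth,
                           if (is.null(records$kind)) "bright" else records$kind)
  ord <- order(records$frame, records$aline, records$depth)
  records <- records[ord, , drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(records, json, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
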