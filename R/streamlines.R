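#' Construct a streamline set
#'
#' A `streamline_set` is a list of polylines in world mm coordinates together
#' with a reference geometry (grid shape + affine) so that streamlines can be
#' rasterised into volumes.
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2 vertices each).
#' @param reference either a `volume_grid` or a list with elements `dim`
#'   (length-3 integer) and `affine` (4x4).
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, reference) {
  if (inherits(reference, "volume_grid"))
    reference <- list(dim = dim(reference$data), affine = reference$affine)
  stopifnot(is.list(streamlines))
  for (i in seq_along(streamlines)) {
    m <- streamlines[[i]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) < 2L)
      stop("streamline ", i, " is not an n x 3 matrix with >= 2 vertices")
    if (!all(is.finite(m)))
      stop("streamline ", i, " contains non-finite coordinates")
  }
  structure(list(streamlines = streamlines, reference = reference),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("<streamline_set> ", length(x$streamlines), " streamlines\n", sep = "")
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Write streamlines to an MRtrix track (TCK) file
#'
#' Vertices are stored as little-endian float32 triplets; tracks are separated
#' by a NaN triplet and the stream is terminated by an Inf triplet.
#'
#' @param ss a `streamline_set`.
#' @param path output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(ss, path) {
  stopifnot(inherits(ss, "streamline_set"))
  n <- length(ss$streamlines)
  fixed <- c("mrtrix tracks",
             sprintf("count: %d", n),
             "datatype: Float32LE")
  # the offset line's own width depends on the offset; iterate to fixed point
  offset <- 0L
  for (i in 1:3) {
    header <- c(fixed, sprintf("file: . %d", offset), "END")
    new_offset <- sum(nchar(header, type = "bytes")) + length(header)  # + newlines
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writChar <- paste0(paste(header, collapse = "\n"), "\n")
  writeBin(charToRaw(writChar), con)
  for (m in ss$streamlines) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix track (TCK) file
#'
#' @param path path to a `.tck` file.
#' @param reference optional reference geometry (`volume_grid` or list with
#'   `dim` and `affine`); TCK files carry no grid, so one must be supplied for
#'   any rasterisation step.
#' @return a `streamline_set`.
#' @export
read_streamlines <- function(path, reference = NULL) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  hdr_max <- min(length(raw), 4096L)
  pat <- charToRaw("END\n")
  end_pos <- -1L
  for (i in seq_len(max(0L, hdr_max - 3L))) {
    if (raw[i] == pat[1] && raw[i + 1] == pat[2] &&
        raw[i + 2] == pat[3] && raw[i + 3] == pat[4]) { end_pos <- i; break }
  }
  if (end_pos < 0)
    stop("TCK parse error in '", path, "': no END-of-header marker in the first ",
         hdr_max, " bytes")
  header <- strsplit(rawToChar(raw[seq_len(end_pos - 1L)]), "\n", fixed = TRUE)[[1]]
  if (length(header) == 0L || header[1] != "mrtrix tracks")
    stop("TCK parse error: missing 'mrtrix tracks' magic line")
  fields <- header[-1]
  kv <- regmatches(fields, regexec("^([^:]+): *(.*)$", fields))
  keys <- vapply(kv, function(x) if (length(x) == 3) trimws(x[2]) else NA_character_, "")
  vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  get_field <- function(k) vals[match(k, keys)]
  dtype <- get_field("datatype")
  if (is.na(dtype)) dtype <- "Float32LE"
  endian <- if (grepl("BE$", dtype)) "big" else "little"
  if (!grepl("^Float32", dtype))
    stop("TCK parse error: unsupported datatype '", dtype, "'")
  file_field <- get_field("file")
  off <- suppressWarnings(as.integer(sub("^\\. *", "", file_field)))
  if (is.na(off))
    stop("TCK parse error: missing or malformed 'file' offset field")
  count <- suppressWarnings(as.integer(get_field("count")))
  nfl <- (length(raw) - off) %/% 4L
  v <- readBin(raw[(off + 1L):length(raw)], what = "numeric", size = 4L,
               n = nfl, endian = endian)
  ntrip <- length(v) %/% 3L
  m <- matrix(v[seq_len(ntrip * 3L)], ncol = 3L, byrow = TRUE)
  is_sep <- rowSums(is.nan(m)) == 3L
  is_end <- rowSums(is.infinite(m)) == 3L
  endrow <- which(is_end)
  if (length(endrow) == 0L)
    stop("TCK parse error in '", path, "': no Inf terminator triplet (byte offset ",
         off + ntrip * 12L, ")")
  m <- m[seq_len(endrow[1] - 1L), , drop = FALSE]
  is_sep <- is_sep[seq_len(endrow[1] - 1L)]
  track_id <- cumsum(c(TRUE, is_sep[-length(is_sep)])) # constant within track
  streamlines <- list()
  if (nrow(m)) {
    keep <- !is_sep
    ids <- track_id[keep]
    pieces <- split.data.frame(m[keep, , drop = FALSE], ids)
    streamlines <- lapply(pieces, function(p) unname(as.matrix(p)))
    names(streamlines) <- NULL
  }
  if (!is.na(count) && count != length(streamlines))
    stop("TCK parse error in '", path, "': header count ", count,
         " does not match ", length(streamlines), " parsed tracks")
  if (is.null(reference))
    reference <- list(dim = NULL, affine = NULL)
  else if (inherits(reference, "volume_grid"))
    reference <- list(dim = dim(reference$data), affine = reference$affine)
  structure(list(streamlines = streamlines, reference = reference),
            class = "streamline_set")
}

# Internal: resample a polyline at fixed arc-length steps (mm).
resample_polyline <- function(m, step_mm) {
  seg <- sqrt(rowSums(diff(m)^2))
  len <- sum(seg)
  if (len == 0) return(m[1, , drop = FALSE])
  s <- c(0, cumsum(seg))
  t_out <- seq(0, len, by = step_mm)
  if (t_out[length(t_out)] < len) t_out <- c(t_out, len)
  cbind(approx(s, m[, 1], xout = t_out)$y,
        approx(s, m[, 2], xout = t_out)$y,
        approx(s, m[, 3], xout = t_out)$y)
}

# Internal: distinct 0-based voxel linear indices (1-based R index) visited by
# a streamline, sampled at <= half the minimum voxel dimension. Points outside
# the grid are clipped (dropped).
streamline_voxels <- function(m, dim3, affine, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- min(sqrt(colSums(affine[1:3, 1:3]^2))) / 2
  pts <- resample_polyline(m, step_mm)
  ijk <- round(world_to_voxel(affine, pts))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < dim3[1] &
        ijk[, 2] >= 0 & ijk[, 2] < dim3[2] &
        ijk[, 3] >= 0 & ijk[, 3] < dim3[3]
  ijk <- ijk[ok, , drop = FALSE]
  if (!nrow(ijk)) return(integer(0))
  unique(as.integer(ijk[, 1] + dim3[1] * (ijk[, 2] + dim3[2] * ijk[, 3])) + 1L)
}
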