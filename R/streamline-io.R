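## Streamline I/O in the two community formats. TCK stores points natively
## in world (scanner) mm, which is this package's working space; TRK stores
## them in corner-origin "voxel-mm" and is converted on read/write using the
## affine in its header. Bundle labels travel in a JSON sidecar
## ("<file>.json") because neither format reserves a per-streamline integer
## field portably.

.tckWrite <- function(ts, path) {
  n <- length(ts@tracts)
  mkHeader <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           sprintf("count: %d\n", n),
           sprintf("file: . %d\n", offset),
           "END\n")
  }
  ## fixed-point iteration on the offset field width
  off <- 0L
  repeat {
    h <- mkHeader(off)
    if (nchar(h, type = "bytes") == off) break
    off <- nchar(h, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(h, con, eos = NULL)
  for (tr in ts@tracts) {
    writeBin(as.numeric(t(tr)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

.tckRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    stop("streamline format error: not a TCK file")
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || identical(ln, "END")) break
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (trimws(kv[1]) == "file")
      offset <- as.integer(strsplit(trimws(kv[2]), "\\s+")[[1]][2])
  }
  if (is.na(offset)) stop("streamline format error: TCK header lacks file offset")
  close(con)
  on.exit(NULL)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, offset)
  vals <- readBin(con, "numeric", n = (sz - offset) / 4, size = 4L,
                  endian = "little")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  tracts <- list()
  cur <- 0L
  brk <- which(!is.finite(pts[, 1]))
  start <- 1L
  for (b in brk) {
    if (any(is.infinite(pts[b, ]))) break
    if (b > start) tracts[[length(tracts) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
  }
  tractSet(tracts)
}

.trkWrite <- function(ts, path, refAffine = diag(4), refDim = c(1L, 1L, 1L)) {
  vs <- sqrt(colSums(refAffine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(width - length(raw))), con)
  }
  wchar("TRACK", 6L)
  writeBin(as.integer(refDim), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")   # origin (unused)
  writeBin(0L, con, size = 2L, endian = "little")           # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2L, endian = "little")           # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(refAffine)), con, size = 4L, endian = "little")
  writeBin(raw(444), con)
  wchar("RAS", 4L)                                          # voxel_order
  writeBin(raw(4), con)                                     # pad2
  writeBin(numeric(6), con, size = 4L, endian = "little")   # img orientation
  writeBin(raw(2), con)                                     # pad1
  writeBin(raw(6), con)                                     # invert/swap flags
  writeBin(length(ts@tracts), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")           # version
  writeBin(1000L, con, size = 4L, endian = "little")        # hdr_size
  for (tr in ts@tracts) {
    vox <- worldToVoxel(tr, refAffine)
    voxmm <- sweep(vox + 0.5, 2L, vs, `*`)
    writeBin(nrow(tr), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

.trkRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("streamline format error: not a TRK file")
  readBin(con, "integer", n = 3L, size = 2L, endian = "little")        # dim
  vs <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")        # origin
  nScalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  readBin(con, "raw", n = 200L)
  nProps <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  readBin(con, "raw", n = 200L)
  aff <- matrix(readBin(con, "numeric", n = 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", n = 444L + 4L + 4L)
  readBin(con, "numeric", n = 6L, size = 4L, endian = "little")
  readBin(con, "raw", n = 2L + 6L)
  nCount <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  readBin(con, "integer", n = 1L, size = 4L, endian = "little")        # hdr_size
  if (version < 2L || all(aff == 0)) aff <- diag(4)                    # v1: no affine
  tracts <- list()
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!length(np)) break
    vals <- readBin(con, "numeric", n = np * (3L + nScalars), size = 4L,
                    endian = "little")
    if (nProps > 0) readBin(con, "numeric", n = nProps, size = 4L,
                            endian = "little")
    m <- matrix(vals, ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, vs, `/`) - 0.5
    tracts[[length(tracts) + 1L]] <- voxelToWorld(vox, aff)
    if (length(tracts) == nCount && nCount > 0) break
  }
  tractSet(tracts)
}

.labelSidecar <- function(path) paste0(path, ".json")

#' Save a TractSet to a TCK or TRK file
#'
#' The path extension selects the dialect. Coordinates are written so that a
#' round-trip preserves world-mm positions within 1e-4 mm (float32
#' precision). When any bundle labels are present they are written to a JSON
#' sidecar next to the file.
#'
#' @param ts a [TractSet-class].
#' @param path output path ending in .tck or .trk.
#' @param refAffine,refDim reference grid geometry stored in TRK headers
#'   (ignored for TCK).
#' @return invisibly, the path.
#' @export
saveTracts <- function(ts, path, refAffine = diag(4), refDim = c(1L, 1L, 1L)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = .tckWrite(ts, path),
    trk = .trkWrite(ts, path, refAffine, refDim),
    stop("streamline format error: unknown extension '", ext,
         "' (use .tck or .trk)"))
  if (any(!is.na(ts@labels)))
    jsonlite::write_json(list(bundle_labels = ts@labels),
                         .labelSidecar(path), auto_unbox = FALSE, na = "null")
  invisible(path)
}

#' Load a TractSet from a TCK or TRK file
#'
#' Reads bundle labels from the JSON sidecar when present.
#'
#' @param path input path ending in .tck or .trk.
#' @return a [TractSet-class] in world-mm RAS space.
#' @export
loadTracts <- function(path) {
  ext <- tolower(tools::file_ext(path))
  ts <- switch(ext,
    tck = .tckRead(path),
    trk = .trkRead(path),
    stop("streamline format error: unknown extension '", ext,
         "' (use .tck or .trk)"))
  sc <- .labelSidecar(path)
  if (file.exists(sc)) {
    labs <- jsonlite::read_json(sc, simplifyVector = TRUE)$bundle_labels
    if (length(labs) == length(ts@tracts))
      ts@labels <- as.integer(labs)
  }
  ts
}
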