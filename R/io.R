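## File formats: TSV per-vertex tables (with provenance headers), OFF
## meshes, FreeSurfer binary triangle-surface and curv morph files (both
## big-endian), and a small configuration hash for provenance blocks.
## Degrees everywhere in files; radians are never serialized.

#' Hash a configuration for provenance blocks
#'
#' 32-bit FNV-1a over the deparsed object, hex-encoded.  Stable across
#' sessions for plain lists of atomic values.
#'
#' @param x any serializable R object.
#' @return an 8-character hex string.
#' @export
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor affects only the low 16 bits (b < 256); the multiply is split so
    # every intermediate stays exactly representable in a double
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

.provenanceLines <- function(extra = list()) {
  info <- c(list(tool = paste0("retinomap ",
                               as.character(utils::packageVersion("retinomap")))),
            extra)
  vapply(names(info), function(k) sprintf("# %s: %s", k, format(info[[k]])),
         character(1))
}

#' Read / write per-vertex pRF tables (TSV)
#'
#' The interchange format for measurements and predictions: a tab-separated
#' table with columns vertex_id, polar_angle_deg, eccentricity_deg,
#' prf_size_deg, variance_explained (plus optional visual_area).  Leading
#' '#' lines carry provenance and are preserved on read.  Row order is
#' irrelevant; rows are keyed by vertex_id.
#'
#' @param path file path.
#' @param hemisphere hemisphere flag attached to the result.
#' @return a [RetinotopyData-class] with the provenance header in
#'   \code{attr(, "provenance")}.
#' @export
readPrfTable <- function(path, hemisphere = "rh") {
  lines <- readLines(path, warn = FALSE)
  prov <- grep("^#", lines, value = TRUE)
  tab <- read.delim(text = lines, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("vertex_id", "polar_angle_deg", "eccentricity_deg",
            "prf_size_deg", "variance_explained")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pRF table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cn in need) {
    if (!is.numeric(tab[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[cn]]))) &
                     !is.na(tab[[cn]]))[1]
      stop(sprintf("non-numeric value in column '%s' (data row %d)", cn,
                   if (is.na(bad)) -1L else bad))
    }
  }
  ord <- order(tab$vertex_id)
  tab <- tab[ord, , drop = FALSE]
  out <- retinotopyData(tab$vertex_id, tab$polar_angle_deg,
                        tab$eccentricity_deg, tab$prf_size_deg,
                        tab$variance_explained, hemisphere)
  attr(out, "provenance") <- prov
  attr(out, "extraColumns") <- tab[setdiff(names(tab), need)]
  out
}

#' @rdname readPrfTable
#' @param data a [RetinotopyData-class] (or data.frame with matching
#'   columns).
#' @param provenance named list appended to the provenance header.
#' @param extra optional data.frame of extra columns (e.g. visual_area).
#' @export
writePrfTable <- function(data, path, provenance = list(), extra = NULL) {
  if (is(data, "RetinotopyData")) {
    tab <- data.frame(vertex_id = data@vertexId,
                      polar_angle_deg = data@polarAngle,
                      eccentricity_deg = data@eccentricity,
                      prf_size_deg = data@prfSize,
                      variance_explained = data@varianceExplained)
  } else tab <- as.data.frame(data)
  if (!is.null(extra)) tab <- cbind(tab, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLines(provenance), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read / write OFF meshes
#'
#' Plain-text Object File Format; 2D maps are written with z = 0.
#'
#' @param path file path.
#' @return \code{readOff}: list with \code{coords} (n x 3) and \code{faces}.
#' @export
readOff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle faces are supported")
  list(coords = verts, faces = fl[, 2:4, drop = FALSE] + 1L)
}

#' @rdname readOff
#' @param coords n x 2 or n x 3 vertex coordinates.
#' @param faces m x 3 face matrix (1-based).
#' @export
writeOff <- function(coords, faces, path) {
  coords <- as.matrix(coords)
  if (ncol(coords) == 2) coords <- cbind(coords, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(coords), nrow(faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g", coords[, 1], coords[, 2],
                     coords[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}

.FS_TRIANGLE_MAGIC <- 16777214  # 0xFFFFFE
.FS_CURV_MAGIC <- 16777215      # 0xFFFFFF

.readInt3 <- function(con) {
  b <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  if (length(b) < 3) stop("truncated FreeSurfer file")
  b[1] * 65536 + b[2] * 256 + b[3]
}

.writeInt3 <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536, (x %/% 256) %% 256, x %% 256)),
           con, size = 1)
}

#' Read / write FreeSurfer binary triangle surfaces
#'
#' The big-endian triangle-file format: a 3-byte magic (16777214), two
#' comment lines ended by an empty line, vertex and face counts as int32,
#' float32 coordinates in mm, and int32 0-based face indices.
#'
#' @param path file path.
#' @return a [Mesh3D-class].
#' @export
readFreeSurferSurface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .readInt3(con)
  if (magic != .FS_TRIANGLE_MAGIC)
    stop(sprintf("bad magic number %d: not a FreeSurfer triangle surface",
                 magic))
  # comment: bytes up to "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b)) stop("truncated FreeSurfer surface (comment)")
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  co <- readBin(con, "numeric", 3 * nv, size = 4, endian = "big")
  fc <- readBin(con, "integer", 3 * nf, size = 4, endian = "big")
  if (length(co) < 3 * nv || length(fc) < 3 * nf)
    stop("truncated FreeSurfer surface (payload shorter than header counts)")
  mesh3D(matrix(co, ncol = 3, byrow = TRUE),
         matrix(fc, ncol = 3, byrow = TRUE) + 1L)
}

#' @rdname readFreeSurferSurface
#' @param mesh a [Mesh3D-class].
#' @param comment comment string stored in the header.
#' @export
writeFreeSurferSurface <- function(mesh, path, comment = "created by retinomap") {
  con <- file(path, "wb")
  on.exit(close(con))
  .writeInt3(con, .FS_TRIANGLE_MAGIC)
  writeBin(charToRaw(paste0(comment, "\n\n")), con)
  co <- coords(mesh); fc <- faces(mesh)
  writeBin(as.integer(nrow(co)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(fc)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(co)), con, size = 4, endian = "big")
  writeBin(as.integer(t(fc) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write FreeSurfer curv (per-vertex morph) files
#'
#' The new-format curv file: 3-byte magic (16777215), int32 vertex count,
#' face count and values-per-vertex, then big-endian float32 values.
#'
#' @param path file path.
#' @param mesh optional [Mesh3D-class]; when given, the value count must
#'   match its vertex count.
#' @return numeric vector of per-vertex values.
#' @export
readFreeSurferMorph <- function(path, mesh = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .readInt3(con)
  if (magic != .FS_CURV_MAGIC)
    stop(sprintf("bad magic number %d: not a FreeSurfer curv file", magic))
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 1, size = 4, endian = "big")  # face count, unused
  vpv <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (vpv != 1L) stop("only one value per vertex is supported")
  vals <- readBin(con, "numeric", nv, size = 4, endian = "big")
  if (length(vals) < nv) stop("truncated FreeSurfer curv file")
  if (!is.null(mesh) && nv != nrow(coords(mesh)))
    stop(sprintf("curv file has %d values but the mesh has %d vertices",
                 nv, nrow(coords(mesh))))
  vals
}

#' @rdname readFreeSurferMorph
#' @param values numeric per-vertex values.
#' @param faceCount face count stored in the header.
#' @export
writeFreeSurferMorph <- function(values, path, faceCount = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  .writeInt3(con, .FS_CURV_MAGIC)
  writeBin(as.integer(length(values)), con, size = 4, endian = "big")
  writeBin(as.integer(faceCount), con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}
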