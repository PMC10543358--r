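#' Coordinate frames and affine transforms
#'
#' An `affine_transform` is a 4x4 homogeneous matrix (mm) tagged with the
#' coordinate frame of its input points (`source_frame`) and of its output
#' points (`dest_frame`). The package's internal world frame is scanner RAS;
#' ITK/ANTs-style files use LPS and are sign-flipped on read. Tagging the
#' frames makes frame mismatches detectable at composition time instead of
#' silently producing wrong geometry.
#'
#' @param matrix numeric 4x4 homogeneous matrix; bottom row must be
#'   `(0, 0, 0, 1)`.
#' @param source_frame,dest_frame one of `"surface_tkr"`, `"scanner_ras"`,
#'   `"scanner_lps"`, `"voxel"`.
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, source_frame = "scanner_ras",
                             dest_frame = "scanner_ras") {
  matrix <- base::matrix(as.numeric(matrix), 4, 4)
  frames <- c("surface_tkr", "scanner_ras", "scanner_lps", "voxel")
  source_frame <- match.arg(source_frame, frames)
  dest_frame <- match.arg(dest_frame, frames)
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stopf("affine bottom row must be (0,0,0,1)")
  if (abs(det(matrix)) < .Machine$double.eps)
    stopf("affine matrix is not invertible")
  structure(list(matrix = matrix, source_frame = source_frame,
                 dest_frame = dest_frame),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform: %s -> %s>\n", x$source_frame, x$dest_frame))
  print(x$matrix)
  invisible(x)
}

#' Test whether a transform is rigid
#'
#' Rigid means the 3x3 block is orthonormal with determinant +1.
#' @param xfm an `affine_transform`.
#' @param tol numeric tolerance on orthonormality and determinant.
#' @export
is_rigid <- function(xfm, tol = 1e-6) {
  r <- xfm$matrix[1:3, 1:3]
  max(abs(crossprod(r) - diag(3))) < tol && abs(det(r) - 1) < tol
}

#' Apply an affine transform to points
#'
#' @param xfm an `affine_transform`.
#' @param points numeric N x 3 matrix (or length-3 vector) in the transform's
#'   source frame.
#' @param frame optional frame tag of the points; when given it must match
#'   `xfm$source_frame`.
#' @return N x 3 matrix in the destination frame.
#' @export
apply_transform <- function(xfm, points, frame = NULL) {
  if (!is.null(frame) && !identical(frame, xfm$source_frame))
    stopf("frame mismatch: points are '%s' but transform expects '%s'",
          frame, xfm$source_frame)
  pts <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  out <- cbind(pts, 1) %*% t(xfm$matrix)
  out <- out[, 1:3, drop = FALSE]
  if (is.null(dim(points))) out[1, ] else out
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `first` then `second`.
#' Frames must chain: `first$dest_frame == second$source_frame`.
#' @param second,first `affine_transform` objects.
#' @export
compose_transforms <- function(second, first) {
  if (!identical(first$dest_frame, second$source_frame))
    stopf("frame mismatch: cannot compose '%s->%s' after '%s->%s'",
          second$source_frame, second$dest_frame,
          first$source_frame, first$dest_frame)
  affine_transform(second$matrix %*% first$matrix,
                   first$source_frame, second$dest_frame)
}

#' Invert an affine transform
#' @param xfm an `affine_transform`.
#' @export
invert_transform <- function(xfm) {
  affine_transform(solve(xfm$matrix), xfm$dest_frame, xfm$source_frame)
}

# LPS <-> RAS: flip the sign of the first two world axes on both sides
lps_to_ras_matrix <- function(m) {
  f <- diag(c(-1, -1, 1, 1))
  f %*% m %*% f
}

#' Read a 4x4 affine transform file
#'
#' Supports plain-text 4x4 whitespace-delimited matrices and ITK-style
#' transform parameter files (`#Insight Transform File V1.0` with
#' `Parameters:` and `FixedParameters:` lines). ITK files are always in LPS;
#' plain-text files are read under the declared `convention`. LPS matrices
#' are converted to scanner RAS on read by sign-flipping the first two axes.
#'
#' @param path file path.
#' @param convention `"ras"` or `"lps"`: the world convention the file's
#'   numbers are written in (ignored for ITK files, which are LPS).
#' @param source_frame,dest_frame frame tags for the returned transform.
#' @return an `affine_transform` in scanner-RAS convention.
#' @export
read_affine <- function(path, convention = c("ras", "lps"),
                        source_frame = "scanner_ras",
                        dest_frame = "scanner_ras") {
  convention <- match.arg(convention)
  if (!file.exists(path)) stopf("affine file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^#Insight Transform File", lines[1])) {
    pl <- grep("^Parameters:", lines, value = TRUE)
    if (!length(pl)) stopf("malformed ITK transform file: %s", path)
    p <- as.numeric(strsplit(sub("^Parameters:\\s*", "", pl[1]), "\\s+")[[1]])
    fl <- grep("^FixedParameters:", lines, value = TRUE)
    ctr <- if (length(fl))
      as.numeric(strsplit(sub("^FixedParameters:\\s*", "", fl[1]), "\\s+")[[1]])
    else c(0, 0, 0)
    if (length(p) < 12) stopf("ITK transform must have 12 parameters: %s", path)
    r <- matrix(p[1:9], 3, 3, byrow = TRUE)
    tr <- p[10:12]
    m <- diag(4)
    m[1:3, 1:3] <- r
    # ITK: y = R (x - c) + t + c
    m[1:3, 4] <- tr + ctr - r %*% ctr
    convention <- "lps"
  } else {
    vals <- as.numeric(unlist(strsplit(trimws(lines[nzchar(trimws(lines))]),
                                       "\\s+")))
    if (length(vals) != 16 || anyNA(vals))
      stopf("expected 16 numbers in affine file: %s", path)
    m <- matrix(vals, 4, 4, byrow = TRUE)
  }
  if (convention == "lps") m <- lps_to_ras_matrix(m)
  if (abs(det(m)) < 1e-12) stopf("affine in %s is not invertible", path)
  affine_transform(m, source_frame, dest_frame)
}

#' Write an affine transform as a plain-text 4x4 matrix
#'
#' Numbers are written with 17 significant digits so a read round trip is
#' exact at double precision.
#' @param xfm an `affine_transform`.
#' @param path output file.
#' @export
write_affine <- function(xfm, path) {
  rows <- apply(xfm$matrix, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' Volume grid with world geometry
#'
#' @param data numeric or integer 3-D (or 4-D) array.
#' @param vox2world `affine_transform` mapping 0-based voxel indices to
#'   scanner-RAS mm.
#' @return object of class `volume_grid` with fields `data`, `shape`,
#'   `vox2world`.
#' @export
volume_grid <- function(data, vox2world) {
  if (!inherits(vox2world, "affine_transform"))
    stopf("vox2world must be an affine_transform")
  if (!identical(vox2world$source_frame, "voxel"))
    stopf("vox2world must map from the 'voxel' frame")
  data <- as.array(data)
  if (any(dim(data) <= 0)) stopf("volume shape must be strictly positive")
  structure(list(data = data, shape = dim(data), vox2world = vox2world),
            class = "volume_grid")
}

#' Read a NIfTI-1 volume
#'
#' The sform is honoured when both sform and qform are present. Integer-typed
#' files are returned as integer arrays so label volumes survive round trips.
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return a `volume_grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   imagedim = NULL, code = NULL)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  dt <- RNifti::niftiHeader(img)$datatype
  # NIfTI integer datatype codes: 2/4/8/256/512/768
  if (dt %in% c(2L, 4L, 8L, 256L, 512L, 768L)) storage.mode(arr) <- "integer"
  volume_grid(arr, affine_transform(matrix(as.numeric(aff), 4, 4),
                                    "voxel", "scanner_ras"))
}

#' Write a `volume_grid` as NIfTI-1
#' @param grid a `volume_grid`.
#' @param path output path.
#' @export
write_volume <- function(grid, path) {
  dtype <- if (is.integer(grid$data)) "int32" else "double"
  img <- RNifti::asNifti(grid$data, datatype = dtype)
  RNifti::sform(img) <- structure(grid$vox2world$matrix, code = 2L)
  RNifti::qform(img) <- structure(grid$vox2world$matrix, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- surface formats -------------------------------------------------------

FS_SURF_MAGIC <- 16777214L  # 0xFFFFFE, triangle binary surface
FS_CURV_MAGIC <- 16777215L  # 0xFFFFFF, "new" curv format

read_int3_be <- function(con) {
  b <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(b) < 3) return(NA_integer_)
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_int3_be <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536, (x %/% 256) %% 256, x %% 256)),
           con, size = 1)
}

read_freesurfer_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3_be(con)
  if (is.na(magic) || magic != FS_SURF_MAGIC)
    stopf("not a FreeSurfer triangle surface (bad magic): %s", path)
  # comment line(s) terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (!length(ch)) stopf("truncated FreeSurfer surface: %s", path)
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!length(nv) || !length(nf) || nv < 0 || nf < 0)
    stopf("truncated FreeSurfer surface: %s", path)
  v <- readBin(con, "numeric", nv * 3, size = 4, endian = "big")
  f <- readBin(con, "integer", nf * 3, size = 4, endian = "big")
  if (length(v) < nv * 3 || length(f) < nf * 3)
    stopf("truncated FreeSurfer surface: %s", path)
  list(vertices = matrix(v, nv, 3, byrow = TRUE),
       faces = matrix(f, nf, 3, byrow = TRUE))
}

write_freesurfer_surface <- function(vertices, faces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3_be(con, FS_SURF_MAGIC)
  writeBin(charToRaw("created by linetarget\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(faces)), con, size = 4, endian = "big")
  invisible(path)
}

#' Read a per-vertex scalar overlay in FreeSurfer curv format
#' @param path curv-format file.
#' @return numeric vector of per-vertex values.
#' @export
read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3_be(con)
  if (is.na(magic) || magic != FS_CURV_MAGIC)
    stopf("not a FreeSurfer curv file (bad magic): %s", path)
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 1, size = 4, endian = "big")  # face count, unused
  vpv <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (vpv != 1L) stopf("only 1 value per vertex supported: %s", path)
  vals <- readBin(con, "numeric", nv, size = 4, endian = "big")
  if (length(vals) < nv) stopf("truncated curv file: %s", path)
  vals
}

#' Write a per-vertex scalar overlay in FreeSurfer curv format
#' @param values numeric per-vertex vector.
#' @param path output path.
#' @param n_faces face count recorded in the header (informational).
#' @export
write_curv <- function(values, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3_be(con, FS_CURV_MAGIC)
  writeBin(as.integer(length(values)), con, size = 4, endian = "big")
  writeBin(as.integer(n_faces), con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

# ---- GIFTI (surf + func), base64-encoded little-endian ---------------------

gifti_data_array <- function(doc_node, intent, dtype, dims, values) {
  enc <- jsonlite::base64_enc(writeBin(
    if (dtype == "NIFTI_TYPE_FLOAT32") as.numeric(values) else as.integer(values),
    raw(), size = 4, endian = "little"))
  da <- xml2::xml_add_child(doc_node, "DataArray",
    Intent = intent, DataType = dtype, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "Base64Binary", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  xml2::xml_add_child(da, "Data", enc)
  invisible(da)
}

write_gifti_surface <- function(vertices, faces, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   dim(vertices), t(vertices))
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   dim(faces), t(faces))
  xml2::write_xml(doc, path)
  invisible(path)
}

gifti_decode_array <- function(da) {
  enc <- xml2::xml_attr(da, "Encoding")
  dtype <- xml2::xml_attr(da, "DataType")
  endian <- xml2::xml_attr(da, "Endian")
  ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
  dims <- vapply(seq_len(ndim) - 1L, function(i)
    as.integer(xml2::xml_attr(da, paste0("Dim", i))), integer(1))
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
  if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, "gzip")
  n <- prod(dims)
  what <- if (dtype == "NIFTI_TYPE_INT32") "integer" else "numeric"
  vals <- readBin(raw, what, n = n, size = 4,
                  endian = if (identical(endian, "BigEndian")) "big" else "little")
  order <- xml2::xml_attr(da, "ArrayIndexingOrder")
  if (ndim == 2L) {
    m <- if (identical(order, "ColumnMajorOrder"))
      matrix(vals, dims[1], dims[2]) else matrix(vals, dims[1], dims[2], byrow = TRUE)
    m
  } else vals
}

read_gifti_surface <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("unreadable GIFTI file: %s", path))
  das <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- vapply(das, xml2::xml_attr, "", attr = "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(ip) || !length(it))
    stopf("GIFTI file lacks pointset/triangle arrays: %s", path)
  list(vertices = gifti_decode_array(das[[ip[1]]]),
       faces = gifti_decode_array(das[[it[1]]]))
}

#' Read a per-vertex scalar overlay from a functional GIFTI file
#' @param path `.func.gii`-style file (first data array is used).
#' @return numeric vector.
#' @export
read_gifti_func <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("unreadable GIFTI file: %s", path))
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stopf("GIFTI file has no data arrays: %s", path)
  as.numeric(gifti_decode_array(das[[1]]))
}

#' Write a per-vertex scalar overlay as functional GIFTI
#' @param values numeric vector.
#' @param path output path.
#' @export
write_gifti_func <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  gifti_data_array(doc, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                   length(values), values)
  xml2::write_xml(doc, path)
  invisible(path)
}

is_gifti_file <- function(path) {
  head <- tryCatch(readBin(path, "raw", 256), error = function(e) raw(0))
  ascii <- head[head >= as.raw(32) & head <= as.raw(126)]
  length(head) > 0 && grepl("GIFTI|<\\?xml", rawToChar(ascii))
}

#' Read a cortical surface mesh
#'
#' Dispatches on content: FreeSurfer binary triangle surfaces (big-endian,
#' magic `0xFFFFFE`) and GIFTI surface files are supported. Vertex
#' coordinates are interpreted in the FreeSurfer surface (TKR) frame, in mm;
#' faces are returned 0-based.
#'
#' @param path surface file.
#' @return a [surface_mesh].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stopf("surface file not found: %s", path)
  if (file.size(path) == 0) stopf("empty surface file: %s", path)
  s <- if (is_gifti_file(path)) read_gifti_surface(path)
       else read_freesurfer_surface(path)
  surface_mesh(s$vertices, s$faces)
}

#' Write a cortical surface mesh
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @param format `"freesurfer"` or `"gifti"`.
#' @export
write_surface <- function(mesh, path, format = c("freesurfer", "gifti")) {
  format <- match.arg(format)
  if (format == "gifti") write_gifti_surface(mesh$vertices, mesh$faces, path)
  else write_freesurfer_surface(mesh$vertices, mesh$faces, path)
  invisible(path)
}

# ---- pRF parameter tables --------------------------------------------------

#' Read a per-vertex pRF parameter table
#'
#' A TSV with at least the columns `x0`, `y0`, `sigma`, `r2` (visual degrees
#' and unitless variance explained). `NA`/`NaN` rows mark unfitted vertices.
#'
#' @param path TSV file.
#' @return a `prf_map`: a data.frame with class attribute.
#' @export
read_prf_map <- function(path) {
  if (!file.exists(path)) stopf("pRF map file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  prf_map(df)
}

#' Construct / validate a pRF map table
#' @param df data.frame with columns `x0`, `y0`, `sigma`, `r2`.
#' @export
prf_map <- function(df) {
  need <- c("x0", "y0", "sigma", "r2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("pRF map is missing required column(s): %s",
          paste(missing, collapse = ", "))
  class(df) <- c("prf_map", "data.frame")
  df
}

#' Write a pRF map table as TSV
#' @param map a `prf_map` or data.frame.
#' @param path output path.
#' @export
write_prf_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair a pRF map with a mesh, enforcing matching vertex counts
#' @param map a `prf_map`.
#' @param mesh a [surface_mesh].
#' @export
pair_prf_map <- function(map, mesh) {
  if (nrow(map) != nrow(mesh$vertices))
    stopf("pRF map has %d rows but mesh has %d vertices",
          nrow(map), nrow(mesh$vertices))
  invisible(map)
}
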