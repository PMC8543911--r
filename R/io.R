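## File formats: NIfTI-1 volumes (.nii / .nii.gz), 3-component deformation
## fields, 4x4 affine text files, legacy-ASCII VTK polydata meshes, ratings
## CSV. No NIfTI package exists in the supported R stack, so the 348-byte
## NIfTI-1 header is read and written directly here.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nifti_write_header <- function(con, dims, datatype, bitpix, spacing, srow) {
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wshort <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wfloat <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wint(348L)                                  # sizeof_hdr
  wraw(36L)                                   # data_type..dim_info
  wshort(dims)                                # dim[8]
  wfloat(c(0, 0, 0)); wshort(0L)              # intent_p1-3, intent_code
  wshort(datatype); wshort(bitpix); wshort(0L)
  wfloat(c(1, spacing, rep(1, 7 - length(spacing))))  # pixdim (qfac first)
  wfloat(352); wfloat(1); wfloat(0)           # vox_offset, scl_slope, scl_inter
  wshort(0L); wraw(1L)
  writeBin(as.raw(2L), con)                   # xyzt_units: mm
  wfloat(c(0, 0, 0, 0)); wint(0L); wint(0L)   # cal/slice/toffset, glmax/glmin
  desc <- charToRaw("mtlatlas")
  wraw0 <- raw(80); wraw0[seq_along(desc)] <- desc; writeBin(wraw0, con)
  wraw(24L)                                   # aux_file
  wshort(0L); wshort(1L)                      # qform_code=0, sform_code=1
  wfloat(rep(0, 6))                           # quatern, qoffset
  wfloat(srow[1, ]); wfloat(srow[2, ]); wfloat(srow[3, ])
  wraw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  wraw(4L)                                    # pad to vox_offset = 352
}

#' Write a volume as NIfTI-1
#'
#' Images are stored as float32, label volumes as int32 with a JSON label
#' table sidecar (`<path stem>.labels.json`). Geometry goes into the sform.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  d <- vol_dim(vol)
  is_lab <- inherits(vol, "label_volume")
  srow <- cbind(vol$orientation %*% diag(vol$spacing_mm), vol$origin_mm)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  nifti_write_header(con, dims = c(3L, d, 1L, 1L, 1L, 1L),
                     datatype = if (is_lab) 8L else 16L, bitpix = 32L,
                     spacing = vol$spacing_mm, srow = srow)
  if (is_lab) {
    writeBin(as.integer(vol$voxels), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(vol$voxels), con, size = 4L, endian = "little")
  }
  if (is_lab) {
    side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
    jsonlite::write_json(as.list(vol$label_table), side, auto_unbox = TRUE)
  }
  invisible(path)
}

nifti_read_header <- function(con) {
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: truncated header")
  rint <- function(off, endian) readBin(hdr[(off + 1):(off + 4)], "integer", size = 4L, endian = endian)
  sz <- rint(0, "little")
  endian <- if (sz == 348L) "little" else "big"
  if (rint(0, endian) != 348L) stop("not a NIfTI-1 file: bad sizeof_hdr")
  rshort <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)], "integer", size = 2L, n = n, endian = endian)
  rfloat <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "numeric", size = 4L, n = n, endian = endian)
  list(endian = endian,
       dim = rshort(40, 8),
       datatype = rshort(70), bitpix = rshort(72),
       pixdim = rfloat(76, 8),
       vox_offset = rfloat(108),
       scl_slope = rfloat(112), scl_inter = rfloat(116),
       sform_code = rshort(254),
       srow = rbind(rfloat(280, 4), rfloat(296, 4), rfloat(312, 4)))
}

#' Read a NIfTI-1 volume
#'
#' 3D volumes only; 4D files are rejected. If a `.labels.json` sidecar is
#' present (or `as_labels = TRUE`) the result is a [label_volume()] and the
#' data must be integer-valued.
#'
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param as_labels force label-volume interpretation.
#' @return [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, as_labels = NA) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  h <- nifti_read_header(con)
  nd <- h$dim[1]
  if (nd > 3L && any(h$dim[(5:8)[seq_len(nd - 3)]] > 1L))
    stop("read_volume: file is ", nd, "D; only 3D volumes are supported")
  d <- h$dim[2:4]
  if (any(d < 1L)) stop("read_volume: degenerate dimensions")
  n <- prod(d)
  skip <- h$vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(h$datatype),
                 "2" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
                 "4" = as.numeric(readBin(con, "integer", n = n, size = 2L, endian = h$endian)),
                 "8" = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = h$endian)),
                 "16" = readBin(con, "numeric", n = n, size = 4L, endian = h$endian),
                 "64" = readBin(con, "numeric", n = n, size = 8L, endian = h$endian),
                 stop("read_volume: unsupported NIfTI datatype ", h$datatype))
  if (length(vals) < n) stop("read_volume: truncated data section")
  if (h$scl_slope != 0 && !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  if (h$sform_code < 1L) stop("read_volume: missing affine (sform_code = 0)")
  linear <- h$srow[, 1:3]
  spacing <- sqrt(colSums(linear^2))
  if (any(spacing <= 0)) stop("read_volume: degenerate affine")
  orientation <- sweep(linear, 2, spacing, `/`)
  origin <- h$srow[, 4]
  arr <- array(vals, d)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  want_labels <- isTRUE(as_labels) || (is.na(as_labels) && file.exists(side))
  if (want_labels) {
    if (max(abs(arr - round(arr))) > 1e-6)
      stop("read_volume: non-integer data in a label file")
    tab <- if (file.exists(side)) {
      unlist(jsonlite::read_json(side))
    } else {
      v <- sort(setdiff(unique(round(as.vector(arr))), 0))
      stats::setNames(as.integer(v), paste0("label_", v))
    }
    label_volume(array(as.integer(round(arr)), d), tab, spacing, origin, orientation)
  } else {
    image_volume(arr, spacing, origin, orientation)
  }
}

#' Deformation field I/O
#'
#' Fields are stored as 5D NIfTI (dim = \[x, y, z, 1, 3\]) with displacement
#' in mm on the fixed grid, the convention used by most registration tools.
#'
#' @param field a `deformation_field`.
#' @param path `.nii`/`.nii.gz` path.
#' @rdname deformation_io
#' @export
write_deformation_field <- function(field, path) {
  d <- dim(field$displacement_mm)[1:3]
  srow <- cbind(field$orientation %*% diag(field$spacing_mm), field$origin_mm)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  nifti_write_header(con, dims = c(5L, d, 1L, 3L, 1L, 1L),
                     datatype = 16L, bitpix = 32L,
                     spacing = field$spacing_mm, srow = srow)
  writeBin(as.numeric(field$displacement_mm), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname deformation_io
#' @export
read_deformation_field <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  h <- nifti_read_header(con)
  if (h$dim[1] != 5L || h$dim[6] != 3L)
    stop("read_deformation_field: expected a 5D vector NIfTI")
  d <- h$dim[2:4]
  n <- prod(d) * 3
  skip <- h$vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = h$endian)
  linear <- h$srow[, 1:3]
  spacing <- sqrt(colSums(linear^2))
  deformation_field(array(vals, c(d, 3L)), spacing_mm = spacing,
                    origin_mm = h$srow[, 4],
                    orientation = sweep(linear, 2, spacing, `/`))
}

#' Affine transform I/O (4x4 row-major text, physical coordinates)
#' @param tf an `affine_transform`.
#' @param path text file path.
#' @rdname affine_io
#' @export
write_affine <- function(tf, path) {
  m <- rbind(cbind(tf$matrix, tf$translation_mm), c(0, 0, 0, 1))
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname affine_io
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  stopifnot(nrow(m) == 4, ncol(m) == 4)
  affine_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write a surface mesh as legacy-ASCII VTK polydata
#'
#' Named per-vertex scalar fields are written as POINT_DATA arrays.
#'
#' @param mesh a `surface_mesh`.
#' @param path output `.vtk` path.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               paste("mtlatlas surface", mesh$structure_tag),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nv)), con)
  utils::write.table(format(mesh$vertices, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  flds <- mesh$vertex_fields
  if (length(flds)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(flds)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(flds[[nm]]), digits = 8), con)
    }
  }
  invisible(path)
}

#' Ratings table I/O
#'
#' Long-format CSV with columns `id, age_years, side, location, tau, tdp43`;
#' `side` is `ipsi`/`contra`, `location` one of `ERC`, `DG`, `CA`.
#'
#' @param specimens list of specimens (each with `id`, `age_years`, `ratings`).
#' @param path CSV path.
#' @rdname ratings_io
#' @export
write_ratings_csv <- function(specimens, path) {
  rows <- do.call(rbind, lapply(specimens, function(sp) {
    df <- sp$ratings$table
    data.frame(id = sp$id, age_years = sp$age_years,
               side = df$side, location = df$location,
               tau = df$tau, tdp43 = df$tdp43)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ratings_io
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age_years", "side", "location", "tau", "tdp43")
  if (!all(need %in% names(df))) stop("read_ratings_csv: missing columns")
  split(df, df$id)
}
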