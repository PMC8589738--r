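#' Read a CT volume from NIfTI or a DICOM series
#'
#' For NIfTI the stored affine (sform) is taken as the voxel-to-world map in
#' LPS millimetres; a label sidecar `<stem>_labels.nii(.gz)` with identical
#' geometry is loaded when present. For DICOM the directory must contain one
#' single-frame CT file per slice; slices are sorted by their position along
#' the slice normal.
#'
#' @param path file path (NIfTI) or directory path (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return A [ct_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "nifti") read_nifti_volume(path) else read_dicom_series(path)
}

#' Write a CT volume as NIfTI
#'
#' Writes the HU grid to `path` (int16) and the label grid to a sidecar
#' `<stem>_labels.nii.gz` with identical geometry. There is no standard
#' single-file HU+label format, hence the sidecar.
#'
#' @param volume A [ct_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return Invisibly, a character vector of the files written.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  aff <- diag(4)
  aff[1:3, 1:3] <- volume$axes %*% diag(volume$spacing)
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  lab_path <- nifti_sidecar_path(path)
  lab <- RNifti::asNifti(volume$labels, pixdim = volume$spacing)
  lab <- RNifti::`sform<-`(lab, structure(aff, code = 2L))
  RNifti::writeNifti(lab, lab_path, datatype = "int16")
  invisible(c(path, lab_path))
}

nifti_sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- if (grepl("\\.nii\\.gz$", path)) ".nii.gz" else ".nii"
  paste0(stem, "_labels", ext)
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) {
    abort_ct("format_error", "cannot read NIfTI volume: '%s' does not exist", path)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_ct(
                    "format_error", "failed to parse NIfTI file '%s': %s",
                    path, conditionMessage(e)))
  geom <- geometry_from_affine(unclass(RNifti::xform(img)), path)
  data <- array(as.integer(round(as.array(img))), dim(img))
  labels <- NULL
  lab_path <- nifti_sidecar_path(path)
  if (file.exists(lab_path)) {
    lab <- RNifti::readNifti(lab_path)
    if (!identical(dim(lab), dim(img))) {
      abort_ct("format_error", "label sidecar '%s' shape differs from volume", lab_path)
    }
    labels <- array(as.integer(round(as.array(lab))), dim(lab))
  }
  ct_volume(data, labels = labels, spacing = geom$spacing,
            origin = geom$origin, axes = geom$axes)
}

geometry_from_affine <- function(aff, path) {
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0)) {
    abort_ct("format_error", "degenerate affine in '%s'", path)
  }
  axes <- sweep(m, 2, spacing, "/")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6) {
    abort_ct("validation_error",
             "non-orthonormal direction matrix in '%s'", path)
  }
  list(spacing = spacing, origin = aff[1:3, 4], axes = axes)
}

## ---- minimal DICOM (explicit VR little endian, single-frame CT) ----------

dcm_uint <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")

dcm_pad <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

dcm_element <- function(group, elem, vr, value_raw) {
  value_raw <- dcm_pad(value_raw, if (vr == "UI") as.raw(0) else as.raw(0x20))
  head <- c(dcm_uint(group, 2), dcm_uint(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_uint(length(value_raw), 4), value_raw)
  } else {
    c(head, dcm_uint(length(value_raw), 2), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, v) dcm_element(group, elem, "US", dcm_uint(v, 2))
dcm_ds <- function(group, elem, v) {
  dcm_str(group, elem, "DS", paste(formatC(v, format = "g", digits = 10), collapse = "\\"))
}

#' Write a CT volume as a DICOM series (one file per slice)
#'
#' Minimal explicit-VR little-endian single-frame CT writer; HU values are
#' stored as signed 16-bit with identity rescale. Intended for generating
#' small test series; labels are not representable in DICOM and are dropped.
#'
#' @param volume A [ct_volume()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$data)
  iop <- c(volume$axes[, 1], volume$axes[, 2])
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- volume$origin + volume$axes[, 3] * volume$spacing[3] * (k - 1)
    pix <- as.integer(as.vector(volume$data[, , k]))
    meta <- c(
      dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0002, 0x0003, "UI", sprintf("1.2.826.0.1.3680043.9999.1.%d", k)),
      dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    body <- c(
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      dcm_ds(0x0020, 0x0032, ipp),
      dcm_ds(0x0020, 0x0037, iop),
      dcm_us(0x0028, 0x0002, 1),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[2]),         # Rows (y)
      dcm_us(0x0028, 0x0011, d[1]),         # Columns (x)
      dcm_ds(0x0028, 0x0030, c(volume$spacing[2], volume$spacing[1])),
      dcm_us(0x0028, 0x0100, 16),
      dcm_us(0x0028, 0x0101, 16),
      dcm_us(0x0028, 0x0102, 15),
      dcm_us(0x0028, 0x0103, 1),
      dcm_ds(0x0028, 0x1052, 0),
      dcm_ds(0x0028, 0x1053, 1),
      dcm_element(0x7FE0, 0x0010, "OW", writeBin(pix, raw(), size = 2, endian = "little"))
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta), 4)), meta)
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(paths)
}

parse_dicom_file <- function(path) {
  buf <- readBin(path, raw(), n = file.info(path)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM") {
    abort_ct("format_error", "'%s' is not a DICOM file (missing DICM magic)", path)
  }
  pos <- 133L
  rd_u <- function(at, size) {
    readBin(buf[at:(at + size - 1)], "integer", size = size,
            endian = "little", signed = size > 2)
  }
  tags <- list()
  while (pos + 8 <= length(buf) + 1) {
    group <- rd_u(pos, 2); elem <- rd_u(pos + 2, 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd_u(pos + 8, 4); vstart <- pos + 12L
    } else {
      len <- rd_u(pos + 6, 2); vstart <- pos + 8L
    }
    if (len == 4294967295 || vr == "SQ") {
      abort_ct("format_error", "unsupported DICOM encoding (sequence) in '%s'", path)
    }
    key <- sprintf("%04x,%04x", group, elem)
    val_raw <- if (len > 0) buf[vstart:(vstart + len - 1)] else raw(0)
    tags[[key]] <- list(vr = vr, raw = val_raw)
    pos <- vstart + len
    if (key == "7fe0,0010") break
  }
  tags
}

dcm_get_ds <- function(tags, key, path) {
  t <- tags[[key]]
  if (is.null(t)) abort_ct("format_error", "missing DICOM tag (%s) in '%s'", key, path)
  as.numeric(strsplit(trimws(rawToChar(t$raw)), "\\\\")[[1]])
}

dcm_get_us <- function(tags, key, path) {
  t <- tags[[key]]
  if (is.null(t)) abort_ct("format_error", "missing DICOM tag (%s) in '%s'", key, path)
  readBin(t$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) {
    abort_ct("format_error", "DICOM series directory '%s' does not exist", dir)
  }
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    abort_ct("format_error", "no DICOM files found in '%s'", dir)
  }
  slices <- lapply(files, function(f) {
    tags <- parse_dicom_file(f)
    iop <- dcm_get_ds(tags, "0020,0037", f)
    ipp <- dcm_get_ds(tags, "0020,0032", f)
    rows <- dcm_get_us(tags, "0028,0010", f)
    cols <- dcm_get_us(tags, "0028,0011", f)
    ps <- dcm_get_ds(tags, "0028,0030", f)
    slope <- tryCatch(dcm_get_ds(tags, "0028,1053", f), ctbiopsim_error = function(e) 1)
    inter <- tryCatch(dcm_get_ds(tags, "0028,1052", f), ctbiopsim_error = function(e) 0)
    pix_raw <- tags[["7fe0,0010"]]
    if (is.null(pix_raw)) abort_ct("format_error", "missing PixelData in '%s'", f)
    signed <- dcm_get_us(tags, "0028,0103", f) == 1
    pix <- readBin(pix_raw$raw, "integer", n = rows * cols, size = 2,
                   endian = "little", signed = signed)
    list(iop = iop, ipp = ipp, rows = rows, cols = cols, ps = ps,
         hu = matrix(pix * slope + inter, nrow = cols, ncol = rows))
  })
  iop <- slices[[1]]$iop
  xdir <- iop[1:3]; ydir <- iop[4:6]
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  nz <- length(slices)
  dz <- if (nz > 1) mean(diff(zpos)) else slices[[1]]$ps[1]
  data <- array(0L, c(slices[[1]]$cols, slices[[1]]$rows, nz))
  for (k in seq_len(nz)) data[, , k] <- as.integer(round(slices[[k]]$hu))
  axes <- cbind(xdir, ydir, normal)
  ct_volume(data,
            spacing = c(slices[[1]]$ps[2], slices[[1]]$ps[1], dz),
            origin = slices[[1]]$ipp, axes = axes)
}
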