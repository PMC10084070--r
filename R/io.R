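#' Read and write attenuation volumes
#'
#' Lossless round-trip of voxels, voxel size and axis metadata. NIfTI
#' (`.nii` / `.nii.gz`) goes through RNifti; MetaImage (`.mha`, uncompressed,
#' local raw data) is written and parsed directly. Axis order and the time
#' point are carried in the NIfTI description / MetaImage header comments.
#'
#' @param volume an [attenuation_volume()].
#' @param path output path; the extension selects the format.
#' @return [read_volume()] returns an `attenuation_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume(volume))
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(
      structure(volume$voxels, pixdim = volume$voxel_size_um / 1000)
    )
    img <- RNifti::asNifti(img, descrip = sprintf("cartipart t=%s", volume$timepoint_min))
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    write_mha(volume, path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    vs <- RNifti::pixdim(img) * 1000
    descrip <- RNifti::niftiHeader(img)$descrip
    tp <- sub(".*t=([0-9]+).*", "\\1", descrip)
    tp <- suppressWarnings(as.numeric(tp))
    attenuation_volume(array(as.numeric(img), dim = dim(img)),
                       voxel_size_um = vs,
                       timepoint_min = if (is.na(tp)) 60 else tp)
  } else {
    read_mha(path)
  }
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("mha")
  stop("unknown volume extension (use .nii, .nii.gz or .mha): ", path, call. = FALSE)
}

# Minimal MetaImage (.mha) writer: text header + local little-endian raw
write_mha <- function(volume, path) {
  d <- dim(volume$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g\n",
            volume$voxel_size_um[1] / 1000, volume$voxel_size_um[2] / 1000,
            volume$voxel_size_um[3] / 1000),
    sprintf("AnatomicalOrientation = ???\nComment = cartipart t=%s\n",
            volume$timepoint_min),
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n"
  )
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(volume$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line)) stop("corrupt MetaImage header", call. = FALSE)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    fields[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(fields$ElementType, "MET_DOUBLE") ||
      !identical(fields$ElementDataFile, "LOCAL")) {
    stop("unsupported MetaImage variant", call. = FALSE)
  }
  d <- as.integer(strsplit(fields$DimSize, " ")[[1]])
  sp <- as.numeric(strsplit(fields$ElementSpacing, " ")[[1]])
  v <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  tp <- suppressWarnings(as.numeric(sub(".*t=([0-9]+).*", "\\1",
                                        fields$Comment %||% "")))
  attenuation_volume(array(v, dim = d), voxel_size_um = sp * 1000,
                     timepoint_min = if (is.na(tp)) 60 else tp)
}

read_header_line <- function(con) {
  out <- raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0) return(NULL)
    if (ch == as.raw(10)) break
    out <- c(out, ch)
  }
  rawToChar(out)
}

#' Import a 16-bit TIFF slice stack as an attenuation volume
#'
#' Reconstructed stacks exported as unsigned 16-bit TIFF are mapped to HU via
#' a declared linear rescale: `HU = slope * stored + intercept`.
#'
#' @param paths TIFF file paths, one slice each, in lateromedial order.
#' @param slope,intercept rescale parameters.
#' @param voxel_size_um voxel size.
#' @return An [attenuation_volume()].
#' @export
read_tiff_stack <- function(paths, slope = 1, intercept = -1000,
                            voxel_size_um = 80) {
  slices <- lapply(paths, function(p) {
    m <- tiff::readTIFF(p, as.is = TRUE)
    slope * m + intercept
  })
  d <- dim(slices[[1]])
  vox <- array(unlist(slices), dim = c(d[1], d[2], length(slices)))
  attenuation_volume(vox, voxel_size_um = voxel_size_um)
}

#' Write a grey-level image as 16-bit TIFF
#'
#' @param image numeric matrix in \[0, 65535\] (e.g. an `od_section$image`).
#' @param path output path.
#' @export
write_grey_tiff <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_grey_tiff
#' @export
read_grey_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}

#' Write an OD map as 32-bit float TIFF
#'
#' @param od numeric OD matrix.
#' @param path output path.
#' @export
write_od_tiff <- function(od, path) {
  od[is.na(od)] <- -1
  tiff::writeTIFF(od / 4, path, bits.per.sample = 32)
  invisible(path)
}
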