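## Volume I/O: NIfTI through RNifti, MetaImage (.mhd + .raw) through a
## minimal reader/writer (uncompressed, local raw file).

writeMetaImage <- function(vol, path) {
  stopifnot(grepl("\\.mhd$", path))
  rawPath <- sub("\\.mhd$", ".raw", path)
  v <- vol@voxels
  isBinary <- is(vol, "BinaryVolume")
  type <- if (isBinary) "MET_UCHAR" else "MET_DOUBLE"
  d <- dim(v)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", vol@voxelSize, vol@voxelSize,
            vol@voxelSize),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", basename(rawPath)))
  writeLines(header, path)
  con <- file(rawPath, "wb")
  on.exit(close(con))
  if (isBinary)
    writeBin(as.raw(as.integer(v)), con)
  else
    writeBin(as.vector(v), con, size = 8, endian = "little")
  invisible(path)
}

readMetaImage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  get <- function(k) vals[match(k, keys)]
  d <- as.integer(strsplit(trimws(get("DimSize")), "\\s+")[[1]])
  sp <- as.numeric(strsplit(trimws(get("ElementSpacing")), "\\s+")[[1]])
  type <- trimws(get("ElementType"))
  dataFile <- trimws(get("ElementDataFile"))
  rawPath <- file.path(dirname(path), dataFile)
  n <- prod(d)
  con <- file(rawPath, "rb")
  on.exit(close(con))
  v <- switch(type,
    MET_UCHAR = as.numeric(readBin(con, "raw", n)),
    MET_SHORT = readBin(con, "integer", n, size = 2, endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported ElementType: ", type))
  if (length(sp) < 1 || any(abs(sp - sp[1]) > 1e-9))
    stop("anisotropic voxels are not supported")
  GrayVolume(array(as.numeric(v), d), sp[1])
}

#' Read a gray-scale volume (NIfTI or MetaImage)
#'
#' Isotropic voxels are enforced on ingest. NIfTI spacing is taken from
#' pixdim; MetaImage from ElementSpacing.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @return a [GrayVolume-class].
#' @export
readVolume <- function(path) {
  if (grepl("\\.mhd$", path)) return(readMetaImage(path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    if (any(abs(sp - sp[1]) > 1e-9))
      stop("anisotropic voxels are not supported")
    return(GrayVolume(array(as.numeric(img), dim(img)), sp[1]))
  }
  stop("unsupported volume format: ", path)
}

#' Write a volume (NIfTI or MetaImage)
#'
#' Binary volumes are written as 8-bit (0/1); gray volumes as doubles.
#'
#' @param vol a [GrayVolume-class] or [BinaryVolume-class].
#' @param path file path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "VoxelVolume"))
  if (grepl("\\.mhd$", path)) return(writeMetaImage(vol, path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    v <- vol@voxels
    if (is.logical(v)) v <- array(as.integer(v), dim(v))
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- rep(vol@voxelSize, 3)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stop("unsupported volume format: ", path)
}
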