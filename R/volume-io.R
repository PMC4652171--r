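# NIfTI read/write and slice stacking. RNifti does the format work; volumes
# are used in the reader's canonical array order with geometry in mm.

#' Write a volume as NIfTI
#'
#' @param vol A \linkS4class{DiffusionVolume}.
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
saveVolume <- function(vol, path) {
  stopifnot(is(vol, "DiffusionVolume"))
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Intensities and voxel spacing are populated from the file; ground-truth
#' masks do not round-trip (they are analysis-side metadata). The origin is
#' taken as 0 mm: all geometry parameters downstream (projection centre,
#' sectors) are expressed relative to the array grid.
#'
#' @param path Path to a NIfTI file.
#' @return A \linkS4class{DiffusionVolume}.
#' @export
loadVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("unreadable NIfTI file '", path, "': ", conditionMessage(e)))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (length(sp) < 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in ", path)
  DiffusionVolume(values = arr, spacing = sp)
}

#' Stack axial slices into a volume
#'
#' Assembles the 2D image layers of an acquisition into the 3D data stack the
#' pipeline consumes, with through-plane spacing equal to the slice
#' thickness (e.g. 25 slices of 5 mm give a 125 mm deep stack).
#'
#' @param slices List of numeric matrices sharing one in-plane shape, in
#'   acquisition order.
#' @param thickness Slice thickness in mm (> 0).
#' @param inPlaneSpacing In-plane mm per pixel (length 2).
#' @return A \linkS4class{DiffusionVolume}.
#' @export
stackSlices <- function(slices, thickness, inPlaneSpacing = c(1, 1)) {
  stopifnot(length(slices) >= 1, thickness > 0)
  dm <- dim(slices[[1]])
  if (is.null(dm) || length(dm) != 2L)
    stop("slices must be 2D matrices")
  for (s in slices)
    if (!identical(dim(s), dm)) stop("slice shapes do not match")
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(dm, length(slices)))
  DiffusionVolume(values = arr,
                  spacing = c(inPlaneSpacing, thickness))
}

#' Physical extent of a volume in mm
#'
#' @param vol A \linkS4class{DiffusionVolume}.
#' @return Numeric length-3: grid dimensions times voxel spacing.
#' @export
volumeExtent <- function(vol) dim(vol@values) * vol@spacing
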