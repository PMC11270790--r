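#' PET volume container
#'
#' A `pet_volume` wraps a 3-D scalar grid together with its anisotropic voxel
#' spacing and a unit tag. Values are either an activity concentration in
#' kBq/ml (unit `"activity"`, as exported by a scanner before normalisation)
#' or a body-weight standardized uptake value in g/ml (unit `"suv"`). The
#' third array axis is the craniocaudal (axial-stack) direction, so an axial
#' cross-section is the (x, y) plane at fixed z. Voxel indices are 1-based.
#'
#' @param values numeric 3-D array, finite and non-negative.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm,
#'   all strictly positive.
#' @param units `"suv"` (default) or `"activity"`.
#' @return An object of class `pet_volume` with fields `values`, `spacing`
#'   and `units`.
#' @examples
#' vol <- pet_volume(array(1, c(8, 8, 8)), spacing = c(4, 4, 4))
#' dim(vol$values)
#' @export
pet_volume <- function(values, spacing, units = c("suv", "activity")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array", call. = FALSE)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric", call. = FALSE)
  if (any(values < 0))
    stop("'values' must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive voxel sizes in mm",
         call. = FALSE)
  structure(list(values = values, spacing = spacing, units = units),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("PET volume: %s grid, spacing %s mm, units %s\n",
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              x$units))
  cat(sprintf("  value range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Injected-dose and body-weight parameters for SUV normalisation
#'
#' @param injected_dose injected activity in MBq, > 0.
#' @param body_weight patient body weight in kg, > 0.
#' @return An object of class `suv_params`.
#' @examples
#' suv_params(370, 74)
#' @export
suv_params <- function(injected_dose, body_weight) {
  if (!is.numeric(injected_dose) || length(injected_dose) != 1L ||
      !is.finite(injected_dose) || injected_dose <= 0)
    stop("'injected_dose' must be a single positive number (MBq)",
         call. = FALSE)
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("'body_weight' must be a single positive number (kg)", call. = FALSE)
  structure(list(injected_dose = injected_dose, body_weight = body_weight),
            class = "suv_params")
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' Applies the standard body-weight normalisation
#' SUV = C \[kBq/ml\] * W \[g\] / D \[kBq\] voxelwise. With dose in MBq and
#' weight in kg the two factors of 1000 cancel, so SUV = C * W / D. Decay
#' correction is assumed to have been applied upstream by the scanner.
#'
#' @param activity a [pet_volume] tagged `"activity"` (kBq/ml).
#' @param params a [suv_params] object.
#' @return A [pet_volume] tagged `"suv"` on the same grid and spacing.
#' @examples
#' act <- pet_volume(array(5, c(4, 4, 4)), c(4, 4, 4), units = "activity")
#' suv <- suv_convert(act, suv_params(370, 74))
#' range(suv$values)  # uniform 1.0
#' @export
suv_convert <- function(activity, params) {
  stopifnot(inherits(activity, "pet_volume"), inherits(params, "suv_params"))
  if (activity$units != "activity")
    stop("unit mismatch: volume is already in SUV units; ",
         "suv_convert expects an activity-concentration volume",
         call. = FALSE)
  scale <- params$body_weight / params$injected_dose
  pet_volume(activity$values * scale, activity$spacing, units = "suv")
}

#' Read and write PET volumes as NIfTI
#'
#' `read_volume()` loads a 3-D NIfTI image into a [pet_volume];
#' `write_volume()` stores one. Spacing is carried in the NIfTI pixdim and
#' survives the round trip exactly; values survive within float storage
#' precision. The unit tag is not representable in the NIfTI header and is
#' supplied by the caller on read.
#'
#' @param path file path, `.nii` or `.nii.gz`.
#' @param units unit tag to attach on read ("suv" or "activity").
#' @param volume a [pet_volume] to write.
#' @return `read_volume()` returns a [pet_volume]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, units = c("suv", "activity")) {
  units <- match.arg(units)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D NIfTI image, got ", length(d), " dimensions",
         call. = FALSE)
  sp <- abs(RNifti::pixdim(img))
  if (length(sp) < 3L || any(sp[1:3] <= 0))
    stop("NIfTI header has non-positive voxel spacing", call. = FALSE)
  pet_volume(array(as.numeric(img), d), sp[1:3], units = units)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
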