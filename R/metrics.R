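#' Lesion volume and per-slice areas
#'
#' `lesion_volume()` is the metabolic volume of one lesion in cm^3
#' (voxel count x dx*dy*dz / 1000). `slice_areas()` lists the lesion's area
#' on every axial slice it touches, in cm^2 (in-slice voxel count x
#' dx*dy / 100); only the lesion's own voxels count, even where other
#' lesions cross the same slice.
#'
#' @param lesion a `pet_lesion`.
#' @return `lesion_volume()`: a number (cm^3). `slice_areas()`: a data frame
#'   with columns `slice` (z index) and `area_cm2`.
#' @export
lesion_volume <- function(lesion) {
  stopifnot(inherits(lesion, "pet_lesion"))
  nrow(lesion$voxels) * prod(lesion$spacing) / 1000
}

#' @rdname lesion_volume
#' @export
slice_areas <- function(lesion) {
  stopifnot(inherits(lesion, "pet_lesion"))
  tab <- table(lesion$voxels[, 3L])
  data.frame(slice = as.integer(names(tab)),
             area_cm2 = as.numeric(tab) *
               lesion$spacing[1L] * lesion$spacing[2L] / 100)
}

#' Total metabolic tumour volume
#'
#' Sum of the metabolic volumes of all lesions, in cm^3. An empty lesion
#' set has TMTV 0.
#'
#' @param lesions list of `pet_lesion` objects on a common grid.
#' @return TMTV in cm^3.
#' @examples
#' # 1000 voxels at 2 mm isotropic -> 8 cm^3 (see tmtv examples in tests)
#' @export
tmtv <- function(lesions) {
  if (!length(lesions)) return(0)
  sum(vapply(lesions, lesion_volume, numeric(1L)))
}

# Index of the largest lesion: largest metabolic volume, ties broken by
# higher peak SUV, then lower id/list position.
.largest_lesion <- function(lesions) {
  vols <- vapply(lesions, lesion_volume, numeric(1L))
  peaks <- vapply(lesions, function(l) l$peak_suv, numeric(1L))
  order(-vols, -peaks, seq_along(lesions))[1L]
}

#' Metabolic tumour area
#'
#' The maximum axial cross-sectional area of the largest lesion. The
#' largest lesion is the one with the greatest metabolic volume (ties: higher
#' peak SUV, then lower id); its area is evaluated on every axial slice and
#' the maximum is returned. MTA is undefined — an error, not zero — for an
#' empty lesion set.
#'
#' @param lesions list of `pet_lesion` objects on a common grid.
#' @return A list with `mta_cm2`, `lesion_id` (position in `lesions` if ids
#'   are unset), and `slice` (z index of the maximising axial slice; the
#'   lowest such slice on ties).
#' @export
mta <- function(lesions) {
  if (!length(lesions))
    stop("MTA is undefined for an empty lesion set", call. = FALSE)
  k <- .largest_lesion(lesions)
  les <- lesions[[k]]
  sa <- slice_areas(les)
  j <- which.max(sa$area_cm2)
  list(mta_cm2 = sa$area_cm2[j],
       lesion_id = if (is.na(les$id)) k else les$id,
       slice = sa$slice[j])
}

#' Lesion-set SUV statistics
#'
#' SUVmax is the hottest voxel over all lesions; SUVmean is, by default,
#' the pooled mean over all lesion voxels (`"pooled"`), with an unweighted
#' mean of per-lesion means available as `"per_lesion"`.
#'
#' @param lesions list of `pet_lesion` objects.
#' @param mean_mode `"pooled"` (default) or `"per_lesion"`.
#' @return A list with `suvmax` and `suvmean` (g/ml).
#' @export
suv_stats <- function(lesions, mean_mode = c("pooled", "per_lesion")) {
  mean_mode <- match.arg(mean_mode)
  if (!length(lesions))
    stop("SUV statistics are undefined for an empty lesion set",
         call. = FALSE)
  all_vals <- lapply(lesions, function(l) l$values)
  suvmax <- max(unlist(all_vals))
  suvmean <- switch(mean_mode,
    pooled = mean(unlist(all_vals)),
    per_lesion = mean(vapply(all_vals, mean, numeric(1L))))
  list(suvmax = suvmax, suvmean = suvmean)
}

#' Per-patient metabolic profile
#'
#' Bundles the four metabolic parameters — TMTV (cm^3), MTA (cm^2), SUVmax
#' and SUVmean (g/ml) — plus the identity of the largest lesion and the
#' axial slice realising the MTA.
#'
#' @inheritParams suv_stats
#' @return An object of class `metabolic_profile` with fields `tmtv_cm3`,
#'   `mta_cm2`, `suvmax`, `suvmean`, `largest_lesion_id`, `mta_slice`,
#'   `n_lesions`.
#' @export
metabolic_profile <- function(lesions, mean_mode = c("pooled", "per_lesion")) {
  if (!length(lesions))
    stop("metabolic profile is undefined for an empty lesion set",
         call. = FALSE)
  m <- mta(lesions)
  s <- suv_stats(lesions, mean_mode)
  structure(list(tmtv_cm3 = tmtv(lesions), mta_cm2 = m$mta_cm2,
                 suvmax = s$suvmax, suvmean = s$suvmean,
                 largest_lesion_id = m$lesion_id, mta_slice = m$slice,
                 n_lesions = length(lesions)),
            class = "metabolic_profile")
}

#' @export
print.metabolic_profile <- function(x, ...) {
  cat(sprintf(
    paste0("Metabolic profile (%d lesion%s):\n",
           "  TMTV   %8.2f cm^3\n  MTA    %8.2f cm^2 (lesion %s, slice %d)\n",
           "  SUVmax %8.2f g/ml\n  SUVmean%8.2f g/ml\n"),
    x$n_lesions, if (x$n_lesions == 1L) "" else "s",
    x$tmtv_cm3, x$mta_cm2, x$largest_lesion_id, x$mta_slice,
    x$suvmax, x$suvmean))
  invisible(x)
}

#' Metabolic profiles as a one-row data frame
#'
#' @param x a `metabolic_profile`.
#' @param patient_id optional identifier column value.
#' @param ... unused.
#' @return A one-row data frame matching the per-patient metrics CSV schema.
#' @export
as.data.frame.metabolic_profile <- function(x, patient_id = NA, ...) {
  data.frame(patient_id = patient_id, tmtv_cm3 = x$tmtv_cm3,
             mta_cm2 = x$mta_cm2, suvmax = x$suvmax, suvmean = x$suvmean,
             largest_lesion_id = x$largest_lesion_id,
             mta_slice = x$mta_slice)
}
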