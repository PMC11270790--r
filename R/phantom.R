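#' Digital PET phantom specification
#'
#' Describes a synthetic PET volume with lesions of known geometry on a
#' uniform background, optional organ compartments, an isotropic Gaussian
#' point-spread function, and additive Gaussian noise. All randomness is
#' fixed by `seed`, so phantoms are bit-reproducible.
#'
#' Lesion profiles: `"uniform"` sets every voxel whose centre lies within
#' `radius_mm` of the lesion centre to `peak`; `"gaussian"` lays down
#' `peak * exp(-d^2 / (2 sigma_mm^2))`, the blurred-focus model whose 41%
#' isocontour has the closed-form radius sigma * sqrt(2 ln(1/0.41)).
#' Voxels take the maximum of background, organ and lesion contributions.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param background background SUV.
#' @param lesions list of lesion descriptors: `center` (voxel index,
#'   1-based), `peak` SUV, and `radius_mm` (uniform) or `sigma_mm`
#'   (gaussian); `profile` defaults to `"uniform"`.
#' @param organs named list of compartments: each has `shape`
#'   (`"box"` or `"ellipsoid"`), `center` (voxel), half-widths `size_mm`
#'   (length-3, mm), and `suv`.
#' @param psf_fwhm_mm full width at half maximum of the isotropic Gaussian
#'   PSF, in mm; 0 disables blurring.
#' @param noise_sd standard deviation of additive Gaussian noise on SUV;
#'   0 disables noise. Noisy volumes are clamped at 0.
#' @param seed RNG seed fixing the noise realisation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = c(2, 2, 2),
                         background = 0.5, lesions = list(),
                         organs = list(), psf_fwhm_mm = 0, noise_sd = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            background >= 0, psf_fwhm_mm >= 0, noise_sd >= 0)
  for (les in lesions) {
    if (is.null(les$center) || length(les$center) != 3L)
      stop("each lesion needs a length-3 'center' voxel index", call. = FALSE)
    if (any(les$center < 1) || any(les$center > shape))
      stop("lesion centre lies outside the grid", call. = FALSE)
    profile <- if (is.null(les$profile)) "uniform" else les$profile
    if (profile == "uniform" &&
        (is.null(les$radius_mm) || les$radius_mm <= 0))
      stop("uniform lesions need a positive 'radius_mm'", call. = FALSE)
    if (profile == "gaussian" &&
        (is.null(les$sigma_mm) || les$sigma_mm <= 0))
      stop("gaussian lesions need a positive 'sigma_mm'", call. = FALSE)
    if (is.null(les$peak) || les$peak <= background)
      stop("lesion 'peak' must exceed the background SUV", call. = FALSE)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 background = background, lesions = lesions,
                 organs = organs, psf_fwhm_mm = psf_fwhm_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared mm distance of every voxel centre from a centre voxel, as an array.
.dist2_mm <- function(shape, spacing, center) {
  dx2 <- ((seq_len(shape[1L]) - center[1L]) * spacing[1L])^2
  dy2 <- ((seq_len(shape[2L]) - center[2L]) * spacing[2L])^2
  dz2 <- ((seq_len(shape[3L]) - center[3L]) * spacing[3L])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# Separable Gaussian blur with per-axis sigma in voxels; edge-renormalised
# (kernel truncated at 3 sigma and re-scaled so flat fields stay flat).
.gauss_blur <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    # band matrix applying the kernel along this axis, renormalised per row
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1L & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- K %*% matrix(m, nrow = dm[1L])
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

#' Build a digital PET phantom with analytic ground truth
#'
#' Realises a [phantom_spec] as a [pet_volume] plus organ masks and a
#' ground-truth record holding, per lesion, the analytic (pre-PSF,
#' pre-noise) true volume and, for the default 41% percentage-of-max rule,
#' the isocontour volume, radius and maximum axial cross-section area:
#' for a uniform sphere the isocontour is the sphere itself; for a Gaussian
#' focus it is the sphere of radius sigma * sqrt(2 ln(1/fraction)).
#'
#' @param spec a [phantom_spec].
#' @param threshold_fraction fraction used for the isocontour ground truth
#'   (default 0.41).
#' @return A list with `volume` (a [pet_volume]), `masks` (an
#'   [organ_mask_set], or `NULL` without organs) and `truth` (a data frame
#'   with one row per lesion: centre, peak, `true_volume_cm3`,
#'   `iso_radius_mm`, `iso_volume_cm3`, `iso_max_area_cm2`).
#' @examples
#' ph <- make_phantom(phantom_spec(
#'   shape = c(32, 32, 32), spacing = c(2, 2, 2),
#'   lesions = list(list(center = c(16, 16, 16), radius_mm = 15, peak = 10))))
#' ph$truth$iso_volume_cm3  # (4/3) pi 1.5^3 = 14.14 cm^3
#' @export
make_phantom <- function(spec, threshold_fraction = 0.41) {
  stopifnot(inherits(spec, "phantom_spec"))
  vol <- array(spec$background, spec$shape)

  mask_list <- list()
  for (nm in names(spec$organs)) {
    org <- spec$organs[[nm]]
    m <- if (identical(org$shape, "ellipsoid")) {
      dx <- ((seq_len(spec$shape[1L]) - org$center[1L]) * spec$spacing[1L] /
               org$size_mm[1L])^2
      dy <- ((seq_len(spec$shape[2L]) - org$center[2L]) * spec$spacing[2L] /
               org$size_mm[2L])^2
      dz <- ((seq_len(spec$shape[3L]) - org$center[3L]) * spec$spacing[3L] /
               org$size_mm[3L])^2
      outer(outer(dx, dy, `+`), dz, `+`) <= 1
    } else {
      ax <- abs((seq_len(spec$shape[1L]) - org$center[1L]) * spec$spacing[1L])
      ay <- abs((seq_len(spec$shape[2L]) - org$center[2L]) * spec$spacing[2L])
      az <- abs((seq_len(spec$shape[3L]) - org$center[3L]) * spec$spacing[3L])
      outer(outer(ax <= org$size_mm[1L], ay <= org$size_mm[2L], `&`),
            az <= org$size_mm[3L], `&`)
    }
    vol[m] <- pmax(vol[m], org$suv)
    mask_list[[nm]] <- m
  }

  truth <- data.frame()
  for (les in spec$lesions) {
    profile <- if (is.null(les$profile)) "uniform" else les$profile
    d2 <- .dist2_mm(spec$shape, spec$spacing, les$center)
    if (profile == "uniform") {
      inside <- d2 <= les$radius_mm^2
      vol[inside] <- pmax(vol[inside], les$peak)
      r_true <- les$radius_mm
      r_iso <- les$radius_mm
    } else {
      prof <- les$peak * exp(-d2 / (2 * les$sigma_mm^2))
      vol <- pmax(vol, prof)
      r_true <- NA_real_                      # no sharp boundary
      r_iso <- les$sigma_mm * sqrt(2 * log(1 / threshold_fraction))
    }
    truth <- rbind(truth, data.frame(
      x = les$center[1L], y = les$center[2L], z = les$center[3L],
      peak = les$peak, profile = profile,
      true_volume_cm3 = if (is.na(r_true)) NA_real_ else
        4 / 3 * pi * (r_true / 10)^3,
      iso_radius_mm = r_iso,
      iso_volume_cm3 = 4 / 3 * pi * (r_iso / 10)^3,
      iso_max_area_cm2 = pi * (r_iso / 10)^2))
  }

  if (spec$psf_fwhm_mm > 0) {
    sigma_mm <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
    vol <- .gauss_blur(vol, sigma_mm / spec$spacing)
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    vol <- pmax(vol + stats::rnorm(length(vol), sd = spec$noise_sd), 0)
    dim(vol) <- spec$shape
  }

  list(volume = pet_volume(vol, spec$spacing, units = "suv"),
       masks = if (length(mask_list)) organ_mask_set(mask_list) else NULL,
       truth = truth)
}

#' Write a phantom to disk
#'
#' Stores the volume as NIfTI, the masks as a label map + JSON sidecar, and
#' the ground truth as JSON.
#'
#' @param ph result of [make_phantom()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(ph, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$volume, file.path(dir, paste0(stem, ".nii.gz")))
  if (!is.null(ph$masks))
    write_masks(ph$masks, file.path(dir, paste0(stem, "_masks.nii.gz")))
  jsonlite::write_json(ph$truth, file.path(dir, paste0(stem, "_truth.json")),
                       digits = NA)
  invisible(dir)
}
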