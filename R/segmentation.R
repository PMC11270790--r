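#' Segmentation configuration
#'
#' Parameters of percentage-of-maximum lesion delineation. The boundary
#' threshold defaults to 41% of the lesion's peak SUV, the EANM-style
#' percentage-of-max rule. Automatic seed detection uses an absolute floor
#' (default SUV 2.5, a conventional lesion-detection level) and the spleen
#' counts as diffusely involved above 150% of the liver background.
#'
#' @param threshold_fraction fraction of the reference maximum defining the
#'   lesion boundary, in (0, 1). Default 0.41.
#' @param detection_min_suv absolute SUV floor for automatic seed finding
#'   (g/ml), > 0. Default 2.5.
#' @param spleen_diffuse_factor multiple of the liver mean SUV above which
#'   diffuse spleen uptake counts as involvement. Default 1.5.
#' @param threshold_mode `"lesion"` (threshold relative to each lesion's own
#'   local peak, the default), `"patient"` (relative to the global SUVmax of
#'   the volume) or `"absolute"` (threshold is `absolute_suv`, a fixed-SUV
#'   sensitivity mode).
#' @param absolute_suv fixed SUV threshold used when
#'   `threshold_mode = "absolute"`.
#' @return An object of class `seg_config`. Connectivity is fixed at
#'   26-neighbourhood in 3-D.
#' @examples
#' seg_config()
#' seg_config(threshold_fraction = 0.5)
#' @export
seg_config <- function(threshold_fraction = 0.41,
                       detection_min_suv = 2.5,
                       spleen_diffuse_factor = 1.5,
                       threshold_mode = c("lesion", "patient", "absolute"),
                       absolute_suv = 2.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must lie strictly between 0 and 1",
         call. = FALSE)
  if (!is.numeric(detection_min_suv) || detection_min_suv <= 0)
    stop("'detection_min_suv' must be positive", call. = FALSE)
  if (!is.numeric(spleen_diffuse_factor) || spleen_diffuse_factor <= 0)
    stop("'spleen_diffuse_factor' must be positive", call. = FALSE)
  structure(list(threshold_fraction = threshold_fraction,
                 detection_min_suv = detection_min_suv,
                 spleen_diffuse_factor = spleen_diffuse_factor,
                 threshold_mode = threshold_mode,
                 absolute_suv = absolute_suv,
                 connectivity = 26L),
            class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat(sprintf(
    "Segmentation config: %s threshold (%s), seed floor SUV %.2f, spleen factor %.2f\n",
    switch(x$threshold_mode,
           lesion = sprintf("%.0f%% of lesion peak", 100 * x$threshold_fraction),
           patient = sprintf("%.0f%% of patient SUVmax", 100 * x$threshold_fraction),
           absolute = sprintf("SUV %.2f absolute", x$absolute_suv)),
    "26-connectivity", x$detection_min_suv, x$spleen_diffuse_factor))
  invisible(x)
}

# The 26 neighbour offsets of the 3-D Moore neighbourhood, ordered
# lexicographically by (dx, dy, dz) so tie-breaks are deterministic.
.offsets26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[order(g$dx, g$dy, g$dz), c("dx", "dy", "dz")]
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
})

# Linear index (column-major) of 1-based (x, y, z) coordinate rows.
.lin <- function(xyz, dims) {
  xyz[, 1L] + dims[1L] * (xyz[, 2L] - 1L) +
    dims[1L] * dims[2L] * (xyz[, 3L] - 1L)
}

# All in-bounds 26-neighbours of a set of linear indices; returns linear
# indices (with duplicates when neighbourhoods overlap).
.neighbours26 <- function(idx, dims) {
  xyz <- arrayInd(idx, dims)
  n <- nrow(xyz)
  big <- xyz[rep(seq_len(n), each = 26L), , drop = FALSE] +
    .offsets26[rep(seq_len(26L), times = n), , drop = FALSE]
  ok <- big[, 1L] >= 1L & big[, 1L] <= dims[1L] &
        big[, 2L] >= 1L & big[, 2L] <= dims[2L] &
        big[, 3L] >= 1L & big[, 3L] <= dims[3L]
  .lin(big[ok, , drop = FALSE], dims)
}

# 26-connected component of `mask` containing `start` (linear index);
# breadth-first with a vectorised frontier. Returns sorted linear indices.
.flood26 <- function(mask, start, dims) {
  visited <- logical(length(mask))
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nb <- unique(.neighbours26(frontier, dims))
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  which(visited)
}

# Label all 26-connected components of a logical mask. Returns a list of
# integer vectors of linear indices, ordered by each component's smallest
# linear index.
.components26 <- function(mask, dims) {
  remaining <- mask
  comps <- list()
  repeat {
    start <- which.max(remaining)            # first TRUE, column-major order
    if (!length(start) || !remaining[start]) break
    comp <- .flood26(remaining, start, dims)
    remaining[comp] <- FALSE
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# Steepest-ascent hill climb over 26-neighbours from a seed (linear index)
# to a local maximum; among equally-valued best neighbours the
# lexicographically smallest (x, y, z) wins. `allowed` masks out voxels the
# climb may not enter (exclusion organs).
.hill_climb <- function(values, seed, dims, allowed = NULL) {
  cur <- seed
  repeat {
    xyz <- arrayInd(cur, dims)
    nb <- xyz[rep(1L, 26L), , drop = FALSE] + .offsets26
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
    nb <- nb[ok, , drop = FALSE]             # stays in lexicographic order
    nbl <- .lin(nb, dims)
    if (!is.null(allowed)) nbl <- nbl[allowed[nbl]]
    if (!length(nbl)) return(cur)
    v <- values[nbl]
    best <- max(v)
    if (best <= values[cur]) return(cur)
    cur <- nbl[which(v == best)[1L]]         # first = lexicographic smallest
  }
}

# Lexicographic (x, then y, then z) ordering of coordinate rows.
.lex_order <- function(xyz) order(xyz[, 1L], xyz[, 2L], xyz[, 3L])

new_lesion <- function(voxels, values, peak_voxel, peak_suv, threshold,
                       spacing, organ = "other", id = NA_integer_) {
  structure(list(voxels = voxels, values = values, peak_voxel = peak_voxel,
                 peak_suv = peak_suv, threshold = threshold,
                 spacing = spacing, organ = organ, id = id),
            class = "pet_lesion")
}

#' @export
print.pet_lesion <- function(x, ...) {
  cat(sprintf(
    "Lesion (%s): %d voxels, peak SUV %.3g at (%d, %d, %d), threshold %.3g, volume %.3g cm^3\n",
    x$organ, nrow(x$voxels), x$peak_suv,
    x$peak_voxel[1L], x$peak_voxel[2L], x$peak_voxel[3L],
    x$threshold, lesion_volume(x)))
  invisible(x)
}

#' Segment one lesion by percentage-of-maximum thresholding
#'
#' From a seed voxel, climbs (steepest ascent over 26-neighbours) to the
#' lesion's local SUV peak, sets the boundary threshold at
#' `threshold_fraction` times that peak (or per `threshold_mode`), and
#' returns the 26-connected component of the above-threshold region that
#' contains the peak, minus any physiologic-uptake exclusion masks.
#'
#' The result does not depend on where inside the lesion's basin the seed
#' was placed, which mirrors the clinical workflow of clicking anywhere on a
#' hypermetabolic focus.
#'
#' @param volume a [pet_volume] in SUV units.
#' @param seed integer length-3 voxel index (x, y, z), 1-based; must lie
#'   inside the grid, outside all exclusion masks, with SUV > 0.
#' @param config a [seg_config].
#' @param exclusion optional [organ_mask_set] whose exclusion organs are
#'   removed from the search space.
#' @return An object of class `pet_lesion`: `voxels` (n x 3 integer matrix,
#'   lexicographically ordered), per-voxel `values`, `peak_voxel`,
#'   `peak_suv`, the applied `threshold`, `spacing` and an `organ` tag
#'   (assigned later by [tag_lesion_organs()]).
#' @examples
#' v <- array(0.5, c(16, 16, 16))
#' v[6:10, 6:10, 6:10] <- 10
#' vol <- pet_volume(v, c(2, 2, 2))
#' les <- segment_lesion(vol, c(8, 8, 8))
#' nrow(les$voxels)  # the 5^3 uniform block
#' @export
segment_lesion <- function(volume, seed, config = seg_config(),
                           exclusion = NULL) {
  stopifnot(inherits(volume, "pet_volume"), inherits(config, "seg_config"))
  if (volume$units != "suv")
    stop("segmentation requires a volume in SUV units", call. = FALSE)
  dims <- dim(volume$values)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dims))
    stop("seed voxel lies outside the grid", call. = FALSE)
  excl <- combined_exclusion(exclusion, dims)
  seedl <- .lin(matrix(seed, 1L), dims)
  if (!is.null(excl) && excl[seedl])
    stop("rejected seed: voxel lies inside an exclusion mask", call. = FALSE)
  if (volume$values[seedl] <= 0)
    stop("rejected seed: SUV at seed must be positive", call. = FALSE)

  allowed <- if (is.null(excl)) NULL else !excl
  peak <- .hill_climb(volume$values, seedl, dims, allowed)
  peak_suv <- volume$values[peak]
  thr <- switch(config$threshold_mode,
    lesion = config$threshold_fraction * peak_suv,
    patient = config$threshold_fraction *
      max(if (is.null(excl)) volume$values else volume$values[!excl]),
    absolute = config$absolute_suv)

  mask <- volume$values >= thr
  if (!is.null(excl)) mask <- mask & !excl
  if (!mask[peak])     # can only happen in patient/absolute modes
    stop("lesion peak falls below the segmentation threshold", call. = FALSE)
  comp <- .flood26(mask, peak, dims)
  xyz <- arrayInd(comp, dims)
  ord <- .lex_order(xyz)
  xyz <- xyz[ord, , drop = FALSE]
  new_lesion(voxels = xyz, values = volume$values[comp[ord]],
             peak_voxel = arrayInd(peak, dims)[1L, ], peak_suv = peak_suv,
             threshold = thr, spacing = volume$spacing)
}

#' Automatic seed detection
#'
#' Finds one seed per 26-connected component of the super-threshold region
#' \{SUV >= detection_min_suv\} after removing exclusion organs, placed at
#' each component's hottest voxel (ties broken by lexicographically smallest
#' index). This replaces the physician's click in a fully automatic run;
#' manually supplied seed lists always take precedence in pipelines.
#'
#' @inheritParams segment_lesion
#' @return Integer matrix with columns x, y, z (possibly zero rows), ordered
#'   lexicographically by seed coordinate.
#' @export
auto_seeds <- function(volume, config = seg_config(), exclusion = NULL) {
  stopifnot(inherits(volume, "pet_volume"), inherits(config, "seg_config"))
  if (volume$units != "suv")
    stop("seed detection requires a volume in SUV units", call. = FALSE)
  dims <- dim(volume$values)
  mask <- volume$values >= config$detection_min_suv
  excl <- combined_exclusion(exclusion, dims)
  if (!is.null(excl)) mask <- mask & !excl
  comps <- .components26(mask, dims)
  if (!length(comps))
    return(matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "z"))))
  seeds <- t(vapply(comps, function(comp) {
    v <- volume$values[comp]
    cand <- comp[v == max(v)]
    xyz <- arrayInd(cand, dims)
    xyz[.lex_order(xyz)[1L], ]
  }, integer(3L)))
  colnames(seeds) <- c("x", "y", "z")
  seeds[.lex_order(seeds), , drop = FALSE]
}

#' Spleen involvement rule
#'
#' The spleen counts as involved if it shows focal uptake, or diffuse uptake
#' exceeding 150% of the liver background (strict inequality). Diffuse:
#' mean SUV over the spleen mask > factor x mean SUV over the liver mask.
#' Focal: an automatically detected seed inside the spleen whose peak SUV is
#' at least the detection floor and above factor x liver mean.
#'
#' @param volume a [pet_volume] in SUV units.
#' @param spleen_mask,liver_mask logical 3-D arrays on the volume's grid.
#' @param config a [seg_config].
#' @return A list with `involved` (logical) and
#'   `mode` (`"focal"`, `"diffuse"` or `"none"`); when both rules fire the
#'   uptake is reported as diffuse (a uniformly hot spleen is diffuse
#'   involvement even though it also contains super-threshold voxels).
#' @export
spleen_involved <- function(volume, spleen_mask, liver_mask,
                            config = seg_config()) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!any(liver_mask))
    stop("missing reference: the liver mask is empty", call. = FALSE)
  if (!any(spleen_mask))
    stop("the spleen mask is empty", call. = FALSE)
  liver_mean <- mean(volume$values[liver_mask])
  spleen_mean <- mean(volume$values[spleen_mask])

  dims <- dim(volume$values)
  seeds <- auto_seeds(volume, config)
  focal <- FALSE
  if (nrow(seeds)) {
    inside <- spleen_mask[.lin(seeds, dims)]
    if (any(inside)) {
      peaks <- volume$values[.lin(seeds[inside, , drop = FALSE], dims)]
      focal <- any(peaks >= config$detection_min_suv &
                   peaks > config$spleen_diffuse_factor * liver_mean)
    }
  }
  diffuse <- spleen_mean > config$spleen_diffuse_factor * liver_mean
  mode <- if (diffuse) "diffuse" else if (focal) "focal" else "none"
  list(involved = focal || diffuse, mode = mode)
}

#' Tag lesions with their organ of origin
#'
#' Assigns each lesion the organ whose mask covers the majority of its
#' voxels; a lesion mostly outside every mask is tagged `"nodal"`, and an
#' exact tie between organs yields `"other"`.
#'
#' @param lesions list of `pet_lesion` objects.
#' @param masks an [organ_mask_set] (typically spleen / liver / bone_marrow).
#' @return The lesion list with `organ` tags filled in.
#' @export
tag_lesion_organs <- function(lesions, masks) {
  stopifnot(inherits(masks, "organ_mask_set"))
  dims <- dim(masks$masks[[1L]])
  lapply(lesions, function(les) {
    idx <- .lin(les$voxels, dims)
    counts <- vapply(masks$masks, function(m) sum(m[idx]), numeric(1L))
    n <- nrow(les$voxels)
    if (!length(counts) || max(counts) <= n / 2) {
      les$organ <- "nodal"
    } else {
      top <- names(counts)[counts == max(counts)]
      les$organ <- if (length(top) > 1L) "other" else top
    }
    les
  })
}

#' Conditional-organ filtering
#'
#' The bone marrow and liver count as disease only under focal uptake: a
#' lesion tagged `liver` or `bone_marrow` is kept only when its peak SUV
#' reaches the automatic detection floor (the focality proxy); diffusely
#' elevated background in those organs never enters the lesion set. Nodal,
#' splenic and other lesions pass through unchanged.
#'
#' @param lesions list of `pet_lesion` objects with organ tags (see
#'   [tag_lesion_organs()]).
#' @param config a [seg_config] supplying `detection_min_suv`.
#' @return The filtered lesion list.
#' @export
filter_conditional_organs <- function(lesions, config = seg_config()) {
  keep <- vapply(lesions, function(les) {
    if (les$organ %in% c("liver", "bone_marrow"))
      les$peak_suv >= config$detection_min_suv
    else TRUE
  }, logical(1L))
  lesions[keep]
}

#' Segment every detected lesion in a volume
#'
#' Convenience wrapper: detect seeds automatically (or take a supplied seed
#' matrix), segment each, deduplicate lesions that climbed to the same peak,
#' tag organs when masks are given, and apply conditional-organ filtering.
#'
#' @inheritParams segment_lesion
#' @param seeds optional integer matrix of seed voxels (columns x, y, z);
#'   when `NULL`, [auto_seeds()] is used.
#' @param masks optional [organ_mask_set] used both for exclusions and for
#'   organ tagging.
#' @return A list of `pet_lesion` objects with `id` fields 1..k.
#' @export
segment_all <- function(volume, config = seg_config(), masks = NULL,
                        seeds = NULL) {
  if (is.null(seeds)) seeds <- auto_seeds(volume, config, masks)
  if (!nrow(seeds)) return(list())
  lesions <- lapply(seq_len(nrow(seeds)), function(i)
    segment_lesion(volume, seeds[i, ], config, masks))
  peaks <- vapply(lesions, function(l)
    paste(l$peak_voxel, collapse = ","), character(1L))
  lesions <- lesions[!duplicated(peaks)]
  if (!is.null(masks)) {
    lesions <- tag_lesion_organs(lesions, masks)
    lesions <- filter_conditional_organs(lesions, config)
  }
  if (length(lesions))
    for (i in seq_along(lesions)) lesions[[i]]$id <- i
  lesions
}

#' Read seed voxels from CSV or JSON
#'
#' CSV files need integer columns `x`, `y`, `z` (1-based voxel indices);
#' JSON files hold an array of `{x, y, z}` objects or of `[x, y, z]` triples.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return Integer matrix with columns x, y, z.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- if (is.data.frame(raw)) as.matrix(raw[, c("x", "y", "z")])
         else matrix(as.integer(unlist(raw)), ncol = 3L, byrow = TRUE)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("x", "y", "z") %in% names(df)))
      stop("seed CSV must have columns x, y, z", call. = FALSE)
    m <- as.matrix(df[, c("x", "y", "z")])
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Write a lesion set as a label map and summary CSV
#'
#' @param lesions list of `pet_lesion` objects on a common grid.
#' @param dims grid dimensions of the source volume.
#' @param nifti_path optional path for an integer label map (lesion ids).
#' @param csv_path optional path for a per-lesion summary (id, peak SUV,
#'   volume cm^3, max axial slice area cm^2, organ tag).
#' @return The summary data frame, invisibly.
#' @export
write_lesions <- function(lesions, dims, nifti_path = NULL, csv_path = NULL) {
  if (!is.null(nifti_path)) {
    lab <- array(0L, dims)
    for (les in lesions) lab[.lin(les$voxels, dims)] <- les$id
    img <- RNifti::asNifti(lab)
    if (length(lesions)) RNifti::pixdim(img) <- lesions[[1L]]$spacing
    RNifti::writeNifti(img, nifti_path, datatype = "int32")
  }
  df <- data.frame(
    id = vapply(lesions, function(l) l$id, integer(1L)),
    peak_suv = vapply(lesions, function(l) l$peak_suv, numeric(1L)),
    volume_cm3 = vapply(lesions, lesion_volume, numeric(1L)),
    max_slice_area_cm2 = vapply(lesions, function(l)
      max(slice_areas(l)$area_cm2), numeric(1L)),
    organ = vapply(lesions, function(l) l$organ, character(1L)))
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}
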