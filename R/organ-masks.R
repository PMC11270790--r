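#' Organ mask set
#'
#' Named binary organ masks on the same grid as a PET volume. Masks play
#' three roles in lesion quantification: physiologic-uptake organs are
#' excluded from segmentation outright (brain, bladder, kidneys, myocardium),
#' the liver serves as the uptake reference for the spleen rule, and the
#' spleen, bone marrow and liver are conditional targets that count as
#' disease only under focal/diffuse uptake rules.
#'
#' @param masks named list of logical (or 0/1) arrays, all with identical
#'   dimensions.
#' @param exclusion_organs character; names treated as physiologic-uptake
#'   exclusions. Defaults to the standard four where present.
#' @return An object of class `organ_mask_set`.
#' @examples
#' m <- array(FALSE, c(8, 8, 8)); m[1:3, 1:3, 1:3] <- TRUE
#' oms <- organ_mask_set(list(liver = m))
#' names(oms$masks)
#' @export
organ_mask_set <- function(masks,
                           exclusion_organs = c("brain", "bladder",
                                                "kidneys", "myocardium")) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("'masks' must be a named list of binary arrays", call. = FALSE)
  dims <- NULL
  masks <- lapply(masks, function(m) {
    if (!is.array(m) || length(dim(m)) != 3L)
      stop("each mask must be a 3-D array", call. = FALSE)
    storage.mode(m) <- "logical"
    m
  })
  for (m in masks) {
    if (is.null(dims)) dims <- dim(m)
    else if (!identical(dims, dim(m)))
      stop("all masks must share the same grid dimensions", call. = FALSE)
  }
  structure(list(masks = masks,
                 exclusion_organs = intersect(exclusion_organs, names(masks))),
            class = "organ_mask_set")
}

#' @export
print.organ_mask_set <- function(x, ...) {
  cat(sprintf("Organ mask set: %s\n", paste(names(x$masks), collapse = ", ")))
  if (length(x$exclusion_organs))
    cat(sprintf("  exclusions: %s\n",
                paste(x$exclusion_organs, collapse = ", ")))
  invisible(x)
}

# Union of the physiologic-uptake exclusion masks (NULL if none).
combined_exclusion <- function(exclusion, dims = NULL) {
  if (is.null(exclusion)) return(NULL)
  stopifnot(inherits(exclusion, "organ_mask_set"))
  orgs <- exclusion$exclusion_organs
  if (!length(orgs)) return(NULL)
  out <- NULL
  for (nm in orgs) {
    m <- exclusion$masks[[nm]]
    out <- if (is.null(out)) m else (out | m)
  }
  out
}

#' Read and write organ masks as a labelled NIfTI map
#'
#' Masks are stored as one integer label map plus a JSON sidecar mapping
#' label values to organ names, so a mask set round-trips through two small
#' files. Overlapping masks cannot be represented in a single label map;
#' `write_masks()` refuses them.
#'
#' @param oms an [organ_mask_set].
#' @param path NIfTI path for the label map; the sidecar is `<path>.json`
#'   unless given.
#' @param sidecar JSON sidecar path.
#' @param ... passed to [organ_mask_set()] on read (e.g. `exclusion_organs`).
#' @return `read_masks()` returns an [organ_mask_set].
#' @export
write_masks <- function(oms, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(oms, "organ_mask_set"))
  dims <- dim(oms$masks[[1L]])
  lab <- array(0L, dims)
  for (i in seq_along(oms$masks)) {
    m <- oms$masks[[i]]
    if (any(lab[m] != 0L))
      stop("overlapping masks cannot be written as one label map",
           call. = FALSE)
    lab[m] <- i
  }
  RNifti::writeNifti(RNifti::asNifti(lab), path, datatype = "int32")
  jsonlite::write_json(
    list(labels = stats::setNames(as.list(seq_along(oms$masks)),
                                  names(oms$masks)),
         exclusion_organs = oms$exclusion_organs),
    sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path, sidecar = paste0(path, ".json"), ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("mask sidecar not found: ", sidecar, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D label map", call. = FALSE)
  lab <- array(as.integer(img), dim(img))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  masks <- lapply(meta$labels, function(v) lab == as.integer(v))
  args <- list(masks = masks)
  extra <- list(...)
  if (!("exclusion_organs" %in% names(extra)) &&
      !is.null(meta$exclusion_organs) && length(meta$exclusion_organs))
    args$exclusion_organs <- meta$exclusion_organs
  do.call(organ_mask_set, c(args, extra))
}
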