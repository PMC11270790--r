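sphere_volume <- function(center = c(16, 16, 16), r_mm = 15, peak = 10,
                          shape = c(32, 32, 32), spacing = c(2, 2, 2),
                          background = 0.5) {
  make_phantom(phantom_spec(
    shape = shape, spacing = spacing, background = background,
    lesions = list(list(center = center, radius_mm = r_mm,
                        peak = peak))))$volume
}

test_that("a uniform hot sphere is segmented in its entirety from any seed", {
  vol <- sphere_volume()
  truth <- which(vol$values == 10, arr.ind = TRUE)
  for (seed in list(c(16, 16, 16), c(12, 16, 16), c(16, 20, 18))) {
    les <- segment_lesion(vol, seed)
    expect_equal(nrow(les$voxels), nrow(truth))
    expect_equal(les$peak_suv, 10)
    expect_equal(les$threshold, 4.1)
  }
})

test_that("the 41% isocontour of a Gaussian focus has the analytic radius", {
  sigma <- 6
  ph <- make_phantom(phantom_spec(
    shape = c(48, 48, 48), spacing = c(2, 2, 2), background = 0.1,
    lesions = list(list(center = c(24, 24, 24), profile = "gaussian",
                        sigma_mm = sigma, peak = 10))))
  les <- segment_lesion(ph$volume, c(24, 24, 24))
  r_analytic <- sigma * sqrt(2 * log(10 / 4.1))
  # volume-equivalent radius of the segmented set, within one voxel
  r_measured <- (3 * lesion_volume(les) * 1000 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_measured - r_analytic), 2)
  # maximum in-lesion extent along x through the centre, within one voxel
  ctr_row <- les$voxels[, 2] == 24 & les$voxels[, 3] == 24
  r_extent <- (max(les$voxels[ctr_row, 1]) - min(les$voxels[ctr_row, 1])) / 2 * 2
  expect_lt(abs(r_extent - r_analytic), 2)
})

test_that("segmentation respects connectivity: only the seeded sphere", {
  ph <- make_phantom(phantom_spec(
    shape = c(48, 32, 32), spacing = c(2, 2, 2), background = 0.2,
    lesions = list(list(center = c(12, 16, 16), radius_mm = 8, peak = 10),
                   list(center = c(36, 16, 16), radius_mm = 8, peak = 8))))
  les <- segment_lesion(ph$volume, c(12, 16, 16))
  expect_true(all(les$voxels[, 1] < 24))
  expect_equal(les$peak_suv, 10)
})

test_that("segment_lesion agrees with a brute-force flood-fill oracle", {
  for (seed in 1:10) {
    vol <- random_blob_volume(seed)
    hot <- which(vol$values > 2, arr.ind = TRUE)
    if (!nrow(hot)) next
    set.seed(seed + 1000)
    start <- hot[sample(nrow(hot), 1), ]
    les <- segment_lesion(vol, start)
    oracle <- oracle_flood(vol$values, les$peak_voxel, 0.41)
    expect_identical(unname(les$voxels), unname(oracle))
  }
})

test_that("lowering the threshold fraction never shrinks the lesion", {
  vol <- random_blob_volume(99)
  seed <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  keys <- function(les) paste(les$voxels[, 1], les$voxels[, 2],
                              les$voxels[, 3])
  prev <- character(0)
  for (f in c(0.8, 0.6, 0.41, 0.25, 0.1)) {
    les <- segment_lesion(vol, seed, seg_config(threshold_fraction = f))
    cur <- keys(les)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("exclusion masks are never part of a lesion and reject seeds", {
  vol <- sphere_volume(background = 0.2)
  brain <- array(FALSE, c(32, 32, 32))
  brain[14:18, 14:18, 14:18] <- TRUE        # carve out the sphere's core
  oms <- organ_mask_set(list(brain = brain))
  expect_error(segment_lesion(vol, c(16, 16, 16), exclusion = oms),
               "rejected seed")
  les <- segment_lesion(vol, c(16, 16, 22), exclusion = oms)
  inside <- brain[cbind(les$voxels[, 1], les$voxels[, 2], les$voxels[, 3])]
  expect_false(any(inside))
})

test_that("seeds anywhere in the same basin give identical lesions", {
  vol <- random_blob_volume(7)
  peak <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  ref <- segment_lesion(vol, peak)
  in_basin <- ref$voxels[c(1, nrow(ref$voxels) %/% 2, nrow(ref$voxels)), ]
  for (i in seq_len(nrow(in_basin))) {
    les <- segment_lesion(vol, in_basin[i, ])
    if (!identical(les$peak_voxel, ref$peak_voxel)) next  # different basin
    expect_identical(les$voxels, ref$voxels)
  }
})

test_that("auto_seeds finds one seed per hot component", {
  # all-background volume: nothing to find
  bg <- pet_volume(array(0.5, c(16, 16, 16)), c(2, 2, 2))
  expect_equal(nrow(auto_seeds(bg)), 0)

  # three disjoint spheres above the detection floor
  ph <- make_phantom(phantom_spec(
    shape = c(64, 32, 32), spacing = c(2, 2, 2), background = 0.2,
    lesions = list(list(center = c(10, 16, 16), radius_mm = 6, peak = 10),
                   list(center = c(32, 16, 16), radius_mm = 6, peak = 6),
                   list(center = c(54, 16, 16), radius_mm = 6, peak = 4))))
  seeds <- auto_seeds(ph$volume)
  expect_equal(nrow(seeds), 3)
  comps <- oracle_components(ph$volume$values >= 2.5)
  expect_equal(length(comps), 3)
  # each seed is its own component's hottest voxel
  for (i in seq_len(nrow(seeds))) {
    holds <- sapply(comps, function(cm)
      any(cm[, 1] == seeds[i, 1] & cm[, 2] == seeds[i, 2] &
          cm[, 3] == seeds[i, 3]))
    expect_equal(sum(holds), 1)
    cm <- comps[[which(holds)]]
    expect_equal(ph$volume$values[seeds[i, 1], seeds[i, 2], seeds[i, 3]],
                 max(ph$volume$values[cm]))
  }

  # a peak just below the floor is not detected
  ph2 <- make_phantom(phantom_spec(
    shape = c(32, 32, 32), spacing = c(2, 2, 2), background = 0.2,
    lesions = list(list(center = c(16, 16, 16), radius_mm = 6,
                        peak = 2.4))))
  expect_equal(nrow(auto_seeds(ph2$volume)), 0)
})

test_that("spleen involvement follows the focal/diffuse uptake rules", {
  mk <- function(spleen_suv, liver_suv, focus = NULL) {
    v <- array(0.3, c(32, 32, 16))
    spleen <- array(FALSE, dim(v)); spleen[4:12, 4:12, 4:12] <- TRUE
    liver <- array(FALSE, dim(v)); liver[20:28, 20:28, 4:12] <- TRUE
    v[spleen] <- spleen_suv
    v[liver] <- liver_suv
    if (!is.null(focus)) v[8, 8, 8] <- focus
    list(vol = pet_volume(v, c(2, 2, 2)), spleen = spleen, liver = liver)
  }
  s <- mk(3.1, 2.0)
  res <- spleen_involved(s$vol, s$spleen, s$liver)
  expect_true(res$involved)
  expect_equal(res$mode, "diffuse")      # ratio 1.55 > 1.5

  s <- mk(3.0, 2.0)
  res <- spleen_involved(s$vol, s$spleen, s$liver)
  expect_false(res$involved)             # ratio exactly 1.5: strict rule
  expect_equal(res$mode, "none")

  s <- mk(1.0, 2.0, focus = 6)
  res <- spleen_involved(s$vol, s$spleen, s$liver)
  expect_true(res$involved)
  expect_equal(res$mode, "focal")

  empty <- array(FALSE, c(32, 32, 16))
  expect_error(spleen_involved(s$vol, s$spleen, empty), "reference")
})

test_that("liver and bone marrow lesions need focal uptake to count", {
  spacing <- c(2, 2, 2)
  mk_tagged <- function(organ, peak) {
    vox <- matrix(c(1, 1, 1), 1, 3)
    l <- mk_lesion(vox, peak, spacing, organ = organ)
    l
  }
  lesions <- list(mk_tagged("nodal", 8), mk_tagged("nodal", 5),
                  mk_tagged("bone_marrow", 1.8))   # diffuse-level BM
  kept <- filter_conditional_organs(lesions)
  expect_length(kept, 2)
  expect_true(all(sapply(kept, function(l) l$organ) == "nodal"))

  # focal liver lesion above the detection floor is retained
  lesions2 <- list(mk_tagged("liver", 6))
  expect_length(filter_conditional_organs(lesions2), 1)
  # diffusely elevated liver is not
  lesions3 <- list(mk_tagged("liver", 2.0))
  expect_length(filter_conditional_organs(lesions3), 0)
})

test_that("organ tagging uses majority overlap", {
  dims <- c(16, 16, 16)
  spleen <- array(FALSE, dims); spleen[1:8, , ] <- TRUE
  oms <- organ_mask_set(list(spleen = spleen))
  vox_in <- as.matrix(expand.grid(x = 2:6, y = 2:4, z = 2:4))
  vox_out <- as.matrix(expand.grid(x = 10:14, y = 2:4, z = 2:4))
  l_in <- mk_lesion(vox_in, rep(5, nrow(vox_in)), c(2, 2, 2))
  l_out <- mk_lesion(vox_out, rep(5, nrow(vox_out)), c(2, 2, 2))
  tagged <- tag_lesion_organs(list(l_in, l_out), oms)
  expect_equal(tagged[[1]]$organ, "spleen")
  expect_equal(tagged[[2]]$organ, "nodal")
})

test_that("seed files round trip from CSV and JSON", {
  m <- matrix(c(1L, 2L, 3L, 10L, 11L, 12L), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("x", "y", "z")))
  fc <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(m), fc, row.names = FALSE)
  expect_equal(read_seeds(fc), m)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(as.data.frame(m), fj)
  expect_equal(read_seeds(fj), m)
})
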