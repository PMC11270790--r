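block_lesion <- function(nx, ny, nz, spacing, value = 10, offset = c(0, 0, 0)) {
  vox <- as.matrix(expand.grid(x = seq_len(nx) + offset[1],
                               y = seq_len(ny) + offset[2],
                               z = seq_len(nz) + offset[3]))
  mk_lesion(vox, rep(value, nrow(vox)), spacing)
}

test_that("TMTV is voxel count times voxel volume, summed over lesions", {
  les <- block_lesion(10, 10, 10, c(2, 2, 2))   # 1000 voxels at 8 mm^3
  expect_equal(tmtv(list(les)), 8)
  expect_equal(tmtv(list()), 0)

  # additivity over disjoint lesion sets
  les2 <- block_lesion(5, 5, 4, c(2, 2, 2), offset = c(20, 0, 0))
  expect_equal(tmtv(list(les, les2)), tmtv(list(les)) + tmtv(list(les2)))
})

test_that("digitised sphere metrics approach the analytic values", {
  ph <- make_phantom(phantom_spec(
    shape = c(32, 32, 32), spacing = c(2, 2, 2), background = 0.3,
    lesions = list(list(center = c(16, 16, 16), radius_mm = 15,
                        peak = 10))))
  les <- segment_lesion(ph$volume, c(16, 16, 16))
  expect_equal(tmtv(list(les)), 4 / 3 * pi * 1.5^3, tolerance = 0.05)
  expect_equal(mta(list(les))$mta_cm2, pi * 1.5^2, tolerance = 0.05)
})

test_that("MTA selects the largest lesion by volume, then its best slice", {
  # single voxel at 2 x 2 mm in-plane: 0.04 cm^2
  one <- mk_lesion(matrix(c(3, 3, 3), 1, 3), 5, c(2, 2, 2))
  expect_equal(mta(list(one))$mta_cm2, 0.04)

  # selection by volume, not by slice area: A has 10 cm^3 with 3 cm^2 max
  # slice, B has 8 cm^3 with a 5 cm^2 slice; MTA comes from A
  sp <- c(10, 10, 10)                       # 1 voxel = 1 cm^3, 1 cm^2
  vox_a <- rbind(as.matrix(expand.grid(1:3, 1, 1)),
                 as.matrix(expand.grid(1:3, 1, 2)),
                 as.matrix(expand.grid(1:3, 1, 3)),
                 matrix(c(1, 1, 4), 1, 3))
  colnames(vox_a) <- NULL
  a <- mk_lesion(vox_a, rep(10, 10), sp)
  vox_b <- rbind(as.matrix(expand.grid(11:15, 1, 1)),
                 as.matrix(expand.grid(11:13, 1, 2)))
  colnames(vox_b) <- NULL
  b <- mk_lesion(vox_b, rep(10, 8), sp)
  res <- mta(list(a, b))
  expect_equal(res$mta_cm2, 3)
  expect_equal(res$lesion_id, 1)

  expect_error(mta(list()), "undefined")
})

test_that("SUV statistics pool voxels across lesions", {
  l1 <- mk_lesion(matrix(c(1, 1, 1, 2, 1, 1, 3, 1, 1), 3, 3, byrow = TRUE),
                  c(2, 4, 6), c(2, 2, 2))
  s <- suv_stats(list(l1))
  expect_equal(s$suvmax, 6)
  expect_equal(s$suvmean, 4)

  l2 <- mk_lesion(matrix(c(9, 9, 9), 1, 3), 10, c(2, 2, 2))
  l3 <- mk_lesion(matrix(c(1, 5, 5, 2, 5, 5), 2, 3, byrow = TRUE),
                  c(2, 2), c(2, 2, 2))
  s2 <- suv_stats(list(l2, l3))
  expect_equal(s2$suvmax, 10)
  expect_equal(s2$suvmean, 14 / 3)
  expect_equal(suv_stats(list(l2, l3), mean_mode = "per_lesion")$suvmean, 6)

  l4 <- mk_lesion(matrix(c(1, 1, 1, 2, 1, 1), 2, 3, byrow = TRUE),
                  c(5, 5), c(2, 2, 2))
  s3 <- suv_stats(list(l4))
  expect_equal(s3$suvmax, 5)
  expect_equal(s3$suvmean, 5)
  expect_error(suv_stats(list()), "undefined")
})

test_that("metric scaling and the slice-volume bound hold", {
  les <- block_lesion(4, 5, 6, c(2, 2, 2))
  les_2x <- mk_lesion(les$voxels, les$values, c(4, 4, 4))
  expect_equal(tmtv(list(les_2x)), 8 * tmtv(list(les)))
  expect_equal(mta(list(les_2x))$mta_cm2, 4 * mta(list(les))$mta_cm2)

  # MTA x slice thickness never exceeds the largest lesion's volume;
  # equality exactly for one-slice lesions
  for (seed in 1:5) {
    vol <- random_blob_volume(seed)
    peak <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
    les <- segment_lesion(vol, peak)
    m <- mta(list(les))
    expect_lte(m$mta_cm2 * vol$spacing[3] / 10,
               lesion_volume(les) + 1e-12)
  }
  flat <- block_lesion(4, 4, 1, c(2, 2, 2))
  expect_equal(mta(list(flat))$mta_cm2 * 2 / 10, lesion_volume(flat))
})

test_that("metabolic profile bundles the four parameters consistently", {
  ph <- make_phantom(phantom_spec(
    shape = c(48, 32, 32), spacing = c(2, 2, 2), background = 0.2,
    lesions = list(list(center = c(12, 16, 16), radius_mm = 9, peak = 10),
                   list(center = c(36, 16, 16), radius_mm = 5, peak = 14))))
  lesions <- segment_all(ph$volume)
  prof <- metabolic_profile(lesions)
  expect_equal(prof$tmtv_cm3, tmtv(lesions))
  expect_equal(prof$mta_cm2, mta(lesions)$mta_cm2)
  expect_gte(prof$suvmax, prof$suvmean)
  expect_equal(prof$n_lesions, 2)
  # larger-volume lesion wins even though the other is hotter
  expect_equal(prof$largest_lesion_id, 1)
  df <- as.data.frame(prof, patient_id = "p1")
  expect_equal(df$tmtv_cm3, prof$tmtv_cm3)
})
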