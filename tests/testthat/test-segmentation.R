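test_that("lifetime gate is inclusive and NaN-safe", {
  lt <- matrix(c(1300, 700, 800, 1500, 1501, NaN), 2, 3)
  g <- gate_lifetime(lt, 800, 1500)
  expect_identical(as.vector(g), c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_false(any(gate_lifetime(matrix(NaN, 4, 4), 800, 1500)))
  expect_error(gate_lifetime(lt, 1500, 800), class = "omiflim_config_error")
})

test_that("intensity/lifetime merge is an exact pixelwise conjunction", {
  set.seed(11)
  fg <- matrix(runif(400) > 0.5, 20, 20)
  gate <- matrix(runif(400) > 0.5, 20, 20)
  merged <- merge_intensity_lifetime(fg, gate)
  oracle <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20) oracle[i, j] <- fg[i, j] && gate[i, j]
  expect_identical(merged, oracle)
  expect_identical(merge_intensity_lifetime(fg, matrix(TRUE, 20, 20)), fg)
  expect_false(any(merge_intensity_lifetime(fg, matrix(FALSE, 20, 20))))
  expect_error(merge_intensity_lifetime(fg, matrix(TRUE, 10, 10)),
               class = "omiflim_dimension_error")
})

test_that("component labelling matches a flood-fill oracle at both connectivities", {
  set.seed(13)
  for (i in 1:4) {
    mask <- matrix(runif(24 * 24) < 0.4, 24, 24)
    for (conn in c(4, 8)) {
      expect_true(same_partition(label_components(mask, conn),
                                 flood_label(mask, conn)),
                  info = sprintf("rep %d conn %d", i, conn))
    }
  }
  # diagonal adjacency merges only at connectivity 8
  m <- matrix(FALSE, 8, 8); m[3, 3] <- TRUE; m[4, 4] <- TRUE
  expect_equal(max(label_components(m, 4)), 2)
  expect_equal(max(label_components(m, 8)), 1)
})

test_that("edge-guided labelling recovers disjoint blobs and empty masks", {
  mask <- disk_mask(64, 18, 18, 6) | disk_mask(64, 45, 45, 7)
  lab <- label_rois(mask)
  expect_equal(max(lab), 2)
  expect_identical(lab > 0, mask)       # labels cover exactly the mask support
  expect_equal(length(unique(lab[disk_mask(64, 18, 18, 6)])), 1)
  empty <- label_rois(matrix(FALSE, 32, 32))
  expect_equal(max(empty), 0)
})

test_that("label-aware expansion grows regions without merging them", {
  lab <- matrix(0L, 40, 40)
  lab[disk_mask(40, 15, 20, 4)] <- 1L
  lab[disk_mask(40, 24, 20, 4)] <- 2L   # 3-4 px gap between the disks
  grown <- expand_labels(lab, 2, "dilate")
  expect_equal(sort(unique(grown[grown > 0])), c(1L, 2L))
  expect_true(all(grown[lab > 0] == lab[lab > 0]))   # original pixels keep owners
  expect_gt(sum(grown == 1), sum(lab == 1))
  expect_gt(sum(grown == 2), sum(lab == 2))
  # split regions stay split (no bridge between the two labels' supports)
  comp <- label_components(grown == 1, 8)
  expect_equal(max(comp), 1)
})

test_that("refinement applies dilation, border clearing and the area filter", {
  cfg <- segmentation_config(struct_radius_1 = 1, struct_radius_2 = 1, min_area = 20)
  lab <- matrix(0L, 48, 48)
  lab[disk_mask(48, 24, 24, 5)] <- 1L
  out <- refine_rois(lab, cfg)
  expect_equal(max(out), 1)
  expect_gt(sum(out > 0), sum(lab > 0))            # dilation grows the region

  border <- matrix(0L, 48, 48)
  border[1:4, 10:14] <- 1L                          # touches row 1
  border[disk_mask(48, 30, 30, 5)] <- 2L
  out2 <- refine_rois(border, cfg)
  expect_equal(max(out2), 1)                        # border region cleared
  expect_false(any(out2[1:4, 10:14] > 0))

  speck <- matrix(0L, 48, 48)
  speck[24, 24:26] <- 1L                            # 3-pixel speck
  expect_equal(max(refine_rois(speck, segmentation_config(
    struct_radius_1 = 0, struct_radius_2 = 0, min_area = 20))), 0)
})

test_that("dice coefficient: identity, disjointness, arithmetic, symmetry", {
  a <- disk_mask(32, 16, 16, 6)
  expect_equal(dice_coefficient(a, a), 1)
  b <- disk_mask(32, 5, 5, 3)
  expect_equal(dice_coefficient(a, b), 0)
  x <- matrix(FALSE, 20, 20); y <- matrix(FALSE, 20, 20)
  x[1:10, 1:10] <- TRUE                              # |A| = 100
  y[6:15, 1:10] <- TRUE                              # |B| = 100, overlap 50
  expect_equal(dice_coefficient(x, y), 0.5)
  expect_equal(dice_coefficient(y, x), 0.5)
  expect_error(dice_coefficient(x & FALSE, y & FALSE), class = "omiflim_undefined_dice")
})

test_that("argmax ensemble selection attains the supremum and dominates", {
  truth <- matrix(0L, 32, 32)
  truth[disk_mask(32, 16, 16, 6)] <- 1L
  cands <- list(
    list(variant_id = "off", mask = disk_mask(32, 8, 8, 4) * 1L, n_cells = 1, dice = NA),
    list(variant_id = "exact", mask = truth, n_cells = 1, dice = NA),
    list(variant_id = "close", mask = disk_mask(32, 16, 16, 5) * 1L, n_cells = 1, dice = NA))
  sel <- ensemble_select(cands, truth, "per_image_argmax")
  expect_identical(sel$variant_id, "exact")
  expect_equal(sel$dice, 1)
  expect_true(all(sel$dice >= sel$report$dice))
  expect_error(ensemble_select(list(), truth), class = "omiflim_empty_ensemble")
  expect_error(ensemble_select(cands, NULL, "per_image_argmax"),
               class = "omiflim_missing_truth")
})

test_that("global calibration picks the row-mean argmax of the Dice table", {
  truths <- lapply(c(4, 5, 6), function(r) disk_mask(32, 16, 16, r) * 1L)
  v1 <- disk_mask(32, 16, 16, 5) * 1L   # good for all three
  v2 <- disk_mask(32, 8, 8, 5) * 1L     # poor overlap everywhere
  imgs <- lapply(1:3, function(i) list(
    list(variant_id = "v1", mask = v1, n_cells = 1, dice = NA),
    list(variant_id = "v2", mask = v2, n_cells = 1, dice = NA)))
  sel <- ensemble_select(imgs, truths, "global_calibration")
  # brute-force 2x3 table
  tab <- sapply(1:3, function(i) c(dice_coefficient(v1, truths[[i]]),
                                   dice_coefficient(v2, truths[[i]])))
  expect_identical(sel$variant_id, c("v1", "v2")[which.max(rowMeans(tab))])
  expect_equal(sel$mean_dice, max(rowMeans(tab)))
  expect_length(sel$masks, 3)
})

test_that("variants are deterministic and masks stay near the gated foreground", {
  sc <- small_scene(seed = 21)
  cfg <- segmentation_config(threshold_methods = c("otsu", "yen", "otsu|yen"))
  v1 <- run_variant(sc$intensity$MCHERRY, sc$lifetime,
                    list(method = "otsu", expansion = "dilate"), cfg)
  v2 <- run_variant(sc$intensity$MCHERRY, sc$lifetime,
                    list(method = "otsu", expansion = "dilate"), cfg)
  expect_identical(v1$mask, v2$mask)

  # containment: output pixels lie within r1+r2 of the gate/threshold merge
  gate <- gate_lifetime(sc$lifetime, cfg$gate_low, cfg$gate_high)
  fg <- threshold_intensity(sc$intensity$MCHERRY, "otsu",
                            cfg$local_block, cfg$local_offset)
  merged <- merge_intensity_lifetime(fg, gate)
  reach <- EBImage::dilate(matrix(as.numeric(merged), nrow(merged), ncol(merged)),
                           EBImage::makeBrush(2 * cfg$struct_radius_1 + 1, "disc"))
  reach <- EBImage::dilate(reach, EBImage::makeBrush(2 * cfg$struct_radius_2 + 1, "disc"))
  expect_true(all(reach[v1$mask > 0] > 0))
})

test_that("scenes with only out-of-gate distractors segment to zero cells", {
  sc <- generate_scene(scene_spec(size = 128, n_cells = 0, n_distractors = 5,
                                  n_bins = 64, seed = 9))
  sel <- segment_fov(sc$intensity$MCHERRY, sc$lifetime, segmentation_config(),
                     truth = sc$truth$mask)
  expect_equal(max(sel$mask), 0)
})
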