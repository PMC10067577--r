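test_that("scenes honor the spec and are seed-reproducible", {
  sc <- small_scene(seed = 61, n_cells = 5)
  expect_equal(max(sc$truth$mask), 5)
  expect_equal(sort(unique(sc$truth$mask[sc$truth$mask > 0])), 1:5)
  expect_equal(nrow(sc$truth$cells), 5)
  sc2 <- small_scene(seed = 61, n_cells = 5)
  expect_identical(sc$channels, sc2$channels)
  expect_identical(sc$truth$mask, sc2$truth$mask)
  sc3 <- small_scene(seed = 62, n_cells = 5)
  expect_false(identical(sc$channels$MCHERRY, sc3$channels$MCHERRY))
  # truth masks never overlap the distractor blobs
  expect_false(any(sc$truth$mask > 0 & sc$truth$distractor_mask > 0))
})

test_that("background photon totals follow the specified Poisson law", {
  sc <- generate_scene(scene_spec(size = 100, n_cells = 0, n_distractors = 0,
                                  background_rate = 3, n_bins = 64, seed = 63))
  totals <- as.vector(sc$intensity$NADPH)   # 1e4 pixels, expected Poisson(3)
  n <- length(totals)
  kcut <- qpois(1 - 5 / n, 3)               # lump the tail so E[count] >= 5
  obs <- tabulate(pmin(totals, kcut) + 1, nbins = kcut + 1)
  p <- dpois(0:kcut, 3); p[kcut + 1] <- 1 - ppois(kcut - 1, 3)
  gof <- chisq.test(obs, p = p / sum(p))
  expect_gt(gof$p.value, 0.01)
})

test_that("infeasible packings raise a packing error", {
  expect_error(generate_scene(scene_spec(size = 64, n_cells = 40, n_bins = 32,
                                         max_place_tries = 50, seed = 64)),
               class = "omiflim_packing_error")
})

test_that("mCherry lifetimes sit in the gate and distractors outside it", {
  sc <- small_scene(seed = 65, n_cells = 5, size = 160)
  nuc <- sc$lifetime[sc$truth$mask > 0 & !is.na(sc$lifetime)]
  expect_gt(mean(nuc >= 800 & nuc <= 1500), 0.9)
  dis <- sc$lifetime[sc$truth$distractor_mask > 0 & !is.na(sc$lifetime)]
  if (length(dis)) expect_lt(mean(dis >= 800 & dis <= 1500), 0.1)
})

test_that("a zero-effect dataset shows no spurious tissue contrasts", {
  null_case <- apply_tissue_effects(c(fad_tau_m = 0), size_sd = 20)
  ds <- generate_dataset(n_scenes = 20, cells_per_scene = 25, seed = 66,
                         case = null_case, size = 192, n_bins = 32,
                         n_distractors = 0, background_rate = 1,
                         collect = function(scene) NA)
  cmp <- compare_groups(ds$truth, "tissue", "spleen")
  expect_true(all(cmp$glass_delta < 0.2))
})

test_that("the built-in contrasts and size ratio are recovered from truth tables", {
  ds <- generate_dataset(n_scenes = 8, cells_per_scene = 25, seed = 67,
                         size = 224, n_bins = 32, collect = function(scene) NA)
  cmp <- compare_groups(ds$truth, "tissue", "spleen")
  d <- cmp$glass_delta[cmp$parameter == "fad_tau_m"]
  expect_gt(d, 1.25); expect_lt(d, 1.75)
  ratio <- mean(ds$truth$cell_size[ds$truth$tissue == "tumor"]) /
    mean(ds$truth$cell_size[ds$truth$tissue == "spleen"])
  built_in <- population_tumor()$size_px[1] / population_spleen()$size_px[1]
  expect_lt(abs(ratio - built_in) / built_in, 0.1)
})

test_that("fitting pooled decays under truth masks recovers per-cell lifetimes", {
  df <- dataset_features(n_scenes = 2, cells_per_scene = 12, seed = 68, size = 224)
  merged <- merge(df$features, df$truth, by = c("fov_id", "cell_id"),
                  suffixes = c("_fit", "_true"))
  expect_gte(nrow(merged), 40)
  for (ch in c("nadph_tau_m", "fad_tau_m")) {
    rel <- abs(merged[[paste0(ch, "_fit")]] - merged[[paste0(ch, "_true")]]) /
      merged[[paste0(ch, "_true")]]
    expect_lt(median(rel), 0.05)
  }
})
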