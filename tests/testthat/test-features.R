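make_maps <- function(vals, size) {
  lapply(vals, function(v) matrix(v, size, size))
}

test_that("cells with uniform parameters reproduce the pixel values exactly", {
  size <- 24
  lab <- matrix(0L, size, size)
  lab[disk_mask(size, 8, 8, 3)] <- 1L
  lab[disk_mask(size, 17, 17, 3)] <- 2L
  nm <- make_maps(list(tau1 = 400, tau2 = 2500, alpha1 = 0.8, alpha2 = 0.2,
                       tau_m = 820), size)
  fm <- make_maps(list(tau1 = 200, tau2 = 2400, alpha1 = 0.9, alpha2 = 0.1,
                       tau_m = 420), size)
  ni <- matrix(120, size, size); fi <- matrix(80, size, size)
  tab <- extract_cell_features(lab, nm, fm, ni, fi, tissue = "spleen")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$nadph_tau_m, c(820, 820))
  expect_equal(tab$fad_alpha1, c(0.9, 0.9))
  expect_equal(tab$redox_ratio, rep(120 / 200, 2))
  expect_equal(tab$cell_size, c(sum(lab == 1), sum(lab == 2)))
})

test_that("parameter means are photon weighted", {
  lab <- matrix(0L, 4, 4); lab[1, 1:2] <- 1L
  tau_m <- matrix(NaN, 4, 4); tau_m[1, 1] <- 500; tau_m[1, 2] <- 900
  maps <- list(tau1 = tau_m, tau2 = tau_m, alpha1 = tau_m * 0 + 0.5,
               alpha2 = tau_m * 0 + 0.5, tau_m = tau_m)
  inten <- matrix(0, 4, 4); inten[1, 1] <- 100; inten[1, 2] <- 300
  tab <- extract_cell_features(lab, maps, maps, inten, inten)
  expect_equal(tab$nadph_tau_m, (100 * 500 + 300 * 900) / 400)  # 800 ps
})

test_that("aggregation matches a per-pixel loop oracle", {
  set.seed(31)
  size <- 20
  lab <- matrix(0L, size, size)
  lab[disk_mask(size, 6, 6, 3)] <- 1L
  lab[disk_mask(size, 14, 14, 4)] <- 2L
  rnd_map <- function() {
    m <- matrix(runif(size * size, 100, 3000), size, size)
    m[sample(size * size, 12)] <- NaN
    m
  }
  nm <- list(tau1 = rnd_map(), tau2 = rnd_map(), alpha1 = rnd_map(),
             alpha2 = rnd_map(), tau_m = rnd_map())
  fm <- list(tau1 = rnd_map(), tau2 = rnd_map(), alpha1 = rnd_map(),
             alpha2 = rnd_map(), tau_m = rnd_map())
  ni <- matrix(rpois(size * size, 50), size, size)
  fi <- matrix(rpois(size * size, 40), size, size)
  tab <- extract_cell_features(lab, nm, fm, ni, fi)
  for (l in 1:2) {
    idx <- which(lab == l)
    for (p in c("tau1", "alpha1", "tau_m")) {
      v <- nm[[p]][idx]; w <- ni[idx]
      ok <- is.finite(v)
      oracle <- sum(v[ok] * w[ok]) / sum(w[ok])
      expect_equal(tab[[paste0("nadph_", p)]][tab$cell_id == l], oracle,
                   tolerance = 1e-9)
    }
    expect_equal(tab$redox_ratio[tab$cell_id == l],
                 sum(ni[idx]) / (sum(ni[idx]) + sum(fi[idx])), tolerance = 1e-12)
  }
  expect_lte(sum(tab$cell_size), sum(lab > 0))
})

test_that("cells without fittable pixels are excluded with a message", {
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L; lab[7:9, 7:9] <- 2L
  nan_map <- matrix(NaN, 10, 10)
  good <- matrix(1000, 10, 10)
  nm <- list(tau1 = good, tau2 = good, alpha1 = good, alpha2 = good, tau_m = good)
  nm_bad <- nm; for (p in names(nm_bad)) nm_bad[[p]][lab == 2] <- NaN
  inten <- matrix(10, 10, 10)
  expect_message(
    tab <- extract_cell_features(lab, nm_bad, nm, inten, inten),
    "excluded")
  expect_equal(tab$cell_id, 1L)
  expect_lt(sum(tab$cell_size), sum(lab > 0))
})

test_that("feature tables combine with schema and key integrity", {
  t1 <- extract_cell_features(matrix(rep(c(0L, 1L), c(90, 10)), 10, 10),
                              make_maps(list(tau1 = 1, tau2 = 2, alpha1 = 0.5,
                                             alpha2 = 0.5, tau_m = 1.5), 10),
                              make_maps(list(tau1 = 1, tau2 = 2, alpha1 = 0.5,
                                             alpha2 = 0.5, tau_m = 1.5), 10),
                              matrix(5, 10, 10), matrix(5, 10, 10), fov_id = "A")
  t2 <- t1; t2$fov_id <- "B"
  both <- build_feature_table(list(t1, t2))
  expect_equal(nrow(both), 2)
  expect_identical(build_feature_table(list()), omiflim:::empty_feature_table())
  expect_error(build_feature_table(list(t1, t1)), class = "omiflim_integrity_error")
})

test_that("feature CSVs round trip", {
  sc <- small_scene(seed = 41, n_cells = 3)
  tab <- sc$truth$cells[, omiflim:::feature_schema()]
  path <- tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  back <- read_feature_csv(path)
  expect_equal(back$nadph_tau_m, tab$nadph_tau_m, tolerance = 1e-12)
  expect_identical(back$cell_id, tab$cell_id)
})
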