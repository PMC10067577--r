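test_that("glass delta arithmetic and oracle agreement", {
  expect_equal(as.numeric(glass_delta(c(2, 3, 4), c(0, 1, 2))), 2 / 1)
  x <- c(1, 2, 3)
  expect_equal(as.numeric(glass_delta(x, x)), 0)
  set.seed(51)
  a <- rnorm(200, 1.3, 2); b <- rnorm(200, 0.2, 1.4)
  oracle <- abs(mean(a) - mean(b)) / sqrt(sum((b - mean(b))^2) / (length(b) - 1))
  expect_equal(as.numeric(glass_delta(a, b)), oracle, tolerance = 1e-12)
  expect_true(attr(glass_delta(a + 10, b), "significant"))
  expect_error(glass_delta(a, rep(3, 10)), class = "omiflim_degenerate_control")
})

test_that("glass delta is affine invariant but asymmetric in the standardizer", {
  set.seed(52)
  a <- rnorm(100, 2); b <- rnorm(100, 0)
  d0 <- as.numeric(glass_delta(a, b))
  expect_equal(as.numeric(glass_delta(3 * a + 5, 3 * b + 5)), d0, tolerance = 1e-12)
  # swapping groups swaps the control SD, changing the value
  a_wide <- rnorm(100, 2, 3)
  expect_false(isTRUE(all.equal(as.numeric(glass_delta(a_wide, b)),
                                as.numeric(glass_delta(b, a_wide)))))
})

test_that("group comparisons recover a known shift and the null", {
  set.seed(53)
  n <- 500
  base <- data.frame(cell_id = 1:(2 * n), fov_id = rep(c("A", "B"), each = n),
                     mouse_id = "M1", tissue = rep(c("spleen", "tumor"), each = n),
                     cell_type = "immune")
  for (p in omi_parameters()) base[[p]] <- rnorm(2 * n)
  base$fad_tau_m <- c(rnorm(n, 0, 1), rnorm(n, 2, 1))
  cmp <- compare_groups(base, "tissue", "spleen")
  row <- cmp[cmp$parameter == "fad_tau_m", ]
  expect_gt(row$glass_delta, 1.8); expect_lt(row$glass_delta, 2.2)
  expect_lt(row$mw_p, 1e-6)
  expect_true(row$significant)
  null_row <- cmp[cmp$parameter == "nadph_tau1", ]
  expect_lt(null_row$glass_delta, 0.2)

  same <- base; same$tissue <- rep(c("spleen", "tumor"), n)
  for (p in omi_parameters()) same[[p]] <- rep(rnorm(n), each = 2)
  cmp2 <- compare_groups(same, "tissue", "spleen")
  expect_true(all(cmp2$glass_delta < 1e-12))
  expect_true(all(cmp2$mw_p > 0.99))
  expect_error(compare_groups(base, "tissue", "liver"), class = "omiflim_config_error")
})

test_that("z-score matrices standardize, clip at 4 SD and handle degenerate columns", {
  tab <- data.frame(cell_id = 1:3, fov_id = "A", mouse_id = "M1",
                    tissue = "spleen", cell_type = "immune")
  for (p in omi_parameters()) tab[[p]] <- c(1, 2, 3)
  z <- zscore_matrix(tab)
  expect_equal(as.vector(z$z[, "nadph_tau1"]), c(-1, 0, 1))

  set.seed(54)
  tab2 <- tab[rep(1, 60), ]
  tab2$cell_id <- 1:60
  for (p in omi_parameters()) tab2[[p]] <- rnorm(60)
  tab2$fad_tau_m[1] <- 1e6           # raw z far above 4
  z2 <- zscore_matrix(tab2)
  expect_equal(max(z2$z), 4)
  expect_true(all(z2$z >= -4 & z2$z <= 4))
  # pre-clip columns have mean 0 and sample SD 1
  raw <- scale(as.matrix(tab2[, omi_parameters()]))
  expect_true(all(abs(colMeans(raw)) < 1e-9))
  expect_true(all(abs(apply(raw, 2, sd) - 1) < 1e-9))

  tab3 <- tab2; tab3$redox_ratio <- 0.5
  expect_warning(z3 <- zscore_matrix(tab3), "constant")
  expect_true(all(z3$z[, "redox_ratio"] == 0))
  expect_error(zscore_matrix(tab[1, ]), class = "omiflim_insufficient_data")
})

test_that("ward clustering merges the closest pair first and is monotone", {
  m <- matrix(c(0, 1, 10), ncol = 1)
  cl <- ward_cluster(m)
  # exhaustive first-merge oracle: the pair with minimal Euclidean distance
  d <- as.matrix(dist(m)); diag(d) <- Inf
  first <- sort(unname(which(d == min(d), arr.ind = TRUE)[1, ]))
  expect_identical(as.integer(sort(-cl$hclust$merge[1, ])), as.integer(first))
  expect_equal(cl$hclust$height[1], 1)

  dup <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9))
  expect_equal(ward_cluster(dup)$hclust$height[1], 0)

  set.seed(55)
  z <- matrix(rnorm(300), 25, 12)
  cl2 <- ward_cluster(z, k = 3)
  expect_length(cl2$order, 25)
  expect_true(all(diff(cl2$hclust$height) >= -1e-12))
  expect_equal(length(unique(cl2$labels)), 3)
  zna <- z; zna[1, 1] <- NA
  expect_error(ward_cluster(zna), class = "omiflim_data_error")
})

test_that("well-separated synthetic tissues cluster by tissue label", {
  skip_if_not_installed("mclust")
  set.seed(56)
  n <- 100
  m <- rbind(matrix(rnorm(n * 12), n), matrix(rnorm(n * 12, 4), n))  # 4-SD shifts
  lab <- rep(c("spleen", "tumor"), each = n)
  cl <- ward_cluster(scale(m), k = 2)
  expect_gte(mclust::adjustedRandIndex(cl$labels, lab), 0.9)
})

test_that("dropping a constant redox column leaves the clustering unchanged", {
  set.seed(57)
  tab <- data.frame(cell_id = 1:40, fov_id = "A", mouse_id = "M1",
                    tissue = "spleen", cell_type = "immune")
  for (p in omi_parameters()) tab[[p]] <- rnorm(40)
  tab$redox_ratio <- 0.5
  z12 <- suppressWarnings(zscore_matrix(tab))
  z11 <- zscore_matrix(tab, parameters = setdiff(omi_parameters(), "redox_ratio"))
  expect_equal(ward_cluster(z12)$hclust$height, ward_cluster(z11)$hclust$height,
               tolerance = 1e-12)
})
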