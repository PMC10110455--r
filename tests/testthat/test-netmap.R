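mask_of <- function(idx, dims = c(10, 10, 10)) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}

test_that("jaccard index matches intersection over union", {
  a <- mask_of(1:3)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(mask_of(1:3), mask_of(4:6)), 0)
  expect_equal(jaccard_index(mask_of(1:3), mask_of(2:4)), 2 / 4)
})

test_that("jaccard is symmetric, bounded, and decreasing in disjoint voxels", {
  set.seed(1)
  for (i in 1:20) {
    a <- mask_of(sample(1000, 50))
    b <- mask_of(sample(1000, 70))
    j <- jaccard_index(a, b)
    expect_equal(j, jaccard_index(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
    # adding voxels disjoint from b to a cannot increase J
    extra <- setdiff(which(!a & !b), integer(0))[1:10]
    a2 <- a; a2[extra] <- TRUE
    expect_lte(jaccard_index(a2, b), j)
  }
})

test_that("mask geometry errors are informative", {
  expect_error(jaccard_index(mask_of(1:3), mask_of(1:3, c(5, 5, 5))),
               "different grids")
  expect_error(jaccard_index(mask_of(integer(0)), mask_of(1:3)), "empty mask")
})

test_that("assignment enforces the minimum similarity threshold", {
  # nested masks give exact J = |A|/|B|
  tpl <- list(net = mask_of(1:1000))
  expect_false(assign_networks(list(IC1 = mask_of(1:149)), tpl)$accepted)
  expect_true(assign_networks(list(IC1 = mask_of(1:150)), tpl)$accepted)
  out <- assign_networks(list(IC1 = mask_of(1:149)), tpl)
  expect_equal(out$jaccard, 0.149)
})

test_that("components merge only when the union improves similarity", {
  dims <- c(20, 10, 10)
  tpl <- list(net = mask_of(1:600, dims))
  # two disjoint halves: each J = 0.5, union J = 1 -> combined
  comps <- list(IC1 = mask_of(1:300, dims), IC2 = mask_of(301:600, dims))
  out <- assign_networks(comps, tpl)
  expect_equal(nrow(out), 1)
  expect_true(out$combined)
  expect_equal(out$jaccard, 1)
  expect_equal(out$component, "IC1+IC2")

  # overlapping union with off-template voxels: union worse than the
  # stronger component alone -> both kept (mirrors the split-network case)
  compA <- mask_of(1:260, dims)            # J = 260/600
  compB <- mask_of(c(200:320, 601:1400), dims)  # weak, mostly off template
  out2 <- assign_networks(list(ICa = compA, ICb = compB), tpl)
  jA <- jaccard_index(compA, tpl$net)
  jU <- jaccard_index(compA | compB, tpl$net)
  expect_lt(jU, jA)
  expect_equal(nrow(out2), 2)
  expect_false(any(out2$combined))
})

test_that("synthetic component maps hit their target similarity", {
  tpl <- box_template()
  maps1 <- simulate_component_maps(tpl, 1.0, seed = 1)
  expect_equal(sum(maps1$comp1), sum(tpl == 1))
  expect_equal(jaccard_index(maps1$comp1, tpl == 1), 1)

  maps5 <- simulate_component_maps(tpl, 0.5, seed = 2)
  for (m in maps5) {
    j <- attr(m, "achieved_jaccard")
    expect_gte(j, 0.45); expect_lte(j, 0.55)
  }
  # threshold-level maps are accepted by the assignment stage
  maps15 <- simulate_component_maps(tpl, 0.16, seed = 3)
  out <- assign_networks(maps15, list(net1 = tpl == 1, net2 = tpl == 2),
                         j_min = 0.15)
  expect_true(all(out$accepted))
  expect_error(simulate_component_maps(array(c(1L, rep(0L, 7)), c(2, 2, 2)),
                                       0.5), "too small|misses target")
})

test_that("assignment recovers the designated template for J >= 0.2", {
  tpl <- box_template()
  for (target in c(0.2, 0.4, 0.7)) {
    maps <- simulate_component_maps(tpl, target, seed = round(100 * target))
    out <- assign_networks(maps, list(net1 = tpl == 1, net2 = tpl == 2))
    expect_equal(out$template[out$component == "comp1"], "net1")
    expect_equal(out$template[out$component == "comp2"], "net2")
    expect_true(all(out$accepted))
  }
})

test_that("ROI spheres match a brute-force voxel distance scan", {
  dims <- c(20, 20, 16)
  vox <- c(2.5, 2.5, 3)
  clusters <- array(1L, dims)  # whole volume is one cluster
  peaks <- data.frame(x = 10, y = 10, z = 8, value = 5, cluster = 1)
  rois <- build_rois(clusters, peaks, radius_mm = 5, voxel_mm = vox)
  # oracle: exhaustive scan over all voxel centers
  grid <- as.matrix(expand.grid(x = 1:20, y = 1:20, z = 1:16))
  d <- sqrt(colSums((t(sweep(grid, 2, vox, `*`)) - c(10, 10, 8) * vox)^2))
  expect_equal(rois[[1]]$n_voxels, sum(d <= 5))
})

test_that("at most three ROIs per cluster, ranked by peak value", {
  clusters <- array(0L, c(30, 10, 10))
  clusters[1:30, , ] <- 1L
  peaks <- data.frame(x = c(3, 10, 18, 26), y = 5, z = 5,
                      value = c(9, 7, 8, 2), cluster = 1)
  rois <- build_rois(clusters, peaks, radius_mm = 2,
                     max_peaks_per_cluster = 3, voxel_mm = c(1, 1, 1))
  expect_equal(length(rois), 3)
  kept_x <- vapply(rois, function(r) unname(r$peak["x"]), numeric(1))
  expect_setequal(kept_x, c(3, 18, 10))  # weakest peak (x=26) dropped
})

test_that("ROI voxels never leave their cluster", {
  clusters <- array(0L, c(12, 12, 12))
  clusters[1:6, , ] <- 1L
  clusters[7:12, , ] <- 2L
  peaks <- data.frame(x = c(6, 7), y = 6, z = 6, value = 1, cluster = c(1, 2))
  rois <- build_rois(clusters, peaks, radius_mm = 4, voxel_mm = c(1, 1, 1))
  for (r in rois)
    expect_true(all(clusters[r$voxels] == r$cluster))
  # relabeling clusters leaves the voxel sets unchanged
  relab <- clusters
  relab[clusters == 1L] <- 5L; relab[clusters == 2L] <- 3L
  peaks2 <- peaks; peaks2$cluster <- c(5, 3)
  rois2 <- build_rois(relab, peaks2, radius_mm = 4, voxel_mm = c(1, 1, 1))
  # same voxel sets regardless of label values (matched by peak location)
  key <- function(r) paste(r$peak, collapse = ",")
  m1 <- lapply(rois, `[[`, "voxels")[order(vapply(rois, key, ""))]
  m2 <- lapply(rois2, `[[`, "voxels")[order(vapply(rois2, key, ""))]
  expect_equal(unname(m2), unname(m1))
  expect_error(build_rois(clusters,
                          data.frame(x = 40, y = 1, z = 1, value = 1,
                                     cluster = 1)),
               "outside")
})

test_that("coverage filter applies the strict >15% exclusion rule", {
  cov <- matrix(10, 30, 3, dimnames = list(NULL, c("roiA", "roiB", "roiC")))
  cov[1:5, "roiA"] <- 0   # 5/30 = 16.7% -> excluded
  cov[1:3, "roiB"] <- 0   # 3/20... 3/30 = 10% -> retained
  out <- coverage_filter(cov)
  expect_equal(out$excluded$roi, "roiA")
  expect_equal(out$excluded$missing_fraction, 5 / 30)
  expect_setequal(out$retained, c("roiB", "roiC"))

  # exactly 15% is retained (strict inequality)
  cov2 <- matrix(10, 20, 1, dimnames = list(NULL, "roi"))
  cov2[1:3, 1] <- 0  # 3/20 = 15%
  expect_equal(coverage_filter(cov2)$retained, "roi")
  # the stricter any-subject-zero harmonization rule drops it
  expect_equal(nrow(coverage_filter(cov2, 0, strict = FALSE)$excluded), 1)
  cov2[cov2 == 0] <- 1
  expect_equal(coverage_filter(cov2)$retained, "roi")
  expect_error(coverage_filter(matrix(c(1, NA), 1, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "missing")
})

test_that("masks survive a NIfTI round trip", {
  m <- mask_of(sample(1000, 80))
  attr(m, "pixdim") <- c(2.5, 2.5, 3)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, path)
  back <- RNifti::readNifti(path)
  expect_equal(sum(as.array(back) != 0), sum(m))
  expect_equal(jaccard_index(m, path), 1)
})
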