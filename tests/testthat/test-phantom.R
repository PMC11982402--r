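# Synthetic phantom structure: geometry oracle, modality contrast
# relationships, determinism, multi-center datasets.

test_that("phantom anatomy matches its specification", {
  spec <- phantomSpec(shape = c(48L, 48L), nTumors = 1L,
                      tumorRadiusRange = c(4, 4), nConfounders = 0L,
                      noiseSdCT = 0, noiseSdPET = 0, petBlurSigma = 0,
                      seed = 9L)
  s <- generatePhantom(spec)
  ct <- volData(ctVolume(s)); pet <- volData(petVolume(s))
  mask <- volData(maskVolume(s))
  expect_equal(ct[1, 1], -1000)                  # air background
  expect_true(any(ct > 600))                     # dense structure
  body <- ct > -500
  expect_true(mean(ct[body & mask == 0 & ct < 600]) > -100)  # soft tissue
  # noiseless, blurless PET: tumor voxels carry full uptake, body baseline 1
  expect_equal(unique(as.numeric(pet[mask == 1])), 8)
  expect_equal(sort(unique(as.numeric(pet))), c(0, 1, 8))
  expect_identical(sampleCenter(s), "A")
})

test_that("ellipsoid rasterization equals brute-force voxel membership", {
  raster <- anatofuse:::.ellipsoidMask
  set.seed(13)
  for (i in 1:5) {
    ctr <- runif(3, 8, 24)
    semi <- runif(3, 2, 5)
    m <- raster(c(32L, 32L, 32L), ctr, semi)
    cnt <- 0L
    for (x in 1:32) for (y in 1:32) for (z in 1:32)
      if (sum(((c(x, y, z) - ctr) / semi)^2) <= 1) cnt <- cnt + 1L
    expect_identical(sum(m), as.numeric(cnt))
    expect_true(all(m %in% c(0, 1)))
  }
  # a fixed-radius single-tumor phantom's mask is one such ellipsoid: its
  # voxel count must match a brute-force count at some feasible volume
  spec <- phantomSpec(shape = c(32L, 32L, 32L), nTumors = 1L,
                      tumorRadiusRange = c(3.5, 3.5), nConfounders = 0L,
                      noiseSdCT = 0, noiseSdPET = 0, seed = 13L)
  s <- generatePhantom(spec)
  mask <- volData(maskVolume(s))
  expect_gt(sum(mask), 0)
  expect_true(all(mask %in% c(0, 1)))
})

test_that("no-tumor spec yields empty mask and baseline-only PET", {
  spec <- phantomSpec(shape = c(32L, 32L), nTumors = 0L, nConfounders = 0L,
                      noiseSdCT = 0, noiseSdPET = 0, seed = 3L)
  s <- generatePhantom(spec)
  expect_equal(sum(volData(maskVolume(s))), 0)
  expect_lte(max(volData(petVolume(s))), 1)
})

test_that("identical specs generate bit-identical samples", {
  spec <- phantomSpec(seed = 77L)
  a <- generatePhantom(spec); b <- generatePhantom(spec)
  expect_identical(volData(petVolume(a)), volData(petVolume(b)))
  expect_identical(volData(ctVolume(a)), volData(ctVolume(b)))
  expect_identical(volData(maskVolume(a)), volData(maskVolume(b)))
})

test_that("modality relationship rewards anatomy-guided fusion", {
  s <- generatePhantom(phantomSpec(seed = 23L, nConfounders = 2L))
  pet <- volData(petVolume(s)); ct <- volData(ctVolume(s))
  mask <- volData(maskVolume(s))
  body <- ct > -500
  # PET is hot inside the tumor relative to body background
  expect_gt(mean(pet[mask == 1]), mean(pet[body & mask == 0]) + 1)
  # confounders: PET-hot voxels outside the mask exist by construction,
  # flooring the precision of a PET-only thresholder
  hot <- pet > (1 + 0.5 * (8 - 1))
  expect_gt(sum(hot & mask == 0), 0)
  precFloor <- sum(hot & mask == 1) / sum(hot)
  expect_lt(precFloor, 0.95)
  # blur ordering: the tumor edge is crisper in CT than in PET. Sharpness is
  # scale-free: the median absolute in/out step across the boundary divided
  # by the tumor-to-surround contrast of that image
  sharpness <- function(img) {
    b <- which(mask == 1, arr.ind = TRUE)
    steps <- c()
    for (k in seq_len(nrow(b))) {
      v <- b[k, ]
      for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nb <- v + off
        if (all(nb >= 1 & nb <= dim(img)) && mask[nb[1], nb[2]] == 0)
          steps <- c(steps, abs(img[v[1], v[2]] - img[nb[1], nb[2]]))
      }
    }
    ring <- mask == 0 & body
    contrast <- abs(mean(img[mask == 1]) - mean(img[ring]))
    median(steps) / contrast
  }
  expect_gt(sharpness(ct), sharpness(pet))
})

test_that("multi-center datasets are deterministic with per-center jitter", {
  base <- phantomSpec(shape = c(32L, 32L), noiseSdCT = 20)
  d1 <- generateDataset(base, nPerCenter = 2L, centers = c("A", "B", "C"),
                        seed = 5L)
  d2 <- generateDataset(base, nPerCenter = 2L, centers = c("A", "B", "C"),
                        seed = 5L)
  expect_length(d1, 6L)
  expect_setequal(unique(vapply(d1, sampleCenter, character(1))),
                  c("A", "B", "C"))
  expect_identical(lapply(d1, function(s) volData(petVolume(s))),
                   lapply(d2, function(s) volData(petVolume(s))))
  # centers differ in CT noise: air-region sd tracks the per-center factors
  airSd <- vapply(d1, function(s) {
    ct <- volData(ctVolume(s))
    sd(ct[ct < -500])
  }, numeric(1))
  ctr <- vapply(d1, sampleCenter, character(1))
  bySd <- tapply(airSd, ctr, mean)
  expect_equal(as.numeric(bySd[c("A", "B", "C")]) / 20, c(0.6, 1.0, 1.5),
               tolerance = 0.15)
})

test_that("datasets round-trip through the NIfTI tree", {
  dir <- withr::local_tempdir()
  d <- generateDataset(phantomSpec(shape = c(16L, 16L),
                                   tumorRadiusRange = c(2, 2.5),
                                   nConfounders = 0L),
                       nPerCenter = 1L, centers = c("A", "B"), seed = 2L)
  writePhantomDataset(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- readPhantomDataset(dir)
  expect_length(back, 2L)
  expect_equal(volData(petVolume(back[[1]])), volData(petVolume(d[[1]])),
               tolerance = 1e-6)
  expect_identical(volData(maskVolume(back[[2]])),
                   volData(maskVolume(d[[2]])))
  expect_identical(vapply(back, sampleCenter, character(1)), c("A", "B"))
})

test_that("infeasible geometry raises a generation error", {
  expect_error(generatePhantom(phantomSpec(shape = c(16L, 16L),
                                           nTumors = 4L,
                                           tumorRadiusRange = c(6, 7))),
               "1000 attempts")
})
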