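test_that("designs are deterministic, sorted and boost targeted regions", {
  d1 <- makeDesign(2000, seed = 5)
  d2 <- makeDesign(2000, seed = 5)
  expect_identical(start(designProbes(d1)), start(designProbes(d2)))
  expect_identical(as.character(seqnames(designProbes(d1))),
                   as.character(seqnames(designProbes(d2))))
  p <- designProbes(d1)
  expect_false(is.unsorted(start(p[seqnames(p) == "1"])))

  # minimal design on a 1 Mb chromosome
  tiny <- makeDesign(2, genome = c(`1` = 1e6), seed = 1)
  expect_equal(length(designProbes(tiny)), 2L)

  # boosted region receives ~boost-fold probe density
  region <- gi("1", 10e6, 20e6, genome = toyGenome())
  db <- makeDesign(5000, genome = toyGenome(), targetedRegions = region,
                   boostFactor = 10L, seed = 3)
  inR <- sum(countOverlaps(designProbes(db), region))
  # region is 10% of the 100 Mb toy genome; boosted weight 10x
  expect_gt(inR / 5000, 0.35)
  expect_error(makeDesign(100, genome = toyGenome(),
                          targetedRegions = gi("1", 1, 9e7),
                          boostFactor = 2L),
               "outside genome|beyond chromosome")
})

test_that("noise-free ratios equal the intensity-model means exactly", {
  del <- toyCnv("1", 10e6, 20e6, copies = 1)
  dup <- toyCnv("2", 10e6, 20e6, copies = 3)
  sim <- toyRun(nProbes = 600, nArrays = 1,
                placements = list(list(array = 1, channel = "cy3",
                                       cnvs = c(del, dup))),
                noiseSd = 0, affinitySd = 0, seed = 2)
  r <- log2Ratios(runArrays(sim$run)[[1]])
  p <- designProbes(runDesign(sim$run))
  inDel <- overlapsAny(p, del)
  inDup <- overlapsAny(p, dup)
  expect_equal(unique(r[inDel]), log2(1 / 2))
  expect_equal(unique(r[inDup]), log2(3 / 2))
  expect_equal(unique(r[!inDel & !inDup]), 0)
})

test_that("cy5-carried CNVs shift the ratio with opposite sign", {
  del <- toyCnv("1", 10e6, 20e6, copies = 1)
  sim3 <- toyRun(nProbes = 400, nArrays = 1,
                 placements = list(list(array = 1, channel = "cy3",
                                        cnvs = del)),
                 noiseSd = 0, affinitySd = 0.2, seed = 4)
  sim5 <- toyRun(nProbes = 400, nArrays = 1,
                 placements = list(list(array = 1, channel = "cy5",
                                        cnvs = del)),
                 noiseSd = 0, affinitySd = 0.2, seed = 4)
  r3 <- log2Ratios(runArrays(sim3$run)[[1]])
  r5 <- log2Ratios(runArrays(sim5$run)[[1]])
  expect_equal(r3, -r5)  # exact antisymmetry at zero noise, same seed
  expect_equal(sim3$truth$channel, "cy3")
  expect_equal(sim5$truth$channel, "cy5")
})

test_that("mosaic fractions blend copies linearly", {
  half <- toyCnv("1", 10e6, 20e6, copies = 1, fraction = 0.5)
  sim <- toyRun(nProbes = 400, nArrays = 1,
                placements = list(list(array = 1, channel = "cy3",
                                       cnvs = half)),
                noiseSd = 0, affinitySd = 0, seed = 6)
  r <- log2Ratios(runArrays(sim$run)[[1]])
  p <- designProbes(runDesign(sim$run))
  expect_equal(unique(r[overlapsAny(p, half)]), log2(0.75))
})

test_that("ratio noise matches the two-channel model", {
  sim <- toyRun(nProbes = 4000, nArrays = 1, noiseSd = 0.2, seed = 8)
  r <- log2Ratios(runArrays(sim$run)[[1]])
  expect_equal(sd(r), 0.2 * sqrt(2), tolerance = 0.05)
  # identical seeds give bit-identical runs
  sim2 <- toyRun(nProbes = 4000, nArrays = 1, noiseSd = 0.2, seed = 8)
  expect_identical(runArrays(sim$run)[[1]]@cy3,
                   runArrays(sim2$run)[[1]]@cy3)
})

test_that("overlapping truth CNVs within a sample are rejected", {
  a <- toyCnv("1", 10e6, 20e6, copies = 1)
  b <- toyCnv("1", 15e6, 25e6, copies = 3)
  expect_error(sampleSpec("s", cnvs = c(a, b)), "must not overlap")
})

test_that("truth matching uses reciprocal overlap with sane tie-breaks", {
  truth <- c(toyCnv("1", 10e6, 20e6, copies = 1),
             toyCnv("2", 10e6, 20e6, copies = 3))
  call <- gi("1", 10e6, 20e6, genome = toyGenome())
  hit <- truthOverlap(call, truth)
  expect_equal(as.character(seqnames(hit)), "1")
  expect_equal(reciprocalOverlap(call, hit), 1.0)
  # different chromosome: no match
  expect_null(truthOverlap(gi("22", 10e6, 20e6), truth))
  # half-covering call matches iff the truth also covers half the call
  half <- gi("1", 15e6, 20e6, genome = toyGenome())   # inside truth
  expect_null(truthOverlap(half, truth, minReciprocal = 0.6))
  expect_false(is.null(truthOverlap(half, truth, minReciprocal = 0.5)))
})

test_that("probe-snapped random truth CNVs respect their constraints", {
  d <- makeDesign(4000, seed = 9)
  tr <- randomTruthCnvs(d, 4, seed = 10)
  expect_equal(length(tr), 4L)
  expect_equal(sum(countOverlaps(tr, tr) > 1L), 0L)
  expect_true(all(intervalSize(tr) >= 1e6))
  p <- designProbes(d)
  # boundaries coincide with probes
  expect_true(all(start(tr) %in% start(p)))
  expect_true(all(end(tr) %in% end(p)))
  expect_true(all(tr$copies %in% c(1L, 3L)))
})

test_that("runs round-trip through the probe-matrix interchange format", {
  del <- toyCnv("1", 10e6, 20e6, copies = 1)
  sim <- toyRun(nProbes = 300, nArrays = 2,
                placements = list(list(array = 1, channel = "cy3",
                                       cnvs = del)), seed = 11)
  dir <- tempfile()
  mf <- writeRun(sim$run, dir)
  back <- readRun(mf, genome = toyGenome())
  expect_equal(arrayIds(back), arrayIds(sim$run))
  expect_equal(log2Ratios(runArrays(back)[[1]]),
               log2Ratios(runArrays(sim$run)[[1]]), tolerance = 1e-9)
  expect_equal(start(designProbes(runDesign(back))),
               start(designProbes(runDesign(sim$run))))
})
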