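test_that("classification separates backbone, target and masked calls", {
  cfg <- defaultConfig()
  # ~35.9 Mb deletion: backbone
  big <- parseResultString("4p16.3p14(72,446-35,935,983)x1")
  expect_equal(classifyCalls(big, cfg)$status, "reportable_backbone")
  # ~2.54 Mb deletion inside the 22q11.2 syndrome target
  dg <- parseResultString("22q11.21(18,896,971-21,440,514)x1")
  got <- classifyCalls(dg, cfg)
  expect_equal(got$status, "reportable_target")
  expect_match(got$reasons, "DiGeorge")
  # susceptibility locus: masked despite falling in a targeted band
  bp <- parseResultString("15q11.2(22,765,627-23,085,096)x1")
  expect_equal(classifyCalls(bp, cfg)$status, "masked")
  # the TAR-case CNV: masked by default, targetable per case
  tar <- parseResultString("1q21.1(145,413,387-145,747,269)x1")
  expect_equal(classifyCalls(tar, cfg)$status, "masked")
  cfgT <- suppressWarnings(addCaseTarget(cfg, gi("1", 145507556, 145513535),
                                         name = "RBM8A"))
  gotT <- classifyCalls(tar, cfgT)
  expect_equal(gotT$status, "reportable_target")
  expect_match(gotT$reasons, "RBM8A")
  # fingerprint recorded
  expect_identical(metadata(gotT)$configFingerprint, configFingerprint(cfgT))
})

test_that("backbone precedes target in the reason ordering", {
  cfg <- defaultConfig()
  x <- parseResultString("17p11.2(16,532,735-20,221,695)x3")  # 3.7 Mb, on-target
  got <- classifyCalls(x, cfg)
  expect_equal(got$status, "reportable_backbone")
  expect_match(got$reasons, "^backbone:.*target:Smith-Magenis")
})

test_that("per-target direction filters apply when set", {
  t <- gi("22", 18877787, 21465672)
  mcols(t)$name <- "DG_loss_only"
  mcols(t)$direction <- "loss"
  cfg <- analysisConfig(targets = t)
  del <- parseResultString("22q11.21(18,896,971-21,440,514)x1")
  dup <- parseResultString("22q11.21(18,896,971-21,801,661)x3")
  expect_equal(classifyCalls(del, cfg)$status, "reportable_target")
  expect_equal(classifyCalls(dup, cfg)$status, "masked")
})

test_that("exclusions veto default targets but not case-specific ones", {
  region <- gi("16", 29700000, 30100000)   # inside proximal 16p11.2
  excl <- gi("16", 29652999, 30199351)
  mcols(excl)$name <- "16p11.2_proximal"
  tDefault <- region
  mcols(tDefault)$name <- "bad_default"
  cfgD <- analysisConfig(targets = tDefault, exclusions = excl)
  call <- region
  mcols(call)$direction <- "loss"
  expect_equal(classifyCalls(call, cfgD)$status, "masked")
  cfgC <- analysisConfig(exclusions = excl)
  cfgC <- suppressWarnings(addCaseTarget(cfgC, region, name = "case_region"))
  expect_equal(classifyCalls(call, cfgC)$status, "reportable_target")
})

test_that("the adjacency rule co-reports contiguous calls", {
  cfg <- defaultConfig()
  pair <- parseResultString(
    "9p24.3(214,366-2,197,859)x1,9p24.2p13.1(2,418,074-40,508,819)x3")
  cls <- applyAdjacencyRule(classifyCalls(pair, cfg), cfg)
  expect_equal(cls$status, c("reportable_adjacent", "reportable_backbone"))
  # 220,214 intervening bases between 2,197,859 and 2,418,074
  expect_match(cls$reasons[1], "adjacent:gap=220214")
  # far-away masked call stays masked
  far <- c(parseResultString("4p16.3p14(72,446-35,935,983)x1"),
           parseResultString("4q24(107,063,807-107,248,637)x1"))
  clsF <- applyAdjacencyRule(classifyCalls(far, cfg), cfg)
  expect_equal(clsF$status, c("reportable_backbone", "masked"))
  # no reportable call anywhere: nothing changes
  lone <- parseResultString("4q24(107,063,807-107,248,637)x1")
  clsL <- applyAdjacencyRule(classifyCalls(lone, cfg), cfg)
  expect_equal(clsL$status, "masked")
  # chains propagate to a fixed point
  chain <- gi(rep("5", 3), c(1e6, 5.2e6, 6.0e6), c(4.5e6, 5.5e6, 6.2e6))
  mcols(chain)$direction <- "loss"
  clsC <- applyAdjacencyRule(classifyCalls(chain, cfg), cfg)
  expect_equal(clsC$status, c("reportable_backbone", "reportable_adjacent",
                              "reportable_adjacent"))
})

test_that("sample status aggregates reportable calls", {
  cfg <- defaultConfig()
  fx <- loadFixtures()
  # the TAR sample: NAD by default, abnormal once the case target exists
  tar <- fx$reported[fx$reported$sampleKey == "S02"]
  expect_equal(classifySample(tar, cfg)$status, "no_abnormality_detected")
  cfgT <- suppressWarnings(addCaseTarget(cfg, gi("1", 145507556, 145513535),
                                         name = "RBM8A"))
  expect_equal(classifySample(tar, cfgT)$status, "abnormal")
  # two >3 Mb gains on different chromosomes
  s15 <- fx$reported[fx$reported$sampleKey == "S15"]
  got <- classifySample(s15, cfg)
  expect_equal(got$status, "abnormal")
  expect_equal(got$classified$status, rep("reportable_backbone", 2))
  # empty call set
  expect_equal(classifySample(fx$reported[0], cfg)$status,
               "no_abnormality_detected")
})

test_that("classification partitions calls and is threshold-monotone", {
  cfg <- defaultConfig()
  set.seed(71)
  chroms <- sample(c(as.character(1:22), "X"), 40, replace = TRUE)
  starts <- sample.int(2e7, 40)
  sizes <- round(10^runif(40, 3, 7.2))
  calls <- gi(chroms, starts, starts + sizes - 1)
  mcols(calls)$direction <- sample(c("loss", "gain"), 40, replace = TRUE)
  prev <- NULL
  for (mb in c(10, 5, 3, 2, 1)) {
    cfgT <- cfg; cfgT@backboneMinSize <- mb * 1e6
    cls <- classifyCalls(calls, cfgT)
    expect_true(all(cls$status %in% c("reportable_backbone",
                                      "reportable_target", "masked")))
    reportable <- cls$status != "masked"
    if (!is.null(prev))  # lowering the threshold never demotes
      expect_true(all(reportable[prev]))
    prev <- reportable
  }
})
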