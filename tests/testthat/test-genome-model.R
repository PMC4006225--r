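test_that("interval sizes follow the 1-based inclusive convention", {
  expect_equal(intervalSize(gi("2", 222834667, 224926273)), 2091607)
  expect_equal(intervalSize(gi("X", 23018416, 23021667)), 3252)
  expect_equal(intervalSize(gi("1", 5, 5)), 1)
  # translation invariance and positivity on random intervals
  set.seed(7)
  for (k in 1:25) {
    s <- sample.int(1e6, 1); w <- sample.int(1e5, 1)
    shift <- sample.int(1e6, 1)
    expect_equal(intervalSize(gi("3", s, s + w)),
                 intervalSize(gi("3", s + shift, s + w + shift)))
    expect_gte(intervalSize(gi("3", s, s + w)), 1)
  }
})

test_that("closed-interval overlap is symmetric, reflexive, chromosome-aware", {
  a <- gi("22", 18896971, 21440514)
  b <- gi("22", 18900000, 21900000)
  expect_true(intervalsOverlap(a, b))
  expect_true(intervalsOverlap(b, a))
  expect_true(intervalsOverlap(a, a))
  expect_false(intervalsOverlap(gi("15", 22318596, 23085096),
                                gi("15", 23100000, 28400000)))
  # same coordinates, different chromosome: never overlaps
  expect_false(intervalsOverlap(gi("1", 100, 200), gi("2", 100, 200)))
  # touching endpoints do overlap (closed intervals)
  expect_true(intervalsOverlap(gi("5", 100, 200), gi("5", 200, 300)))
  expect_false(intervalsOverlap(gi("5", 100, 200), gi("5", 201, 300)))
})

test_that("interval constructor enforces invariants", {
  expect_error(gi("1", 0, 10), "start")
  expect_error(gi("1", 10, 5), "end")
  expect_error(gi("chr25", 1, 10), "unknown chromosome")
  expect_error(gi("1", 1, 3e9), "beyond chromosome end")
  expect_equal(as.character(seqnames(gi("chrX", 1, 10))), "X")
})

test_that("result strings parse into intervals and copy states", {
  x <- parseResultString("22q11.21(18,896,971-21,440,514)x1")
  expect_equal(length(x), 1L)
  expect_equal(as.character(seqnames(x)), "22")
  expect_equal(start(x), 18896971)
  expect_equal(end(x), 21440514)
  expect_equal(x$copies, 1L)
  expect_equal(x$kind, "loss")

  two <- parseResultString(
    "9p24.3(214,366-2,197,859)x1,9p24.2p13.1(2,418,074-40,508,819)x3")
  expect_equal(length(two), 2L)
  expect_equal(two$kind, c("loss", "gain"))
  expect_equal(two$bandStart, c("p24.3", "p24.2"))
  expect_equal(two$bandEnd, c("p24.3", "p13.1"))

  mos <- parseResultString("Xp11.3p11.21(44,307,282-58,051,765)x1∼2")
  expect_equal(mos$kind, "mosaic")
  expect_equal(mos$copies, 1L)
  expect_equal(mos$copiesHigh, 2L)
  # ASCII tilde accepted too
  mos2 <- parseResultString("Xp11.3p11.21(44,307,282-58,051,765)x1~2")
  expect_equal(mos2$copiesHigh, 2L)

  amp <- parseResultString("6p25.3p22.2(259,527-25,416,824)amp")
  expect_equal(amp$kind, "amplification")
  expect_true(is.na(amp$copies))

  # hyphenated band pair dialect
  hy <- parseResultString("19p13.2-p13.13(13,865,337-13,933,080)x3")
  expect_equal(hy$bandEnd, "p13.13")

  # sex-aware reference: x2 on a single-copy X is a gain
  xg <- parseResultString("Xq28(154,133,237-154,560,375)x2", reference = 1L)
  expect_equal(xg$kind, "gain")
  expect_equal(xg$direction, "gain")
})

test_that("malformed result strings fail with the offending token", {
  expect_error(parseResultString("22q11.21(18896971)x1"), "malformed")
  expect_error(parseResultString("not a result"), "malformed")
  expect_error(parseResultString("22q11.21(1-2)x1,banana"), "banana")
  expect_error(parseResultString("22q11.21(5-6)x2~1"), "ordered")
})

test_that("formatting produces the printed dialect and round-trips", {
  bands <- sharedBands()
  x <- parseResultString("17p11.2(16,532,735-20,221,695)x3")
  expect_identical(formatResultString(x, bands),
                   "17p11.2(16,532,735-20,221,695)x3")
  amp <- parseResultString("6p25.3p22.2(259,527-25,416,824)amp")
  expect_match(formatResultString(amp, bands), "amp$")
  mos <- parseResultString("Xp11.3p11.21(44,307,282-58,051,765)x1∼2")
  expect_match(formatResultString(mos, bands), "x1~2$", fixed = FALSE)

  # parse . format identity on a multi-CNV string
  s <- "9p24.3(214,366-2,197,859)x1,9p24.2p13.1(2,418,074-40,508,819)x3"
  back <- parseResultString(formatResultString(parseResultString(s), bands))
  orig <- parseResultString(s)
  expect_equal(start(back), start(orig))
  expect_equal(end(back), end(orig))
  expect_equal(back$copies, orig$copies)
})

test_that("cytoband map tiles chromosomes and locates bands", {
  bands <- sharedBands()
  expect_s4_class(bands, "CytobandMap")
  expect_equal(bandAt(bands, "22", 18896971), "q11.21")
  expect_equal(bandAt(bands, "22", 21801661), "q11.21")
  expect_error(readCytoband(tempfile()), "not found")
  # a gap in the tiling is rejected by the validity method
  broken <- data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300),
                       band = c("p11", "q11"), stain = "gneg")
  f <- tempfile(); write.table(broken, f, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE)
  expect_error(readCytoband(f), "tile")
})

test_that("BED round-trips through the 0-based half-open convention", {
  gr <- gi(c("1", "X"), c(1, 500), c(100, 900))
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f, name = c("a", "b"))
  raw <- read.delim(f, header = FALSE)
  expect_equal(raw$V2, c(0, 499))  # 0-based starts
  back <- readBed(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
})
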