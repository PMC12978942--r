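test_that("binarization handles blank and noiseless inputs", {
  zero <- array(0, dim = c(20, 20, 3))
  bm <- binarize_channels(zero)
  expect_false(any(bm$uv1) || any(bm$uv2) || any(bm$b) || any(bm$merged))

  # noiseless render on zero background: masks equal ground-truth footprints
  m <- generate_mosaic(mosaic_spec(4, 5, c(0.2, 0.4, 0.4),
                                   p_coexpress = 0.5, seed = 7))
  sec <- render_ihc_section(m, imaging_config(noise_sd = 0))
  bm <- binarize_channels(sec)
  tm <- truth_masks(sec)
  expect_identical(bm$uv1, tm$uv1)
  expect_identical(bm$uv2, tm$uv2)
  expect_identical(bm$b, tm$b)

  # merged is the union of the channels
  expect_identical(bm$merged, bm$uv1 | bm$uv2 | bm$b)
  expect_gte(sum(bm$merged), max(sum(bm$uv1), sum(bm$uv2), sum(bm$b)))

  expect_error(binarize_channels(array(0, c(5, 5, 2))), "3-channel")
})

test_that("a pure-noise channel is treated as blank", {
  set.seed(42)
  arr <- array(0, dim = c(60, 60, 3))
  arr[10:20, 10:20, 1] <- 255                        # real staining in UV1
  arr <- arr + array(rnorm(length(arr), 0, 8), dim = dim(arr))
  arr <- round(pmin(pmax(arr, 0), 255))
  bm <- binarize_channels(arr)
  expect_false(any(bm$uv2))                          # noise-only channels
  expect_false(any(bm$b))
  expect_gt(sum(bm$uv1), 100)
})

test_that("segmentation applies the area filter to 8-connected components", {
  mk <- matrix(FALSE, 12, 12)
  mk[2:3, 2:3] <- TRUE; mk[2, 4] <- TRUE             # 5-px blob
  mk[8:9, 8:9] <- TRUE; mk[10, 10] <- TRUE           # 5-px blob (diag-joined)
  bm <- masks_from_logical(mk)
  seg <- segment_ommatidia(bm, area_range = c(3, 10))
  expect_equal(nrow(seg), 2)
  expect_equal(seg$area_px, c(5L, 5L))

  mk2 <- matrix(FALSE, 12, 12); mk2[5, 5:6] <- TRUE  # 2-px blob: filtered
  expect_equal(nrow(segment_ommatidia(masks_from_logical(mk2), c(3, 10))), 0)

  empty <- masks_from_logical(matrix(FALSE, 5, 5))
  expect_equal(nrow(segment_ommatidia(empty, c(1, 10))), 0)

  expect_error(segment_ommatidia(bm, c(0, 10)), "A_min")
})

test_that("labels follow raster-scan order of the first pixel", {
  mk <- matrix(FALSE, 10, 10)
  mk[6:7, 2:3] <- TRUE       # leftmost but lower
  mk[2:3, 6:7] <- TRUE       # topmost: must get label 1
  seg <- segment_ommatidia(masks_from_logical(mk), c(1, 100))
  expect_equal(seg$min_row, c(2L, 6L))
  expect_equal(seg$label, c(1L, 2L))
})

test_that("segmentation matches the flood-fill oracle on random masks", {
  set.seed(314)
  for (i in 1:40) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    mk <- random_mask(h, w, runif(1, 0.2, 0.6))
    rng <- c(1, sample(c(3, 8, h * w), 1))
    seg <- segment_ommatidia(masks_from_logical(mk), rng)
    got <- attr(seg, "pixels")
    want <- label_partition(flood_fill_label(mk), rng)
    expect_equal(lapply(got, sort), want)
  }
})

test_that("the 4% positivity rule is inclusive and drives the class call", {
  # component of area 100 built in UV1; B overlaps 4 px (fill exactly 0.04)
  base <- matrix(FALSE, 20, 20); base[3:12, 3:12] <- TRUE
  b4 <- matrix(FALSE, 20, 20); b4[3, 3:6] <- TRUE
  bm <- masks_from_logical(base, b = b4)
  seg <- segment_ommatidia(bm, c(1, 1000))
  cp <- score_and_classify(seg, bm)
  st <- attr(cp, "segments")
  expect_true(st$pos_b)                       # 0.04 >= 0.04: positive
  expect_equal(st$call, "UV-B")

  # B overlap of 3 px (0.03) with 50 px of UV1: UV-UV
  b3 <- matrix(FALSE, 20, 20); b3[3, 3:5] <- TRUE
  bm3 <- masks_from_logical(base, b = b3)
  cp3 <- score_and_classify(segment_ommatidia(bm3, c(1, 1000)), bm3)
  expect_equal(attr(cp3, "segments")$call, "UV-UV")
  expect_equal(cp3$counts[["UV-UV"]], 1L)

  # boundary exactness on a 1000-px component: 39 px negative, 40 positive
  big <- matrix(FALSE, 50, 50); big[3:42, 3:27] <- TRUE  # 40 x 25 = 1000 px
  for (k in c(39, 40)) {
    bk <- matrix(FALSE, 50, 50); bk[which(big)[1:k]] <- TRUE  # inside component
    bmk <- masks_from_logical(big, b = bk)
    cpk <- score_and_classify(segment_ommatidia(bmk, c(1, 2000)), bmk)
    expect_identical(attr(cpk, "segments")$pos_b, k >= 40)
  }
})

test_that("positivity is monotone in channel overlap", {
  base <- matrix(FALSE, 20, 20); base[3:12, 3:12] <- TRUE
  was_positive <- FALSE
  for (k in 1:20) {
    bk <- matrix(FALSE, 20, 20); bk[which(base)[1:k]] <- TRUE
    bmk <- masks_from_logical(base, b = bk)
    cpk <- score_and_classify(segment_ommatidia(bmk, c(1, 1000)), bmk)
    pos <- attr(cpk, "segments")$pos_b
    expect_false(was_positive && !pos)        # never flips back to negative
    was_positive <- pos
  }
})

test_that("noiseless sections recover the generating classes exactly", {
  m <- generate_mosaic(mosaic_spec(8, 10, c(0, 0.5, 0.5),
                                   p_coexpress = 0.5, seed = 9))
  sec <- render_ihc_section(m, imaging_config(noise_sd = 0))
  bm <- binarize_channels(sec)
  cp <- score_and_classify(segment_ommatidia(bm), bm)
  truth <- table(factor(m$omm_class, c("UV-UV", "B-B", "UV-B")))
  expect_equal(unname(cp$counts), unname(as.integer(truth)))
  expect_equal(cp$n_unclassified, 0L)
  expect_equal(sum(cp$fractions), 1)
})

test_that("section consistency applies the 5-percentage-point rule strictly", {
  s1 <- section_consistency(list(props_with_blue(0.50), props_with_blue(0.54)))
  expect_equal(s1$status, "kept")
  expect_equal(s1$consistency_delta, 0.04)
  # mean proportions are the unweighted average across sections
  expect_equal(unname(s1$mean_fractions),
               unname((props_with_blue(0.50)$fractions +
                         props_with_blue(0.54)$fractions) / 2))

  s2 <- section_consistency(list(props_with_blue(0.50), props_with_blue(0.56)))
  expect_equal(s2$status, "excluded")

  # exactly 5 points is kept (rule is "more than 5%")
  s3 <- section_consistency(list(props_with_blue(0.50), props_with_blue(0.55)))
  expect_equal(s3$status, "kept")

  s4 <- section_consistency(list(props_with_blue(0.5), props_with_blue(0.5),
                                 props_with_blue(0.5)))
  expect_equal(s4$consistency_delta, 0)
  expect_equal(s4$status, "kept")

  expect_error(section_consistency(list(props_with_blue(0.5)),
                                   individual = "eye-7"), "eye-7")
})

test_that("manual-vs-automated agreement is a symmetric blue-cell difference", {
  a <- props_with_blue(0.50, 2000)
  b <- props_with_blue(0.541, 2000)
  expect_equal(compare_manual(a, a), 0)
  expect_equal(compare_manual(a, b), 0.041)
  expect_equal(compare_manual(a, b), compare_manual(b, a))
})

test_that("blue_fraction counts cells, not ommatidia", {
  # 10 B-B (2 blue cells each), 20 UV-B (1 each), 10 UV-UV over 40 ommatidia
  cp <- class_proportions(10, 10, 20)
  expect_equal(blue_fraction(cp), (2 * 10 + 20) / (2 * 40))
})
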