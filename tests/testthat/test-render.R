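# single-ommatidium mosaics with a forced class
one_omm_mosaic <- function(omm_class, uv_mode = "UV1_only") {
  pr <- switch(omm_class,
               "UV-UV" = c(1, 0, 0), "B-B" = c(0, 1, 0), "UV-B" = c(0, 0, 1))
  generate_mosaic(mosaic_spec(1, 1, pr, p_coexpress = 0,
                              uv_mode = uv_mode, seed = 1))
}

test_that("channel assignment follows the R1/R2 opsins", {
  # fill 0.5 keeps the two cell footprints disjoint so they can be counted
  cfg <- imaging_config(noise_sd = 0, fill_fraction_mean = 0.5,
                        fill_fraction_sd = 0, fill_fraction_range = c(0, 1))

  sec <- render_ihc_section(one_omm_mosaic("UV-UV"), cfg)
  expect_true(all(sec$image[, , 3] == 0))                       # B empty
  expect_true(all(sec$image[, , 2] == 0))                       # UV2 empty
  lab <- label_components(sec$image[, , 1] > 0)
  expect_equal(max(lab), 2)                                     # 2 footprints

  sec_b <- render_ihc_section(one_omm_mosaic("B-B"), cfg)
  expect_true(all(sec_b$image[, , 1] == 0))
  expect_equal(max(label_components(sec_b$image[, , 3] > 0)), 2)

  sec_c <- render_ihc_section(one_omm_mosaic("UV-UV", "coexpress"), cfg)
  expect_true(any(sec_c$image[, , 2] > 0))                      # UV2 co-stains
})

test_that("rendered fill fraction matches the requested value", {
  cfg <- imaging_config(omm_radius_px = 10, fill_fraction_mean = 0.5,
                        fill_fraction_sd = 0, fill_fraction_range = c(0, 1),
                        noise_sd = 0)
  sec <- render_ihc_section(one_omm_mosaic("UV-UV"), cfg)
  cells <- sec$truth$cells
  # pixel-count oracle on the rendered raster: stained UV1 pixels equal the
  # sum of the two cells' stained areas (footprints are disjoint at f = 0.5)
  expect_equal(sum(sec$image[, , 1] > 0), sum(cells$area_stained_px))
  expect_true(all(abs(cells$area_stained_px - 0.5 * cells$area_full_px) <= 1))
})

test_that("eyeshine renders tile the dv axis and respect pigment", {
  cfg <- imaging_config(omm_radius_px = 5, noise_sd = 0)
  m <- generate_mosaic(mosaic_spec(12, 8, c(0.3, 0.4, 0.3),
                                   p_coexpress = 0, seed = 4))  # all yellow
  imgs <- render_eyeshine(m, cfg, n_images = 4)
  expect_length(imgs, 4)
  # conservation: ground-truth spots partition the mosaic
  ids <- unlist(lapply(imgs, function(x) x$spots$id))
  expect_setequal(ids, m$id)
  expect_equal(length(ids), nrow(m))
  # all-yellow mosaic: zero red spots detected
  sp <- detect_spots(imgs[[1]])
  expect_gt(nrow(sp), 0)
  expect_true(all(classify_spot_color(sp) == "yellow"))
})

test_that("resolution gradient puts more ommatidia in ventral images", {
  cfg <- imaging_config(omm_radius_px = 4, noise_sd = 0)
  m <- generate_mosaic(mosaic_spec(30, 10, c(0.3, 0.4, 0.3),
                                   p_coexpress = 0.5, seed = 6))
  imgs <- render_eyeshine(m, cfg, n_images = 4, resolution_gradient = 2)
  counts <- vapply(imgs, function(x) nrow(x$spots), integer(1))
  expect_equal(sum(counts), nrow(m))
  ratio <- counts[4] / counts[1]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("reflectance model obeys the pigment and cutoff constraints", {
  mod <- reflectance_model()
  lam <- mod$wavelengths
  for (dv in c(0, 0.5, 1)) {
    y <- model_reflectance(mod, "yellow", dv)
    r <- model_reflectance(mod, "red", dv)
    expect_true(all(y >= 0 & y <= 1 & r >= 0 & r <= 1))
    band <- lam >= 550 & lam <= 660
    expect_true(all(r[band] <= y[band]))
    expect_true(all(r <= y))                 # red never exceeds yellow
    expect_lt(max(y[lam > 730]), 0.05)       # tapetal cutoff
  }
  expect_error(reflectance_model(wavelengths = seq(500, 790, 10)),
               "10 nm steps")
})

test_that("rendered stacks follow the model: pigment order, cutoff, redshift", {
  cfg <- imaging_config(omm_radius_px = 6, noise_sd = 0)
  mod <- reflectance_model(dv_redshift_per_unit = 20)
  # tall skinny mosaic: dorsal rows yellow-only information comes from truth
  m <- generate_mosaic(mosaic_spec(9, 4, c(0, 0.5, 0.5),
                                   p_coexpress = 0.5, seed = 8))
  st <- render_reflectance_stack(m, mod, cfg)
  tr <- st$truth$ommatidia
  lam <- st$wavelengths

  # red <= yellow at 600 nm on the rendered planes
  sp <- extract_spectra(st, stack_rois(st), color_call = tr$pigment)
  i600 <- which(lam == 600)
  expect_lt(max(sp$reflectance[tr$pigment == "red", i600]),
            min(sp$reflectance[tr$pigment == "yellow", i600]) + 1e-9)

  # planes above 740 nm are at background
  expect_lte(max(st$planes[, , lam > 740]), 2)

  # half-maximum redshift of the yellow spectrum across the dv axis
  half_max_wl <- function(v) {
    hm <- max(v) / 2
    i <- which(v >= hm)[1]
    stats::approx(v[(i - 1):i], lam[(i - 1):i], xout = hm)$y
  }
  dorsal_yellow <- which(tr$dv_position == 0 & tr$pigment == "yellow")[1]
  ventral_yellow <- which(tr$dv_position == 1 & tr$pigment == "yellow")[1]
  shift <- half_max_wl(sp$reflectance[ventral_yellow, ]) -
    half_max_wl(sp$reflectance[dorsal_yellow, ])
  expect_lt(abs(shift - 20), 10)  # within the 10 nm grid resolution
})

test_that("renders are bit-identical under a fixed seed", {
  cfg <- imaging_config(noise_sd = 6)
  m <- generate_mosaic(mosaic_spec(4, 4, c(0.2, 0.4, 0.4),
                                   p_coexpress = 0.5, seed = 2))
  expect_identical(render_ihc_section(m, cfg, seed = 31)$image,
                   render_ihc_section(m, cfg, seed = 31)$image)
  expect_identical(render_eyeshine(m, cfg, 2, seed = 32)[[1]]$rgb,
                   render_eyeshine(m, cfg, 2, seed = 32)[[1]]$rgb)
  mod <- reflectance_model()
  expect_identical(render_reflectance_stack(m, mod, cfg, seed = 33)$planes,
                   render_reflectance_stack(m, mod, cfg, seed = 33)$planes)
})

test_that("images round-trip through TIFF and PNG", {
  cfg <- imaging_config(noise_sd = 3)
  m <- generate_mosaic(mosaic_spec(3, 3, c(0.2, 0.4, 0.4),
                                   p_coexpress = 0.5, seed = 2))
  sec <- render_ihc_section(m, cfg, seed = 1)
  f <- withr::local_tempfile(fileext = ".tif")
  write_ihc_tiff(sec, f)
  expect_equal(read_ihc_tiff(f), sec$image, ignore_attr = TRUE)

  img <- render_eyeshine(m, cfg, 1, seed = 2)[[1]]
  g <- withr::local_tempfile(fileext = ".png")
  write_eyeshine_png(img, g)
  expect_equal(read_eyeshine_png(g)$rgb, img$rgb, ignore_attr = TRUE)

  st <- render_reflectance_stack(m, reflectance_model(), cfg, seed = 3)
  h <- withr::local_tempfile(fileext = ".tif")
  write_reflectance_tiff(st, h)
  expect_equal(read_reflectance_tiff(h)$planes, st$planes, ignore_attr = TRUE)
})
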