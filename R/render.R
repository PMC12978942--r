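#' Imaging configuration for synthetic renders
#'
#' Controls the rasterization of a [generate_mosaic()] ground truth into the
#' three imaging modalities (IHC sections, eyeshine photographs, reflectance
#' stacks). All renders are 8-bit.
#'
#' @param omm_radius_px Ommatidium footprint radius in pixels (>= 2).
#' @param fill_fraction_mean,fill_fraction_sd Mean and SD of the per-cell
#'   stained area fraction (stained pixels / full cell footprint pixels).
#' @param fill_fraction_range Truncation bounds for drawn fill fractions;
#'   the lower bound keeps the two stained cell footprints of an ommatidium
#'   connected so that segmentation sees one component per ommatidium.
#' @param noise_sd Additive Gaussian noise SD in 8-bit intensity units,
#'   clipped to \[0, 255\].
#' @param background_level Background intensity (8-bit units).
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(omm_radius_px = 8,
                           fill_fraction_mean = 0.85,
                           fill_fraction_sd = 0.03,
                           fill_fraction_range = c(0.7, 1),
                           noise_sd = 0,
                           background_level = 0) {
  if (omm_radius_px < 2) stop("omm_radius_px must be >= 2")
  if (fill_fraction_mean <= 0 || fill_fraction_mean > 1) {
    stop("fill_fraction_mean must lie in (0, 1]")
  }
  if (fill_fraction_sd < 0 || noise_sd < 0) {
    stop("fill_fraction_sd and noise_sd must be non-negative")
  }
  if (background_level < 0 || background_level > 255) {
    stop("background_level must lie in [0, 255]")
  }
  structure(
    list(omm_radius_px = as.integer(omm_radius_px),
         fill_fraction_mean = fill_fraction_mean,
         fill_fraction_sd = fill_fraction_sd,
         fill_fraction_range = fill_fraction_range,
         noise_sd = noise_sd,
         background_level = background_level,
         bit_depth = 8L),
    class = "imaging_config"
  )
}

# clip to the 8-bit range and quantize (pmin/pmax keep x's dims first)
clip8 <- function(x) round(pmin(pmax(x, 0), 255))

# hexagonal lattice pixel geometry for a set of mosaic rows
# rows are re-indexed so the band starts at the top of the raster
omm_centers <- function(mosaic, cfg, rows = sort(unique(mosaic$row))) {
  r <- cfg$omm_radius_px
  pitch_x <- 2L * r + 4L
  pitch_y <- as.integer(round(pitch_x * sqrt(3) / 2))
  margin <- r + 2L
  sel <- mosaic$row %in% rows
  m <- mosaic[sel, , drop = FALSE]
  row_local <- match(m$row, sort(rows))
  x <- margin + (m$col - 1L) * pitch_x + (m$row %% 2L) * (pitch_x %/% 2L)
  y <- margin + (row_local - 1L) * pitch_y
  width <- 2L * margin + (max(mosaic$col) - 1L) * pitch_x + pitch_x %/% 2L
  height <- 2L * margin + (length(rows) - 1L) * pitch_y
  list(idx = which(sel), x = x, y = y, width = width, height = height)
}

# pixel set of a disk; returns matrix with columns (row, col) inside [H, W]
disk_pixels <- function(cx, cy, radius, height, width) {
  x0 <- max(1L, floor(cx - radius)); x1 <- min(width, ceiling(cx + radius))
  y0 <- max(1L, floor(cy - radius)); y1 <- min(height, ceiling(cy + radius))
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(row = ys, col = xs)
  d2 <- (g$col - cx)^2 + (g$row - cy)^2
  keep <- d2 <= radius^2
  cbind(row = g$row[keep], col = g$col[keep], d2 = d2[keep])
}

# stained subset of a full cell footprint: the k pixels closest to the
# cell centre (exact pixel-count realization of the fill fraction)
erode_to_fill <- function(px, fill) {
  k <- max(1L, round(fill * nrow(px)))
  ord <- order(px[, "d2"], px[, "row"], px[, "col"])
  px[ord[seq_len(k)], , drop = FALSE]
}

#' Render an immunohistochemistry section from a mosaic
#'
#' Produces a 3-channel (UV1, UV2, B) 8-bit raster in which every
#' ommatidium contributes up to two stained cell footprints, one per R1/R2
#' photoreceptor. Cell footprints are disks offset to either side of the
#' ommatidium centre; the stained area of each is `fill_fraction` times the
#' full footprint area, realized by keeping the pixels closest to the cell
#' centre. Channel assignment follows each cell's opsin; under the
#' `"coexpress"` UV regime a UV cell additionally stains the UV2 channel at
#' the spec's mixing weight.
#'
#' @param mosaic A `retina_mosaic`.
#' @param cfg An [imaging_config()].
#' @param row_band Integer vector of lattice rows to section (default: all).
#' @param seed Optional seed for fill-fraction draws and noise.
#' @return An object of class `ihc_section`: a list with `image` (an
#'   `H x W x 3` integer array, channels named UV1/UV2/B), and `truth`, a
#'   list with per-cell (`cells`) and per-ommatidium (`ommatidia`) tables
#'   plus the stained pixel sets.
#' @export
render_ihc_section <- function(mosaic, cfg, row_band = NULL, seed = NULL) {
  stopifnot(inherits(mosaic, "retina_mosaic"), inherits(cfg, "imaging_config"))
  rows_all <- sort(unique(mosaic$row))
  if (is.null(row_band)) row_band <- rows_all
  row_band <- intersect(row_band, rows_all)
  if (length(row_band) == 0L) stop("row_band selects no lattice rows")

  spec <- attr(mosaic, "spec")
  uv_mode <- if (is.null(spec)) "UV1_only" else spec$uv_mode
  uv_mix <- if (is.null(spec)) 1 else spec$uv_mix

  render <- function() {
    geo <- omm_centers(mosaic, cfg, row_band)
    H <- geo$height; W <- geo$width
    img <- array(cfg$background_level, dim = c(H, W, 3L))
    r <- cfg$omm_radius_px
    cell_r <- 0.55 * r
    offs <- c(-0.45, 0.45) * r

    n_cells <- 2L * length(geo$idx)
    fills <- stats::rnorm(n_cells, cfg$fill_fraction_mean, cfg$fill_fraction_sd)
    fills <- pmin(cfg$fill_fraction_range[2],
                  pmax(cfg$fill_fraction_range[1], fills))

    cells <- vector("list", n_cells)
    pixels <- vector("list", n_cells)
    k <- 0L
    for (j in seq_along(geo$idx)) {
      i <- geo$idx[j]
      for (cell in 1:2) {
        k <- k + 1L
        opsin <- if (cell == 1L) mosaic$r1_opsin[i] else mosaic$r2_opsin[i]
        lw <- if (cell == 1L) mosaic$r1_lw[i] else mosaic$r2_lw[i]
        cx <- geo$x[j] + offs[cell]; cy <- geo$y[j]
        full <- disk_pixels(cx, cy, cell_r, H, W)
        st <- erode_to_fill(full, fills[k])
        w <- c(UV1 = 0, UV2 = 0, B = 0)
        if (opsin == "B") {
          w["B"] <- 1
        } else if (opsin == "UV2") {
          w["UV2"] <- 1
        } else {
          w["UV1"] <- 1
          if (uv_mode == "coexpress") w["UV2"] <- uv_mix
        }
        for (ch in 1:3) {
          if (w[ch] > 0) {
            img[cbind(st[, "row"], st[, "col"], ch)] <-
              pmax(cfg$background_level, round(255 * w[ch]))
          }
        }
        cells[[k]] <- data.frame(
          omm_id = mosaic$id[i], cell = c("R1", "R2")[cell], opsin = opsin,
          lw = lw, center_x = cx, center_y = cy,
          area_full_px = nrow(full), area_stained_px = nrow(st),
          fill_target = fills[k], fill_realized = nrow(st) / nrow(full),
          w_uv1 = w[["UV1"]], w_uv2 = w[["UV2"]], w_b = w[["B"]],
          stringsAsFactors = FALSE)
        pixels[[k]] <- st[, c("row", "col"), drop = FALSE]
      }
    }
    if (cfg$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    }
    img <- clip8(img)
    cells_df <- do.call(rbind, cells)
    omm <- mosaic[geo$idx, c("id", "omm_class", "pigment", "dv_position")]
    omm$center_x <- geo$x; omm$center_y <- geo$y
    structure(
      list(image = img, channels = c("UV1", "UV2", "B"),
           truth = list(cells = cells_df, ommatidia = omm, pixels = pixels)),
      class = "ihc_section")
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Ground-truth channel masks of a rendered section
#'
#' Rebuilds the exact stained footprints of an [render_ihc_section()]
#' render as logical masks, one per channel, for validating binarization.
#'
#' @param section An `ihc_section`.
#' @return A list of logical matrices `uv1`, `uv2`, `b`.
#' @export
truth_masks <- function(section) {
  stopifnot(inherits(section, "ihc_section"))
  d <- dim(section$image)[1:2]
  masks <- list(uv1 = matrix(FALSE, d[1], d[2]),
                uv2 = matrix(FALSE, d[1], d[2]),
                b = matrix(FALSE, d[1], d[2]))
  cells <- section$truth$cells
  for (k in seq_len(nrow(cells))) {
    px <- section$truth$pixels[[k]]
    if (cells$w_uv1[k] > 0) masks$uv1[px] <- TRUE
    if (cells$w_uv2[k] > 0) masks$uv2[px] <- TRUE
    if (cells$w_b[k] > 0) masks$b[px] <- TRUE
  }
  masks
}

#' Render an ordered eyeshine image series
#'
#' Tiles the dorsoventral axis of a mosaic into `n_images` non-overlapping
#' bands (index 0 = most dorsal) and renders each as an RGB photograph:
#' every ommatidium appears as one bright spot whose color follows its
#' ground-truth screening pigment (red vs. yellow eyeshine). A resolution
#' gradient > 1 allocates proportionally more lattice rows to ventral
#' images, emulating the higher ommatidial counts of ventral eyeshine
#' photographs.
#'
#' @param mosaic A `retina_mosaic`.
#' @param cfg An [imaging_config()].
#' @param n_images Number of images tiling the dv axis (>= 1).
#' @param resolution_gradient Ratio of rows per ventral image to rows per
#'   dorsal image (1 = uniform tiling).
#' @param seed Optional seed for render noise.
#' @return A list of `eyeshine_image` objects, each with `rgb`
#'   (`H x W x 3`, 8-bit), `dv_index`, and a ground-truth `spots` table
#'   (`id`, `x`, `y`, `pigment`).
#' @export
render_eyeshine <- function(mosaic, cfg, n_images,
                            resolution_gradient = 1, seed = NULL) {
  stopifnot(inherits(mosaic, "retina_mosaic"), inherits(cfg, "imaging_config"))
  if (n_images < 1L) stop("n_images must be >= 1")
  rows_all <- sort(unique(mosaic$row))
  if (length(rows_all) < n_images) {
    stop("mosaic has fewer lattice rows than requested images")
  }
  # band sizes proportional to a linear dorsal-to-ventral weight ramp
  w <- seq(1, resolution_gradient, length.out = n_images)
  sizes <- pmax(1L, floor(w / sum(w) * length(rows_all)))
  while (sum(sizes) < length(rows_all)) {
    j <- which.max(w / sizes); sizes[j] <- sizes[j] + 1L
  }
  while (sum(sizes) > length(rows_all)) {
    j <- which.max(sizes); sizes[j] <- sizes[j] - 1L
  }
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  palette <- rbind(red = c(220, 45, 25), yellow = c(235, 195, 45))
  render_one <- function(band_rows, dv_index) {
    geo <- omm_centers(mosaic, cfg, band_rows)
    H <- geo$height; W <- geo$width
    img <- array(0, dim = c(H, W, 3L))
    for (j in seq_along(geo$idx)) {
      i <- geo$idx[j]
      px <- disk_pixels(geo$x[j], geo$y[j], cfg$omm_radius_px, H, W)
      colr <- palette[mosaic$pigment[i], ]
      for (ch in 1:3) img[cbind(px[, "row"], px[, "col"], ch)] <- colr[ch]
    }
    if (cfg$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    structure(
      list(rgb = clip8(img), dv_index = dv_index,
           spots = data.frame(id = mosaic$id[geo$idx],
                              x = geo$x, y = geo$y,
                              pigment = mosaic$pigment[geo$idx],
                              stringsAsFactors = FALSE)),
      class = "eyeshine_image")
  }
  render_all <- function() {
    lapply(seq_len(n_images), function(i) {
      render_one(rows_all[starts[i]:ends[i]], i - 1L)
    })
  }
  if (is.null(seed)) render_all() else withr::with_seed(seed, render_all())
}

#' Tapetal reflectance model for eyeshine spectra
#'
#' Parametric reflectance spectrum on the 500-800 nm grid (10 nm steps).
#' The yellow-eyeshine spectrum is a logistic rise (long-pass edge set by
#' the rhodopsin/pigment absorption of the ommatidium) multiplied by a
#' logistic fall modelling the tapetal long-wavelength cutoff, so that
#' reflectance is nearly absent above 730 nm. Red-pigmented ommatidia are
#' additionally attenuated within the red-screening-pigment absorption band
#' (550-660 nm by default), which also lowers their peak reflectance.
#' Moving ventrally the rising edge red-shifts by
#' `dv_redshift_per_unit * dv_position` nanometres (longer ommatidia give a
#' longer optical path).
#'
#' @param wavelengths Wavelength grid; must be 500-800 nm in 10 nm steps.
#' @param peak_reflectance Plateau reflectance of yellow ommatidia (0-1).
#' @param rise_nm,rise_width Half-maximum position and logistic width (nm)
#'   of the rising edge at the dorsal pole.
#' @param cutoff_nm,cutoff_width Half-maximum position and width (nm) of
#'   the tapetal cutoff.
#' @param red_band Wavelength interval (nm) attenuated by the red pigment.
#' @param red_depth Fractional attenuation inside `red_band` (0-1).
#' @param band_edge_width Logistic width (nm) of the band edges.
#' @param dv_redshift_per_unit Red shift (nm) of the rising edge per unit
#'   dv position.
#' @return An object of class `reflectance_model`.
#' @export
reflectance_model <- function(wavelengths = seq(500, 800, by = 10),
                              peak_reflectance = 0.85,
                              rise_nm = 560, rise_width = 12,
                              cutoff_nm = 700, cutoff_width = 7.5,
                              red_band = c(550, 660), red_depth = 0.5,
                              band_edge_width = 8,
                              dv_redshift_per_unit = 15) {
  if (!isTRUE(all.equal(wavelengths, seq(500, 800, by = 10)))) {
    stop("wavelengths must be 500 to 800 nm in 10 nm steps (31 planes)")
  }
  if (peak_reflectance <= 0 || peak_reflectance > 1) {
    stop("peak_reflectance must lie in (0, 1]")
  }
  if (red_depth < 0 || red_depth > 1) stop("red_depth must lie in [0, 1]")
  structure(
    list(wavelengths = wavelengths, peak_reflectance = peak_reflectance,
         rise_nm = rise_nm, rise_width = rise_width,
         cutoff_nm = cutoff_nm, cutoff_width = cutoff_width,
         red_band = red_band, red_depth = red_depth,
         band_edge_width = band_edge_width,
         dv_redshift_per_unit = dv_redshift_per_unit),
    class = "reflectance_model"
  )
}

#' Model reflectance spectrum of one ommatidium
#'
#' @param model A [reflectance_model()].
#' @param pigment `"red"` or `"yellow"`.
#' @param dv dv position in \[0, 1\] (0 = dorsal).
#' @return Reflectance values in \[0, 1\] on the model's wavelength grid.
#' @export
model_reflectance <- function(model, pigment, dv = 0) {
  stopifnot(inherits(model, "reflectance_model"))
  lam <- model$wavelengths
  logis <- function(x) 1 / (1 + exp(-x))
  rise <- logis((lam - (model$rise_nm + model$dv_redshift_per_unit * dv)) /
                  model$rise_width)
  fall <- 1 - logis((lam - model$cutoff_nm) / model$cutoff_width)
  y <- model$peak_reflectance * rise * fall
  if (pigment == "red") {
    band <- logis((lam - model$red_band[1]) / model$band_edge_width) *
      (1 - logis((lam - model$red_band[2]) / model$band_edge_width))
    y <- y * (1 - model$red_depth * band)
  }
  y
}

#' Render a monochromatic reflectance image stack
#'
#' Renders one 8-bit image plane per wavelength (31 planes, 500-800 nm in
#' 10 nm steps). Each ommatidium appears as a uniform disk whose intensity
#' is its model reflectance scaled to the 8-bit range, then noise is added
#' and values are clipped (saturation at 255). Ground-truth spectra and
#' region assignments (dorsal/middle/ventral by dv terciles) are stored
#' alongside.
#'
#' @param mosaic A `retina_mosaic`.
#' @param model A [reflectance_model()].
#' @param cfg An [imaging_config()].
#' @param seed Optional seed for render noise.
#' @return An object of class `reflectance_stack`: list with `planes`
#'   (`H x W x 31`), `wavelengths`, and `truth` (per-ommatidium table,
#'   true reflectance matrix, centre coordinates).
#' @export
render_reflectance_stack <- function(mosaic, model, cfg, seed = NULL) {
  stopifnot(inherits(mosaic, "retina_mosaic"),
            inherits(model, "reflectance_model"),
            inherits(cfg, "imaging_config"))
  render <- function() {
    geo <- omm_centers(mosaic, cfg)
    H <- geo$height; W <- geo$width
    n_lam <- length(model$wavelengths)
    planes <- array(cfg$background_level, dim = c(H, W, n_lam))
    n <- length(geo$idx)
    refl <- matrix(0, n, n_lam)
    for (j in seq_len(n)) {
      i <- geo$idx[j]
      refl[j, ] <- model_reflectance(model, mosaic$pigment[i],
                                     mosaic$dv_position[i])
      px <- disk_pixels(geo$x[j], geo$y[j], cfg$omm_radius_px, H, W)
      for (p in seq_len(n_lam)) {
        planes[cbind(px[, "row"], px[, "col"], p)] <-
          pmax(cfg$background_level, 255 * refl[j, p])
      }
    }
    if (cfg$noise_sd > 0) {
      planes <- planes + stats::rnorm(length(planes), 0, cfg$noise_sd)
    }
    planes <- clip8(planes)
    dv <- mosaic$dv_position[geo$idx]
    region <- cut(dv, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
                  labels = c("dorsal", "middle", "ventral"))
    truth <- list(
      ommatidia = data.frame(id = mosaic$id[geo$idx], x = geo$x, y = geo$y,
                             dv_position = dv,
                             pigment = mosaic$pigment[geo$idx],
                             region = as.character(region),
                             stringsAsFactors = FALSE),
      reflectance = refl)
    structure(list(planes = planes, wavelengths = model$wavelengths,
                   truth = truth, omm_radius_px = cfg$omm_radius_px),
              class = "reflectance_stack")
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Regions of interest at the rendered ommatidium positions
#'
#' Builds one circular ROI per ommatidium of a rendered
#' [render_reflectance_stack()], shrunk slightly inside the footprint so
#' ROI means are unaffected by edge pixels.
#'
#' @param stack A `reflectance_stack`.
#' @param shrink_px Pixels to shave off the footprint radius.
#' @return A named list (by ommatidium id) of 2-column matrices
#'   (`row`, `col`) of ROI pixels.
#' @export
stack_rois <- function(stack, shrink_px = 1) {
  stopifnot(inherits(stack, "reflectance_stack"))
  d <- dim(stack$planes)
  tr <- stack$truth$ommatidia
  r <- max(1, stack$omm_radius_px - shrink_px)
  rois <- lapply(seq_len(nrow(tr)), function(j) {
    disk_pixels(tr$x[j], tr$y[j], r, d[1], d[2])[, c("row", "col"), drop = FALSE]
  })
  names(rois) <- tr$id
  rois
}
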