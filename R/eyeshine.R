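#' Detect eyeshine spots in an RGB image
#'
#' Finds connected bright regions above background (Otsu threshold on the
#' mean-channel luminance, with a blank-image guard) and reports one spot
#' per region with its centroid and mean RGB. Detection is provided for
#' synthetic renders and convenience; manually counted surveys can be
#' imported with [read_eyeshine_counts()] instead. Spots rendered by
#' [render_eyeshine()] never overlap, so no local-maxima splitting is
#' applied.
#'
#' @param image An `eyeshine_image` or a plain `H x W x 3` 8-bit array.
#' @param min_area Minimum spot area in pixels (suppresses noise specks).
#' @param min_contrast Blank-image guard in 8-bit units.
#' @return Data frame with one row per spot: `spot`, `centroid_row`,
#'   `centroid_col`, `area_px`, `r`, `g`, `b` (mean channel intensities).
#'   A dark image yields zero rows.
#' @export
detect_spots <- function(image, min_area = 4, min_contrast = 30) {
  img <- if (inherits(image, "eyeshine_image")) image$rgb else image
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("expected an RGB raster")
  }
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  t <- otsu_threshold(round(lum))
  mask <- lum > t
  none <- data.frame(spot = integer(), centroid_row = numeric(),
                     centroid_col = numeric(), area_px = integer(),
                     r = numeric(), g = numeric(), b = numeric())
  if (!any(mask)) return(none)
  if (any(!mask) && (mean(lum[mask]) - mean(lum[!mask])) < min_contrast) {
    return(none)
  }
  lab <- label_components(mask)
  K <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = K)
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(none)
  H <- nrow(mask)
  fg <- which(lab > 0L)
  lv <- lab[fg]
  sel <- lv %in% keep
  fg <- fg[sel]; lv <- lv[sel]
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  ch_mean <- function(ch) as.numeric(tapply(img[fg + (ch - 1L) * length(mask)],
                                            lv, mean))
  data.frame(spot = seq_along(keep),
             centroid_row = as.numeric(tapply(rows, lv, mean)),
             centroid_col = as.numeric(tapply(cols, lv, mean)),
             area_px = as.integer(tapply(fg, lv, length)),
             r = ch_mean(1L), g = ch_mean(2L), b = ch_mean(3L))
}

#' Classify eyeshine spot color
#'
#' A spot is called red when its red chromaticity `R / (R + G)` is at least
#' `tau`, otherwise yellow. The call is invariant to overall brightness
#' scaling. Spots with `R + G = 0` are unclassifiable and return `NA`.
#'
#' @param spots Data frame with `r` and `g` columns (e.g. from
#'   [detect_spots()]), or a numeric length-3 RGB vector.
#' @param tau Red-chromaticity threshold.
#' @return Character vector of `"red"` / `"yellow"` calls (`NA` where
#'   unclassifiable).
#' @export
classify_spot_color <- function(spots, tau = 0.60) {
  if (is.numeric(spots) && length(spots) == 3L) {
    spots <- data.frame(r = spots[1], g = spots[2], b = spots[3])
  }
  denom <- spots$r + spots$g
  ratio <- ifelse(denom > 0, spots$r / denom, NA_real_)
  ifelse(is.na(ratio), NA_character_, ifelse(ratio >= tau, "red", "yellow"))
}

#' Assemble an eyeshine survey from per-image counts
#'
#' An eyeshine survey is the ordered series of red/yellow ommatidium counts
#' along the dorsoventral axis of one eye (index 0 = most dorsal image).
#' Repeatability duplicates — images counted twice — are flagged through
#' `is_duplicate_of` (the `image_index` of the original) and are excluded
#' from regional summaries.
#'
#' @param counts Data frame with columns `image_index`, `n_red`,
#'   `n_yellow`, and optionally `is_duplicate_of` (`NA` for originals).
#' @param individual Identifier carried through summaries.
#' @return A data frame of class `eyeshine_survey`.
#' @export
eyeshine_survey <- function(counts, individual = "individual") {
  req <- c("image_index", "n_red", "n_yellow")
  if (!all(req %in% names(counts))) {
    stop("counts needs columns image_index, n_red, n_yellow")
  }
  if (is.null(counts$is_duplicate_of)) counts$is_duplicate_of <- NA_integer_
  orig <- counts[is.na(counts$is_duplicate_of), ]
  if (anyDuplicated(orig$image_index)) {
    stop("image_index must be unique among non-duplicate images")
  }
  if (any(counts$n_red < 0 | counts$n_yellow < 0)) stop("counts must be >= 0")
  out <- counts[order(!is.na(counts$is_duplicate_of), counts$image_index), ]
  rownames(out) <- NULL
  attr(out, "individual") <- individual
  class(out) <- c("eyeshine_survey", "data.frame")
  out
}

#' @rdname eyeshine_survey
#' @param path CSV file with the columns of `counts`.
#' @export
read_eyeshine_counts <- function(path, individual = basename(path)) {
  eyeshine_survey(utils::read.csv(path, stringsAsFactors = FALSE), individual)
}

#' Build a survey by detecting and classifying spots in rendered images
#'
#' @param images List of `eyeshine_image` objects (from [render_eyeshine()]
#'   or read from files), in dv order.
#' @param tau Red-chromaticity threshold for [classify_spot_color()].
#' @param individual Identifier carried through summaries.
#' @inheritParams detect_spots
#' @return An [eyeshine_survey()].
#' @export
survey_from_images <- function(images, tau = 0.60, individual = "individual",
                               min_area = 4) {
  counts <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    dv <- if (inherits(img, "eyeshine_image")) img$dv_index else i - 1L
    sp <- detect_spots(img, min_area = min_area)
    call <- classify_spot_color(sp, tau = tau)
    data.frame(image_index = dv,
               n_red = sum(call == "red", na.rm = TRUE),
               n_yellow = sum(call == "yellow", na.rm = TRUE),
               is_duplicate_of = NA_integer_)
  })
  eyeshine_survey(do.call(rbind, counts), individual)
}

#' Regional yellow-eyeshine proportions of a survey
#'
#' Pools the two most dorsal images into the dorsal summary and the ventral
#' half of the series (the last `ceiling(n / 2)` images) into the ventral
#' summary; duplicates are excluded. Fractions are
#' `yellow / (yellow + red)` over the pooled counts.
#'
#' @param survey An [eyeshine_survey()] with at least 4 original images.
#' @return List with `dorsal_yellow`, `ventral_yellow` (fractions) and the
#'   pooled `counts` table.
#' @export
regional_proportions <- function(survey) {
  stopifnot(inherits(survey, "eyeshine_survey"))
  orig <- survey[is.na(survey$is_duplicate_of), ]
  orig <- orig[order(orig$image_index), ]
  n <- nrow(orig)
  if (n < 4L) stop("regional summaries need at least 4 images in dv order")
  dorsal <- orig[1:2, ]
  ventral <- orig[(n - ceiling(n / 2) + 1L):n, ]
  frac <- function(d) sum(d$n_yellow) / (sum(d$n_yellow) + sum(d$n_red))
  counts <- data.frame(
    region = c("dorsal", "ventral"),
    n_images = c(2L, ceiling(n / 2)),
    n_yellow = c(sum(dorsal$n_yellow), sum(ventral$n_yellow)),
    n_red = c(sum(dorsal$n_red), sum(ventral$n_red)))
  counts$yellow_fraction <- counts$n_yellow / (counts$n_yellow + counts$n_red)
  list(dorsal_yellow = frac(dorsal), ventral_yellow = frac(ventral),
       counts = counts, individual = attr(survey, "individual"))
}

#' Repeatability report from duplicated images
#'
#' For each image counted twice, reports the absolute difference in the
#' yellow proportion (percentage points) and the relative difference in the
#' total ommatidium count (percent of the original total).
#'
#' @param survey An [eyeshine_survey()] with duplicates flagged via
#'   `is_duplicate_of`.
#' @return Data frame with one row per duplicated image:`image_index`,
#'   `prop_diff_pct`, `count_diff_pct`; zero rows when nothing was
#'   duplicated.
#' @export
repeatability_check <- function(survey) {
  stopifnot(inherits(survey, "eyeshine_survey"))
  dup <- survey[!is.na(survey$is_duplicate_of), ]
  if (nrow(dup) == 0L) {
    return(data.frame(image_index = integer(), prop_diff_pct = numeric(),
                      count_diff_pct = numeric()))
  }
  orig <- survey[is.na(survey$is_duplicate_of), ]
  out <- lapply(seq_len(nrow(dup)), function(i) {
    o <- orig[orig$image_index == dup$is_duplicate_of[i], ]
    if (nrow(o) != 1L) {
      stop(sprintf("duplicate refers to unknown image %s",
                   dup$is_duplicate_of[i]))
    }
    p1 <- o$n_yellow / (o$n_yellow + o$n_red)
    p2 <- dup$n_yellow[i] / (dup$n_yellow[i] + dup$n_red[i])
    t1 <- o$n_yellow + o$n_red
    t2 <- dup$n_yellow[i] + dup$n_red[i]
    data.frame(image_index = o$image_index,
               prop_diff_pct = 100 * abs(p1 - p2),
               count_diff_pct = 100 * abs(t1 - t2) / t1)
  })
  do.call(rbind, out)
}
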