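#' Ommatidial class proportions
#'
#' Container for counts and proportions of the three ommatidial classes
#' (UV-UV, B-B, UV-B) in one eye region or section. Components positive in
#' no channel are carried as `n_unclassified` and excluded from the
#' proportions; their count doubles as a tiling-quality metric.
#'
#' @param n_uvuv,n_bb,n_uvb Class counts.
#' @param n_unclassified Count of segmented components positive in no
#'   channel.
#' @return An object of class `class_proportions` with elements `counts`,
#'   `fractions` (summing to 1 over classified ommatidia), `n_total` and
#'   `n_unclassified`.
#' @export
class_proportions <- function(n_uvuv, n_bb, n_uvb, n_unclassified = 0) {
  counts <- c("UV-UV" = as.integer(n_uvuv), "B-B" = as.integer(n_bb),
              "UV-B" = as.integer(n_uvb))
  if (any(counts < 0) || n_unclassified < 0) stop("counts must be >= 0")
  n_total <- sum(counts)
  fractions <- if (n_total > 0) counts / n_total else counts * NA_real_
  structure(list(counts = counts, fractions = fractions,
                 n_total = n_total,
                 n_unclassified = as.integer(n_unclassified)),
            class = "class_proportions")
}

#' @export
print.class_proportions <- function(x, ...) {
  cat(sprintf("Ommatidial classes (n = %d classified, %d unclassified)\n",
              x$n_total, x$n_unclassified))
  for (k in names(x$counts)) {
    cat(sprintf("  %-5s %4d  (%.3f)\n", k, x$counts[k], x$fractions[k]))
  }
  cat(sprintf("  blue-photoreceptor proportion: %.3f\n", blue_fraction(x)))
  invisible(x)
}

#' Blue-photoreceptor proportion of a class distribution
#'
#' Cell-level proportion of blue photoreceptors among R1/R2 cells:
#' `(2 * n_BB + n_UVB) / (2 * n_total)`. B-B ommatidia contribute two blue
#' cells, UV-B one, UV-UV none.
#'
#' @param x A [class_proportions()] object.
#' @return Fraction in \[0, 1\].
#' @export
blue_fraction <- function(x) {
  stopifnot(inherits(x, "class_proportions"))
  if (x$n_total == 0) return(NA_real_)
  (2 * x$counts[["B-B"]] + x$counts[["UV-B"]]) / (2 * x$n_total)
}

# Otsu threshold on an 8-bit intensity array: the cut t (pixels > t are
# foreground) maximizing between-class variance; lowest t on ties.
otsu_threshold <- function(x) {
  h <- as.numeric(tabulate(as.integer(x) + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[256]
  # candidate cuts t = 0..254: class 0 is <= t, class 1 is > t
  w0 <- w0[1:255]; m0 <- m0[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, 255)
  sb[valid] <- (mt * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * w1[valid] / n)
  if (!any(is.finite(sb))) return(lev[which.max(h)])  # constant image
  which.max(sb) - 1L
}

#' Binarize the channels of an IHC section
#'
#' Produces one binary mask per antibody channel plus a merged mask (the
#' pixelwise OR of the three). The default method thresholds each channel
#' with Otsu's criterion on its 8-bit histogram; a channel whose foreground
#' and background mean intensities differ by less than `min_contrast` is
#' treated as blank (no genuine staining, only noise) and gets an empty
#' mask. Fixed per-channel thresholds can be supplied instead.
#'
#' @param section An `ihc_section` from [render_ihc_section()], or a plain
#'   `H x W x 3` numeric array with 8-bit values.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param thresholds Numeric length-3 vector of per-channel thresholds
#'   (pixels strictly above are foreground); required for
#'   `method = "fixed"`.
#' @param min_contrast Blank-channel guard for the Otsu method, in 8-bit
#'   intensity units.
#' @return An object of class `channel_masks`: logical matrices `uv1`,
#'   `uv2`, `b`, `merged`, plus the method and realized thresholds.
#' @export
binarize_channels <- function(section, method = c("otsu", "fixed"),
                              thresholds = NULL, min_contrast = 30) {
  method <- match.arg(method)
  img <- if (inherits(section, "ihc_section")) section$image else section
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("expected a 3-channel (UV1, UV2, B) raster")
  }
  used <- numeric(3)
  masks <- vector("list", 3)
  for (ch in 1:3) {
    v <- img[, , ch]
    if (method == "fixed") {
      if (is.null(thresholds) || length(thresholds) != 3L) {
        stop("method = 'fixed' requires three thresholds")
      }
      t <- thresholds[ch]
      m <- v > t
    } else {
      t <- otsu_threshold(v)
      m <- v > t
      if (any(m) && any(!m) &&
          (mean(v[m]) - mean(v[!m])) < min_contrast) {
        m[] <- FALSE  # blank channel: Otsu split plain noise
      }
    }
    used[ch] <- t
    masks[[ch]] <- m
  }
  structure(list(uv1 = masks[[1]], uv2 = masks[[2]], b = masks[[3]],
                 merged = masks[[1]] | masks[[2]] | masks[[3]],
                 binarization_method = method, threshold_params = used),
            class = "channel_masks")
}

#' Label connected components of a binary mask
#'
#' 8-connectivity components, computed on the pixel adjacency graph.
#' Labels are assigned in raster-scan order of each component's first
#' pixel (scanning row by row, left to right), so labelling is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered 1..K.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  vid <- matrix(0L, H, W)
  vid[fg] <- seq_along(fg)
  edges <- list()
  k <- 0L
  # neighbor offsets covering all 8-connected pairs once:
  # right, down, down-right, down-left
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r0 <- 1L:(H - dr)
    c0 <- if (dc >= 0L) 1L:(W - dc) else (1L - dc):W
    a <- mask[r0, c0, drop = FALSE] & mask[r0 + dr, c0 + dc, drop = FALSE]
    if (any(a)) {
      w <- which(a)
      rr <- ((w - 1L) %% length(r0)) + r0[1]
      cc <- ((w - 1L) %/% length(r0)) + c0[1]
      k <- k + 1L
      edges[[k]] <- cbind(vid[cbind(rr, cc)], vid[cbind(rr + dr, cc + dc)])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (k > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  memb <- igraph::components(g)$membership
  # deterministic relabel: order components by raster rank of first pixel
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  rank <- (rows - 1L) * W + cols
  first <- tapply(rank, memb, min)
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  lab[fg] <- relab[memb]
  lab
}

#' Segment ommatidia from a merged binary mask
#'
#' Re-implementation of area-filtered connected-component segmentation
#' (the `bwareafilt` step): 8-connected components of the merged mask whose
#' pixel area lies within `area_range` become candidate ommatidia. With
#' `area_range = NULL` the range defaults to `[0.3, 3] x` the median
#' component area, estimated in a first pass, which is scale-free across
#' magnifications.
#'
#' @param masks A [binarize_channels()] result.
#' @param area_range Length-2 numeric `(A_min, A_max)`, `A_min >= 1`.
#' @return An object of class `omm_segments`: a data frame with one row per
#'   retained component (`label`, `area_px`, `min_row`, `min_col`,
#'   `centroid_row`, `centroid_col`) and the pixel sets as attribute
#'   `"pixels"` (linear indices into the mask). Empty mask gives zero rows.
#' @export
segment_ommatidia <- function(masks, area_range = NULL) {
  stopifnot(inherits(masks, "channel_masks"))
  lab <- label_components(masks$merged)
  K <- max(lab)
  empty <- function(rng) {
    out <- data.frame(label = integer(), area_px = integer(),
                      min_row = integer(), min_col = integer(),
                      centroid_row = numeric(), centroid_col = numeric())
    attr(out, "pixels") <- list()
    attr(out, "mask_dim") <- dim(masks$merged)
    attr(out, "area_range") <- rng
    class(out) <- c("omm_segments", "data.frame")
    out
  }
  if (K == 0L) return(empty(area_range))
  areas <- tabulate(lab[lab > 0L], nbins = K)
  if (is.null(area_range)) {
    med <- stats::median(areas)
    area_range <- c(0.3 * med, 3 * med)
  }
  if (length(area_range) != 2L || area_range[1] < 1 ||
      area_range[2] < area_range[1]) {
    stop("area_range must be (A_min, A_max) with A_min >= 1, A_max >= A_min")
  }
  keep <- which(areas >= area_range[1] & areas <= area_range[2])
  if (length(keep) == 0L) return(empty(area_range))
  H <- nrow(masks$merged)
  fg <- which(lab > 0L)
  lv <- lab[fg]
  sel <- lv %in% keep
  fg <- fg[sel]; lv <- lv[sel]
  ord <- order(lv, fg)
  fg <- fg[ord]; lv <- lv[ord]
  pixels <- split(fg, lv)   # split by old label; names are sorted old labels
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  out <- data.frame(
    label = seq_along(pixels),   # old-label order == raster first-pixel order
    area_px = as.integer(lengths(pixels)),
    min_row = as.integer(tapply(rows, lv, min)),
    min_col = as.integer(tapply(cols, lv, min)),
    centroid_row = as.numeric(tapply(rows, lv, mean)),
    centroid_col = as.numeric(tapply(cols, lv, mean)))
  attr(out, "pixels") <- unname(pixels)
  attr(out, "mask_dim") <- dim(masks$merged)
  attr(out, "area_range") <- area_range
  class(out) <- c("omm_segments", "data.frame")
  out
}

#' Score channel fill fractions and classify segmented ommatidia
#'
#' For each segmented component, the fill fraction of a channel is the
#' share of the component's pixels that are foreground in that channel's
#' mask; the component is positive in the channel when the fill fraction is
#' at least `fill_threshold` (inclusive, 4% by default). A component
#' positive in UV1 or UV2 counts as UV-positive. Calls: UV-positive only
#' gives UV-UV, B-positive only gives B-B, both give UV-B, neither is
#' unclassified (reported, excluded from proportions).
#'
#' @param segments An [segment_ommatidia()] result.
#' @param masks The [binarize_channels()] result the segments came from.
#' @param fill_threshold Inclusive positivity threshold on fill fraction.
#' @return A [class_proportions()] object; the per-segment table (fill
#'   fractions, positivity, call) is attached as attribute `"segments"`.
#' @export
score_and_classify <- function(segments, masks, fill_threshold = 0.04) {
  stopifnot(inherits(segments, "omm_segments"), inherits(masks, "channel_masks"))
  if (!identical(attr(segments, "mask_dim"), dim(masks$merged))) {
    stop("segments and masks have different raster shapes")
  }
  pixels <- attr(segments, "pixels")
  n <- nrow(segments)
  fill <- matrix(0, n, 3, dimnames = list(NULL, c("uv1", "uv2", "b")))
  for (i in seq_len(n)) {
    px <- pixels[[i]]
    fill[i, ] <- c(sum(masks$uv1[px]), sum(masks$uv2[px]),
                   sum(masks$b[px])) / length(px)
  }
  pos <- fill >= fill_threshold
  uv_pos <- pos[, "uv1"] | pos[, "uv2"]
  b_pos <- pos[, "b"]
  call <- rep("unclassified", n)
  call[uv_pos & !b_pos] <- "UV-UV"
  call[!uv_pos & b_pos] <- "B-B"
  call[uv_pos & b_pos] <- "UV-B"
  out <- class_proportions(sum(call == "UV-UV"), sum(call == "B-B"),
                           sum(call == "UV-B"),
                           n_unclassified = sum(call == "unclassified"))
  seg_table <- cbind(as.data.frame(segments),
                     fill_uv1 = fill[, 1], fill_uv2 = fill[, 2],
                     fill_b = fill[, 3],
                     pos_uv1 = pos[, 1], pos_uv2 = pos[, 2], pos_b = pos[, 3],
                     call = call)
  attr(out, "segments") <- seg_table
  out
}

#' Cross-section consistency check for one individual
#'
#' The automated counts are run on 2-4 consecutive sections of the same
#' eye. Class proportions are averaged (unweighted) across sections, and
#' the individual is excluded when the blue-photoreceptor proportion
#' differs by more than `tol` (5 percentage points by default, strict)
#' between any two sections.
#'
#' @param series List of 2-4 [class_proportions()] (one per section).
#' @param tol Exclusion threshold on the max pairwise difference of the
#'   blue-photoreceptor proportion.
#' @param individual Optional label used in error messages.
#' @return An object of class `section_series`: per-section blue
#'   proportions, `consistency_delta`, `status` (`"kept"`/`"excluded"`) and
#'   the mean class proportions.
#' @export
section_consistency <- function(series, tol = 0.05, individual = "individual") {
  if (length(series) < 2L) {
    stop(sprintf("%s has fewer than 2 sections; cannot check consistency",
                 individual))
  }
  if (length(series) > 4L) {
    stop(sprintf("%s has more than 4 sections", individual))
  }
  stopifnot(all(vapply(series, inherits, logical(1), "class_proportions")))
  blues <- vapply(series, blue_fraction, numeric(1))
  delta <- max(blues) - min(blues)
  # strict inequality; the 1e-12 guard keeps a hand-computed difference of
  # exactly tol from being excluded through floating-point representation
  status <- if (delta > tol + 1e-12) "excluded" else "kept"
  mean_fr <- colMeans(do.call(rbind, lapply(series, `[[`, "fractions")))
  structure(list(blue_fractions = blues, consistency_delta = delta,
                 status = status, mean_fractions = mean_fr,
                 sections = series, individual = individual),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("Section series (%s): %d sections, status %s\n",
              x$individual, length(x$sections), x$status))
  cat(sprintf("  blue proportions: %s (max pairwise diff %.3f)\n",
              paste(sprintf("%.3f", x$blue_fractions), collapse = ", "),
              x$consistency_delta))
  cat(sprintf("  mean proportions (UV-UV, B-B, UV-B): %s\n",
              paste(sprintf("%.3f", x$mean_fractions), collapse = ", ")))
  invisible(x)
}

#' Automated vs. manual count agreement
#'
#' Absolute difference in the blue-photoreceptor proportion between an
#' automated and a manual classification of the same eye, as a fraction.
#' Symmetric in its arguments.
#'
#' @param auto,manual [class_proportions()] objects.
#' @return `|p_blue_auto - p_blue_manual|`.
#' @export
compare_manual <- function(auto, manual) {
  abs(blue_fraction(auto) - blue_fraction(manual))
}
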