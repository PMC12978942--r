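# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code.

# Flood-fill connected-component labelling (8-connectivity). Scans pixels
# in raster order (row by row, left to right) and grows each new component
# by breadth-first waves, so labels are numbered by first raster pixel.
flood_fill_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextlab <- 0L
  # raster order = row-major; matrices are column-major, so order explicitly
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  scan <- order((rr - 1L) * W + cc)
  for (s in scan) {
    i <- rr[s]; j <- cc[s]
    if (!mask[i, j] || lab[i, j] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- (j - 1L) * H + i
    lab[frontier] <- nextlab
    while (length(frontier) > 0L) {
      fi <- ((frontier - 1L) %% H) + 1L
      fj <- ((frontier - 1L) %/% H) + 1L
      ni <- c(fi - 1L, fi - 1L, fi - 1L, fi, fi, fi + 1L, fi + 1L, fi + 1L)
      nj <- c(fj - 1L, fj, fj + 1L, fj - 1L, fj + 1L, fj - 1L, fj, fj + 1L)
      ok <- ni >= 1L & ni <= H & nj >= 1L & nj <= W
      lin <- unique((nj[ok] - 1L) * H + ni[ok])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nextlab
      frontier <- lin
    }
  }
  lab
}

# area filter + partition extraction on a label matrix: list of sorted
# pixel-index vectors, ordered by component label
label_partition <- function(lab, area_range) {
  K <- max(lab)
  if (K == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = K)
  keep <- which(areas >= area_range[1] & areas <= area_range[2])
  out <- lapply(keep, function(k) sort(which(lab == k)))
  out
}

# Holm-Bonferroni by direct sequential rejection: sort ascending, reject
# while p_(i) <= alpha / (m - i + 1), stop at the first failure.
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

# O(n^3) UPGMA: inter-cluster distance recomputed each step as the mean of
# all cross-pair distances from the original distance matrix.
upgma_oracle <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < bestd) { bestd <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# random binary mask
random_mask <- function(h, w, density) {
  matrix(stats::runif(h * w) < density, h, w)
}

# channel_masks object with a given merged-driving mask in the UV1 channel
# and optional extra channel masks (built through the public binarizer)
masks_from_logical <- function(uv1, uv2 = NULL, b = NULL) {
  H <- nrow(uv1); W <- ncol(uv1)
  zero <- matrix(0, H, W)
  arr <- array(0, dim = c(H, W, 3))
  arr[, , 1] <- uv1 * 255
  if (!is.null(uv2)) arr[, , 2] <- uv2 * 255
  if (!is.null(b)) arr[, , 3] <- b * 255
  binarize_channels(arr, method = "fixed", thresholds = c(0, 0, 0))
}

# omm_spectra object built directly from a reflectance matrix
spectra_object <- function(refl, color_call = NULL, region = NULL) {
  structure(list(reflectance = refl,
                 wavelengths = seq(500, 800, by = 10),
                 id = as.character(seq_len(nrow(refl))),
                 color_call = color_call, region = region,
                 qc_status = rep("kept", nrow(refl))),
            class = "omm_spectra")
}

# class_proportions with a prescribed blue-photoreceptor proportion
# (uses only B-B vs UV-UV ommatidia: blue = n_bb / n_total)
props_with_blue <- function(blue, n_total = 1000) {
  n_bb <- round(blue * n_total)
  class_proportions(n_total - n_bb, n_bb, 0)
}
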