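#' Shutter time delivering a target photon flux
#'
#' Monochromatic eyeshine images are exposed so that every wavelength
#' delivers the same photon flux (1e15 photons by default, the dose that
#' fills the camera's 8-bit dynamic range); the shutter time at a
#' wavelength is simply `target / flux_rate`.
#'
#' @param flux_rate Photon flux rate(s), photons per second; must be > 0.
#' @param target Target photon dose per exposure, photons.
#' @return Shutter time(s) in seconds.
#' @examples
#' shutter_time_for_flux(2.0e14)  # 5 s
#' @export
shutter_time_for_flux <- function(flux_rate, target = 1.0e15) {
  if (any(!is.finite(flux_rate)) || any(flux_rate <= 0)) {
    stop("flux_rate must be positive")
  }
  target / flux_rate
}

#' Constant-flux shutter calibration table
#'
#' @param rates Data frame with columns `wavelength` (nm) and `flux_rate`
#'   (photons/s).
#' @param target Target photon dose per exposure.
#' @return Object of class `flux_calibration`: the input table plus the
#'   `shutter_time` column (seconds).
#' @export
flux_calibration <- function(rates, target = 1.0e15) {
  if (!all(c("wavelength", "flux_rate") %in% names(rates))) {
    stop("rates needs columns wavelength and flux_rate")
  }
  rates$shutter_time <- shutter_time_for_flux(rates$flux_rate, target)
  attr(rates, "target_flux") <- target
  class(rates) <- c("flux_calibration", "data.frame")
  rates
}

#' Extract per-ommatidium spectra from a reflectance stack
#'
#' The reflectance of an ommatidium at each wavelength is the mean pixel
#' intensity over its ROI in that plane. Spectra are quality-controlled on
#' the 8-bit dynamic range: a spectrum whose maximum is below 50% of the
#' range is `excluded_low`, above 95% `excluded_saturated`, otherwise
#' `kept`. Excluded spectra are retained but flagged.
#'
#' @param stack A `reflectance_stack` (or a plain `H x W x 31` array).
#' @param rois Named list of 2-column (`row`, `col`) pixel matrices, one
#'   per ommatidium (see [stack_rois()]).
#' @param color_call Optional per-ommatidium `"red"`/`"yellow"` labels from
#'   the reference photo.
#' @param region Optional per-ommatidium region labels
#'   (`"dorsal"`/`"middle"`/`"ventral"`).
#' @param low_frac,saturated_frac QC bounds as fractions of the 8-bit
#'   range.
#' @return Object of class `omm_spectra`: list with `reflectance`
#'   (`n x 31` matrix of ROI means, 8-bit units), `wavelengths`, `id`,
#'   `color_call`, `region`, `qc_status`.
#' @export
extract_spectra <- function(stack, rois, color_call = NULL, region = NULL,
                            low_frac = 0.50, saturated_frac = 0.95) {
  planes <- if (inherits(stack, "reflectance_stack")) stack$planes else stack
  wl <- if (inherits(stack, "reflectance_stack")) stack$wavelengths
        else seq(500, 800, by = 10)
  if (length(dim(planes)) != 3L || dim(planes)[3] != length(wl)) {
    stop(sprintf("stack must have %d wavelength planes", length(wl)))
  }
  H <- dim(planes)[1]; W <- dim(planes)[2]
  ids <- if (is.null(names(rois))) as.character(seq_along(rois)) else names(rois)
  n <- length(rois)
  refl <- matrix(NA_real_, n, length(wl))
  for (i in seq_len(n)) {
    px <- rois[[i]]
    if (is.null(px) || nrow(px) == 0L) {
      stop(sprintf("empty ROI for ommatidium %s", ids[i]))
    }
    if (any(px[, 1] < 1 | px[, 1] > H | px[, 2] < 1 | px[, 2] > W)) {
      stop(sprintf("ROI for ommatidium %s falls outside the stack", ids[i]))
    }
    lin <- (px[, 2] - 1L) * H + px[, 1]
    for (p in seq_along(wl)) {
      refl[i, p] <- mean(planes[lin + (p - 1L) * H * W])
    }
  }
  mx <- apply(refl, 1, max)
  qc <- ifelse(mx < low_frac * 255, "excluded_low",
               ifelse(mx > saturated_frac * 255, "excluded_saturated", "kept"))
  structure(list(reflectance = refl, wavelengths = wl, id = ids,
                 color_call = color_call, region = region, qc_status = qc),
            class = "omm_spectra")
}

#' @export
print.omm_spectra <- function(x, ...) {
  cat(sprintf("Ommatidium spectra: %d ommatidia x %d wavelengths (%d-%d nm)\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat("  QC: ", paste(sprintf("%s %d", names(table(x$qc_status)),
                              table(x$qc_status)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-wavelength group comparison of eyeshine spectra
#'
#' Compares kept spectra between groups at every wavelength and controls
#' the familywise error over the 31 wavelengths with Holm-Bonferroni.
#' `design = "two_group"` runs a two-sample t-test (Welch by default)
#' between red and yellow ommatidia; `design = "three_region"` runs a
#' one-way ANOVA across the dorsal, middle and ventral regions.
#'
#' @param spectra An [extract_spectra()] result carrying `color_call`
#'   (two-group) or `region` (three-region) labels.
#' @param design `"two_group"` or `"three_region"`.
#' @param alpha Familywise significance level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Object of class `spectral_comparison`: a data frame with one row
#'   per wavelength (group means, SEMs, raw `p`, Holm-adjusted `p_adj`,
#'   `significant`), with the design and alpha as attributes.
#' @export
compare_spectra <- function(spectra, design = c("two_group", "three_region"),
                            alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(spectra, "omm_spectra"))
  design <- match.arg(design)
  keep <- spectra$qc_status == "kept"
  g <- if (design == "two_group") spectra$color_call else spectra$region
  if (is.null(g)) {
    stop(sprintf("spectra carry no %s labels",
                 if (design == "two_group") "color_call" else "region"))
  }
  g <- factor(g[keep])
  x <- spectra$reflectance[keep, , drop = FALSE]
  if (design == "two_group" && nlevels(g) != 2L) {
    stop("two_group design needs exactly 2 groups")
  }
  if (design == "three_region" && nlevels(g) != 3L) {
    stop("three_region design needs dorsal, middle and ventral spectra")
  }
  cnt <- table(g)
  if (any(cnt < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 kept spectra",
                 names(cnt)[which.min(cnt)]))
  }
  wl <- spectra$wavelengths
  m <- length(wl)
  pvals <- numeric(m)
  means <- matrix(NA_real_, m, nlevels(g))
  sems <- matrix(NA_real_, m, nlevels(g))
  colnames(means) <- paste0("mean_", levels(g))
  colnames(sems) <- paste0("sem_", levels(g))
  for (p in seq_len(m)) {
    v <- x[, p]
    means[p, ] <- tapply(v, g, mean)
    sems[p, ] <- tapply(v, g, function(z) stats::sd(z) / sqrt(length(z)))
    if (design == "two_group") {
      pvals[p] <- stats::t.test(v ~ g, var.equal = var_equal)$p.value
    } else {
      pvals[p] <- stats::anova(stats::lm(v ~ g))[["Pr(>F)"]][1]
    }
  }
  p_adj <- stats::p.adjust(pvals, method = "holm")
  out <- data.frame(wavelength = wl, means, sems, p = pvals, p_adj = p_adj,
                    significant = p_adj <= alpha)
  attr(out, "design") <- design
  attr(out, "alpha") <- alpha
  class(out) <- c("spectral_comparison", "data.frame")
  out
}

#' Peak reflectance excess of yellow over red ommatidia
#'
#' Mean peak (maximum over wavelengths) of kept yellow spectra relative to
#' kept red spectra, reported as `(yellow - red) / red` in percent. The red
#' peak is the denominator.
#'
#' @param spectra An [extract_spectra()] result with `color_call` labels.
#' @return Percent excess of the mean yellow peak over the mean red peak.
#' @export
peak_excess_pct <- function(spectra) {
  stopifnot(inherits(spectra, "omm_spectra"))
  keep <- spectra$qc_status == "kept"
  peaks <- apply(spectra$reflectance[keep, , drop = FALSE], 1, max)
  cc <- spectra$color_call[keep]
  100 * (mean(peaks[cc == "yellow"]) - mean(peaks[cc == "red"])) /
    mean(peaks[cc == "red"])
}
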