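#' Specify a synthetic retinal mosaic
#'
#' A `mosaic_spec` fixes everything needed to draw a ground-truth retinal
#' mosaic: the lattice size, the ommatidial class proportions at the two
#' poles of the dorsoventral (dv) axis, the probability that a blue (B)
#' photoreceptor co-expresses the long-wavelength (LW) opsin, and the UV
#' opsin expression regime.
#'
#' Ommatidia fall into three classes defined by the opsins of the R1 and R2
#' photoreceptors: UV-UV, B-B and UV-B. Class proportions are interpolated
#' linearly along the dv axis between `props_dorsal` (at `dv_position = 0`,
#' the dorsal pole) and `props_ventral` (at `dv_position = 1`). Each B cell
#' independently co-expresses LW with probability `p_coexpress`
#' (interpolated between `p_coexpress_dorsal` and `p_coexpress` the same
#' way); an ommatidium carries red screening pigment if and only if at
#' least one of its R1/R2 cells is LW-positive, otherwise its eyeshine is
#' yellow.
#'
#' @param n_rows,n_cols Lattice dimensions (rows run dorsal to ventral).
#' @param props_ventral,props_dorsal Length-3 proportions
#'   `(UV-UV, B-B, UV-B)`; each must sum to 1. `props_dorsal` defaults to
#'   `props_ventral` (no gradient).
#' @param p_coexpress Probability in \[0, 1\] that a single B cell
#'   co-expresses LW at the ventral pole.
#' @param p_coexpress_dorsal Same probability at the dorsal pole; defaults
#'   to `p_coexpress`.
#' @param uv_mode UV opsin regime: `"UV1_only"`, `"UV2_only"`, or
#'   `"coexpress"` (both UV opsins in the same cell, UV2 scaled by
#'   `uv_mix` at render time).
#' @param uv_mix Mixing weight in \[0, 1\] for the secondary UV channel
#'   under `uv_mode = "coexpress"`.
#' @param gradient Dorsoventral interpolation of proportions; only
#'   `"linear"` is implemented.
#' @param seed Optional integer seed making the mosaic reproducible.
#'
#' @return An object of class `mosaic_spec`.
#' @seealso [generate_mosaic()]
#' @export
mosaic_spec <- function(n_rows, n_cols,
                        props_ventral,
                        props_dorsal = props_ventral,
                        p_coexpress = 0.5,
                        p_coexpress_dorsal = p_coexpress,
                        uv_mode = c("UV1_only", "UV2_only", "coexpress"),
                        uv_mix = 1,
                        gradient = "linear",
                        seed = NULL) {
  uv_mode <- match.arg(uv_mode)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be >= 1")
  }
  check_props <- function(p, what) {
    if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop(sprintf("%s must be three fractions in [0, 1]", what))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("%s (%s) must sum to 1", what,
                   paste(format(p), collapse = ", ")))
    }
    p <- as.numeric(p)
    names(p) <- c("UV-UV", "B-B", "UV-B")
    p
  }
  props_ventral <- check_props(props_ventral, "props_ventral")
  props_dorsal <- check_props(props_dorsal, "props_dorsal")
  for (p in c(p_coexpress, p_coexpress_dorsal, uv_mix)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("p_coexpress, p_coexpress_dorsal and uv_mix must lie in [0, 1]")
    }
  }
  if (!identical(gradient, "linear")) {
    stop("only gradient = 'linear' is implemented")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         props_ventral = props_ventral, props_dorsal = props_dorsal,
         p_coexpress = p_coexpress, p_coexpress_dorsal = p_coexpress_dorsal,
         uv_mode = uv_mode, uv_mix = uv_mix,
         gradient = gradient, seed = seed),
    class = "mosaic_spec"
  )
}

#' @export
print.mosaic_spec <- function(x, ...) {
  cat(sprintf("Retinal mosaic spec: %d x %d hexagonal lattice\n",
              x$n_rows, x$n_cols))
  cat(sprintf("  ventral proportions (UV-UV, B-B, UV-B): %s\n",
              paste(format(x$props_ventral), collapse = ", ")))
  cat(sprintf("  dorsal  proportions (UV-UV, B-B, UV-B): %s\n",
              paste(format(x$props_dorsal), collapse = ", ")))
  cat(sprintf("  LW co-expression p: ventral %.3f, dorsal %.3f\n",
              x$p_coexpress, x$p_coexpress_dorsal))
  cat(sprintf("  UV regime: %s (mix %.2f)\n", x$uv_mode, x$uv_mix))
  invisible(x)
}

#' Generate a ground-truth retinal mosaic
#'
#' Draws one ommatidium per lattice site. The class of each ommatidium is
#' sampled from the dv-interpolated class proportions; each B photoreceptor
#' is then independently LW-positive with the dv-interpolated co-expression
#' probability, and the screening pigment is red if and only if at least
#' one R1/R2 cell is LW-positive. The expected yellow-eyeshine fraction at
#' a given dv position is therefore
#' `UVUV + (1 - p)^2 * BB + (1 - p) * UVB`.
#'
#' @param spec A [mosaic_spec()].
#' @return A data frame of class `retina_mosaic` with one row per
#'   ommatidium and columns `id`, `row`, `col`, `dv_position`, `omm_class`,
#'   `r1_opsin`, `r2_opsin`, `r1_lw`, `r2_lw`, `pigment`. The generating
#'   spec is attached as attribute `"spec"`.
#' @examples
#' m <- generate_mosaic(mosaic_spec(20, 20, c(0.1, 0.5, 0.4),
#'                                  p_coexpress = 0.25, seed = 1))
#' mean(m$pigment == "yellow")
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  draw <- function() {
    n <- spec$n_rows * spec$n_cols
    row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
    col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
    dv <- if (spec$n_rows == 1L) rep(0, n) else (row - 1) / (spec$n_rows - 1)

    # dv-interpolated class proportions, one triple per ommatidium
    pm <- outer(1 - dv, spec$props_dorsal) + outer(dv, spec$props_ventral)
    u <- stats::runif(n)
    cls_idx <- 1L + (u >= pm[, 1L]) + (u >= pm[, 1L] + pm[, 2L])
    omm_class <- c("UV-UV", "B-B", "UV-B")[cls_idx]

    uv_label <- switch(spec$uv_mode,
                       UV2_only = "UV2",
                       "UV1")
    r1 <- ifelse(omm_class == "B-B", "B", uv_label)
    r2 <- ifelse(omm_class == "UV-UV", uv_label, "B")

    p_lw <- (1 - dv) * spec$p_coexpress_dorsal + dv * spec$p_coexpress
    r1_lw <- r1 == "B" & stats::runif(n) < p_lw
    r2_lw <- r2 == "B" & stats::runif(n) < p_lw
    pigment <- ifelse(r1_lw | r2_lw, "red", "yellow")

    data.frame(id = seq_len(n), row = row, col = col, dv_position = dv,
               omm_class = omm_class, r1_opsin = r1, r2_opsin = r2,
               r1_lw = r1_lw, r2_lw = r2_lw, pigment = pigment,
               stringsAsFactors = FALSE)
  }
  out <- if (is.null(spec$seed)) draw() else withr::with_seed(spec$seed, draw())
  attr(out, "spec") <- spec
  class(out) <- c("retina_mosaic", "data.frame")
  out
}

#' @export
print.retina_mosaic <- function(x, ...) {
  cat(sprintf("Retinal mosaic: %d ommatidia\n", nrow(x)))
  tab <- table(factor(x$omm_class, levels = c("UV-UV", "B-B", "UV-B")))
  cat("  classes: ",
      paste(sprintf("%s %d (%.1f%%)", names(tab), tab, 100 * tab / nrow(x)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  pigment: %d red, %d yellow (yellow fraction %.3f)\n",
              sum(x$pigment == "red"), sum(x$pigment == "yellow"),
              mean(x$pigment == "yellow")))
  invisible(x)
}

#' Expected yellow-eyeshine fraction of a mosaic spec
#'
#' Closed-form expectation of the yellow fraction under the generative
#' model, averaged over the lattice rows (each row has its own
#' dv-interpolated class proportions and co-expression probability).
#'
#' @param spec A [mosaic_spec()].
#' @return Expected fraction of yellow ommatidia.
#' @export
expected_yellow_fraction <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  dv <- if (spec$n_rows == 1L) 0 else (seq_len(spec$n_rows) - 1) / (spec$n_rows - 1)
  pm <- outer(1 - dv, spec$props_dorsal) + outer(dv, spec$props_ventral)
  p <- (1 - dv) * spec$p_coexpress_dorsal + dv * spec$p_coexpress
  mean(pm[, 1L] + (1 - p)^2 * pm[, 2L] + (1 - p) * pm[, 3L])
}

#' Write / read mosaic ground truth as CSV
#'
#' One row per ommatidium with the full ground-truth annotation
#' (`id, row, col, dv_position, class, r1_opsin, r2_opsin, r1_lw, r2_lw,
#' pigment`).
#'
#' @param mosaic A `retina_mosaic`.
#' @param path File path.
#' @return `write_mosaic_csv()` returns `path` invisibly;
#'   `read_mosaic_csv()` returns a `retina_mosaic` data frame (without the
#'   generating spec attribute).
#' @export
write_mosaic_csv <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "retina_mosaic"))
  df <- as.data.frame(mosaic)
  names(df)[names(df) == "omm_class"] <- "class"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mosaic_csv
#' @export
read_mosaic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "class"] <- "omm_class"
  class(df) <- c("retina_mosaic", "data.frame")
  df
}
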