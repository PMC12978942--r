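#' Yellow-eyeshine fraction predicted from class proportions
#'
#' Forward model linking the ommatidial class proportions to the fraction
#' of yellow eyeshine. With `p` the probability that a single blue (B)
#' photoreceptor co-expresses the LW opsin, an ommatidium shows yellow
#' eyeshine when none of its B cells is LW-positive:
#'
#' `Yellow = UVUV + (1 - p)^2 * BB + (1 - p) * UVB`
#'
#' since `(1 - p)^2` is the probability that neither B cell of a B-B
#' ommatidium co-expresses and `(1 - p)` that the single B cell of a UV-B
#' ommatidium does not. UV-UV ommatidia have no B cell and are always
#' yellow. The prediction is strictly decreasing in `p` whenever
#' `BB + UVB > 0` and ranges from `UVUV` (at `p = 1`) to 1 (at `p = 0`).
#'
#' @param proportions Length-3 numeric `(UVUV, BB, UVB)` summing to 1, or a
#'   [class_proportions()] object.
#' @param p Co-expression probability (or vector of probabilities) in
#'   \[0, 1\].
#' @return Predicted yellow fraction(s).
#' @examples
#' predict_yellow(c(0.1, 0.5, 0.4), 0.25)  # 0.68125
#' @export
predict_yellow <- function(proportions, p) {
  pr <- as_proportions(proportions)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  q <- 1 - p
  unname(pr[1] + q^2 * pr[2] + q * pr[3])
}

# normalize a proportions argument to a checked numeric triple
as_proportions <- function(proportions, tol = 1e-6) {
  pr <- if (inherits(proportions, "class_proportions")) {
    as.numeric(proportions$fractions)
  } else {
    as.numeric(proportions)
  }
  if (length(pr) != 3L || any(!is.finite(pr)) || any(pr < 0)) {
    stop("proportions must be three non-negative fractions (UVUV, BB, UVB)")
  }
  if (abs(sum(pr) - 1) > tol) {
    stop(sprintf("proportions (%s) must sum to 1",
                 paste(format(pr), collapse = ", ")))
  }
  names(pr) <- c("UVUV", "BB", "UVB")
  pr
}

#' Fit the blue-cell LW co-expression probability
#'
#' Inverts the forward model of [predict_yellow()] by least squares: given
#' an observed yellow-eyeshine fraction and the ommatidial class
#' proportions of the same eye region, estimates the probability `p` that a
#' blue photoreceptor co-expresses the LW opsin. Substituting `q = 1 - p`
#' the model is the quadratic `BB q^2 + UVB q + (UVUV - Y) = 0`, solved in
#' closed form with the root in \[0, 1\] (the prediction is strictly
#' monotone in `q`, so at most one root can lie there; in the degenerate
#' case of two admissible roots the one closer to 0.5 is taken and the fit
#' is flagged ambiguous). When no root is admissible — the observation
#' falls outside the attainable range `[UVUV, 1]` — the boundary value of
#' `p` minimizing the squared error is returned and the fit is flagged
#' infeasible. When `BB = UVB = 0` the model is constant and `p` is
#' unidentifiable; `p_hat` is `NA` and the fit is feasible only if the
#' observation equals `UVUV`.
#'
#' @param yellow Observed yellow-eyeshine fraction in \[0, 1\].
#' @param proportions Length-3 `(UVUV, BB, UVB)` summing to 1 (within
#'   1e-6), or a [class_proportions()] object.
#' @param method `"closed_form"` (default) or `"grid"` (minimizes the
#'   squared error over a uniform grid on p; used as a cross-check).
#' @param tolerance Feasibility tolerance on the squared residual.
#' @param grid_step Step of the grid search.
#' @return An object of class `coexpr_fit` with elements `p_hat`,
#'   `residual` (squared error at `p_hat`), `feasible`, `identifiable`,
#'   `ambiguous`, `method`, and the echoed inputs `yellow` and
#'   `proportions`. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `residuals()`, `plot()` and `simulate()`.
#' @examples
#' fit_coexpression(0.68125, c(0.1, 0.5, 0.4))  # p_hat = 0.25
#' @export
fit_coexpression <- function(yellow, proportions,
                             method = c("closed_form", "grid"),
                             tolerance = 1e-8, grid_step = 1e-6) {
  method <- match.arg(method)
  pr <- as_proportions(proportions)
  if (!is.finite(yellow) || yellow < 0 || yellow > 1) {
    stop("yellow must lie in [0, 1]")
  }
  uvuv <- pr[[1]]; bb <- pr[[2]]; uvb <- pr[[3]]
  sq_err <- function(q) (uvuv + q^2 * bb + q * uvb - yellow)^2

  identifiable <- (bb + uvb) > 0
  ambiguous <- FALSE
  if (!identifiable) {
    p_hat <- NA_real_
    residual <- sq_err(0)
  } else if (method == "grid") {
    qs <- seq(0, 1, by = grid_step)
    e <- sq_err(qs)
    q <- qs[which.min(e)]
    p_hat <- 1 - q
    residual <- min(e)
  } else {
    if (bb == 0) {
      q <- (yellow - uvuv) / uvb
      q <- min(1, max(0, q))
    } else {
      disc <- uvb^2 - 4 * bb * (uvuv - yellow)
      if (disc < 0) {
        roots <- numeric(0)
      } else {
        s <- sqrt(disc)
        roots <- c((-uvb + s) / (2 * bb), (-uvb - s) / (2 * bb))
        roots <- roots[roots >= -1e-12 & roots <= 1 + 1e-12]
        roots <- pmin(1, pmax(0, roots))
      }
      if (length(roots) == 0L) {
        # observation outside [UVUV, 1]: pick the better boundary
        q <- if (sq_err(0) <= sq_err(1)) 0 else 1
      } else if (length(unique(roots)) > 1L) {
        q <- roots[which.min(abs(roots - 0.5))]
        ambiguous <- TRUE
      } else {
        q <- roots[1]
      }
    }
    p_hat <- 1 - q
    residual <- sq_err(q)
  }
  structure(
    list(p_hat = unname(p_hat), residual = unname(residual),
         feasible = unname(residual <= tolerance),
         identifiable = identifiable, ambiguous = ambiguous,
         method = method, tolerance = tolerance,
         yellow = yellow, proportions = pr),
    class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, digits = 4, ...) {
  cat("Blue-cell LW co-expression fit\n")
  if (!x$identifiable) {
    cat("  p is unidentifiable (no B-B or UV-B ommatidia)\n")
  } else {
    cat(sprintf("  p_hat = %s  (method: %s%s)\n",
                format(x$p_hat, digits = digits), x$method,
                if (x$ambiguous) ", ambiguous root" else ""))
  }
  cat(sprintf("  squared residual = %.3g, %s\n", x$residual,
              if (x$feasible) "feasible" else "infeasible (boundary fit)"))
  invisible(x)
}

#' @export
summary.coexpr_fit <- function(object, ...) {
  fitted_y <- if (object$identifiable) {
    predict_yellow(object$proportions, object$p_hat)
  } else {
    object$proportions[[1]]
  }
  structure(list(fit = object, fitted_yellow = fitted_y,
                 observed_yellow = object$yellow),
            class = "summary.coexpr_fit")
}

#' @export
print.summary.coexpr_fit <- function(x, ...) {
  print(x$fit)
  pr <- x$fit$proportions
  cat(sprintf("  inputs: Y_obs = %.4f; proportions UVUV %.3f, BB %.3f, UVB %.3f\n",
              x$observed_yellow, pr[1], pr[2], pr[3]))
  cat(sprintf("  fitted yellow fraction = %.4f\n", x$fitted_yellow))
  invisible(x)
}

#' @export
coef.coexpr_fit <- function(object, ...) c(p = object$p_hat)

#' @export
#' @method predict coexpr_fit
predict.coexpr_fit <- function(object, proportions = object$proportions,
                               p = object$p_hat, ...) {
  predict_yellow(proportions, p)
}

#' @export
residuals.coexpr_fit <- function(object, ...) {
  fitted_y <- if (object$identifiable) {
    predict_yellow(object$proportions, object$p_hat)
  } else {
    object$proportions[[1]]
  }
  object$yellow - fitted_y
}

#' @export
plot.coexpr_fit <- function(x, ...) {
  p <- seq(0, 1, by = 0.005)
  y <- predict_yellow(x$proportions, p)
  graphics::plot(p, y, type = "l",
                 xlab = "LW co-expression probability p",
                 ylab = "yellow eyeshine fraction", ylim = c(0, 1), ...)
  graphics::abline(h = x$yellow, lty = 2)
  if (x$identifiable && !is.na(x$p_hat)) {
    graphics::abline(v = x$p_hat, lty = 3)
    graphics::points(x$p_hat, predict_yellow(x$proportions, x$p_hat), pch = 19)
  }
  invisible(x)
}

#' Simulate yellow-eyeshine fractions from a fitted model
#'
#' Draws replicate eyes of `n_ommatidia` ommatidia each: the yellow count
#' is binomial with the fitted yellow probability
#' `predict_yellow(proportions, p_hat)`.
#'
#' @param object A `coexpr_fit`.
#' @param nsim Number of replicate eyes.
#' @param seed Optional seed.
#' @param n_ommatidia Ommatidia per simulated eye.
#' @param ... Unused.
#' @return Data frame with columns `sim` and `yellow`.
#' @export
#' @method simulate coexpr_fit
simulate.coexpr_fit <- function(object, nsim = 1, seed = NULL,
                                n_ommatidia = 3700, ...) {
  if (!object$identifiable) stop("cannot simulate from an unidentifiable fit")
  prob <- predict_yellow(object$proportions, object$p_hat)
  draw <- function() stats::rbinom(nsim, n_ommatidia, prob) / n_ommatidia
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(sim = seq_len(nsim), yellow = y)
}

#' Fit the co-expression probability per group
#'
#' Applies [fit_coexpression()] row by row to a table of group means (mean
#' yellow-eyeshine fraction from the eyeshine survey, mean class
#' proportions from the antibody staining). Rows with missing values are
#' skipped with a warning.
#'
#' @param table Data frame with columns `group`, `yellow`, `p_uvuv`,
#'   `p_bb`, `p_uvb`.
#' @param ... Passed to [fit_coexpression()].
#' @return Data frame with one row per fitted group (`group`, `p_hat`,
#'   `residual`, `feasible`, `identifiable`); the full `coexpr_fit`
#'   objects are attached as attribute `"fits"`.
#' @export
fit_group_p <- function(table, ...) {
  req <- c("group", "yellow", "p_uvuv", "p_bb", "p_uvb")
  if (!all(req %in% names(table))) {
    stop("table needs columns group, yellow, p_uvuv, p_bb, p_uvb")
  }
  num <- c("yellow", "p_uvuv", "p_bb", "p_uvb")
  ok <- stats::complete.cases(table[num])
  if (any(!ok)) {
    warning(sprintf("skipping %d group(s) with missing values: %s",
                    sum(!ok), paste(table$group[!ok], collapse = ", ")))
  }
  rows <- which(ok)
  fits <- lapply(rows, function(i) {
    fit_coexpression(table$yellow[i],
                     c(table$p_uvuv[i], table$p_bb[i], table$p_uvb[i]), ...)
  })
  out <- data.frame(
    group = table$group[rows],
    p_hat = vapply(fits, `[[`, numeric(1), "p_hat"),
    residual = vapply(fits, `[[`, numeric(1), "residual"),
    feasible = vapply(fits, `[[`, logical(1), "feasible"),
    identifiable = vapply(fits, `[[`, logical(1), "identifiable"))
  names(fits) <- table$group[rows]
  attr(out, "fits") <- fits
  out
}

#' Bootstrap confidence intervals for per-group co-expression fits
#'
#' Nonparametric bootstrap over individuals: within each group the
#' per-individual rows are resampled with replacement, group means are
#' recomputed and refitted, and percentile intervals of `p_hat` are
#' reported. This is an extension beyond the group-mean fit, provided for
#' uncertainty reporting.
#'
#' @param individuals Data frame with one row per individual: columns
#'   `group`, `yellow`, `p_uvuv`, `p_bb`, `p_uvb`.
#' @param B Number of bootstrap replicates.
#' @param level Confidence level of the percentile interval.
#' @param seed Optional seed.
#' @return Data frame with one row per group: `group`, `p_hat` (fit on the
#'   observed means), `lower`, `upper`, `B`.
#' @export
bootstrap_group_p <- function(individuals, B = 1000, level = 0.95,
                              seed = NULL) {
  run <- function() {
    groups <- unique(individuals$group)
    out <- lapply(groups, function(gr) {
      d <- individuals[individuals$group == gr, ]
      fit0 <- fit_coexpression(mean(d$yellow),
                               prop_means(d))
      reps <- vapply(seq_len(B), function(b) {
        i <- sample.int(nrow(d), replace = TRUE)
        fit_coexpression(mean(d$yellow[i]), prop_means(d[i, ]))$p_hat
      }, numeric(1))
      qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                            na.rm = TRUE, names = FALSE)
      data.frame(group = gr, p_hat = fit0$p_hat,
                 lower = qs[1], upper = qs[2], B = B)
    })
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# mean class proportions of a per-individual table, renormalized
prop_means <- function(d) {
  m <- c(mean(d$p_uvuv), mean(d$p_bb), mean(d$p_uvb))
  m / sum(m)
}
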