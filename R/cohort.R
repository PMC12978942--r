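#' Average-linkage clustering of ommatidial class distributions
#'
#' Agglomerative (UPGMA) clustering of per-individual class proportion
#' triples `(p_uvuv, p_bb, p_uvb)` using the Euclidean distance, as used to
#' group ventral-eye class distributions across individuals. Flat labels
#' are obtained by cutting the tree at `k` clusters (or height `h`).
#'
#' @param points Numeric matrix or data frame with 3 columns (one row per
#'   individual), or anything `as.matrix()` can coerce.
#' @param k Number of flat clusters (default 2); ignored if `h` is given.
#' @param h Optional cut height.
#' @return An object of class `omm_clusters`: list with the `stats::hclust`
#'   tree (`tree`), the flat `labels`, and the input `points`.
#' @export
hclust_average <- function(points, k = 2, h = NULL) {
  x <- as.matrix(points)
  if (nrow(x) < 2L) stop("clustering needs at least 2 points")
  tree <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "average")
  labels <- if (is.null(h)) stats::cutree(tree, k = k)
            else stats::cutree(tree, h = h)
  structure(list(tree = tree, labels = labels, points = x),
            class = "omm_clusters")
}

#' @export
print.omm_clusters <- function(x, ...) {
  cat(sprintf("UPGMA clustering of %d class distributions\n",
              nrow(x$points)))
  cat("  flat labels:", paste(table(x$labels), collapse = " / "),
      "members per cluster\n")
  invisible(x)
}

#' @export
plot.omm_clusters <- function(x, ...) {
  graphics::plot(x$tree, ...)
  invisible(x)
}

#' Pairwise t-tests with Holm-Bonferroni correction and letter display
#'
#' All pairwise two-sample t-tests (Welch by default) between named groups,
#' Holm-Bonferroni corrected over the family of pairs. Groups are
#' summarised with a compact letter display: two groups share a letter if
#' and only if their adjusted test is non-significant, so groups with no
#' letter in common differ significantly.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param alpha Familywise significance level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Object of class `pairwise_holm`: list with the `pairs` decision
#'   table (`group1`, `group2`, `p`, `p_adj`, `significant`) and `letters`,
#'   a named character vector per group.
#' @export
pairwise_tests_holm <- function(values, groups, alpha = 0.05,
                                var_equal = FALSE) {
  g <- factor(groups)
  if (any(table(g) < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 observations",
                 names(which(table(g) < 2L))[1]))
  }
  lev <- levels(g)
  cmb <- utils::combn(lev, 2)
  p <- apply(cmb, 2, function(pr) {
    stats::t.test(values[g == pr[1]], values[g == pr[2]],
                  var.equal = var_equal)$p.value
  })
  p_adj <- stats::p.adjust(p, method = "holm")
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                      p = p, p_adj = p_adj, significant = p_adj <= alpha)
  letters <- cld_letters(lev, pairs)
  structure(list(pairs = pairs, letters = letters, alpha = alpha),
            class = "pairwise_holm")
}

#' @export
print.pairwise_holm <- function(x, ...) {
  cat(sprintf("Pairwise t-tests, Holm-Bonferroni at alpha = %.2f\n", x$alpha))
  print(x$pairs, row.names = FALSE)
  cat("letters: ",
      paste(sprintf("%s = %s", names(x$letters), x$letters), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# compact letter display from the pairwise decision table: one letter per
# maximal clique of the non-significance graph; deterministic via group
# order and clique ordering by lowest member index
cld_letters <- function(lev, pairs) {
  n <- length(lev)
  adj <- matrix(FALSE, n, n, dimnames = list(lev, lev))
  diag(adj) <- TRUE
  for (i in seq_len(nrow(pairs))) {
    if (!pairs$significant[i]) {
      adj[pairs$group1[i], pairs$group2[i]] <- TRUE
      adj[pairs$group2[i], pairs$group1[i]] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  members <- lapply(cl, function(v) sort(as.integer(v)))
  members <- members[order(vapply(members, min, integer(1)),
                           vapply(members, function(m) m[min(2, length(m))],
                                  integer(1)))]
  out <- stats::setNames(rep("", n), lev)
  for (j in seq_along(members)) {
    out[members[[j]]] <- paste0(out[members[[j]]], letters[j])
  }
  out
}

#' Two-way factorial ANOVA for species and sex
#'
#' Tests the effects of species, sex and their interaction on a numeric
#' response (e.g. the ventral yellow-eyeshine fraction). Unbalanced designs
#' are handled with Type-II sums of squares via model comparison; on
#' balanced designs these coincide with the textbook factorial
#' decomposition. A zero residual sum of squares (perfect fit) yields
#' infinite F, reported and flagged rather than capped silently.
#'
#' @param data Data frame.
#' @param response,species,sex Column names (strings).
#' @return Object of class `anova_ss`: a data frame with one row per term
#'   (`term`, `df`, `sum_sq`, `F`, `p`) plus the residual row, with a
#'   `perfect_fit` attribute.
#' @export
anova_species_sex <- function(data, response = "response",
                              species = "species", sex = "sex") {
  d <- data.frame(y = data[[response]],
                  species = factor(data[[species]]),
                  sex = factor(data[[sex]]))
  if (nlevels(d$species) < 2L || nlevels(d$sex) < 2L) {
    stop("species and sex each need at least 2 levels")
  }
  cells <- table(d$species, d$sex)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: species '%s' x sex '%s'",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  fit <- stats::lm(y ~ species * sex, data = d)
  rss <- sum(stats::residuals(fit)^2)
  ss_total <- sum((d$y - mean(d$y))^2)
  perfect <- rss <= 1e-12 * max(ss_total, 1)
  if (!perfect) {
    a <- car::Anova(fit, type = 2)
    rs <- which(rownames(a) == "Residuals")
    out <- data.frame(term = c(rownames(a)[-rs], "Residuals"),
                      df = c(a[-rs, "Df"], a[rs, "Df"]),
                      sum_sq = c(a[-rs, "Sum Sq"], a[rs, "Sum Sq"]),
                      F = c(a[-rs, "F value"], NA),
                      p = c(a[-rs, "Pr(>F)"], NA))
    df_res <- a[rs, "Df"]
  } else {
    # zero residual variance: Type-II sums of squares by model comparison,
    # F reported as Inf (p = 0) for terms with positive sum of squares
    dev <- function(f) stats::deviance(stats::lm(f, data = d))
    full <- dev(y ~ species * sex)
    additive <- dev(y ~ species + sex)
    ss <- c(dev(y ~ sex) - additive,      # species, adjusted for sex
            dev(y ~ species) - additive,  # sex, adjusted for species
            additive - full)              # interaction
    df_terms <- c(nlevels(d$species) - 1L, nlevels(d$sex) - 1L,
                  (nlevels(d$species) - 1L) * (nlevels(d$sex) - 1L))
    df_res <- nrow(d) - nlevels(d$species) * nlevels(d$sex)
    pos <- ss > 1e-12 * max(ss_total, 1)
    out <- data.frame(term = c("species", "sex", "species:sex", "Residuals"),
                      df = c(df_terms, df_res),
                      sum_sq = c(ss, rss),
                      F = c(ifelse(pos, Inf, 0), NA),
                      p = c(ifelse(pos, 0, 1), NA))
  }
  attr(out, "perfect_fit") <- perfect
  attr(out, "df_residual") <- df_res
  class(out) <- c("anova_ss", "data.frame")
  out
}

#' qPCR triplicate quality control
#'
#' Applies the replicate-spread rule to a table of triplicate Ct values:
#' a record whose sample standard deviation across the replicates exceeds 1
#' is discarded (flagged for re-testing); kept records carry the mean Ct.
#'
#' @param records Data frame with columns `sample`, `gene`, `ct1`, `ct2`,
#'   `ct3`. Genes are typically UV1, UV2, LW, EF1a.
#' @return The input with added columns `sd`, `status`
#'   (`"kept"`/`"discarded"`) and `mean_ct` (`NA` when discarded).
#' @export
qpcr_qc <- function(records) {
  req <- c("sample", "gene", "ct1", "ct2", "ct3")
  if (!all(req %in% names(records))) {
    stop("records needs columns sample, gene, ct1, ct2, ct3")
  }
  ct <- as.matrix(records[c("ct1", "ct2", "ct3")])
  sds <- apply(ct, 1, stats::sd)
  records$sd <- sds
  records$status <- ifelse(sds > 1, "discarded", "kept")
  records$mean_ct <- ifelse(sds > 1, NA_real_, rowMeans(ct))
  records
}

#' Relative UV2:UV1 expression for one sample
#'
#' Applies the triplicate QC first, then converts the Ct difference to a
#' fold change assuming 100% amplification efficiency:
#' `UV2:UV1 = 2^(meanCt_UV1 - meanCt_UV2)` (a lower Ct means more
#' transcript). LW and EF1a records are used only as presence controls.
#'
#' @param records Data frame of triplicate records (see [qpcr_qc()]) for
#'   one sample.
#' @param sample Sample id to analyse (default: the only sample present).
#' @return List with `sample`, `fold_uv2_uv1`, `log2_ratio`, `detected`
#'   (logical per gene) and `status` (`"ok"`, `"not_detected"`, or
#'   `"retest"` when all replicates of a needed gene were discarded).
#' @export
qpcr_relative <- function(records, sample = NULL) {
  qc <- qpcr_qc(records)
  if (is.null(sample)) {
    sample <- unique(qc$sample)
    if (length(sample) != 1L) stop("specify which sample to analyse")
  }
  qc <- qc[qc$sample == sample, ]
  detected <- c(UV1 = any(qc$gene == "UV1"), UV2 = any(qc$gene == "UV2"))
  res <- list(sample = sample, fold_uv2_uv1 = NA_real_,
              log2_ratio = NA_real_, detected = detected, status = "ok")
  if (!all(detected)) {
    res$status <- "not_detected"
    return(res)
  }
  mean_ct <- function(gene) {
    kept <- qc[qc$gene == gene & qc$status == "kept", ]
    if (nrow(kept) == 0L) return(NA_real_)
    mean(kept$mean_ct)
  }
  m1 <- mean_ct("UV1"); m2 <- mean_ct("UV2")
  if (is.na(m1) || is.na(m2)) {
    res$status <- "retest"
    return(res)
  }
  res$log2_ratio <- m1 - m2
  res$fold_uv2_uv1 <- 2^(m1 - m2)
  res
}
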