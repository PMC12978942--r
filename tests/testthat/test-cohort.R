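test_that("average linkage reproduces hand-computed merges", {
  # two points: single merge at their Euclidean distance
  cl2 <- hclust_average(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(cl2$tree$height, 5)

  # collinear points at 0, 1, 10: merge {0,1} at 1, then at mean(9, 10)
  cl3 <- hclust_average(matrix(c(0, 1, 10), 3, 1))
  expect_equal(sort(cl3$tree$height), c(1, 9.5))

  expect_error(hclust_average(matrix(1, 1, 3)), "at least 2")
})

test_that("UPGMA merge heights equal the O(n^3) oracle", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    x <- matrix(runif(n * 3), n, 3)
    cl <- hclust_average(x)
    expect_equal(sort(cl$tree$height), upgma_oracle(x), tolerance = 1e-12)
  }
})

test_that("planted class-distribution clusters are recovered at k = 2", {
  set.seed(52)
  centers <- rbind(c(0.05, 0.55, 0.40),   # B-B dominated eyes
                   c(0.05, 0.25, 0.70))   # UV-B dominated eyes
  pts <- rbind(matrix(rnorm(30, rep(centers[1, ], each = 10), 0.02), 10),
               matrix(rnorm(30, rep(centers[2, ], each = 10), 0.02), 10))
  cl <- hclust_average(pts, k = 2)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agree, 1)
})

test_that("pairwise Holm letters match the significance structure", {
  set.seed(53)
  same <- rnorm(30, 0, 1)
  r1 <- pairwise_tests_holm(same, rep(c("a", "b", "c"), each = 10))
  expect_true(all(r1$letters == r1$letters[1]))  # identical groups share one letter

  vals <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  r2 <- pairwise_tests_holm(vals, rep(c("g1", "g2", "g3"), each = 10))
  expect_equal(unname(r2$letters), c("a", "a", "b"))

  # Holm decisions equal the sequential-rejection oracle
  expect_identical(unname(r2$pairs$significant),
                   holm_oracle(r2$pairs$p, 0.05))

  # property: two groups share a letter iff their test is non-significant
  for (i in 1:10) {
    v <- rnorm(40, rep(sample(0:3, 4, replace = TRUE), each = 10), 1)
    g <- rep(paste0("G", 1:4), each = 10)
    r <- pairwise_tests_holm(v, g)
    for (k in seq_len(nrow(r$pairs))) {
      l1 <- strsplit(r$letters[r$pairs$group1[k]], "")[[1]]
      l2 <- strsplit(r$letters[r$pairs$group2[k]], "")[[1]]
      share <- length(intersect(l1, l2)) > 0
      expect_identical(share, !r$pairs$significant[k])
    }
  }

  expect_error(pairwise_tests_holm(1:5, c("a", "a", "a", "a", "b")),
               "fewer than 2")
})

test_that("two-way ANOVA handles constant, perfect-fit and balanced designs", {
  d <- expand.grid(species = c("s1", "s2"), sex = c("f", "m"),
                   rep = 1:5)
  d$response <- 0
  a0 <- anova_species_sex(d)
  expect_true(all(a0$F[1:3] == 0))

  # cell means {0,0,0,10} with zero within-cell variance: interaction blows up
  d2 <- d
  d2$response <- ifelse(d2$species == "s2" & d2$sex == "m", 10, 0)
  a2 <- anova_species_sex(d2)
  expect_true(attr(a2, "perfect_fit"))
  expect_equal(a2$F[a2$term == "species:sex"], Inf)
  expect_equal(a2$df[a2$term == "species:sex"], 1)
  expect_equal(attr(a2, "df_residual"), nrow(d2) - 4)

  # balanced design: SS decomposition is exact
  set.seed(54)
  d3 <- expand.grid(species = paste0("s", 1:3), sex = c("f", "m"), rep = 1:6)
  d3$response <- rnorm(nrow(d3)) + as.integer(d3$species) +
    2 * as.integer(d3$sex)
  a3 <- anova_species_sex(d3)
  ss_total <- sum((d3$response - mean(d3$response))^2)
  expect_equal(sum(a3$sum_sq), ss_total, tolerance = 1e-9)

  expect_error(anova_species_sex(data.frame(
    response = 1:3, species = c("a", "a", "b"), sex = c("f", "m", "m"))),
    "empty design cell")
})

test_that("two-way ANOVA holds its nominal type-I error under the null", {
  set.seed(55)
  n_rep <- 1200
  rej <- matrix(FALSE, n_rep, 3)
  d <- expand.grid(species = paste0("s", 1:3), sex = c("f", "m"), rep = 1:7)
  for (r in seq_len(n_rep)) {
    d$response <- rnorm(nrow(d))
    a <- anova_species_sex(d)
    rej[r, ] <- a$p[1:3] <= 0.05
  }
  mc <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_true(all(abs(colMeans(rej) - 0.05) < mc + 0.005))
})

test_that("qPCR triplicate QC applies the strict SD > 1 rule", {
  rec <- data.frame(sample = "s", gene = c("UV1", "UV2", "LW"),
                    ct1 = c(20, 20, 20), ct2 = c(21.5, 21, 20.99),
                    ct3 = c(23, 22, 21.98))
  qc <- qpcr_qc(rec)
  expect_equal(qc$sd[1], 1.5)          # sample SD (n - 1 denominator)
  expect_equal(qc$status, c("discarded", "kept", "kept"))  # sd = 1 is kept
  expect_true(is.na(qc$mean_ct[1]))

  # idempotent and replicate-order independent
  qc2 <- qpcr_qc(qc[names(rec)])
  expect_identical(qc2$status, qc$status)
  rec_perm <- rec; rec_perm[c("ct1", "ct2", "ct3")] <- rec[c("ct3", "ct1", "ct2")]
  expect_identical(qpcr_qc(rec_perm)$status, qc$status)
})

test_that("relative expression follows 2^deltaCt with QC applied first", {
  rec <- data.frame(sample = "s", gene = c("UV1", "UV2"),
                    ct1 = c(24, 20), ct2 = c(24, 20), ct3 = c(24, 20))
  r <- qpcr_relative(rec)
  expect_equal(r$fold_uv2_uv1, 16)     # deltaCt = 4
  expect_equal(r$log2_ratio, 4)

  eq <- data.frame(sample = "s", gene = c("UV1", "UV2"),
                   ct1 = 22, ct2 = 22, ct3 = 22)
  re <- qpcr_relative(eq)
  expect_equal(re$fold_uv2_uv1, 1)
  expect_equal(re$log2_ratio, 0)

  nd <- qpcr_relative(data.frame(sample = "s", gene = "UV1",
                                 ct1 = 22, ct2 = 22, ct3 = 22))
  expect_equal(nd$status, "not_detected")

  bad <- data.frame(sample = "s", gene = c("UV1", "UV2"),
                    ct1 = c(20, 20), ct2 = c(21.5, 20), ct3 = c(23, 20))
  expect_equal(qpcr_relative(bad)$status, "retest")
})
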