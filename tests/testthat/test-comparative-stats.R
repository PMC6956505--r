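star_tree <- function(n, bl = 1) {
  txt <- paste0("(", paste0("t", seq_len(n), ":", bl, collapse = ","), "):0;")
  read_tree(txt)
}

test_that("phylogenetic PCA reduces to ordinary PCA on a star tree", {
  set.seed(10)
  n <- 20
  tr <- star_tree(n)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(tr$tip.label, paste0("tr", 1:4)))
  d <- dplyr::bind_cols(tibble::tibble(species = rownames(X)), tibble::as_tibble(X))
  for (sc in c(TRUE, FALSE)) {
    pp <- phylo_pca(tr, d, scale = sc)
    op <- prcomp(X, center = TRUE, scale. = sc)
    expect_equal(pp$eigenvalues, op$sdev^2, tolerance = 1e-8)
    expect_equal(abs(unclass(pp$loadings)), abs(unname(op$rotation)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(unclass(pp$scores)), abs(unname(op$x)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("phylogenetic PCA agrees with an independent implementation on a random tree", {
  skip_if_not_installed("phytools")
  set.seed(11)
  tr <- ape::rtree(15)
  X <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(tr$tip.label, paste0("v", 1:3)))
  d <- dplyr::bind_cols(tibble::tibble(species = rownames(X)), tibble::as_tibble(X))
  pp <- phylo_pca(tr, d, scale = FALSE)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(sort(pp$eigenvalues), sort(as.numeric(diag(ref$Eval))), tolerance = 1e-6)
  expect_equal(abs(unclass(pp$loadings)), abs(unclass(ref$Evec)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("phylogenetic PCA bookkeeping: variance fractions and edge cases", {
  set.seed(12)
  tr <- ape::rtree(10)
  x1 <- rnorm(10)
  d <- tibble::tibble(species = tr$tip.label, a = x1)
  pp <- phylo_pca(tr, d)
  expect_equal(pp$variance_explained, 1)

  d2 <- tibble::tibble(species = tr$tip.label, a = x1, b = x1 + 1e-9 * rnorm(10),
                       c = rnorm(10))
  pp2 <- phylo_pca(tr, d2, scale = TRUE)
  expect_equal(sum(pp2$variance_explained), 1)
  expect_gt(pp2$variance_explained[1], 0.6) # duplicate column absorbed by PC1
  expect_true(all(diff(pp2$variance_explained) <= 1e-12))

  expect_error(phylo_pca(tr, tibble::tibble(species = tr$tip.label, a = rep(1, 10))),
               "constant")
})

test_that("independent contrasts match the closed form and BM standardisation", {
  tr <- read_tree("(A:1,B:1):0;")
  cc <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(abs(cc$contrast), sqrt(2))

  tr16 <- simulate_tree(16, seed = 13)
  expect_equal(pic_contrasts(tr16, setNames(rep(2.5, 16), tr16$tip.label))$contrast,
               rep(0, 15))

  # contrasts of BM data have unit variance at every position
  nrep <- 1000
  set.seed(14)
  cons <- replicate(nrep, {
    y <- simulate_bm_traits(tr16, Sigma = 1, seed = sample.int(1e8, 1))
    pic_contrasts(tr16, setNames(y$trait1, y$species))$contrast
  })
  pos_var <- apply(cons, 1, var)
  se <- sqrt(2 / nrep) # var of sample variance of N(0,1)
  expect_true(all(abs(pos_var - 1) < 5 * se))
})

test_that("contrast regression recovers exact linear relations and applies Bonferroni", {
  set.seed(15)
  tr <- ape::rtree(12)
  x <- rnorm(12)
  d <- tibble::tibble(species = tr$tip.label, x = x, y = 2 * x + rnorm(12, 0, 1e-6))
  res <- pic_regression(tr, d, "x", "y")
  expect_equal(res$slope, 2, tolerance = 1e-4)
  expect_lt(res$p_raw, 1e-10)

  # slope invariant to adding constants at the tips
  d2 <- dplyr::mutate(d, x = x + 100, y = y - 7)
  expect_equal(pic_regression(tr, d2, "x", "y")$slope, res$slope, tolerance = 1e-10)

  expect_equal(min(1, 5 * 0.02), 0.10) # the Bonferroni arithmetic contract
  res_m <- pic_regression(tr, d, "x", "y", m = 5)
  expect_equal(res_m$p_bonferroni, min(1, 5 * res_m$p_raw))

  batch <- pic_regression_batch(tr, dplyr::mutate(d, z = rnorm(12)), "x", c("y", "z"))
  expect_equal(batch$m, c(2, 2))
})

test_that("phylogenetic ANOVA matches parametric ANOVA on a star tree", {
  set.seed(16)
  n <- 40
  tr <- star_tree(n)
  d <- tibble::tibble(species = tr$tip.label,
                      g = rep(c("a", "b", "c", "d"), each = 10),
                      y = rnorm(n) + rep(c(0, 0, 0.5, 1), each = 10))
  res <- phylo_anova(tr, d, "g", "y", nsim = 2000, seed = 3)
  mc_se <- sqrt(res$p_parametric * (1 - res$p_parametric) / 2000)
  expect_lt(abs(res$p_phylo - res$p_parametric), 3 * mc_se)
  f_ref <- summary(aov(y ~ g, data = d))[[1]]$`F value`[1]
  expect_equal(res$F, f_ref, tolerance = 1e-10)
})

test_that("phylogenetic correction is conservative for clumped groups on a comb tree", {
  set.seed(17)
  n <- 24
  comb <- ape::stree(n, type = "left")
  comb$edge.length <- rep(1, nrow(comb$edge))
  groups <- rep(c("a", "b"), each = n / 2) # perfectly phylogenetically clumped
  ps <- t(replicate(40, {
    y <- simulate_bm_traits(comb, Sigma = 1, seed = sample.int(1e8, 1))
    d <- tibble::tibble(species = y$species, g = groups[match(y$species, comb$tip.label)],
                        y = y$trait1)
    r <- phylo_anova(comb, d, "g", "y", nsim = 300, seed = sample.int(1e8, 1))
    c(r$p_phylo, r$p_parametric)
  }))
  expect_gt(mean(ps[, 1]), mean(ps[, 2])) # simulation p larger on average
})

test_that("phylo_anova validates group sizes", {
  tr <- star_tree(5)
  d <- tibble::tibble(species = tr$tip.label, g = c("a", "a", "b", "b", "c"),
                      y = rnorm(5))
  expect_error(phylo_anova(tr, d, "g", "y", nsim = 50), "c")
  expect_warning(res <- phylo_anova(tr, d, "g", "y", nsim = 50, drop_small = TRUE),
                 "dropping")
  expect_equal(res$n, 4)
})

test_that("Brown-Forsythe equals ANOVA on absolute deviations from medians", {
  g1 <- c(1, 2, 3); g2 <- c(0, 5, 10)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(g1, g2))
  res <- brown_forsythe(d, "g", "y")
  ref <- summary(aov(z ~ g, data = tibble::tibble(g = d$g, z = c(1, 0, 1, 5, 0, 5))))[[1]]
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # identical spreads give F ~ 0
  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 11, 12, 13))
  expect_equal(brown_forsythe(d2, "g", "y")$F, 0, tolerance = 1e-12)
  expect_error(brown_forsythe(tibble::tibble(g = c("a", "a", "b", "b"), y = rep(1, 4)),
                              "g", "y"), "constant")
})

test_that("Brown-Forsythe holds its size under equal variances", {
  set.seed(18)
  rej <- mean(replicate(1000, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
    brown_forsythe(d, "g", "y")$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.025)
})

test_that("Kruskal-Wallis matches the direct rank formula", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 2), y = c(1, 2, 3, 4, 5, 6))
  res <- kruskal_wallis(d, "g", "y")
  # brute-force rank formula, no ties
  r <- rank(d$y); n <- 6
  H <- 12 / (n * (n + 1)) * sum(tapply(r, d$g, sum)^2 / 2) - 3 * (n + 1)
  expect_equal(res$chi2, H, tolerance = 1e-10)
  expect_equal(res$df, 2)

  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  expect_equal(kruskal_wallis(d2, "g", "y")$chi2, 0, tolerance = 1e-10)
})
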