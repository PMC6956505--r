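# Phylogenetically corrected syndrome statistics: phylogenetic PCA under
# Brownian motion, independent contrasts and regressions through the origin,
# simulation-based phylogenetic ANOVA, and the two non-phylogenetic
# companions (Brown-Forsythe, Kruskal-Wallis).

#' Phylogenetic principal components analysis
#'
#' PCA of continuous traits under a Brownian-motion model of evolution. The
#' ancestral mean of each trait is estimated by generalised least squares
#' using the phylogenetic covariance matrix C, the evolutionary
#' (co)variance matrix is R = (X - 1a)' C^-1 (X - 1a) / (n - 1), and the
#' principal axes are the eigenvectors of R (of its correlation analogue
#' when `scale = TRUE`). Scores are the GLS-centered data projected on the
#' axes.
#'
#' @param tree A `phylo` object whose tips cover the species in `data`.
#' @param data A data frame with a species column and numeric trait columns.
#' @param traits Character vector of trait columns; default all numeric
#'   columns.
#' @param species Name of the species column.
#' @param scale Use the evolutionary correlation matrix (traits standardised;
#'   default `TRUE`).
#' @return An object of class `phylo_pca` with elements `eigenvalues`,
#'   `loadings`, `scores`, `variance_explained`, `traits`, `taxa`, `scale`.
#' @export
phylo_pca <- function(tree, data, traits = NULL, species = "species", scale = TRUE) {
  data <- tibble::as_tibble(data)
  stopifnot(species %in% names(data))
  data[[species]] <- normalize_taxa(data[[species]])
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  X <- as.matrix(data[, traits, drop = FALSE])
  rownames(X) <- data[[species]]
  if (anyNA(X)) stop("trait matrix contains missing values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column(s): ", paste(traits[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  tree <- prune_to_taxa(tree, rownames(X))
  C <- phylo_vcv(tree)
  X <- X[rownames(C), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more species than traits", call. = FALSE)
  Cinv <- solve_vcv(C)
  one <- matrix(1, n, 1)
  a <- solve(t(one) %*% Cinv %*% one) %*% t(one) %*% Cinv %*% X
  Xc <- X - one %*% a
  R <- t(Xc) %*% Cinv %*% Xc / (n - 1)
  if (scale) {
    s <- sqrt(diag(R))
    R <- R / tcrossprod(s)
    Xc <- sweep(Xc, 2, s, "/")
  }
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  # sign convention: largest-magnitude loading positive, for reproducibility
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(traits, paste0("PC", seq_len(p)))
  scores <- Xc %*% V
  structure(list(
    eigenvalues = pmax(eig$values, 0),
    loadings = V,
    scores = scores,
    variance_explained = pmax(eig$values, 0) / sum(pmax(eig$values, 0)),
    traits = traits, taxa = rownames(C), scale = scale
  ), class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat("Phylogenetic PCA (", length(x$taxa), " species, ",
      length(x$traits), " traits, ",
      if (x$scale) "correlation" else "covariance", " mode)\n", sep = "")
  ve <- round(100 * x$variance_explained, 1)
  cat("Variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy phylo_pca
#' @export
tidy.phylo_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @method glance phylo_pca
#' @export
glance.phylo_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 eigenvalue = x$eigenvalues,
                 variance_explained = x$variance_explained,
                 cumulative = cumsum(x$variance_explained))
}

#' Scores of a phylogenetic PCA as a tibble
#' @param x A `phylo_pca` object.
#' @return Tibble with `species` and one column per component.
#' @export
pca_scores <- function(x) {
  stopifnot(inherits(x, "phylo_pca"))
  tibble::as_tibble(x$scores, rownames = "species")
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein's standardised contrasts for one trait. Polytomies are first
#' resolved to zero-length branches (deterministically, in tip-label order).
#'
#' @param tree A `phylo` object.
#' @param x Named numeric vector of tip values (names = species), or a data
#'   frame with `species` and one trait column.
#' @param trait Trait column when `x` is a data frame.
#' @return A tibble with `node` and `contrast` (n - 1 rows for n species).
#' @export
pic_contrasts <- function(tree, x, trait = NULL) {
  if (is.data.frame(x)) {
    stopifnot("species" %in% names(x))
    if (is.null(trait)) trait <- setdiff(names(x), "species")[1]
    v <- stats::setNames(x[[trait]], normalize_taxa(x$species))
  } else {
    v <- x
    names(v) <- normalize_taxa(names(v))
  }
  miss <- setdiff(tree$tip.label, names(v))
  if (length(miss)) stop("no trait value for: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  pics <- ape::pic(v[tree$tip.label], tree, scaled = TRUE)
  tibble::tibble(node = as.integer(names(pics)), contrast = as.numeric(pics))
}

#' Regression of independent contrasts through the origin
#'
#' Ordinary least squares of the y-contrasts on the x-contrasts with the
#' intercept fixed at zero (contrasts have arbitrary sign, so a free
#' intercept is not identified). The p-value may be Bonferroni-adjusted for
#' a family of `m` comparisons.
#'
#' @param tree A `phylo` object.
#' @param data Data frame with a `species` column and the two traits.
#' @param x,y Names of the predictor and response trait columns.
#' @param m Bonferroni family size (default 1 = no adjustment).
#' @return A tibble with `x`, `y`, `slope`, `r_squared`, `p_raw`,
#'   `p_bonferroni`, `n_contrasts`, `m`.
#' @export
pic_regression <- function(tree, data, x, y, m = 1) {
  cx <- pic_contrasts(tree, data, trait = x)$contrast
  cy <- pic_contrasts(tree, data, trait = y)$contrast
  if (length(cx) < 3) stop("need at least 3 contrasts", call. = FALSE)
  fit <- stats::lm(cy ~ cx + 0)
  sm <- summary(fit)
  p_raw <- sm$coefficients[1, 4]
  tibble::tibble(
    x = x, y = y,
    slope = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_raw = p_raw,
    p_bonferroni = min(1, m * p_raw),
    n_contrasts = length(cx),
    m = m
  )
}

#' Batch of contrast regressions against one predictor
#'
#' Runs [pic_regression()] of each response on the shared predictor, with
#' the Bonferroni family size defaulting to the number of regressions run.
#'
#' @param tree A `phylo` object.
#' @param data Data frame with `species`, the predictor and the responses.
#' @param x Predictor column name.
#' @param responses Character vector of response columns.
#' @param m Bonferroni family size (default `length(responses)`).
#' @return One tibble row per response.
#' @export
pic_regression_batch <- function(tree, data, x, responses, m = length(responses)) {
  dplyr::bind_rows(lapply(responses, function(yy)
    pic_regression(tree, data, x = x, y = yy, m = m)))
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed statistic is the ordinary one-way ANOVA F of `y` across
#' `groups`; its null distribution is generated by simulating the trait
#' under Brownian motion on the tree (rate estimated from the contrasts)
#' with the group labels held fixed, so the p-value accounts for
#' phylogenetic non-independence.
#'
#' @param tree A `phylo` object.
#' @param data Data frame with `species`, a group column and a trait column.
#' @param group,y Column names of the grouping factor and the response.
#' @param nsim Number of Brownian-motion null simulations.
#' @param seed Integer seed.
#' @param drop_small Drop groups with fewer than 2 members (with a warning)
#'   instead of erroring.
#' @return A tibble with `F`, `p_phylo`, `p_parametric`, `nsim`, `seed`,
#'   `n`, `k_groups`.
#' @export
phylo_anova <- function(tree, data, group, y, nsim = 1000, seed = 1L,
                        drop_small = FALSE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("species", group, y) %in% names(data)))
  data$species <- normalize_taxa(data$species)
  tab <- table(data[[group]])
  small <- names(tab)[tab < 2]
  if (length(small)) {
    if (drop_small) {
      warning("dropping group(s) with < 2 members: ", paste(small, collapse = ", "))
      data <- data[!data[[group]] %in% small, , drop = FALSE]
    } else {
      stop("group(s) with < 2 members: ", paste(small, collapse = ", "), call. = FALSE)
    }
  }
  if (length(unique(data[[group]])) < 2) stop("need at least 2 groups", call. = FALSE)
  tree <- prune_to_taxa(tree, data$species)
  C <- phylo_vcv(tree)
  data <- data[match(rownames(C), data$species), , drop = FALSE]
  g <- factor(data[[group]])
  yv <- data[[y]]
  n <- length(yv)
  f_obs <- anova_f(yv, g)
  # BM rate from the mean squared standardized contrast (F is scale
  # invariant, so the rate only matters cosmetically)
  sig2 <- mean(pic_contrasts(tree, stats::setNames(yv, data$species))$contrast^2)
  L <- t(chol(C + diag(1e-10 * max(diag(C)), n)))
  f_sim <- withr_seed(seed, {
    Z <- matrix(stats::rnorm(n * nsim), n, nsim)
    Ysim <- sqrt(sig2) * (L %*% Z)
    apply(Ysim, 2, anova_f, g = g)
  })
  tibble::tibble(
    F = f_obs,
    p_phylo = (sum(f_sim >= f_obs) + 1) / (nsim + 1),
    p_parametric = stats::pf(f_obs, nlevels(g) - 1, n - nlevels(g), lower.tail = FALSE),
    nsim = nsim, seed = as.integer(seed), n = n, k_groups = nlevels(g)
  )
}

anova_f <- function(y, g) {
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  if (ssw == 0) {
    if (ssb == 0) return(0)
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Brown-Forsythe test for equality of group variances
#'
#' One-way ANOVA on the absolute deviations from the group medians.
#'
#' @param data Data frame in long form.
#' @param group,y Column names of the grouping factor and the response.
#' @return A tibble with `F`, `df1`, `df2`, `p`.
#' @export
brown_forsythe <- function(data, group, y) {
  data <- tibble::as_tibble(data)
  g <- factor(data[[group]])
  yv <- data[[y]]
  if (nlevels(g) < 2 || any(tabulate(g) < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  med <- tapply(yv, g, stats::median)
  z <- abs(yv - med[g])
  if (all(z == 0)) stop("all groups constant: F undefined", call. = FALSE)
  f <- anova_f(z, g)
  df1 <- nlevels(g) - 1; df2 <- length(z) - nlevels(g)
  tibble::tibble(F = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tidy wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-squared reference with k - 1 df).
#'
#' @param data Data frame in long form.
#' @param group,y Column names of the grouping factor and the response.
#' @return A tibble with `chi2`, `df`, `p`.
#' @export
kruskal_wallis <- function(data, group, y) {
  data <- tibble::as_tibble(data)
  kt <- stats::kruskal.test(data[[y]], factor(data[[group]]))
  tibble::tibble(chi2 = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value)
}
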