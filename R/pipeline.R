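# The two composite analyses: syndrome identification on a joint
# spectra + trait + tree dataset, and fruit-color evolution on a tree with
# discrete states. Each returns a structured, seeded report whose numbers
# can be reproduced from the recorded provenance.

#' Run the fruit-syndrome identification analysis
#'
#' Full syndrome pipeline on one dataset: process the reflectance spectra
#' and place species in avian color space; join the five syndrome traits;
#' phylogenetic PCA; contrast regressions of each trait on short-wave cone
#' stimulation with Bonferroni correction; phylogenetic ANOVA (plus
#' Brown-Forsythe and Kruskal-Wallis) of log endocarp flatness across color
#' categories; and the pairwise hull-volume overlap of categories in color
#' space.
#'
#' @param data A list with elements `tree` (`phylo`), `traits` (tibble with
#'   `species` and the trait columns), `states` (tibble `species`/`state`),
#'   and `spectra` (long tibble `species`/`fruit`/`wavelength`/
#'   `reflectance`), e.g. from [simulate_syndrome_dataset()].
#' @param traits Trait columns used in the PCA and regressions.
#' @param anova_trait Trait tested across categories (log-transformed when
#'   `log_anova`); default `"flatness"`.
#' @param log_anova Apply `log()` before the group tests (default TRUE).
#' @param scale Passed to [phylo_pca()].
#' @param nsim Simulations for the phylogenetic ANOVA.
#' @param n_samples Monte-Carlo samples per hull-overlap pair.
#' @param seed Integer seed for all stochastic stages.
#' @param vm Avian visual model.
#' @return A list of class `syndrome_report`: `color_points`, `pca`,
#'   `pca_variance`, `pic_regressions`, `anova`, `brown_forsythe`,
#'   `kruskal_wallis`, `overlap`, `provenance`.
#' @export
run_syndromes <- function(data,
                          traits = c("lipid", "moisture", "pulp_volume",
                                     "flatness", "fruit_width"),
                          anova_trait = "flatness", log_anova = TRUE,
                          scale = TRUE, nsim = 1000, n_samples = 1e5,
                          seed = 1L, vm = avian_visual_model()) {
  stopifnot(is.list(data), all(c("tree", "traits", "states", "spectra") %in% names(data)))
  tree <- data$tree
  trait_tab <- tibble::as_tibble(data$traits)
  states <- tibble::as_tibble(data$states)
  trait_tab$species <- normalize_taxa(trait_tab$species)
  states$species <- normalize_taxa(states$species)
  check_taxa(tree$tip.label, trait_tab$species, "trait table")
  check_taxa(tree$tip.label, states$species, "state table")

  points <- species_color_points(data$spectra, vm = vm)
  points <- dplyr::left_join(points, states, by = "species")
  names(points)[names(points) == "state"] <- "category"

  joined <- dplyr::inner_join(trait_tab, points, by = "species")
  pca <- phylo_pca(tree, joined, traits = traits, scale = scale)
  regs <- pic_regression_batch(tree, joined, x = "s", responses = traits)

  grp <- dplyr::inner_join(trait_tab, states, by = "species")
  grp$y_anova <- if (log_anova) log(grp[[anova_trait]]) else grp[[anova_trait]]
  av <- phylo_anova(tree, grp, group = "state", y = "y_anova",
                    nsim = nsim, seed = seed, drop_small = TRUE)
  keep <- grp$state %in% names(which(table(grp$state) >= 2))
  bf <- brown_forsythe(grp[keep, ], group = "state", y = "y_anova")
  kw <- kruskal_wallis(grp[keep, ], group = "state", y = "y_anova")

  overlap <- category_overlap_matrix(points, n_samples = n_samples, seed = seed)

  structure(list(
    color_points = points,
    pca = pca,
    pca_variance = glance(pca),
    pic_regressions = regs,
    anova = av,
    brown_forsythe = bf,
    kruskal_wallis = kw,
    overlap = overlap,
    provenance = list(seed = as.integer(seed), nsim = nsim,
                      n_samples = n_samples, traits = traits,
                      anova_trait = anova_trait, log_anova = log_anova,
                      scale = scale, n_species = length(tree$tip.label))
  ), class = "syndrome_report")
}

#' @export
print.syndrome_report <- function(x, ...) {
  cat("Fruit-syndrome report (", x$provenance$n_species, " species)\n", sep = "")
  ve <- round(100 * x$pca$variance_explained[1:2], 1)
  cat("PC1/PC2 variance explained: ", ve[1], "% / ", ve[2], "%\n", sep = "")
  cat("Phylogenetic ANOVA: F = ", format(x$anova$F, digits = 4),
      ", p = ", format(x$anova$p_phylo, digits = 3), "\n", sep = "")
  invisible(x)
}

check_taxa <- function(tips, species, what) {
  missing_in_tab <- setdiff(tips, species)
  missing_in_tree <- setdiff(species, tips)
  if (length(missing_in_tab) || length(missing_in_tree)) {
    stop("taxa mismatch with ", what,
         if (length(missing_in_tab))
           paste0("; in tree only: ", paste(missing_in_tab, collapse = ", ")),
         if (length(missing_in_tree))
           paste0("; in ", what, " only: ", paste(missing_in_tree, collapse = ", ")),
         call. = FALSE)
  }
}

#' Run the fruit-color evolution analysis
#'
#' Fits the equal-rates, symmetric, all-rates-different and paedomorphy Mk
#' models, ranks them by AICc, reconstructs marginal ancestral states under
#' the best standard model and under the paedomorphy model, runs parsimony
#' under equal (all-ones) costs and under the developmental step matrix,
#' and samples stochastic character maps under the symmetric model to
#' estimate transition counts.
#'
#' @param tree A `phylo` object.
#' @param states Tibble with `species` and `state`, or a named character
#'   vector.
#' @param models Standard models to fit (default ER, SYM, ARD).
#' @param pattern Paedomorphy constraint pattern (default
#'   [build_paedomorphy_pattern()] restricted to the observed states, when
#'   possible).
#' @param step_matrix Parsimony cost matrix (default [build_step_matrix()]).
#' @param simmap_model Model used for the stochastic maps (default `"SYM"`).
#' @param nsim Number of stochastic maps (default 1000).
#' @param seed Integer seed.
#' @return A list of class `color_evolution_report`: `model_table`, `fits`,
#'   `asr_best`, `asr_paedomorphy`, `parsimony_equal`, `parsimony_step`,
#'   `simmap`, `provenance`.
#' @export
run_color_evolution <- function(tree, states, models = c("ER", "SYM", "ARD"),
                                pattern = NULL, step_matrix = NULL,
                                simmap_model = "SYM", nsim = 1000, seed = 1L) {
  if (is.data.frame(states)) {
    states <- stats::setNames(states$state, states$species)
  }
  names(states) <- normalize_taxa(names(states))
  check_taxa(tree$tip.label, names(states), "state table")
  obs <- sort(unique(states))
  cs <- color_states()
  if (!all(obs %in% cs$state)) {
    stop("unknown fruit color state(s): ",
         paste(setdiff(obs, cs$state), collapse = ", "), call. = FALSE)
  }
  # model over all states that are observed or reachable along allowed paths:
  # restrict the default decomposition to the observed categories, keeping
  # the full pattern only when every category occurs
  sub <- cs[cs$state %in% obs, ]
  if (is.null(pattern)) {
    default_pairs <- list(
      c("black-sequential", "black-synchronous"),
      c("black-sequential", "red"),
      c("black-sequential", "yellow"),
      c("black-synchronous", "blue")
    )
    keep <- Filter(function(p) all(p %in% obs), default_pairs)
    pattern <- build_paedomorphy_pattern(sub, allowed = keep)
  }
  if (is.null(step_matrix)) {
    step_matrix <- build_step_matrix(sub)
  }
  st_space <- colnames(pattern)
  fits <- lapply(models, function(m)
    fit_mk(tree, states, model = m, states = st_space, seed = seed))
  names(fits) <- models
  fits$paedomorphy <- fit_mk(tree, states, model = pattern, seed = seed)
  tab <- compare_models(fits)
  best_standard <- tab$model[tab$model != "paedomorphy"][1]
  asr_best <- marginal_asr(tree, states, fits[[best_standard]]$Q)
  asr_paedo <- marginal_asr(tree, states, fits$paedomorphy$Q)
  ones <- matrix(1L, length(obs), length(obs), dimnames = list(obs, obs))
  diag(ones) <- 0L
  pars_equal <- sankoff(tree, states, ones)
  pars_step <- sankoff(tree, states, step_matrix)
  sm <- stochastic_map(tree, states, Q = fits[[simmap_model]]$Q,
                       nsim = nsim, seed = seed, keep_paths = FALSE)
  structure(list(
    model_table = tab,
    fits = fits,
    best_standard = best_standard,
    asr_best = asr_best,
    asr_paedomorphy = asr_paedo,
    parsimony_equal = pars_equal,
    parsimony_step = pars_step,
    simmap = sm,
    provenance = list(seed = as.integer(seed), nsim = nsim,
                      models = c(models, "paedomorphy"),
                      simmap_model = simmap_model,
                      n_tips = length(tree$tip.label))
  ), class = "color_evolution_report")
}

#' @export
print.color_evolution_report <- function(x, ...) {
  cat("Fruit-color evolution report (", x$provenance$n_tips, " tips)\n", sep = "")
  print(x$model_table)
  cat("Best standard model:", x$best_standard, "\n")
  cat("Mean transitions (simmap, nsim = ", x$simmap$nsim, "): ",
      format(x$simmap$mean_total, digits = 4), "\n", sep = "")
  cat("Parsimony cost: equal = ", x$parsimony_equal$min_cost,
      ", step matrix = ", x$parsimony_step$min_cost, "\n", sep = "")
  invisible(x)
}
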