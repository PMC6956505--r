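# Synthetic-data generators: birth-death trees, Mk character histories with
# recorded true change counts, correlated Brownian traits with syndrome
# structure, and parameterised reflectance spectra per fruit color category.
# Every generator is a pure function of its seed.

#' Simulate an ultrametric birth-death tree
#'
#' Birth-death tree conditioned on the number of extant tips (via
#' [ape::rphylo()]), reproducible by seed. Tip labels are `s1 ... sn`.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates, `birth > death >= 0`.
#' @param seed Integer seed.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (!(birth > death && death >= 0)) {
    stop("need birth > death >= 0", call. = FALSE)
  }
  tr <- withr_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  tr$tip.label <- paste0("s", seq_len(n_tips))
  tr
}

#' Simulate a discrete character history on a tree
#'
#' Exact Gillespie simulation of a continuous-time Markov chain along every
#' branch, recording every change, so the true history (and its transition
#' counts) is available as a recovery target for [stochastic_map()].
#'
#' @param tree A `phylo` object.
#' @param Q Generating rate matrix with state dimnames.
#' @param root_state Starting state (name); default the first state.
#' @param seed Integer seed.
#' @return A list: `tip_states` (named character), `node_states`,
#'   `n_changes` (true total), `counts` (K x K true transition counts),
#'   `history` (tibble of per-edge segments), `Q`, `seed`.
#' @export
simulate_mk_history <- function(tree, Q, root_state = NULL, seed = 1L) {
  st <- colnames(Q)
  if (is.null(st)) stop("Q must have state dimnames", call. = FALSE)
  k <- length(st)
  if (is.null(root_state)) root_state <- st[1]
  stopifnot(root_state %in% st)
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  withr_seed(seed, {
    node_state <- integer(n + tr$Nnode)
    node_state[n + 1L] <- match(root_state, st)
    counts <- matrix(0, k, k, dimnames = list(st, st))
    segs <- vector("list", nrow(tr$edge))
    for (e in rev(seq_len(nrow(tr$edge)))) { # preorder
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      cur <- node_state[par]
      t_end <- tr$edge.length[e]
      states <- cur; times <- numeric(0); now <- 0
      repeat {
        rate <- -Q[cur, cur]
        if (rate <= 0) break
        now <- now + stats::rexp(1, rate)
        if (now >= t_end) break
        nxt <- sample.int(k, 1, prob = pmax(Q[cur, ], 0) * (seq_len(k) != cur))
        counts[cur, nxt] <- counts[cur, nxt] + 1
        states <- c(states, nxt); times <- c(times, now)
        cur <- nxt
      }
      node_state[ch] <- cur
      segs[[e]] <- tibble::tibble(edge = e, parent = par, child = ch,
                                  state = st[states],
                                  duration = diff(c(0, times, t_end)))
    }
    list(
      tip_states = stats::setNames(st[node_state[seq_len(n)]], tr$tip.label),
      node_states = st[node_state],
      n_changes = sum(counts),
      counts = counts,
      history = dplyr::bind_rows(segs),
      Q = Q, seed = as.integer(seed)
    )
  })
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Multivariate Brownian motion with trait covariance `Sigma`: across tips,
#' cov(x_a(i), x_b(j)) = Sigma[a, b] * C[i, j] with C the phylogenetic
#' covariance matrix.
#'
#' @param tree A `phylo` object.
#' @param Sigma p x p positive semi-definite trait covariance (per unit
#'   branch length); a scalar is taken as a single trait's rate.
#' @param root_mean Length-p ancestral mean (recycled).
#' @param seed Integer seed.
#' @param trait_names Optional column names.
#' @return A tibble with `species` and p trait columns.
#' @export
simulate_bm_traits <- function(tree, Sigma, root_mean = 0, seed = 1L,
                               trait_names = NULL) {
  if (is.null(dim(Sigma))) Sigma <- matrix(Sigma, 1, 1)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("Sigma is not positive semi-definite", call. = FALSE)
  }
  p <- nrow(Sigma)
  root_mean <- rep_len(root_mean, p)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  Lc <- t(chol(C + diag(1e-12 * max(diag(C), 1), n)))
  Ls <- chol_psd(Sigma)
  X <- withr_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    Lc %*% Z %*% t(Ls)
  })
  X <- sweep(X, 2, root_mean, "+")
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(p))
  colnames(X) <- trait_names
  dplyr::bind_cols(tibble::tibble(species = rownames(C)), tibble::as_tibble(X))
}

# Cholesky-like factor for a PSD (possibly singular) matrix
chol_psd <- function(S) {
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(vals), nrow(S))
}

#' Reflectance spectrum templates per fruit color category
#'
#' Idealised mean reflectance curves on the 5 nm grid: red fruits reflect
#' long wavelengths (logistic edge near 600 nm), blue fruits peak in the
#' short-wave region (Gaussian at 450 nm with a UV shoulder), yellow fruits
#' have an edge near 550 nm, and the two black categories are dark and
#' nearly flat with a slight long-wave rise (black-synchronous marginally
#' darker, as glaucous-dark fruits tend to be).
#'
#' @param category One of the [color_states()] state names (vectorised).
#' @return A tibble with `category`, `wavelength`, `reflectance`.
#' @export
spectrum_template <- function(category) {
  grid <- spectral_grid()
  one <- function(cat) {
    r <- switch(cat,
      "red" = 0.02 + 0.55 / (1 + exp(-(grid - 600) / 12)),
      "yellow" = 0.03 + 0.50 / (1 + exp(-(grid - 550) / 12)),
      "blue" = 0.04 + 0.28 * exp(-0.5 * ((grid - 450) / 40)^2) +
        0.06 * exp(-0.5 * ((grid - 360) / 30)^2),
      "black-sequential" = 0.045 + 0.02 * (grid - 300) / 400,
      "black-synchronous" = 0.035 + 0.015 * (grid - 300) / 400,
      stop("unknown category: ", cat, call. = FALSE)
    )
    tibble::tibble(category = cat, wavelength = grid, reflectance = r)
  }
  dplyr::bind_rows(lapply(category, one))
}

#' Simulate per-fruit reflectance spectra for a set of species
#'
#' Each fruit's spectrum is its category template plus smooth multiplicative
#' brightness noise and band-wise measurement noise (which may dip below
#' zero, as raw spectrometer output does).
#'
#' @param states Named character vector (species -> category) or
#'   `species`/`state` data frame.
#' @param n_per_species Fruits measured per species (default 20).
#' @param noise_sd Band-wise measurement noise SD (default 0.01).
#' @param brightness_sd SD of the per-fruit log-brightness factor (default
#'   0.1).
#' @param seed Integer seed.
#' @return A long tibble: `species`, `category`, `fruit`, `wavelength`,
#'   `reflectance`.
#' @export
simulate_spectra <- function(states, n_per_species = 20, noise_sd = 0.01,
                             brightness_sd = 0.1, seed = 1L) {
  if (is.data.frame(states)) {
    states <- stats::setNames(states$state, states$species)
  }
  grid <- spectral_grid()
  templates <- spectrum_template(unique(states))
  withr_seed(seed, {
    rows <- lapply(names(states), function(sp) {
      tmpl <- templates$reflectance[templates$category == states[[sp]]]
      per_fruit <- lapply(seq_len(n_per_species), function(f) {
        bright <- exp(stats::rnorm(1, 0, brightness_sd))
        refl <- bright * tmpl + stats::rnorm(length(grid), 0, noise_sd)
        tibble::tibble(species = sp, category = states[[sp]], fruit = f,
                       wavelength = grid, reflectance = refl)
      })
      dplyr::bind_rows(per_fruit)
    })
    dplyr::bind_rows(rows)
  })
}

#' Specification of a synthetic fruit-syndrome study
#'
#' Bundles the generating conditions for [simulate_syndrome_dataset()]: tree
#' size and birth-death rates, the symmetric generating rate matrix over the
#' four main color categories, per-category mean shifts for the five
#' syndrome traits (lipid, moisture, pulp volume, endocarp flatness, fruit
#' width), the Brownian covariance around those means, and the reflectance
#' noise levels. Defaults emulate a 29-species study in which blue fruits
#' are high-lipid, low-moisture, with large round endocarps (low pulp
#' volume, low flatness) and red fruits are the watery, flat-endocarp
#' opposite.
#'
#' @param n_species Number of species (default 29).
#' @param birth,death Tree simulation rates.
#' @param mk_rate Symmetric transition rate between categories, per unit of
#'   (unit-depth-rescaled) tree length.
#' @param categories Category set used for the syndrome fixture.
#' @param category_means Data frame of per-category trait means.
#' @param Sigma Brownian trait covariance around the category means.
#' @param n_per_species,noise_sd,brightness_sd Spectra settings.
#' @param seed Mandatory integer seed.
#' @return A list of class `syndrome_spec`.
#' @export
syndrome_spec <- function(n_species = 29, birth = 1, death = 0, mk_rate = 0.15,
                          categories = c("black-sequential", "black-synchronous",
                                         "red", "blue"),
                          category_means = NULL, Sigma = NULL,
                          n_per_species = 20, noise_sd = 0.01,
                          brightness_sd = 0.1, seed = 1L) {
  if (is.null(category_means)) {
    category_means <- tibble::tibble(
      category = c("black-sequential", "black-synchronous", "red", "blue", "yellow"),
      lipid    = c(0.06, 0.10, 0.02, 0.18, 0.03),
      moisture = c(0.78, 0.68, 0.85, 0.55, 0.80),
      pulp_volume = c(0.80, 0.68, 0.85, 0.55, 0.82),
      flatness = c(1.8, 1.5, 2.3, 1.05, 1.9),
      fruit_width = c(8, 7, 7.5, 6, 8)
    )
  }
  if (is.null(Sigma)) {
    # Brownian sd per unit depth, modest relative to the category separation
    sds <- c(lipid = 0.02, moisture = 0.04, pulp_volume = 0.05,
             flatness = 0.25, fruit_width = 1.0)
    Sigma <- diag(sds^2)
    dimnames(Sigma) <- list(names(sds), names(sds))
  }
  structure(list(
    n_species = n_species, birth = birth, death = death, mk_rate = mk_rate,
    categories = categories, category_means = category_means, Sigma = Sigma,
    n_per_species = n_per_species, noise_sd = noise_sd,
    brightness_sd = brightness_sd, seed = as.integer(seed)
  ), class = "syndrome_spec")
}

#' Simulate a complete synthetic fruit-syndrome dataset
#'
#' Simulates a birth-death tree (rescaled to unit depth so rates are
#' comparable across tree sizes), evolves the fruit color category under a
#' symmetric Mk process, draws the five continuous traits as Brownian motion
#' around zero plus the category mean of each tip's state, and generates
#' per-fruit reflectance spectra from the category templates.
#'
#' @param spec A [syndrome_spec()].
#' @return A list: `tree`, `states` (tibble species/state), `traits`
#'   (tibble), `spectra` (long tibble), `history` (true Mk history), `spec`.
#' @export
simulate_syndrome_dataset <- function(spec = syndrome_spec()) {
  stopifnot(inherits(spec, "syndrome_spec"))
  seed <- spec$seed
  tree <- simulate_tree(spec$n_species, spec$birth, spec$death, seed = seed)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  k <- length(spec$categories)
  Q <- matrix(spec$mk_rate, k, k,
              dimnames = list(spec$categories, spec$categories))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # The empirical design this emulates sampled species to span every fruit
  # color category, so condition the simulated history on all categories
  # being represented (stratified-sampling analogue).
  hist <- NULL
  for (j in 0:199) {
    cand <- simulate_mk_history(tree, Q, root_state = spec$categories[1],
                                seed = seed + 1L + 7919L * j)
    if (all(spec$categories %in% cand$tip_states)) { hist <- cand; break }
  }
  if (is.null(hist)) {
    stop("could not simulate a history spanning all categories; ",
         "increase mk_rate or n_species", call. = FALSE)
  }
  traits <- simulate_bm_traits(tree, spec$Sigma, root_mean = 0,
                               seed = seed + 2L,
                               trait_names = colnames(spec$Sigma))
  cm <- spec$category_means
  shift <- cm[match(hist$tip_states[traits$species], cm$category),
              colnames(spec$Sigma), drop = FALSE]
  traits[colnames(spec$Sigma)] <- traits[colnames(spec$Sigma)] + shift
  spectra <- simulate_spectra(hist$tip_states,
                              n_per_species = spec$n_per_species,
                              noise_sd = spec$noise_sd,
                              brightness_sd = spec$brightness_sd,
                              seed = seed + 3L)
  list(
    tree = tree,
    states = tibble::tibble(species = names(hist$tip_states),
                            state = unname(hist$tip_states)),
    traits = traits,
    spectra = spectra,
    history = hist,
    spec = spec
  )
}

#' Simulate a genus-scale discrete color dataset
#'
#' A larger fixture for the color-evolution pipeline: a birth-death tree
#' (default 163 tips, matching a genus-scale study) with a 5-state character
#' simulated under a symmetric Mk model.
#'
#' @param n_tips Number of tips (default 163).
#' @param mk_rate Symmetric transition rate on the unit-depth tree.
#' @param states State set (default the five [color_states()]).
#' @param seed Integer seed.
#' @return A list: `tree`, `states` (tibble), `history`, `Q_true`.
#' @export
simulate_color_dataset <- function(n_tips = 163, mk_rate = 0.1,
                                   states = color_states()$state, seed = 1L) {
  tree <- simulate_tree(n_tips, seed = seed)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  k <- length(states)
  Q <- matrix(mk_rate, k, k, dimnames = list(states, states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  hist <- simulate_mk_history(tree, Q, root_state = states[1], seed = seed + 1L)
  list(
    tree = tree,
    states = tibble::tibble(species = names(hist$tip_states),
                            state = unname(hist$tip_states)),
    history = hist,
    Q_true = Q
  )
}
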