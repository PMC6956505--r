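# Discrete fruit-color evolution: Mk likelihoods by Felsenstein pruning,
# constrained models (including the paedomorphy model), AICc comparison,
# marginal ancestral states, step-matrix (Sankoff) parsimony, and stochastic
# character mapping with transition counts.

#' Fruit color states and their developmental decomposition
#'
#' The five fruit color categories, decomposed into elementary developmental
#' attributes: the sequence of color stages passed through (green, yellow,
#' red, black/blue), whether fruits in an infructescence ripen synchronously,
#' and whether the mature color is a structural blue. Both the paedomorphy
#' transition pattern and the parsimony step matrix are derived from this
#' decomposition, and both are user-overridable.
#'
#' @return A tibble with columns `state`, `final_stage`, `intermediates`
#'   (list of character vectors), `synchronous`, `structural_blue`.
#' @export
color_states <- function() {
  tibble::tibble(
    state = c("black-sequential", "black-synchronous", "red", "yellow", "blue"),
    final_stage = c("black", "black", "red", "yellow", "black"),
    intermediates = list(c("yellow", "red"), character(), character(),
                         character(), character()),
    synchronous = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    structural_blue = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Step matrix from the developmental decomposition
#'
#' The parsimony cost of a transition is the number of elementary
#' developmental changes it requires: replacement of the final color stage
#' counts one loss plus one gain (cost 2), gaining or losing the suite of
#' intermediate color stages counts 1, a change in synchronicity counts 1,
#' and gaining or losing the structural blue color counts 1. Under the
#' default decomposition the black-sequential to blue transition costs 3
#' (loss of intermediates, synchronicity, structural blue) and red to
#' black-synchronous costs 2 (loss of red final stage, gain of black).
#'
#' @param states A decomposition tibble as returned by [color_states()].
#' @return A symmetric integer cost matrix with zero diagonal, dimnames =
#'   states.
#' @export
build_step_matrix <- function(states = color_states()) {
  k <- nrow(states)
  S <- matrix(0L, k, k, dimnames = list(states$state, states$state))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    final_cost <- if (states$final_stage[i] == states$final_stage[j]) 0L else 2L
    inter_cost <- if (setequal(states$intermediates[[i]], states$intermediates[[j]])) 0L else 1L
    sync_cost <- as.integer(states$synchronous[i] != states$synchronous[j])
    blue_cost <- as.integer(states$structural_blue[i] != states$structural_blue[j])
    S[i, j] <- final_cost + inter_cost + sync_cost + blue_cost
  }
  S
}

#' Paedomorphy transition pattern for the Mk model
#'
#' Builds a symmetric rate-constraint pattern allowing only transitions that
#' correspond to a single paedomorphic change (truncation of the final or
#' intermediate color stages) or, for blue, derivation from the
#' black-synchronous state. Disallowed pairs are fixed at rate zero; each
#' allowed pair gets its own symmetric free rate. By default the allowed
#' single-step pairs are black-sequential with each of black-synchronous,
#' red and yellow, plus black-synchronous with blue; black-sequential cannot
#' move directly to blue.
#'
#' @param states A decomposition tibble as returned by [color_states()].
#' @param allowed A list of length-2 character vectors of allowed unordered
#'   state pairs (default as above).
#' @return An integer K x K pattern matrix (0 = disallowed, equal positive
#'   integers share a rate) of class `mk_pattern`.
#' @export
build_paedomorphy_pattern <- function(states = color_states(), allowed = NULL) {
  if (is.null(allowed)) {
    allowed <- list(
      c("black-sequential", "black-synchronous"),
      c("black-sequential", "red"),
      c("black-sequential", "yellow"),
      c("black-synchronous", "blue")
    )
  }
  k <- nrow(states)
  pat <- matrix(0L, k, k, dimnames = list(states$state, states$state))
  for (i in seq_along(allowed)) {
    pr <- allowed[[i]]
    if (length(pr) != 2 || !all(pr %in% states$state)) {
      stop("allowed pairs must be pairs of known states; got: ",
           paste(pr, collapse = ", "), call. = FALSE)
    }
    pat[pr[1], pr[2]] <- i
    pat[pr[2], pr[1]] <- i # the transition pattern is symmetric
  }
  if (all(pat == 0)) stop("empty allowed set gives a non-ergodic (all-zero) model",
                          call. = FALSE)
  structure(pat, class = c("mk_pattern", "matrix"))
}

# constraint pattern for the standard models over states `st`
standard_pattern <- function(model, st) {
  k <- length(st)
  pat <- matrix(0L, k, k, dimnames = list(st, st))
  if (model == "ER") {
    pat[row(pat) != col(pat)] <- 1L
  } else if (model == "SYM") {
    idx <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1L
      pat[i, j] <- idx; pat[j, i] <- idx
    }
  } else if (model == "ARD") {
    off <- which(row(pat) != col(pat))
    pat[off] <- seq_along(off)
  }
  pat
}

# assemble a rate matrix from a pattern and free-rate vector
pattern_to_Q <- function(pat, rates) {
  Q <- matrix(0, nrow(pat), ncol(pat), dimnames = dimnames(pat))
  nz <- pat > 0
  Q[nz] <- rates[pat[nz]]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# transition-probability generator: decompose Q once, then P(t) cheaply.
# Falls back to scaling-and-squaring when the eigenbasis is ill-conditioned.
make_Pt <- function(Q) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (is.null(eg)) NULL else tryCatch(solve(eg$vectors), error = function(e) NULL)
  use_eigen <- !is.null(Vi) && all(is.finite(Mod(Vi))) &&
    max(Mod(eg$vectors %*% Vi - diag(k))) < 1e-8
  if (use_eigen) {
    V <- eg$vectors; Vi <- solve(V); lam <- eg$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) {
      P <- expm_ss(Q * t)
      P[P < 0] <- 0
      P / rowSums(P)
    }
  }
}

# matrix exponential by scaling and squaring with a Taylor core
expm_ss <- function(A, order = 12) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# tip states -> likelihood matrix (n_tip x k); NA or missing = all ones
tip_likelihoods <- function(tree, tip_states, st) {
  n <- length(tree$tip.label)
  L <- matrix(1, n, length(st), dimnames = list(tree$tip.label, st))
  if (is.data.frame(tip_states)) {
    tip_states <- stats::setNames(tip_states$state,
                                  normalize_taxa(tip_states$species))
  } else {
    names(tip_states) <- normalize_taxa(names(tip_states))
  }
  extra <- setdiff(names(tip_states), tree$tip.label)
  if (length(extra)) stop("tip(s) not in tree: ", paste(extra, collapse = ", "),
                          call. = FALSE)
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) stop("no state for tip(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  for (tip in tree$tip.label) {
    s <- tip_states[[tip]]
    if (is.na(s)) next # ambiguous: all states allowed
    ss <- strsplit(as.character(s), "\\s*\\|\\s*")[[1]]
    if (!all(ss %in% st)) {
      stop("unknown state '", s, "' for tip ", tip,
           " (states: ", paste(st, collapse = ", "), ")", call. = FALSE)
    }
    L[tip, ] <- as.numeric(st %in% ss)
  }
  L
}

# Felsenstein pruning pass. Returns per-node partial (conditional)
# likelihoods on the probability scale plus per-node log scalers.
pruning_pass <- function(tree, tipL, Pt) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  m <- tree$Nnode
  k <- ncol(tipL)
  L <- matrix(1, n + m, k)
  L[seq_len(n), ] <- tipL[tree$tip.label, , drop = FALSE]
  logscale <- numeric(n + m)
  Pe <- lapply(tree$edge.length, Pt)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    msg <- as.numeric(Pe[[e]] %*% L[ch, ])
    L[par, ] <- L[par, ] * msg
    logscale[par] <- logscale[par] + logscale[ch]
    mx <- max(L[par, ])
    if (mx > 0 && (mx < 1e-100 || mx > 1e100)) {
      L[par, ] <- L[par, ] / mx
      logscale[par] <- logscale[par] + log(mx)
    }
  }
  list(tree = tree, L = L, logscale = logscale, Pe = Pe,
       root = n + 1L, n_tip = n)
}

#' Log-likelihood of a discrete character under an Mk model
#'
#' Felsenstein's pruning algorithm over an arbitrary (possibly multifurcating)
#' rooted tree, with branch transition probabilities P(t) = exp(Qt) and a
#' root prior (flat by default). Ambiguous tips may be given as
#' `"stateA|stateB"` or `NA` (all states).
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector (names = species) or a data
#'   frame with `species` and `state` columns.
#' @param Q A valid rate matrix (off-diagonals >= 0, rows summing to 0) with
#'   state dimnames.
#' @param root_prior `"flat"` (default) or a numeric prior over states.
#' @return The log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "flat") {
  st <- colnames(Q)
  if (is.null(st)) stop("Q must have state dimnames", call. = FALSE)
  if (any(Q[row(Q) != col(Q)] < 0) || any(abs(rowSums(Q)) > 1e-8)) {
    stop("invalid rate matrix: off-diagonals must be >= 0 and rows sum to 0",
         call. = FALSE)
  }
  tipL <- tip_likelihoods(tree, tip_states, st)
  ll <- mk_loglik_core(tree, tipL, Q, root_prior_vec(root_prior, length(st)))
  if (!is.finite(ll)) {
    stop("non-finite likelihood (check Q and branch lengths)", call. = FALSE)
  }
  ll
}

mk_loglik_core <- function(tree, tipL, Q, prior) {
  pp <- pruning_pass(tree, tipL, make_Pt(Q))
  lroot <- sum(prior * pp$L[pp$root, ])
  log(lroot) + pp$logscale[pp$root]
}

root_prior_vec <- function(root_prior, k) {
  if (identical(root_prior, "flat")) return(rep(1 / k, k))
  stopifnot(is.numeric(root_prior), length(root_prior) == k)
  root_prior / sum(root_prior)
}

#' Small-sample corrected AIC
#'
#' AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1); infinite when n <= k + 1.
#'
#' @param lnL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips).
#' @return AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit an Mk model of discrete character evolution
#'
#' Maximises the pruning log-likelihood over the free rates of a constraint
#' pattern: `"ER"` (one shared rate), `"SYM"` (one rate per unordered pair),
#' `"ARD"` (one per ordered pair), or a custom integer pattern such as the
#' one from [build_paedomorphy_pattern()]. Rates are optimised on the log
#' scale with box constraints and multiple deterministic restarts.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector or `species`/`state` data frame.
#' @param model `"ER"`, `"SYM"`, `"ARD"`, or an integer pattern matrix.
#' @param states State set; defaults to the sorted states observed (plus the
#'   pattern's dimnames for a custom model).
#' @param n_starts Number of optimiser restarts (default 3).
#' @param seed Seed for the restart draws.
#' @param root_prior Passed to [mk_loglik()].
#' @return An object of class `mk_fit`: `model`, `Q`, `rates`, `pattern`,
#'   `lnL`, `k`, `n_tips`, `AICc`, `convergence`.
#' @export
fit_mk <- function(tree, tip_states, model = "ER", states = NULL,
                   n_starts = 3, seed = 1L, root_prior = "flat") {
  if (is.data.frame(tip_states)) {
    obs <- tip_states$state
  } else {
    obs <- tip_states
  }
  obs_states <- sort(unique(unlist(strsplit(stats::na.omit(as.character(obs)), "\\s*\\|\\s*"))))
  if (is.matrix(model)) {
    pat <- model
    st <- colnames(pat)
    if (is.null(st)) stop("custom pattern needs state dimnames", call. = FALSE)
    model_name <- "custom"
    if (inherits(model, "mk_pattern")) model_name <- "paedomorphy"
  } else {
    model_name <- match.arg(model, c("ER", "SYM", "ARD"))
    st <- if (is.null(states)) obs_states else states
    pat <- standard_pattern(model_name, st)
  }
  if (length(obs_states) < 2) {
    stop("need at least 2 distinct observed states for a meaningful fit",
         call. = FALSE)
  }
  if (!all(obs_states %in% st)) {
    stop("observed states missing from the model's state set: ",
         paste(setdiff(obs_states, st), collapse = ", "), call. = FALSE)
  }
  k_par <- max(pat)
  tipL <- tip_likelihoods(tree, tip_states, st)
  prior <- root_prior_vec(root_prior, length(st))
  negll <- function(logr) {
    Q <- pattern_to_Q(pat, exp(logr))
    ll <- tryCatch(mk_loglik_core(tree, tipL, Q, prior),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # characteristic rate: one expected change per total tree length
  r0 <- length(st) / sum(tree$edge.length)
  starts <- withr_seed(seed, {
    s <- matrix(log(r0), n_starts, k_par)
    if (n_starts > 1) {
      s[-1, ] <- s[-1, ] + matrix(stats::rnorm((n_starts - 1) * k_par, 0, 1.5),
                                  n_starts - 1, k_par)
    }
    s
  })
  best <- NULL
  if (k_par == 1) {
    # one free rate: golden-section search avoids the saturation plateau at
    # extreme rates that gradient methods can jump onto
    for (i in seq_len(n_starts)) {
      opt <- stats::optimize(negll, interval = starts[i, 1] + c(-12, 12),
                             tol = 1e-9)
      opt <- list(par = opt$minimum, value = opt$objective, convergence = 0L)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  } else {
    for (i in seq_len(n_starts)) {
      opt <- tryCatch({
        nm <- stats::optim(starts[i, ], negll, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-10))
        stats::optim(nm$par, negll, method = "L-BFGS-B",
                     lower = nm$par - 3, upper = nm$par + 3,
                     control = list(maxit = 500))
      }, error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  if (is.null(best)) stop("optimizer failed to converge in all restarts", call. = FALSE)
  rates <- exp(best$par)
  Q <- pattern_to_Q(pat, rates)
  n <- length(tree$tip.label)
  lnL <- -best$value
  structure(list(
    model = model_name, Q = Q, rates = rates, pattern = pat,
    lnL = lnL, k = k_par, n_tips = n, AICc = aicc(lnL, k_par, n),
    convergence = best$convergence, states = st,
    n_starts = n_starts, seed = as.integer(seed)
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, "): ", length(x$states), " states, ",
      x$n_tips, " tips\n", sep = "")
  cat("lnL = ", format(x$lnL, digits = 6), ", k = ", x$k,
      ", AICc = ", format(x$AICc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @method tidy mk_fit
#' @export
tidy.mk_fit <- function(x, ...) {
  idx <- which(upper.tri(x$pattern) | lower.tri(x$pattern), arr.ind = TRUE)
  out <- tibble::tibble(
    from = x$states[idx[, 1]],
    to = x$states[idx[, 2]],
    parameter = x$pattern[idx],
    rate = x$Q[idx]
  )
  dplyr::arrange(out, .data$from, .data$to)
}

#' @method glance mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lnL = x$lnL, k = x$k,
                 n_tips = x$n_tips, AICc = x$AICc)
}

#' Compare fitted Mk models by AICc
#'
#' @param ... `mk_fit` objects (or a single list of them), all fitted to the
#'   same tips.
#' @return A tibble sorted by AICc (ties broken by fewer parameters) with a
#'   `delta_AICc` column.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "mk_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "mk_fit")))
  ntips <- vapply(fits, `[[`, numeric(1), "n_tips")
  if (length(unique(ntips)) > 1) {
    stop("fits are on differing tip sets", call. = FALSE)
  }
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab <- dplyr::arrange(tab, .data$AICc, .data$k)
  dplyr::mutate(tab, delta_AICc = .data$AICc - .data$AICc[1])
}

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal posterior state probabilities under an Mk model, from
#' combined downward (pruning) and upward partial likelihoods with the given
#' root prior.
#'
#' @inheritParams mk_loglik
#' @return A tibble with `node` (ape numbering, internal nodes only) and one
#'   probability column per state; rows sum to 1.
#' @export
marginal_asr <- function(tree, tip_states, Q, root_prior = "flat") {
  st <- colnames(Q)
  tipL <- tip_likelihoods(tree, tip_states, st)
  pp <- pruning_pass(tree, tipL, make_Pt(Q))
  tr <- pp$tree
  k <- length(st)
  prior <- root_prior_vec(root_prior, k)
  n <- pp$n_tip
  nnode <- tr$Nnode
  # upward ("above") partials, preorder over the postorder-edge list reversed
  A <- matrix(0, n + nnode, k)
  A[pp$root, ] <- prior
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    # parent's partial excluding the subtree of ch
    sib_msg <- A[par, ]
    for (e2 in which(tr$edge[, 1] == par)) {
      if (e2 == e) next
      ch2 <- tr$edge[e2, 2]
      sib_msg <- sib_msg * as.numeric(pp$Pe[[e2]] %*% pp$L[ch2, ])
    }
    A[ch, ] <- as.numeric(sib_msg %*% pp$Pe[[e]])
    mx <- max(A[ch, ])
    if (mx > 0 && mx < 1e-100) A[ch, ] <- A[ch, ] / mx
  }
  nodes <- (n + 1L):(n + nnode)
  probs <- t(vapply(nodes, function(v) {
    w <- if (v == pp$root) prior * pp$L[v, ] else A[v, ] * pp$L[v, ]
    w / sum(w)
  }, numeric(k)))
  colnames(probs) <- st
  dplyr::bind_cols(tibble::tibble(node = nodes), tibble::as_tibble(probs))
}

#' Step-matrix (Sankoff) parsimony
#'
#' Minimum-cost ancestral reconstruction by dynamic programming: the cost of
#' assigning state s to node v is the sum over children of
#' min_t [S(s, t) + cost_child(t)]. Returns the minimum total cost and the
#' set of minimal-cost states at each internal node (argmins propagated from
#' the root).
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector or `species`/`state` data frame.
#' @param S A symmetric non-negative cost matrix with zero diagonal and
#'   state dimnames (default [build_step_matrix()]).
#' @return A list with `min_cost`, `node_costs` (tibble: node x per-state
#'   cost), and `node_states` (tibble: node, list-column `states` of
#'   minimal-cost assignments).
#' @export
sankoff <- function(tree, tip_states, S = build_step_matrix()) {
  st <- colnames(S)
  if (any(S < 0) || any(diag(S) != 0)) {
    stop("step matrix must be non-negative with zero diagonal", call. = FALSE)
  }
  tipL <- tip_likelihoods(tree, tip_states, st) # reuse validation/ambiguity
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label); nnode <- tr$Nnode; k <- length(st)
  cost <- matrix(0, n + nnode, k)
  cost[seq_len(n), ] <- ifelse(tipL[tr$tip.label, , drop = FALSE] > 0, 0, Inf)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    msg <- vapply(seq_len(k), function(s) min(S[s, ] + cost[ch, ]), numeric(1))
    cost[par, ] <- cost[par, ] + msg
  }
  root <- n + 1L
  min_cost <- min(cost[root, ])
  # propagate optimal state sets down from the root
  opt <- vector("list", n + nnode)
  opt[[root]] <- which(cost[root, ] == min_cost)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sel <- logical(k)
    for (s in opt[[par]]) {
      tot <- S[s, ] + cost[ch, ]
      sel[tot == min(tot)] <- TRUE
    }
    opt[[ch]] <- which(sel)
  }
  nodes <- (n + 1L):(n + nnode)
  list(
    min_cost = min_cost,
    node_costs = dplyr::bind_cols(
      tibble::tibble(node = nodes),
      tibble::as_tibble(`colnames<-`(cost[nodes, , drop = FALSE], st))
    ),
    node_states = tibble::tibble(
      node = nodes,
      states = lapply(nodes, function(v) st[opt[[v]]])
    )
  )
}

#' Stochastic character mapping
#'
#' Samples complete character histories consistent with the tip data and an
#' Mk model: joint node states are drawn from their conditional
#' distributions (root from its marginal, then each child given its parent),
#' and each branch path is simulated conditional on its endpoints by
#' rejection sampling with a uniformization fallback. Transition counts are
#' averaged over the samples.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector or `species`/`state` data frame.
#' @param Q Optional rate matrix; if `NULL` an Mk model is fitted first.
#' @param model Model to fit when `Q` is `NULL` (default `"SYM"`).
#' @param nsim Number of sampled histories (default 100).
#' @param seed Integer seed.
#' @param root_prior Passed to the likelihood machinery.
#' @param keep_paths Keep per-edge state segments for each sample (default
#'   TRUE).
#' @return An object of class `simmap_result`: `mean_counts` (K x K matrix of
#'   average transition counts), `mean_total`, `counts` (per-sample total),
#'   `samples` (list of per-edge segment tibbles if `keep_paths`), `Q`,
#'   `nsim`, `seed`.
#' @export
stochastic_map <- function(tree, tip_states, Q = NULL, model = "SYM",
                           nsim = 100, seed = 1L, root_prior = "flat",
                           keep_paths = TRUE) {
  if (is.null(Q)) {
    fit <- fit_mk(tree, tip_states, model = model, seed = seed)
    Q <- fit$Q
  }
  st <- colnames(Q)
  k <- length(st)
  tipL <- tip_likelihoods(tree, tip_states, st)
  Pt <- make_Pt(Q)
  pp <- pruning_pass(tree, tipL, Pt)
  tr <- pp$tree
  n <- pp$n_tip
  prior <- root_prior_vec(root_prior, k)
  root_w <- prior * pp$L[pp$root, ]
  edges_rev <- rev(seq_len(nrow(tr$edge))) # preorder traversal
  count_mats <- vector("list", nsim)
  samples <- if (keep_paths) vector("list", nsim) else NULL
  withr_seed(seed, {
    for (s in seq_len(nsim)) {
      node_state <- integer(n + tr$Nnode)
      node_state[pp$root] <- sample.int(k, 1, prob = root_w)
      counts <- matrix(0, k, k, dimnames = list(st, st))
      segs <- if (keep_paths) vector("list", nrow(tr$edge)) else NULL
      for (e in edges_rev) {
        par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        w <- pp$Pe[[e]][node_state[par], ] * pp$L[ch, ]
        node_state[ch] <- sample.int(k, 1, prob = w)
        path <- sample_branch_path(Q, node_state[par], node_state[ch],
                                   tr$edge.length[e], Pt)
        if (length(path$states) > 1) {
          for (i in seq_len(length(path$states) - 1)) {
            counts[path$states[i], path$states[i + 1]] <-
              counts[path$states[i], path$states[i + 1]] + 1
          }
        }
        if (keep_paths) {
          segs[[e]] <- tibble::tibble(
            edge = e, parent = par, child = ch,
            state = st[path$states], duration = path$durations
          )
        }
      }
      count_mats[[s]] <- counts
      if (keep_paths) samples[[s]] <- dplyr::bind_rows(segs)
    }
  })
  totals <- vapply(count_mats, sum, numeric(1))
  mean_counts <- Reduce(`+`, count_mats) / nsim
  structure(list(
    mean_counts = mean_counts, mean_total = mean(totals), counts = totals,
    samples = samples, Q = Q, nsim = nsim, seed = as.integer(seed),
    states = st
  ), class = "simmap_result")
}

#' @export
print.simmap_result <- function(x, ...) {
  cat("Stochastic character mapping:", x$nsim, "sampled histories\n")
  cat("Mean total transitions:", format(x$mean_total, digits = 4), "\n")
  invisible(x)
}

# Simulate a CTMC path on one branch conditional on both endpoints.
# Rejection sampling of forward paths; uniformization fallback after `cap`
# failed attempts.
sample_branch_path <- function(Q, a, b, t, Pt, cap = 500) {
  k <- nrow(Q)
  if (t <= 0) {
    if (a != b) stop("state change required across a zero-length branch", call. = FALSE)
    return(list(states = a, durations = 0))
  }
  for (try in seq_len(cap)) {
    states <- a; times <- numeric(0)
    cur <- a; now <- 0
    repeat {
      rate <- -Q[cur, cur]
      if (rate <= 0) break
      now <- now + stats::rexp(1, rate)
      if (now >= t) break
      nxt <- sample.int(k, 1, prob = pmax(Q[cur, ], 0) * (seq_len(k) != cur))
      states <- c(states, nxt); times <- c(times, now)
      cur <- nxt
    }
    if (cur == b) {
      bounds <- c(0, times, t)
      return(list(states = states, durations = diff(bounds)))
    }
  }
  uniformization_path(Q, a, b, t)
}

# endpoint-conditioned path via uniformization
uniformization_path <- function(Q, a, b, t, nmax = 200) {
  k <- nrow(Q)
  mu <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(k) + Q / mu
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1]] <- Rpow[[i]] %*% R
  Pab <- Re(expm_ss(Q * t))[a, b]
  if (Pab <= 0) stop("impossible endpoint combination on branch", call. = FALSE)
  logw <- vapply(0:nmax, function(nn)
    stats::dpois(nn, mu * t, log = TRUE) + log(max(Rpow[[nn + 1]][a, b], 0)),
    numeric(1))
  w <- exp(logw - max(logw)); w[!is.finite(w)] <- 0
  nn <- sample(0:nmax, 1, prob = w)
  if (nn == 0) return(list(states = a, durations = t))
  # sample the jump chain conditioned on endpoints
  chain <- integer(nn + 1); chain[1] <- a; chain[nn + 1] <- b
  if (nn > 1) {
    for (i in 2:nn) {
      rem <- nn + 1 - i # remaining R-steps to reach b
      p <- R[chain[i - 1], ] * vapply(seq_len(k), function(s2) Rpow[[rem + 1]][s2, b], numeric(1))
      chain[i] <- sample.int(k, 1, prob = pmax(p, 0))
    }
  }
  jump_times <- sort(stats::runif(nn, 0, t))
  # drop virtual (self) jumps
  keep <- c(TRUE, chain[-1] != chain[-(nn + 1)])
  states <- chain[keep]
  bounds <- c(0, jump_times[keep[-1]], t)
  list(states = states, durations = diff(bounds))
}
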