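# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct path sums, and
# closed forms.

# log-likelihood of a discrete character by exhaustive enumeration over all
# internal-node state assignments (small trees only)
enum_mk_loglik <- function(tree, tip_states, Q, prior = NULL) {
  st <- colnames(Q)
  k <- length(st)
  if (is.null(prior)) prior <- rep(1 / k, k)
  Pfun <- function(t) {
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * t), k) %*% solve(e$vectors))
  }
  Pe <- lapply(tree$edge.length, Pfun)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_idx <- match(tip_states[tree$tip.label], st)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign_state <- c(tip_idx, combos[r, ])
    lik <- prior[assign_state[n + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_state[tree$edge[e, 1]]
      b <- assign_state[tree$edge[e, 2]]
      lik <- lik * Pe[[e]][a, b]
    }
    total <- total + lik
  }
  log(total)
}

# phylogenetic covariance by per-pair MRCA path enumeration (no vcv call)
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  # path of nodes from root to each tip, with cumulative depths
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    p <- v
    while (v != root) { v <- parent[v]; p <- c(p, v) }
    p
  }
  depth <- function(v) {
    d <- 0
    while (v != root) { d <- d + elen[v]; v <- parent[v] }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    common <- intersect(path_to_root(i), path_to_root(j))
    mrca <- common[which.max(vapply(common, depth, numeric(1)))]
    C[i, j] <- depth(mrca)
  }
  C
}

# all pairwise tip distances via per-pair path sums
brute_tip_distances <- function(tree) {
  C <- brute_vcv(tree)
  d <- outer(diag(C), diag(C), "+") - 2 * C
  d
}

# a random tree with random tip states over `states`
random_instance <- function(n_tips, states, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tips <- setNames(sample(states, n_tips, replace = TRUE), tr$tip.label)
  list(tree = tr, tips = tips)
}

# random valid rate matrix over states
random_Q <- function(states, seed, lo = 0.2, hi = 1.5) {
  set.seed(seed)
  k <- length(states)
  Q <- matrix(runif(k * k, lo, hi), k, k, dimnames = list(states, states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}
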