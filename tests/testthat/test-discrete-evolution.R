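test_that("state decomposition yields the printed step costs and a metric", {
  S <- build_step_matrix()
  expect_equal(S["black-sequential", "blue"], 3)
  expect_equal(S["red", "black-synchronous"], 2)
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(0L, 5))
  st <- colnames(S)
  for (a in st) for (b in st) for (cc in st) {
    expect_lte(S[a, cc], S[a, b] + S[b, cc])
  }
})

test_that("paedomorphy pattern allows truncation steps and forbids direct blue", {
  pat <- build_paedomorphy_pattern()
  expect_equal(pat["black-sequential", "blue"], 0L)
  expect_gt(pat["black-sequential", "red"], 0L)
  expect_gt(pat["black-sequential", "yellow"], 0L)
  expect_gt(pat["black-synchronous", "blue"], 0L)
  expect_true(isSymmetric(unname(unclass(pat))))
  expect_error(build_paedomorphy_pattern(allowed = list()), "non-ergodic")
  expect_error(build_paedomorphy_pattern(allowed = list(c("red", "green"))), "known states")
})

test_that("pruning likelihood equals exhaustive enumeration", {
  # closed form on a cherry: 2 states, symmetric rate
  q <- 0.3; t1 <- 0.8; t2 <- 1.2
  tr <- read_tree(sprintf("(A:%g,B:%g):0;", t1, t2))
  Q <- matrix(c(-q, q, q, -q), 2, dimnames = list(c("0", "1"), c("0", "1")))
  p_same <- function(t) 0.5 + 0.5 * exp(-2 * q * t)
  lik <- 0.5 * p_same(t1) * p_same(t2) +
    0.5 * (1 - p_same(t1)) * (1 - p_same(t2))
  expect_equal(mk_loglik(tr, c(A = "0", B = "0"), Q), log(lik), tolerance = 1e-12)

  # random instances vs the enumeration oracle
  for (i in 1:25) {
    inst <- random_instance(n_tips = sample(3:5, 1), states = c("a", "b", "c"),
                            seed = 100 + i)
    Q <- random_Q(c("a", "b", "c"), seed = 200 + i)
    ll <- mk_loglik(inst$tree, inst$tips, Q)
    expect_equal(ll, enum_mk_loglik(inst$tree, inst$tips, Q), tolerance = 1e-10)
  }

  # rate -> 0 with identical tips: likelihood -> 1/K
  trc <- read_tree("(A:1,(B:1,C:1):1):0;")
  Q0 <- random_Q(c("a", "b", "c"), seed = 1) * 1e-10
  expect_equal(mk_loglik(trc, c(A = "a", B = "a", C = "a"), Q0), log(1 / 3),
               tolerance = 1e-6)
})

test_that("likelihood handles polytomies and ambiguous tips", {
  tr <- read_tree("(A:1,B:1,C:1,D:1):0;") # star polytomy
  Q <- random_Q(c("a", "b"), seed = 3)
  ll <- mk_loglik(tr, c(A = "a", B = "a", C = "b", D = "b"), Q)
  expect_true(is.finite(ll))
  # an ambiguous tip's likelihood is the sum over its allowed states
  tr2 <- read_tree("(A:1,(B:1,C:1):1):0;")
  ll_amb <- mk_loglik(tr2, c(A = "a", B = "a|b", C = "b"), Q)
  lls <- sapply(c("a", "b"), function(s)
    mk_loglik(tr2, c(A = "a", B = s, C = "b"), Q))
  expect_equal(exp(ll_amb), sum(exp(lls)), tolerance = 1e-10)
  expect_error(mk_loglik(tr2, c(A = "a", B = "b"), Q), "no state")
})

test_that("AICc formula and model comparison ordering", {
  expect_equal(aicc(-100, 2, 29), 204 + 12 / 26)
  expect_equal(aicc(-10, 5, 6), Inf)

  f1 <- structure(list(model = "m1", lnL = -50, k = 2, n_tips = 30,
                       AICc = aicc(-50, 2, 30)), class = "mk_fit")
  f2 <- structure(list(model = "m2", lnL = -48.61, k = 5, n_tips = 30,
                       AICc = aicc(-50, 2, 30)), class = "mk_fit")
  tab <- compare_models(f1, f2)
  expect_equal(tab$model, c("m1", "m2")) # equal AICc: fewer parameters first
  expect_equal(tab$delta_AICc, c(0, 0))
  f3 <- structure(list(model = "m3", lnL = -50, k = 2, n_tips = 40,
                       AICc = 1), class = "mk_fit")
  expect_error(compare_models(f1, f3), "differing tip sets")
})

test_that("SYM never fits worse than ER (nesting), and fits recover structure", {
  d <- simulate_color_dataset(n_tips = 80, mk_rate = 0.3, seed = 21)
  fe <- fit_mk(d$tree, d$states, "ER", seed = 1)
  fs <- fit_mk(d$tree, d$states, "SYM", seed = 1)
  expect_gte(fs$lnL, fe$lnL - 1e-4)
  expect_equal(fe$k, 1)
  st <- sort(unique(d$states$state))
  expect_equal(fs$k, length(st) * (length(st) - 1) / 2)
  # rows of the fitted Q sum to zero
  expect_equal(unname(rowSums(fe$Q)), rep(0, length(st)), tolerance = 1e-12)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  d <- simulate_color_dataset(n_tips = 40, mk_rate = 0.4, seed = 22)
  fe <- fit_mk(d$tree, d$states, "ER", seed = 1)
  x <- setNames(d$states$state, d$states$species)
  ref <- phytools::fitMk(d$tree, x, model = "ER", pi = "equal")
  expect_equal(fe$lnL, ref$logLik, tolerance = 1e-3)
})

test_that("marginal ancestral states match brute-force posteriors", {
  for (i in 1:5) {
    inst <- random_instance(4, c("a", "b"), seed = 300 + i)
    Q <- random_Q(c("a", "b"), seed = 400 + i)
    asr <- marginal_asr(inst$tree, inst$tips, Q)
    expect_equal(rowSums(as.matrix(asr[, -1])), rep(1, nrow(asr)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # brute force: posterior of each internal node by enumeration
    st <- c("a", "b")
    n <- 4
    combos <- expand.grid(rep(list(st), inst$tree$Nnode), stringsAsFactors = FALSE)
    Pfun <- function(t) { e <- eigen(Q); Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)) }
    Pe <- lapply(inst$tree$edge.length, Pfun)
    w <- apply(combos, 1, function(cmb) {
      assign_state <- c(match(inst$tips[inst$tree$tip.label], st), match(cmb, st))
      lik <- 0.5
      for (e in seq_len(nrow(inst$tree$edge))) {
        lik <- lik * Pe[[e]][assign_state[inst$tree$edge[e, 1]],
                             assign_state[inst$tree$edge[e, 2]]]
      }
      lik
    })
    for (v in asr$node) {
      col <- combos[, v - n]
      post_a <- sum(w[col == "a"]) / sum(w)
      expect_equal(asr$a[asr$node == v], post_a, tolerance = 1e-8)
    }
  }
})

test_that("marginal ASR limits: near-zero rate and symmetric star trees", {
  tr <- read_tree("(A:1,B:1):0;")
  Q <- matrix(c(-1, 1, 1, -1) * 1e-6, 2, dimnames = list(c("x", "y"), c("x", "y")))
  asr <- marginal_asr(tr, c(A = "x", B = "x"), Q)
  expect_gt(asr$x[1], 0.999)

  star <- read_tree("(A:1,B:1,C:1,D:1):0;")
  Qer <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2, dimnames = list(c("x", "y"), c("x", "y")))
  asr2 <- marginal_asr(star, c(A = "x", B = "x", C = "y", D = "y"), Qer)
  expect_equal(asr2$x[1], 0.5, tolerance = 1e-10)
})

test_that("Sankoff parsimony: printed costs, Fitch equivalence, cost scaling", {
  S <- build_step_matrix()
  cherry <- read_tree("(A:1,B:1):0;")
  expect_equal(sankoff(cherry, c(A = "black-sequential", B = "blue"), S)$min_cost, 3)
  expect_equal(sankoff(cherry, c(A = "red", B = "black-synchronous"), S)$min_cost, 2)
  expect_equal(sankoff(cherry, c(A = "red", B = "red"), S)$min_cost, 0)

  skip_if_not_installed("phangorn")
  for (i in 1:25) {
    inst <- random_instance(8, c("a", "b", "c"), seed = 500 + i)
    ones <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    diag(ones) <- 0
    got <- sankoff(inst$tree, inst$tips, ones)$min_cost
    dat <- phangorn::phyDat(matrix(inst$tips[inst$tree$tip.label], ncol = 1,
                                   dimnames = list(inst$tree$tip.label, NULL)),
                            type = "USER", levels = c("a", "b", "c"))
    expect_equal(got, phangorn::fitch(inst$tree, dat))
    # uniform scaling of the step matrix scales the cost linearly
    expect_equal(sankoff(inst$tree, inst$tips, 3 * ones)$min_cost, 3 * got)
  }
})

test_that("stochastic maps respect endpoints and count transitions sensibly", {
  # cherry with differing states: every sample has >= 1 transition
  cherry <- read_tree("(A:1,B:1):0;")
  Q <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2, dimnames = list(c("x", "y"), c("x", "y")))
  sm <- stochastic_map(cherry, c(A = "x", B = "y"), Q = Q, nsim = 50, seed = 9)
  expect_true(all(sm$counts >= 1))
  expect_gte(sm$mean_total, 1)

  # near-zero rate, uniform tips: essentially no transitions
  sm0 <- stochastic_map(cherry, c(A = "x", B = "x"), Q = Q * 1e-8, nsim = 20, seed = 9)
  expect_lt(sm0$mean_total, 0.01)

  # segment durations on each edge sum to the branch length
  d <- simulate_color_dataset(n_tips = 20, mk_rate = 0.4, seed = 23)
  sm2 <- stochastic_map(d$tree, d$states, Q = d$Q_true, nsim = 5, seed = 2,
                        keep_paths = TRUE)
  tr_post <- ape::reorder.phylo(d$tree, "postorder")
  for (s in sm2$samples) {
    sums <- tapply(s$duration, s$edge, sum)
    expect_equal(as.numeric(sums[as.character(seq_len(nrow(tr_post$edge)))]),
                 tr_post$edge.length, tolerance = 1e-9)
  }
  # determinism given the seed
  sm3 <- stochastic_map(d$tree, d$states, Q = d$Q_true, nsim = 5, seed = 2,
                        keep_paths = TRUE)
  expect_identical(sm2$counts, sm3$counts)
})

test_that("single-branch transition counts follow the Poisson expectation", {
  # cherry with one near-zero, state-ambiguous tip isolates a single branch
  # of length t with only its far endpoint observed: for small q*t the mean
  # number of changes approaches q*t
  q <- 0.05; t <- 2
  tr <- read_tree(sprintf("(A:%g,B:1e-9):0;", t))
  Q <- matrix(c(-q, q, q, -q), 2, dimnames = list(c("x", "y"), c("x", "y")))
  sm <- stochastic_map(tr, c(A = "x", B = NA), Q = Q, nsim = 4000, seed = 10)
  # direct path-simulation oracle: flat root, forward simulation,
  # conditioned on ending in the observed tip state
  set.seed(10)
  sim_counts <- replicate(8000, {
    n_ch <- 0; cur <- sample(1:2, 1); now <- 0
    repeat {
      now <- now + rexp(1, q)
      if (now >= t) break
      n_ch <- n_ch + 1
      cur <- 3 - cur
    }
    if (cur == 1) n_ch else NA # condition on the observed endpoint "x"
  })
  oracle <- mean(sim_counts, na.rm = TRUE)
  expect_equal(sm$mean_total, oracle, tolerance = 0.35)
  expect_lt(abs(sm$mean_total - q * t), 0.05)
})
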