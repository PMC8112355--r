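test_that("tree and state-table input is validated", {
  tr <- read_support_tree("((A:1,B:1):1,C:2);",
                          data.frame(tip = c("A", "B", "C"),
                                     state = c("strong", "weak", "none")))
  expect_length(tr$phy$tip.label, 3)
  expect_identical(unname(tr$states["C"]), "none")
  expect_error(read_support_tree("((A:1,B:1):1,C:2);",
                                 c(A = "strong", B = "weak")), "C")
  expect_error(read_support_tree("((A:1,B:0):1,C:2);",
                                 c(A = "strong", B = "weak", C = "none")),
               "branch length")
  # polytomies are accepted
  tr2 <- read_support_tree("(A:1,B:1,C:1,D:1);",
                           c(A = "strong", B = "weak", C = "none",
                             D = "strong"))
  expect_silent(loglik_sym(tr2, sym_model(rates = 0.3)))
})

test_that("a single tip carries only the prior", {
  tr <- read_support_tree("(A:1);", c(A = "weak"))
  expect_equal(loglik_sym(tr, sym_model(rates = 0.7)), log(1 / 3),
               tolerance = 1e-12)
})

test_that("two-tip likelihood matches the closed-form two-state solution", {
  for (q in c(0.1, 0.5, 2)) for (t12 in list(c(0.7, 1.3), c(0.2, 0.2))) {
    tr_d <- read_support_tree(sprintf("(A:%g,B:%g);", t12[1], t12[2]),
                              c(A = "x", B = "y"))
    tr_s <- read_support_tree(sprintf("(A:%g,B:%g);", t12[1], t12[2]),
                              c(A = "x", B = "x"))
    m <- sym_model(c("x", "y"), q)
    tt <- sum(t12)
    expect_equal(loglik_sym(tr_d, m), log(0.5 * 0.5 * (1 - exp(-2 * q * tt))),
                 tolerance = 1e-10)
    expect_equal(loglik_sym(tr_s, m), log(0.5 * 0.5 * (1 + exp(-2 * q * tt))),
                 tolerance = 1e-10)
  }
})

test_that("discordant tips drive the likelihood to zero as rates vanish", {
  tr <- read_support_tree("(A:1,B:1);", c(A = "x", B = "y"))
  ll <- vapply(c(1e-1, 1e-3, 1e-5, 1e-7),
               function(q) loglik_sym(tr, sym_model(c("x", "y"), q)), 0)
  expect_true(all(diff(ll) < 0))
  expect_lt(ll[4], -10)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(20)
  states <- c("none", "weak", "strong")
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    g <- gen_tree_characters(n, rates = runif(3, 0.1, 2), seed = 300 + rep)
    m <- g$model
    ll <- loglik_sym(g$tree, m)
    bl <- oracle_loglik(g$tree$phy, g$tree$states, states, m$Q)
    expect_equal(ll, bl, tolerance = 1e-10, label = paste("rep", rep))
  }
})

test_that("likelihood is invariant under consistent state relabeling", {
  g <- gen_tree_characters(12, rates = c(0.3, 0.8, 1.4), seed = 77)
  states <- c("none", "weak", "strong")
  perm <- c(2, 3, 1)
  relab <- stats::setNames(states[perm], states)
  tr2 <- g$tree
  tr2$states <- stats::setNames(relab[g$tree$states], names(g$tree$states))
  # rates indexed by unordered pairs must be permuted accordingly
  pair_idx <- function(i, j, k) {
    a <- min(i, j); b <- max(i, j)
    (a - 1) * k - a * (a - 1) / 2 + (b - a)
  }
  k <- 3
  new_rates <- numeric(3)
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    new_rates[pair_idx(perm[i], perm[j], k)] <-
      g$model$rates[pair_idx(i, j, k)]
  m2 <- sym_model(states, new_rates)
  expect_equal(loglik_sym(tr2, m2), loglik_sym(g$tree, g$model),
               tolerance = 1e-10)
})

test_that("uniform-state data pins fitted rates at the lower bound", {
  tr <- read_support_tree("((A:1,B:1):1,(C:1,D:1):1);",
                          c(A = "x", B = "x", C = "x", D = "x"))
  expect_warning(fit <- fit_sym_ml(tr, states = c("x", "y")),
                 "unidentifiable")
  expect_equal(unname(fit$model$rates[1]), 1e-8)
})

test_that("the ML fit dominates the generating model on simulated data", {
  for (rep in 1:5) {
    g <- gen_tree_characters(32, rates = 0.5, seed = 400 + rep)
    fit <- fit_sym_ml(g$tree, states = c("none", "weak", "strong"),
                      equal_rates = TRUE, n_starts = 3)
    expect_gte(fit$loglik, loglik_sym(g$tree, g$model) - 1e-6)
  }
})

test_that("history sampling is seed-reproducible and tip-consistent", {
  g <- gen_tree_characters(10, rates = 0.8, seed = 9)
  h1 <- sample_histories(g$tree, g$model, n = 25, seed = 123)
  h2 <- sample_histories(g$tree, g$model, n = 25, seed = 123)
  f1 <- tempfile(); f2 <- tempfile(); on.exit(unlink(c(f1, f2)))
  write_history_jsonl(h1, f1); write_history_jsonl(h2, f2)
  expect_identical(readLines(f1), readLines(f2))
  h3 <- sample_histories(g$tree, g$model, n = 25, seed = 124)
  expect_false(identical(readLines(f1), {
    f3 <- tempfile(); write_history_jsonl(h3, f3)
    on.exit(unlink(f3), add = TRUE); readLines(f3)
  }))
  # tip states in every history match the data; branch event endpoints chain
  for (hist in h1$histories) {
    expect_identical(hist$node_states[names(g$tree$states)], g$tree$states)
    if (nrow(hist$events))
      for (e in split(hist$events, hist$events$edge)) {
        expect_true(all(e$from[-1] == e$to[-nrow(e)]))
        expect_identical(e$to[nrow(e)],
                         unname(hist$node_states[e$child[1]]))
      }
  }
})

test_that("near-zero rates give constant histories", {
  tr <- read_support_tree("((A:1,B:1):1,C:2);",
                          c(A = "weak", B = "weak", C = "weak"))
  m <- sym_model(rates = 1e-9)
  h <- sample_histories(tr, m, n = 50, seed = 1)
  fr <- node_state_frequencies(h)
  expect_true(all(fr[, "weak"] == 1))
  expect_true(all(vapply(h$histories, function(x) nrow(x$events) == 0, TRUE)))
})

test_that("sampled node frequencies match brute-force marginal posteriors", {
  states <- c("none", "weak", "strong")
  for (rep in 1:3) {
    g <- gen_tree_characters(5, rates = c(0.4, 0.9, 1.6), seed = 500 + rep)
    n <- 2500
    h <- sample_histories(g$tree, g$model, n = n, seed = rep)
    fr <- node_state_frequencies(h)
    post <- oracle_marginals(g$tree$phy, g$tree$states, states, g$model$Q)
    for (nd in rownames(post)) for (s in states) {
      se <- sqrt(max(post[nd, s] * (1 - post[nd, s]), 1e-6) / n)
      expect_lt(abs(fr[nd, s] - post[nd, s]), 4 * se + 1e-9)
    }
    expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-12)
  }
})

test_that("sampled frequencies agree with an independent mapping implementation", {
  skip_if_not_installed("phytools")
  g <- gen_tree_characters(8, rates = 0.7, seed = 31)
  states <- c("none", "weak", "strong")
  Q <- g$model$Q[states, states]
  X <- phytools::to.matrix(g$tree$states, states)[g$tree$phy$tip.label, ]
  sm <- phytools::make.simmap(g$tree$phy, X, Q = Q, nsim = 600,
                              pi = stats::setNames(rep(1 / 3, 3), states),
                              message = FALSE)
  dd <- phytools::describe.simmap(sm)
  ours <- sample_histories(g$tree, g$model, n = 600, seed = 5)
  fr <- node_state_frequencies(ours)[, states]
  theirs <- dd$ace[seq_len(nrow(fr)), states, drop = FALSE]
  expect_lt(max(abs(fr - theirs)), 0.08)
})

test_that("MRCA lookup addresses internal nodes", {
  g <- gen_tree_characters(8, rates = 0.5, seed = 12)
  h <- sample_histories(g$tree, g$model, n = 5, seed = 2)
  nd <- mrca_node(h, g$tree$phy$tip.label[1:3])
  expect_true(nd %in% rownames(node_state_frequencies(h)))
  expect_error(mrca_node(h, g$tree$phy$tip.label[1]), "two tips")
})
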