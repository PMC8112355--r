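# Stochastic character mapping of pathway-support states under a
# symmetric-rates CTMC (SYM): Felsenstein pruning likelihood with per-node
# scaling, bounded multi-start ML rate fitting, exact conditional history
# sampling (node states by backward sampling, within-branch paths by
# uniformization), and ancestral node state frequencies.

#' Symmetric-rates CTMC model
#'
#' `k` states with symmetric exchange rates `q_ij = q_ji` (one free rate per
#' unordered state pair, row order `(1,2), (1,3), ..., (k-1,k)`); generator
#' rows sum to zero and the stationary (root) distribution is uniform.
#'
#' @param states character vector of state names (default the pathway
#'   support states `none`, `weak`, `strong`).
#' @param rates numeric vector of length `k(k-1)/2` (recycled if length 1).
#' @return object of class `sym_model` with elements `states`, `rates`, `Q`.
#' @export
sym_model <- function(states = c("none", "weak", "strong"), rates = 1) {
  k <- length(states)
  np <- k * (k - 1) / 2
  if (length(rates) == 1) rates <- rep(rates, np)
  stopifnot(length(rates) == np, all(rates >= 0))
  Q <- matrix(0, k, k, dimnames = list(states, states))
  idx <- 1L
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    Q[i, j] <- Q[j, i] <- rates[idx]
    idx <- idx + 1L
  }
  diag(Q) <- -rowSums(Q)
  structure(list(states = states, rates = rates, Q = Q,
                 prior = rep(1 / k, k)),
            class = "sym_model")
}

#' @export
print.sym_model <- function(x, ...) {
  cat(sprintf("<sym_model> %d states (%s); rates: %s\n", length(x$states),
              paste(x$states, collapse = ", "),
              paste(signif(x$rates, 4), collapse = ", ")))
  invisible(x)
}

# transition probability matrix exp(Qt) through the symmetric eigensystem
sym_pmat <- function(model, t) {
  e <- model$eig %||% eigen(model$Q, symmetric = TRUE)
  P <- e$vectors %*% (t(e$vectors) * exp(e$values * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# precompute the eigensystem once for repeated P(t) evaluations
with_eig <- function(model) {
  model$eig <- eigen(model$Q, symmetric = TRUE)
  model
}

#' Read a tree plus tip support states
#'
#' @param tree a newick file path, newick string, or `ape::phylo` object;
#'   branch lengths required and strictly positive; polytomies accepted.
#' @param states data frame with columns `tip` and `state`, or a named
#'   character vector; must cover every tip.
#' @return list of class `support_tree` with `phy` (the `phylo`) and
#'   `states` (named character vector over tips).
#' @export
read_support_tree <- function(tree, states) {
  phy <- if (inherits(tree, "phylo")) tree
         else if (length(tree) == 1 && file.exists(tree)) ape::read.tree(tree)
         else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse newick tree")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length <= 0))
    stop("non-positive branch length on ", sum(phy$edge.length <= 0), " edge(s)")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  st <- if (is.data.frame(states)) stats::setNames(states$state, states$tip)
        else states
  miss <- setdiff(phy$tip.label, names(st))
  if (length(miss))
    stop("missing state for tip(s): ", paste(miss, collapse = ", "))
  structure(list(phy = phy, states = st[phy$tip.label]),
            class = "support_tree")
}

# per-node conditional (partial) likelihoods by pruning, with scaling.
# Returns list(partial = nodes x states matrix, logscale = total log scale,
# post = postorder edge matrix).
prune_partials <- function(tr, model) {
  phy <- ape::reorder.phylo(tr$phy, "postorder")
  k <- length(model$states)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  partial <- matrix(1, nnode, k)
  st_idx <- match(tr$states, model$states)
  if (anyNA(st_idx))
    stop("tip state(s) outside model states: ",
         paste(unique(tr$states[is.na(st_idx)]), collapse = ", "))
  partial[seq_len(ntip), ] <- 0
  partial[cbind(seq_len(ntip), st_idx)] <- 1
  logscale <- 0
  Pm <- lapply(phy$edge.length, function(t) sym_pmat(model, t))
  for (i in seq_len(nrow(phy$edge))) {
    par <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    msg <- Pm[[i]] %*% partial[ch, ]
    partial[par, ] <- partial[par, ] * as.numeric(msg)
    # rescale after every accumulation; each factor is recorded exactly once,
    # so the total likelihood is sum(prior * partial[root]) * exp(logscale)
    m <- max(partial[par, ])
    if (m > 0) {
      partial[par, ] <- partial[par, ] / m
      logscale <- logscale + log(m)
    }
  }
  list(partial = partial, logscale = logscale, phy = phy, Pm = Pm, ntip = ntip)
}

#' Pruning log-likelihood of tip states under a SYM model
#'
#' Felsenstein's pruning algorithm with transition probabilities
#' `P(t) = exp(Qt)` and the uniform root prior forced by symmetry; per-node
#' scaling guards underflow.
#'
#' @param tr a `support_tree`.
#' @param model a `sym_model`.
#' @return log-likelihood (scalar).
#' @export
loglik_sym <- function(tr, model) {
  model <- with_eig(model)
  pr <- prune_partials(tr, model)
  ntip <- pr$ntip
  root <- ntip + 1L
  lik <- sum(model$prior * pr$partial[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Maximum-likelihood SYM rates
#'
#' Bounded multi-start optimisation of the pruning log-likelihood over
#' log-rates; rates constrained to `[1e-8, 1e3]` per unit branch length,
#' 5 starts drawn log-uniformly under a fixed seed.
#'
#' @param tr a `support_tree`.
#' @param states state set (default: the distinct tip states, sorted, unless
#'   given).
#' @param equal_rates fit a single shared exchange rate (default `FALSE`:
#'   one rate per state pair).
#' @param n_starts number of optimisation starts.
#' @param seed seed for the start draws.
#' @return list with `model` (fitted `sym_model`), `loglik`, `convergence`
#'   (per-start data frame).
#' @export
fit_sym_ml <- function(tr, states = NULL, equal_rates = FALSE, n_starts = 5,
                       seed = 1) {
  states <- states %||% sort(unique(tr$states))
  k <- length(states)
  if (length(unique(tr$states)) < 2) {
    warning("all tips share one state; rates unidentifiable, set to lower bound")
    m <- sym_model(states, 1e-8)
    return(list(model = m, loglik = loglik_sym(tr, m),
                convergence = data.frame()))
  }
  np <- if (equal_rates) 1L else k * (k - 1L) / 2L
  lo <- log(1e-8); hi <- log(1e3)
  nll <- function(lr) {
    m <- sym_model(states, exp(if (equal_rates) rep(lr, k * (k - 1) / 2) else lr))
    -loglik_sym(tr, m)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * np, log(1e-2), log(10)),
                   n_starts, np)
  starts[1, ] <- log(sum(ifelse(tr$phy$edge.length > 0, 1, 0)) /
                       sum(tr$phy$edge.length))  # crude events-per-length start
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  fits <- lapply(seq_len(n_starts), function(s) {
    tryCatch(stats::optim(starts[s, ], nll, method = "L-BFGS-B",
                          lower = lo, upper = hi),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("SYM optimisation failed from every start")
  vals <- vapply(fits[ok], function(f) f$value, 0)
  bestf <- fits[ok][[which.min(vals)]]
  rates <- exp(if (equal_rates) rep(bestf$par, k * (k - 1) / 2) else bestf$par)
  conv <- data.frame(start = which(ok), nll = vals,
                     converged = vapply(fits[ok], function(f)
                       f$convergence == 0, TRUE))
  if (!any(conv$converged))
    warning("no optimisation start reported clean convergence; returning best value")
  list(model = sym_model(states, rates), loglik = -bestf$value,
       convergence = conv)
}

# sample a CTMC bridge on one branch by uniformization: exact draw of the
# within-branch path conditional on endpoint states a -> b over time t.
# Omega, R and the Poisson weights are hoisted by the caller; Rpow_env
# caches powers of the uniformized jump matrix across calls.
sample_bridge <- function(a, b, t, Pt_ab, Omega, R, Rpow_env) {
  if (Omega <= 0) return(NULL)
  k <- nrow(R)
  getRpow <- function(n) {
    if (n + 1L > length(Rpow_env$p))
      Rpow_env$p[[n + 1L]] <- R %*% getRpow(n - 1L)
    Rpow_env$p[[n + 1L]]
  }
  u <- stats::runif(1) * Pt_ab
  n <- -1L; acc <- 0
  repeat {
    n <- n + 1L
    acc <- acc + stats::dpois(n, Omega * t) * getRpow(n)[a, b]
    if (acc >= u || n > 10000) break
  }
  if (n == 0L) return(NULL)
  s <- integer(n + 1); s[1] <- a; s[n + 1] <- b
  if (n > 1) for (i in 2:n) {
    w <- R[s[i - 1], ] * getRpow(n + 1L - i)[, b]
    s[i] <- sample.int(k, 1, prob = w)
  }
  real <- which(s[-1] != s[-(n + 1)])
  if (!length(real)) return(NULL)
  times <- sort(stats::runif(n)) * t
  list(time = times[real], from = s[real], to = s[real + 1])
}

#' Sample character histories conditional on tip states
#'
#' Stochastic character mapping: (1) conditional likelihoods by pruning;
#' (2) root state drawn from its posterior; (3) each child state drawn
#' proportional to `P(t_edge)[parent, s] * partial_s(child)` in preorder;
#' (4) the within-branch path drawn exactly by uniformization conditional on
#' the sampled endpoints. Seed-reproducible.
#'
#' @param tr a `support_tree`.
#' @param model a `sym_model`.
#' @param n number of histories (default 1000, the conventional sample size
#'   for summarising mapping uncertainty).
#' @param seed integer seed.
#' @return object of class `character_history_set`: list with `histories`
#'   (each `node_states` named state vector and `events` per-branch data
#'   frame), `model`, `phy`, `seed`.
#' @export
sample_histories <- function(tr, model, n = 1000, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  model <- with_eig(model)
  pr <- prune_partials(tr, model)
  phy <- pr$phy
  ntip <- pr$ntip
  k <- length(model$states)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  # preorder edge sequence (parents before children)
  pre <- rev(seq_len(nrow(phy$edge)))
  node_names <- c(phy$tip.label, paste0("node", (ntip + 1L):nnode))
  Omega <- max(-diag(model$Q))
  R <- if (Omega > 0) diag(k) + model$Q / Omega else diag(k)
  Rpow_env <- new.env(); Rpow_env$p <- list(diag(k))
  root_w <- model$prior * pr$partial[root, ]
  if (sum(root_w) <= 0) stop("tip states have zero likelihood under the model")
  histories <- vector("list", n)
  empty_events <- data.frame(edge = integer(), parent = character(),
                             child = character(), time = numeric(),
                             from = character(), to = character())
  for (h in seq_len(n)) {
    st <- integer(nnode)
    st[root] <- sample.int(k, 1, prob = root_w)
    e_edge <- integer(); e_par <- integer(); e_ch <- integer()
    e_time <- numeric(); e_from <- integer(); e_to <- integer()
    for (i in pre) {
      par <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
      w <- pr$Pm[[i]][st[par], ] * pr$partial[ch, ]
      st[ch] <- sample.int(k, 1, prob = w)
      ev <- sample_bridge(st[par], st[ch], phy$edge.length[i],
                          pr$Pm[[i]][st[par], st[ch]], Omega, R, Rpow_env)
      if (!is.null(ev)) {
        m <- length(ev$time)
        e_edge <- c(e_edge, rep.int(i, m))
        e_par <- c(e_par, rep.int(par, m)); e_ch <- c(e_ch, rep.int(ch, m))
        e_time <- c(e_time, ev$time)
        e_from <- c(e_from, ev$from); e_to <- c(e_to, ev$to)
      }
    }
    ev_df <- if (length(e_edge))
      data.frame(edge = e_edge, parent = node_names[e_par],
                 child = node_names[e_ch], time = e_time,
                 from = model$states[e_from], to = model$states[e_to],
                 stringsAsFactors = FALSE)
    else empty_events
    histories[[h]] <- list(
      node_states = stats::setNames(model$states[st], node_names),
      events = ev_df)
  }
  structure(list(histories = histories, model = model, phy = phy,
                 states = model$states, seed = seed),
            class = "character_history_set")
}

#' @export
print.character_history_set <- function(x, ...) {
  cat(sprintf("<character_history_set> %d histories on %d tips (seed %d)\n",
              length(x$histories), length(x$phy$tip.label), x$seed))
  invisible(x)
}

#' Ancestral node state frequencies
#'
#' Empirical frequency of each state at each internal node across sampled
#' histories; per-node frequencies sum to one.
#'
#' @param h a `character_history_set`.
#' @return matrix (internal nodes x states) of frequencies, row names
#'   `node<k>` in `ape` node numbering.
#' @export
node_state_frequencies <- function(h) {
  if (!length(h$histories)) stop("empty history set")
  ntip <- length(h$phy$tip.label)
  nodes <- paste0("node", (ntip + 1L):(ntip + h$phy$Nnode))
  freq <- matrix(0, length(nodes), length(h$states),
                 dimnames = list(nodes, h$states))
  for (hist in h$histories) {
    s <- hist$node_states[nodes]
    for (i in seq_along(nodes))
      freq[i, s[i]] <- freq[i, s[i]] + 1
  }
  freq / length(h$histories)
}

#' Internal node spanned by a set of tips
#'
#' Most recent common ancestor lookup in the `node<k>` labelling used by
#' [node_state_frequencies()].
#' @param h a `character_history_set` or `support_tree` or `phylo`.
#' @param tips character vector of tip labels.
#' @return node id string, e.g. `"node9"`.
#' @export
mrca_node <- function(h, tips) {
  phy <- if (inherits(h, "character_history_set")) h$phy
         else if (inherits(h, "support_tree")) h$phy else h
  if (length(tips) < 2) stop("need at least two tips for an MRCA")
  paste0("node", ape::getMRCA(phy, tips))
}

#' Serialize a history set as JSON-lines
#'
#' One history per line: node states and branch events.
#' @param h a `character_history_set`.
#' @param path output file.
#' @export
write_history_jsonl <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  for (hist in h$histories) {
    ns <- paste(sprintf('"%s":"%s"', esc(names(hist$node_states)),
                        esc(hist$node_states)), collapse = ",")
    ev <- if (nrow(hist$events))
      paste(sprintf('{"edge":%d,"time":%.8g,"from":"%s","to":"%s"}',
                    hist$events$edge, hist$events$time,
                    esc(hist$events$from), esc(hist$events$to)),
            collapse = ",")
    else ""
    writeLines(sprintf('{"node_states":{%s},"events":[%s]}', ns, ev), con)
  }
  invisible(path)
}
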