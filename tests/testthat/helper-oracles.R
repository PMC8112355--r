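# Independent oracles used across the suite: explicit exhaustive
# computations kept deliberately separate from the package's own code paths.

# exhaustive reaction deduction: all ordered molecule pairs, straight
# set-comparison of fact diffs against each library transformation
oracle_deduce <- function(kb) {
  mols <- kb$registry$molecules
  known <- paste(kb$known_reactions$substrate, kb$known_reactions$product)
  rows <- list()
  for (a in sort(names(mols))) for (b in sort(names(mols))) {
    if (a == b || paste(a, b) %in% known) next
    fa <- molecule_facts(mols[[a]]); fb <- molecule_facts(mols[[b]])
    rem <- setdiff(fa, fb); add <- setdiff(fb, fa)
    if (!length(rem) && !length(add)) next
    for (t in kb$library) {
      if (length(rem) == length(t$removed) && all(rem %in% t$removed) &&
          length(add) == length(t$added) && all(add %in% t$added) &&
          all(t$context %in% fa)) {
        rows[[length(rows) + 1L]] <- c(t$name, a, b)
        break
      }
    }
  }
  if (!length(rows))
    return(data.frame(transformation = character(), substrate = character(),
                      product = character()))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("transformation", "substrate", "product")
  df[order(df$substrate, df$product), , drop = FALSE]
}

# all simple source->target paths by plain recursive DFS over an edge list
oracle_paths <- function(edges, source, target) {
  out <- list()
  walk <- function(node, path) {
    if (node == target) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    nxt <- sort(edges$product[edges$substrate == node])
    for (nb in nxt) if (!nb %in% path) walk(nb, c(path, nb))
  }
  walk(source, source)
  out[order(vapply(out, paste, "", collapse = ">"))]
}

# replicate the pathway selection rule on a single-target query:
# min unobserved nodes, then edge count, then lexicographic edge key
oracle_best_path <- function(edges, source, target, observed) {
  paths <- oracle_paths(edges, source, target)
  if (!length(paths)) return(NULL)
  key <- function(p) paste(paste(p[-length(p)], p[-1], sep = "->"),
                           collapse = "|")
  score <- vapply(paths, function(p)
    sum(!p %in% observed) * 1e6 + (length(p) - 1) * 1e3, 0)
  cand <- paths[score == min(score)]
  cand[[order(vapply(cand, key, ""))[1]]]
}

# brute-force tree likelihood: enumerate every internal-state assignment;
# matrix exponentials via ape::matexpo, an independent implementation
oracle_loglik <- function(phy, tip_states, states, Q, prior = NULL) {
  k <- length(states)
  prior <- prior %||% rep(1 / k, k)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  P <- lapply(seq_len(nrow(phy$edge)),
              function(i) ape::matexpo(Q * phy$edge.length[i]))
  tip_idx <- match(tip_states[phy$tip.label], states)
  internal <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    assign_full <- integer(nnode)
    assign_full[seq_len(ntip)] <- tip_idx
    assign_full[internal] <- grid[r, ]
    p <- prior[assign_full[ntip + 1]]
    for (i in seq_len(nrow(phy$edge)))
      p <- p * P[[i]][assign_full[phy$edge[i, 1]], assign_full[phy$edge[i, 2]]]
    total <- total + p
  }
  log(total)
}

# brute-force marginal ancestral posterior for every internal node
oracle_marginals <- function(phy, tip_states, states, Q, prior = NULL) {
  k <- length(states)
  prior <- prior %||% rep(1 / k, k)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  P <- lapply(seq_len(nrow(phy$edge)),
              function(i) ape::matexpo(Q * phy$edge.length[i]))
  tip_idx <- match(tip_states[phy$tip.label], states)
  internal <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  joint <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    assign_full <- integer(nnode)
    assign_full[seq_len(ntip)] <- tip_idx
    assign_full[internal] <- grid[r, ]
    p <- prior[assign_full[ntip + 1]]
    for (i in seq_len(nrow(phy$edge)))
      p <- p * P[[i]][assign_full[phy$edge[i, 1]], assign_full[phy$edge[i, 2]]]
    joint[r] <- p
  }
  joint <- joint / sum(joint)
  out <- matrix(0, length(internal), k,
                dimnames = list(paste0("node", internal), states))
  for (j in seq_along(internal)) for (s in seq_len(k))
    out[j, s] <- sum(joint[grid[, j] == s])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain cosine similarity used to pre-compute expected spectral scores
oracle_cosine <- function(a, b) {
  mz <- union(names(a), names(b))
  va <- ifelse(mz %in% names(a), a[mz], 0)
  vb <- ifelse(mz %in% names(b), b[mz], 0)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# tiny four-molecule registry used in several deduction tests
tiny_registry <- function() {
  mols <- list(
    desmosterol = registry_molecule(brown_registry(), "desmosterol"),
    cholesterol = registry_molecule(brown_registry(), "cholesterol"),
    cycloartenol = registry_molecule(brown_registry(), "cycloartenol"),
    cycloartanol = registry_molecule(brown_registry(), "cycloartanol"))
  structure(list(molecules = mols, aliases = character(),
                 tokens = character()),
            class = "molecule_registry")
}

brown_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- load_molecule_registry(c(
        sterolpath_extdata("molecules", "brown_sterols.facts"),
        sterolpath_extdata("molecules", "alkyl_sterols.facts")))
    cache
  }
})
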