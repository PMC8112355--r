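# Pathway inference: deduce reactions among registry molecules from a
# transformation library, infer unobserved intermediates by closure, assemble
# minimal source->target pathway DAGs under detection constraints, and
# gap-fill with imported or positionally relaxed transformations.

#' Assemble a knowledge base
#'
#' @param registry a `molecule_registry`.
#' @param detection data frame with columns `species`, `molecule`, `status`
#'   (`detected` / `not_detected` / `unknown`); molecules absent from the
#'   table count as `unknown`.
#' @param known_reactions data frame (`transformation`, `substrate`,
#'   `product`) of reactions taken as known (database-registered); may
#'   include boundary reactions from opaque precursor tokens.
#' @param library named list of `transformation`s (strict library); defaults
#'   to the library derived from `known_reactions`.
#' @param source molecule (or token) id the pathway starts from.
#' @param targets character vector of end-metabolite ids.
#' @param species optional subset of species considered in scope for
#'   detection aggregation.
#' @return object of class `knowledge_base`.
#' @export
knowledge_base <- function(registry, detection, known_reactions, source,
                           targets, library = NULL, species = NULL) {
  stopifnot(inherits(registry, "molecule_registry"))
  detection <- as.data.frame(detection, stringsAsFactors = FALSE)
  if (nrow(detection) &&
      !all(c("species", "molecule", "status") %in% names(detection)))
    stop("detection needs columns species, molecule, status")
  bad <- setdiff(detection$status, c("detected", "not_detected", "unknown"))
  if (length(bad)) stop("unknown detection status: ", paste(bad, collapse = ", "))
  resolve_name(registry, source)
  for (t in targets) resolve_name(registry, t)
  for (m in unique(detection$molecule))
    if (detection$status[detection$molecule == m][1] == "detected")
      resolve_name(registry, m)
  if (is.null(library)) library <- derive_library(registry, known_reactions)
  structure(list(registry = registry, detection = detection,
                 known_reactions = known_reactions, library = library,
                 source = source, targets = sort(targets), species = species),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d molecules, %d known reactions, %d transformations\n",
              length(x$registry$molecules), nrow(x$known_reactions),
              length(x$library)))
  cat("  source:", x$source, "-> targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregated detection status of a molecule
#'
#' `detected` if detected in any in-scope species; else `not_detected` if
#' explicitly absent somewhere; else `unknown`.
#' @param kb a `knowledge_base`.
#' @param molecule molecule id (aliases resolved).
#' @return status string.
#' @export
kb_status <- function(kb, molecule) {
  mol <- tryCatch(resolve_name(kb$registry, molecule), error = function(e) molecule)
  d <- kb$detection
  if (!is.null(kb$species)) d <- d[d$species %in% kb$species, , drop = FALSE]
  rows <- d[vapply(d$molecule, function(m)
    tryCatch(resolve_name(kb$registry, m), error = function(e) m), "") == mol, ,
    drop = FALSE]
  if (!nrow(rows)) return("unknown")
  if (any(rows$status == "detected")) return("detected")
  if (any(rows$status == "not_detected")) return("not_detected")
  "unknown"
}

reaction_key <- function(substrate, product) paste(substrate, product, sep = "->")

#' Deduce reactions among registry molecules
#'
#' Returns every ordered pair of registry molecules whose fact diff is
#' identical to a library transformation (with the transformation's context
#' facts present in the substrate) and that is not already a known reaction.
#' Deterministic: sorted by (substrate, product).
#'
#' @param kb a `knowledge_base`.
#' @param library optional library overriding `kb$library`.
#' @return data frame (`transformation`, `substrate`, `product`,
#'   `provenance`).
#' @export
deduce_reactions <- function(kb, library = NULL) {
  lib <- library %||% kb$library
  mols <- kb$registry$molecules
  known <- reaction_key(kb$known_reactions$substrate, kb$known_reactions$product)
  nms <- sort(names(mols))
  facts <- lapply(mols, molecule_facts)
  # diffs and library entries share a canonical key (facts are kept sorted),
  # so identity matching is a single lookup
  lib_keys <- vapply(lib, function(t) diff_key(t$removed, t$added), "")
  out <- list()
  for (a in nms) for (b in nms) {
    if (a == b) next
    if (reaction_key(a, b) %in% known) next
    removed <- setdiff(facts[[a]], facts[[b]])
    added <- setdiff(facts[[b]], facts[[a]])
    if (!length(removed) && !length(added)) next
    hit <- match(diff_key(removed, added), lib_keys)
    if (is.na(hit)) next
    t <- lib[[hit]]
    if (!all(t$context %in% facts[[a]])) next
    out[[length(out) + 1L]] <- data.frame(
      transformation = t$name, substrate = a, product = b,
      provenance = "deduced", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(transformation = character(), substrate = character(),
                  product = character(), provenance = character())
  res <- res[order(res$substrate, res$product), , drop = FALSE]
  rownames(res) <- NULL
  res
}

diff_key <- function(removed, added) {
  paste(paste(sort(removed), collapse = "|"),
        paste(sort(added), collapse = "|"), sep = " => ")
}

#' Infer unobserved intermediate structures
#'
#' Closure of [apply_transformation()] over the registry up to `max_depth`
#' applications: every valid novel structure reachable from a registry
#' molecule is returned, named `inferred-<digest>` and flagged as an inferred
#' intermediate. The generating applications are returned as edges.
#'
#' @param kb a `knowledge_base`.
#' @param max_depth maximum number of successive applications (default 6).
#' @param budget maximum number of novel structures (default 500); exceeding
#'   it is an error.
#' @param library optional library overriding `kb$library`.
#' @return list with `molecules` (named list of `steroid_graph`s) and
#'   `edges` (data frame `transformation`, `substrate`, `product`,
#'   `provenance = "deduced"`).
#' @export
infer_intermediates <- function(kb, max_depth = 6, budget = 500,
                                library = NULL) {
  stopifnot(max_depth >= 1)
  lib <- library %||% kb$library
  lib <- lib[order(names(lib))]
  seen <- vapply(kb$registry$molecules, canonical_id, "")
  novel <- list()
  edges <- list()
  frontier <- kb$registry$molecules[order(names(kb$registry$molecules))]
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (g in frontier) for (t in lib) {
      res <- tryCatch(apply_transformation(t, g), error = function(e) NULL)
      if (is.null(res)) next
      id <- canonical_id(res)
      hit <- names(seen)[match(id, seen)]
      if (is.na(hit)) {
        nm <- paste0("inferred-", short_id(res))
        res <- rename_molecule(res, nm)
        res$annotations <- sort(unique(c(res$annotations, "inferred-intermediate")))
        if (length(novel) + 1L > budget)
          stop("intermediate closure exceeded budget of ", budget, " structures")
        novel[[nm]] <- res
        seen[nm] <- id
        nxt[[nm]] <- res
        hit <- nm
      }
      edges[[length(edges) + 1L]] <- data.frame(
        transformation = t$name, substrate = g$name, product = hit,
        provenance = "deduced", stringsAsFactors = FALSE)
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  edf <- if (length(edges)) unique(do.call(rbind, edges))
  else data.frame(transformation = character(), substrate = character(),
                  product = character(), provenance = character())
  edf <- edf[order(edf$substrate, edf$product), , drop = FALSE]
  rownames(edf) <- NULL
  list(molecules = novel, edges = edf)
}

# all candidate edges of a knowledge base: known + deduced (+ optional extra)
candidate_edges <- function(kb, library = NULL, extra = NULL) {
  known <- kb$known_reactions
  if (nrow(known)) known$provenance <- "known"
  ded <- deduce_reactions(kb, library = library)
  e <- rbind(known, ded, extra)
  e <- e[!duplicated(reaction_key(e$substrate, e$product)), , drop = FALSE]
  e[order(e$substrate, e$product), , drop = FALSE]
}

edge_graph <- function(edges, vertices) {
  igraph::graph_from_data_frame(
    edges[, c("substrate", "product")], directed = TRUE,
    vertices = data.frame(name = vertices))
}

# enumerate simple source->target paths, canonically sorted
simple_paths <- function(g, from, to, cutoff = -1) {
  ps <- igraph::all_simple_paths(g, from = from, to = to, mode = "out",
                                 cutoff = cutoff)
  ps <- lapply(ps, function(p) igraph::V(g)$name[p])
  keys <- vapply(ps, paste, "", collapse = ">")
  ps[order(keys)]
}

path_cost <- function(nodes_union, edges_union, observed) {
  c(inferred = sum(!nodes_union %in% observed), edges = length(edges_union))
}

#' Build a pathway graph
#'
#' Assembles the source->targets pathway DAG from known plus deduced
#' reactions (extending the registry with inferred intermediates when a
#' target is otherwise unreachable). Among all candidate chain combinations
#' the returned pathway minimises, in order: (1) the number of unobserved
#' (inferred-intermediate) nodes, (2) the total edge count, (3) the
#' lexicographic edge order. Molecules detected in an in-scope species must
#' lie on a source->target chain whenever topologically possible -- this is
#' the constraint that places zymosterol on the chain, i.e. the second
#' sterol-4-demethylation before the Delta8->Delta7 isomerization, when
#' zymosterol is detected. Chains tying on criteria (1)-(2) are reported in
#' `$alternatives`.
#'
#' @param kb a `knowledge_base`.
#' @param infer_missing extend the registry by [infer_intermediates()] when
#'   targets are unreachable (default `TRUE`).
#' @param max_depth,budget passed to [infer_intermediates()].
#' @param extra_edges optional extra reaction rows (e.g. admitted by
#'   [gap_fill()]).
#' @param library optional library override.
#' @return object of class `pathway_graph` with `nodes`, `edges`,
#'   `alternatives`, `ordering_witnesses`, `admissible_edges`.
#' @export
build_pathway <- function(kb, infer_missing = TRUE, max_depth = 6,
                          budget = 500, extra_edges = NULL, library = NULL) {
  source <- resolve_name(kb$registry, kb$source)
  targets <- vapply(kb$targets, function(t) resolve_name(kb$registry, t), "")
  edges <- candidate_edges(kb, library = library, extra = extra_edges)
  vertices <- sort(unique(c(names(kb$registry$molecules), kb$registry$tokens,
                            edges$substrate, edges$product)))
  g <- edge_graph(edges, vertices)

  if (identical(source, unname(targets)) && length(targets) == 1) {
    st <- kb_status(kb, source)
    nodes <- data.frame(molecule = source,
                        flag = if (st == "detected") "observed"
                               else "inferred_intermediate")
    return(structure(list(
      nodes = nodes, edges = edges[0, ], alternatives = list(),
      ordering_witnesses = data.frame(molecule = character(), note = character()),
      admissible_edges = edges, source = source, targets = targets),
      class = "pathway_graph"))
  }

  reach <- function(gr) igraph::V(gr)$name[
    !is.infinite(igraph::distances(gr, v = source, mode = "out")[1, ])]
  reachable <- reach(g)
  missing <- setdiff(targets, reachable)
  inferred_mols <- list()
  if (length(missing) && infer_missing) {
    # escalate the closure depth one step at a time: the minimal number of
    # consecutive unobserved applications that restores reachability is what
    # the model needs; deeper closures only add off-chain structures
    base_edges <- edges
    for (depth in seq_len(max_depth)) {
      clo <- infer_intermediates(kb, max_depth = depth, budget = budget,
                                 library = library)
      inferred_mols <- clo$molecules
      edges <- rbind(base_edges, clo$edges)
      edges <- edges[!duplicated(reaction_key(edges$substrate, edges$product)), ]
      vertices <- sort(unique(c(vertices, names(inferred_mols))))
      g <- edge_graph(edges, vertices)
      reachable <- reach(g)
      missing <- setdiff(targets, reachable)
      if (!length(missing)) break
    }
    if (!length(missing) && length(inferred_mols)) {
      # keep only inferred structures on a distance-minimal connection to a
      # target that needed them; equal-length inferred detours parallel to
      # observed chains never improve the unobserved-node criterion
      d_out <- igraph::distances(g, v = source, mode = "out")[1, ]
      d_in <- igraph::distances(g, v = targets, mode = "in")
      needed <- vapply(names(inferred_mols), function(v) {
        any(vapply(seq_along(targets), function(j)
          is.finite(d_out[v]) && is.finite(d_in[j, v]) &&
            d_out[v] + d_in[j, v] <= d_out[targets[j]], TRUE))
      }, TRUE)
      drop <- names(inferred_mols)[!needed]
      if (length(drop)) {
        inferred_mols <- inferred_mols[needed]
        edges <- edges[!(edges$substrate %in% drop | edges$product %in% drop), ,
                       drop = FALSE]
        vertices <- setdiff(vertices, drop)
        g <- edge_graph(edges, vertices)
      }
    }
  }
  if (length(missing)) {
    # nearest reachable predecessor: a reachable molecule with an edge into
    # the unreachable component, reported to guide curation
    frontier <- unique(edges$substrate[edges$substrate %in% reachable &
                                         !edges$product %in% reachable])
    stop("target(s) unreachable from '", source, "': ",
         paste(missing, collapse = ", "),
         if (length(frontier)) paste0(" (frontier: ",
                                      paste(sort(frontier), collapse = ", "), ")")
         else " (no outgoing frontier)")
  }

  status <- vapply(vertices, function(m) kb_status(kb, m), "")
  status[names(inferred_mols)] <- "unknown"
  observed <- vertices[status == "detected"]

  # prune to the subgraph of nodes on some source->target walk before
  # enumerating chains; closure products off every chain are irrelevant
  d_out <- igraph::distances(g, v = source, mode = "out")[1, ]
  d_in <- igraph::distances(g, v = targets, mode = "in")
  relevant <- igraph::V(g)$name[!is.infinite(d_out) &
                                  apply(d_in, 2, min) < Inf]
  keep <- edges$substrate %in% relevant & edges$product %in% relevant
  g <- edge_graph(edges[keep, , drop = FALSE], sort(relevant))

  cand <- lapply(targets, function(t) simple_paths(g, source, t))
  names(cand) <- targets
  on_any_path <- unique(unlist(cand))
  mandatory <- setdiff(intersect(observed, on_any_path), c(source, targets))

  edge_key_of_path <- function(p)
    reaction_key(p[-length(p)], p[-1])
  combo_cost <- function(paths) {
    nodes_u <- unique(unlist(paths))
    edges_u <- unique(unlist(lapply(paths, edge_key_of_path)))
    covered <- all(mandatory %in% nodes_u)
    c(if (covered) 0 else 1,
      sum(!nodes_u %in% observed), length(edges_u))
  }
  idx <- lapply(cand, seq_along)
  n_comb <- prod(vapply(idx, length, 1))
  single_cost <- function(p) c(sum(!p %in% observed), length(p) - 1L)
  if (n_comb > 50000 || n_comb < 1) {
    # deterministic fallback for very dense graphs: pick the per-target best
    # chain (unobserved nodes, length, lexicographic) independently
    best <- lapply(cand, function(ps) {
      sc <- vapply(ps, single_cost, numeric(2))
      ps[[order(sc[1, ], sc[2, ],
                vapply(ps, paste, "", collapse = ">"))[1]]]
    })
  } else {
    grid <- expand.grid(rev(idx), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(idx)), drop = FALSE]
    best <- NULL; best_cost <- NULL; best_key <- NULL
    for (r in seq_len(nrow(grid))) {
      paths <- lapply(seq_along(cand), function(j) cand[[j]][[grid[r, j]]])
      cost <- combo_cost(paths)
      key <- paste(sort(unique(unlist(lapply(paths, edge_key_of_path)))),
                   collapse = "|")
      if (is.null(best) ||
          cost[1] < best_cost[1] ||
          (cost[1] == best_cost[1] && cost[2] < best_cost[2]) ||
          (cost[1] == best_cost[1] && cost[2] == best_cost[2] &&
           cost[3] < best_cost[3]) ||
          (all(cost == best_cost) && key < best_key)) {
        best <- paths; best_cost <- cost; best_key <- key
      }
    }
  }
  # per-target alternatives: paths tying with the chosen one on
  # (coverage-irrelevant) inferred-node and edge counts
  alternatives <- lapply(seq_along(cand), function(j) {
    chosen <- best[[j]]
    single_cost <- function(p) c(sum(!p %in% observed), length(p) - 1L)
    cc <- single_cost(chosen)
    alt <- Filter(function(p) !identical(p, chosen) &&
                    all(single_cost(p) == cc), cand[[j]])
    alt
  })
  names(alternatives) <- targets

  chosen_edges <- unique(unlist(lapply(best, edge_key_of_path)))
  sel <- reaction_key(edges$substrate, edges$product) %in% chosen_edges
  pedges <- edges[sel, , drop = FALSE]
  pedges <- pedges[order(pedges$substrate, pedges$product), , drop = FALSE]
  rownames(pedges) <- NULL
  pnodes_names <- sort(unique(unlist(best)))
  nodes <- data.frame(
    molecule = pnodes_names,
    flag = ifelse(pnodes_names %in% observed, "observed",
                  "inferred_intermediate"),
    stringsAsFactors = FALSE)
  wm <- intersect(mandatory, pnodes_names)
  witnesses <- data.frame(
    molecule = wm,
    note = rep("detected metabolite constrains step order on its chain",
               length(wm)),
    stringsAsFactors = FALSE)
  admissible <- edges
  admissible$optional <- !reaction_key(admissible$substrate,
                                       admissible$product) %in% chosen_edges
  structure(list(nodes = nodes, edges = pedges, alternatives = alternatives,
                 ordering_witnesses = witnesses,
                 admissible_edges = admissible,
                 inferred_molecules = inferred_mols,
                 source = source, targets = targets),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s -> {%s}: %d nodes (%d inferred), %d edges\n",
              x$source, paste(x$targets, collapse = ", "), nrow(x$nodes),
              sum(x$nodes$flag == "inferred_intermediate"), nrow(x$edges)))
  invisible(x)
}

#' Chain of molecules leading to one target
#' @param p a `pathway_graph`.
#' @param target target id.
#' @return character vector of molecule ids from source to target.
#' @export
pathway_chain <- function(p, target) {
  g <- edge_graph(p$edges, sort(unique(c(p$nodes$molecule, p$edges$substrate,
                                         p$edges$product))))
  ps <- simple_paths(g, p$source, target)
  if (!length(ps)) stop("no chain to '", target, "' in pathway")
  ps[[1]]
}

# ---- gap filling ------------------------------------------------------------

#' Gap-fill a pathway with imported and positionally relaxed transformations
#'
#' Escalates through relaxation levels until all targets are reachable:
#' level 0 uses the strict library only; level 1 additionally imports
#' transformations from an auxiliary library (other pathways/organisms);
#' level 2 admits positional variants of any known transformation (the
#' relaxed "type hIIc" matching) instantiated from registry molecule pairs.
#' The admitted set of novel transformation types is minimal, preferring
#' fewer level-2 variants, then fewer level-1 imports, then lexicographic
#' names.
#'
#' @param kb a `knowledge_base` (strict library in `kb$library`).
#' @param aux_library named list of `transformation`s available for import.
#' @param variant_aliases optional named character vector mapping
#'   auto-generated variant names to curated names.
#' @return list with `pathway` (a `pathway_graph`), `admitted` (data frame
#'   `name`, `level`, `basis`), `library` (the extended library).
#' @export
gap_fill <- function(kb, aux_library = list(), variant_aliases = character()) {
  source <- resolve_name(kb$registry, kb$source)
  targets <- vapply(kb$targets, function(t) resolve_name(kb$registry, t), "")
  vertices <- sort(unique(c(names(kb$registry$molecules), kb$registry$tokens)))

  strict <- kb$library
  strict_edges <- candidate_edges(kb)
  reachable_from <- function(edges) {
    # plain BFS; called many times during the subset search
    seen <- source
    frontier <- source
    while (length(frontier)) {
      nxt <- unique(edges$product[edges$substrate %in% frontier])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    list(ok = all(targets %in% seen), reachable = seen)
  }
  r0 <- reachable_from(strict_edges)
  if (r0$ok) {
    return(list(pathway = build_pathway(kb, infer_missing = FALSE),
                admitted = data.frame(name = character(), level = integer(),
                                      basis = character()),
                library = strict))
  }

  # pair diffs are computed once and shared between the level-1 edge scan
  # and the level-2 variant scan
  known_all <- c(strict, aux_library)
  known_keys <- vapply(known_all, function(t) diff_key(t$removed, t$added), "")
  known_sizes <- unique(vapply(known_all, function(t)
    paste(length(t$removed), length(t$added)), ""))
  aux_keys <- vapply(aux_library, function(t) diff_key(t$removed, t$added), "")
  mols <- kb$registry$molecules
  nms <- sort(names(mols))
  facts <- lapply(mols, molecule_facts)
  aux_edges <- lapply(aux_library, function(t) data.frame(
    transformation = character(0), substrate = character(0),
    product = character(0), provenance = character(0),
    stringsAsFactors = FALSE))
  variants <- list(); variant_edges <- list()
  for (a in nms) for (b in nms) {
    if (a == b) next
    removed <- setdiff(facts[[a]], facts[[b]])
    added <- setdiff(facts[[b]], facts[[a]])
    if (!length(removed) && !length(added)) next
    if (!paste(length(removed), length(added)) %in% known_sizes) next
    key <- diff_key(removed, added)
    # level-1: an identical aux diff whose context holds in the substrate
    hit <- match(key, aux_keys)
    if (!is.na(hit) && all(aux_library[[hit]]$context %in% facts[[a]])) {
      aux_edges[[hit]] <- rbind(aux_edges[[hit]], data.frame(
        transformation = names(aux_library)[hit], substrate = a, product = b,
        provenance = "gap_filled", stringsAsFactors = FALSE))
    }
    if (key %in% known_keys) next
    d <- tryCatch(transformation("pair-diff", removed, added),
                  error = function(e) NULL)
    if (is.null(d)) next
    for (t in known_all) {
      if (match_level(d, t) == "positional_variant") {
        auto <- paste0(t$name, "-at-", paste(d$anchors, collapse = "-"))
        nm <- if (auto %in% names(variant_aliases)) variant_aliases[[auto]] else auto
        if (!nm %in% names(variants)) {
          v <- transformation(nm, removed, added,
                              relaxation = "positional_variant")
          attr(v, "basis") <- t$name
          variants[[nm]] <- v
          variant_edges[[nm]] <- data.frame(
            transformation = character(0), substrate = character(0),
            product = character(0), provenance = character(0),
            stringsAsFactors = FALSE)
        }
        variant_edges[[nm]] <- rbind(variant_edges[[nm]], data.frame(
          transformation = nm, substrate = a, product = b,
          provenance = "gap_filled", stringsAsFactors = FALSE))
        break
      }
    }
  }

  useful_aux <- aux_library[vapply(aux_edges, nrow, 1L) > 0]
  cand <- c(lapply(useful_aux, function(t) { attr(t, "level") <- 1L; t }),
            lapply(variants, function(t) { attr(t, "level") <- 2L; t }))
  if (!length(cand)) {
    stop("targets unreachable and no gap-fill candidates; frontier: ",
         paste(sort(intersect(r0$reachable, unique(strict_edges$substrate))),
               collapse = ", "))
  }
  cedges <- c(aux_edges[names(useful_aux)], variant_edges)
  lev <- vapply(cand, function(t) attr(t, "level"), 1L)
  ord <- order(lev, names(cand))
  cand <- cand[ord]; lev <- lev[ord]; cedges <- cedges[names(cand)]

  # minimal admitted subset: fewest level-2 variants, then fewest level-1
  # imports, then lexicographic names; subsets visited lazily in cost order
  # with early exit, so typical calls test only a few dozen combinations
  i1 <- which(lev == 1L); i2 <- which(lev == 2L)
  choose_sets <- function(idx, m) {
    if (m == 0) return(list(integer()))
    if (m > length(idx)) return(list())
    cmb <- utils::combn(idx, m, simplify = FALSE)
    cmb[order(vapply(cmb, function(s)
      paste(names(cand)[s], collapse = "|"), ""))]
  }
  best <- NULL
  for (n2 in 0:length(i2)) {
    for (n1 in 0:length(i1)) {
      for (s2 in choose_sets(i2, n2)) {
        for (s1 in choose_sets(i1, n1)) {
          sel <- sort(c(s1, s2))
          edges <- rbind(strict_edges, do.call(rbind, cedges[sel]))
          if (reachable_from(edges)$ok) { best <- sel; break }
        }
        if (!is.null(best)) break
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    rall <- reachable_from(rbind(strict_edges, do.call(rbind, cedges)))
    stop("targets unreachable even at relaxation level 2; frontier: ",
         paste(sort(intersect(rall$reachable, unique(strict_edges$substrate))),
               collapse = ", "))
  }
  admitted_t <- cand[best]
  admitted <- data.frame(
    name = names(admitted_t),
    level = vapply(admitted_t, function(t) attr(t, "level"), 1L),
    basis = vapply(admitted_t, function(t) attr(t, "basis") %||% t$name, ""),
    stringsAsFactors = FALSE)
  admitted <- admitted[order(admitted$level, admitted$name), , drop = FALSE]
  rownames(admitted) <- NULL
  gap_edges <- do.call(rbind, cedges[best])
  gap_edges$provenance <- "gap_filled"
  list(pathway = build_pathway(kb, infer_missing = FALSE,
                               extra_edges = gap_edges),
       admitted = admitted,
       library = c(strict, admitted_t),
       transformations = admitted_t)
}

# ---- exports ----------------------------------------------------------------

#' Export pathway reactions for metabolic-network curation
#'
#' Emits the pathway's reactions as a flat reaction-addition table for
#' external genome-scale metabolic network curation tools, but only when the
#' species-level support for the pathway is strong; with weak or absent
#' support an empty table is returned whose `rationale` attribute records why
#' (the curation decision rule: do not add a pathway whose key intermediate
#' is undetected in the clade).
#'
#' @param p a `pathway_graph`.
#' @param support a `support_state` object (see [support_state()]) or one of
#'   `"strong"`, `"weak"`, `"none"`.
#' @param rationale optional rationale string for non-strong support.
#' @return data frame (`reaction`, `substrate`, `product`, `provenance`);
#'   zero rows unless support is strong.
#' @export
export_gsmn_additions <- function(p, support, rationale = NULL) {
  lvl <- if (inherits(support, "support_state")) support$state else support
  lvl <- match.arg(lvl, c("strong", "weak", "none"))
  if (lvl == "strong") {
    if (!nrow(p$edges))
      return(structure(data.frame(reaction = character(),
                                  substrate = character(),
                                  product = character(),
                                  provenance = character()),
                       rationale = "empty pathway"))
    out <- data.frame(reaction = p$edges$transformation,
                      substrate = p$edges$substrate,
                      product = p$edges$product,
                      provenance = p$edges$provenance,
                      stringsAsFactors = FALSE)
    return(structure(out, rationale = "strong support"))
  }
  structure(data.frame(reaction = character(), substrate = character(),
                       product = character(), provenance = character()),
            rationale = rationale %||%
              paste0(lvl, " support: key intermediate not detected"))
}

#' Write a pathway edge list as TSV
#' @param p a `pathway_graph`.
#' @param path output file.
#' @param all include non-chosen admissible edges with `optional = TRUE`.
#' @export
write_pathway_tsv <- function(p, path, all = FALSE) {
  df <- if (all) p$admissible_edges else cbind(p$edges, optional = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a pathway as GraphViz DOT text
#' @param p a `pathway_graph`.
#' @return character vector of DOT lines.
#' @export
pathway_to_dot <- function(p) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph pathway {", "  rankdir=TB;")
  for (i in seq_len(nrow(p$nodes))) {
    shape <- if (p$nodes$flag[i] == "observed") "box" else "ellipse"
    style <- if (p$nodes$flag[i] == "observed") "solid" else "dashed"
    lines <- c(lines, sprintf("  %s [shape=%s, style=%s];",
                              q(p$nodes$molecule[i]), shape, style))
  }
  for (i in seq_len(nrow(p$edges)))
    lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                              q(p$edges$substrate[i]), q(p$edges$product[i]),
                              q(p$edges$transformation[i])))
  c(lines, "}")
}
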