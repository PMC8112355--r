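make_kb <- function(registry, detection, reactions, source, targets,
                    library = NULL, species = NULL) {
  knowledge_base(registry, detection, reactions, source = source,
                 targets = targets, library = library, species = species)
}

empty_reactions <- data.frame(transformation = character(),
                              substrate = character(),
                              product = character(), stringsAsFactors = FALSE)

test_that("deduction generalises a known reduction to a new substrate pair", {
  reg <- tiny_registry()
  lib <- list(`sterol-d24-reduction` = derive_transformation(
    reg$molecules$desmosterol, reg$molecules$cholesterol,
    "sterol-d24-reduction"))
  kb <- make_kb(reg,
                data.frame(species = "sp", molecule = names(reg$molecules),
                           status = "detected"),
                data.frame(transformation = "sterol-d24-reduction",
                           substrate = "desmosterol",
                           product = "cholesterol"),
                source = "desmosterol", targets = "cholesterol",
                library = lib)
  ded <- deduce_reactions(kb)
  expect_equal(nrow(ded), 1)
  expect_identical(ded$substrate, "cycloartenol")
  expect_identical(ded$product, "cycloartanol")
  # agrees with the exhaustive enumerator over all 12 ordered pairs
  orc <- oracle_deduce(kb)
  expect_identical(ded[, c("transformation", "substrate", "product")],
                   orc, ignore_attr = TRUE)
})

test_that("deduction on an empty registry returns an empty table", {
  reg <- structure(list(molecules = list(), aliases = character(),
                        tokens = "squalene"),
                   class = "molecule_registry")
  kb <- make_kb(reg, data.frame(species = character(), molecule = character(),
                                status = character()),
                empty_reactions, source = "squalene", targets = "squalene",
                library = list())
  expect_equal(nrow(deduce_reactions(kb)), 0)
})

test_that("the packaged model reproduces its reference edge list", {
  kb <- brown_algal_kb()
  edges <- candidate_edges(kb)
  ref <- brown_model_edges()
  key <- function(df) paste(df$substrate, df$product, df$transformation)
  expect_setequal(key(edges), key(ref))
  pw <- build_pathway(kb)
  expect_setequal(key(pw$edges), key(ref[!ref$optional, ]))
  expect_setequal(key(pw$admissible_edges[!pw$admissible_edges$optional, ]),
                  key(ref[!ref$optional, ]))
})

test_that("deduction context blocks alkylation without the required bond", {
  # 24-methylcholest-22-enol -> 24-ethylcholest-22-enol is exactly the
  # 28-methylation diff, but lacks Delta24(28); it must not be deduced
  kb <- brown_algal_kb()
  ded <- deduce_reactions(kb)
  expect_false(any(ded$substrate == "24-methylcholest-22-enol" &
                     ded$product == "24-ethylcholest-22-enol"))
  expect_false(any(ded$substrate == "24-methylcholesterol" &
                     ded$product == "24-ethylcholesterol"))
  # while the fucosterol route is deduced
  expect_true(any(ded$substrate == "fucosterol" &
                    ded$product == "24-ethylcholesterol"))
})

test_that("intermediate closure regenerates a deleted registry molecule", {
  kb <- brown_algal_kb()
  target_facts <- molecule_facts(
    registry_molecule(kb$registry, "24-ethylcholesterol"))
  kb$registry$molecules[["24-ethylcholesterol"]] <- NULL
  kb$detection <- kb$detection[kb$detection$molecule != "24-ethylcholesterol", ]
  clo <- infer_intermediates(kb, max_depth = 2)
  ids <- vapply(clo$molecules, canonical_id, "")
  expect_true(canonical_id(target_facts) %in% ids)
  for (g in clo$molecules) expect_length(validate_skeleton(g), 0)
  # and the pathway to the 22-enol routes through exactly one inferred
  # structure (the ethyl-side-chain intermediate: either 24-ethylcholesterol
  # or its tying Delta22-first isomer)
  pw <- build_pathway(kb)
  chain <- pathway_chain(pw, "24-ethylcholest-22-enol")
  inferred <- chain[grepl("^inferred-", chain)]
  expect_length(inferred, 1)
  got <- pw$inferred_molecules[[inferred]]
  expect_true(any(got$bonds$from == "c28" & got$bonds$to == "c29"))
  expect_length(validate_skeleton(got), 0)
})

test_that("closure on a registry already closed under the library is empty", {
  reg <- tiny_registry()
  lib <- list(`sterol-d24-reduction` = derive_transformation(
    reg$molecules$desmosterol, reg$molecules$cholesterol,
    "sterol-d24-reduction"))
  kb <- make_kb(reg,
                data.frame(species = "sp", molecule = names(reg$molecules),
                           status = "detected"),
                empty_reactions, source = "desmosterol",
                targets = "cholesterol", library = lib)
  clo <- infer_intermediates(kb, max_depth = 1)
  expect_length(clo$molecules, 0)
})

test_that("closure budget is enforced", {
  kb <- brown_algal_kb()
  expect_error(infer_intermediates(kb, max_depth = 6, budget = 2),
               "budget")
})

test_that("a detected metabolite pins the step order of its chain", {
  kb <- brown_algal_kb()
  pw <- build_pathway(kb)
  chain <- pathway_chain(pw, "cholesterol")
  expect_true("zymosterol" %in% chain)
  # demethylation of the 4alpha-methyl precedes the Delta8->Delta7 step
  expect_lt(match("zymosterol", chain), match("cholesta-7-24-dienol", chain))
  expect_true("zymosterol" %in% pw$ordering_witnesses$molecule)
  # every tying chain keeps zymosterol (the only surviving ambiguity is the
  # cycloartenol/lanosterol bifurcation upstream of it)
  for (alt in pw$alternatives[["cholesterol"]])
    expect_true("zymosterol" %in% alt)

  kb$detection$status[kb$detection$molecule == "zymosterol"] <- "not_detected"
  pw2 <- build_pathway(kb)
  chains <- c(list(pathway_chain(pw2, "cholesterol")),
              pw2$alternatives[["cholesterol"]])
  has_zymo <- vapply(chains, function(p) "zymosterol" %in% p, TRUE)
  has_late <- vapply(chains, function(p)
    "4a-methylcholesta-7-24-dienol" %in% p, TRUE)
  expect_true(any(has_zymo) && any(has_late))
})

test_that("source equal to target yields a single-node pathway", {
  kb <- brown_algal_kb(targets = "cholesterol")
  kb$source <- "cholesterol"
  pw <- build_pathway(kb)
  expect_equal(nrow(pw$edges), 0)
  expect_identical(pw$nodes$molecule, "cholesterol")
})

test_that("unreachable targets produce an informative error", {
  reg <- tiny_registry()
  kb <- make_kb(reg,
                data.frame(species = "sp", molecule = names(reg$molecules),
                           status = "detected"),
                empty_reactions, source = "cholesterol",
                targets = "cycloartanol", library = list())
  expect_error(build_pathway(kb, infer_missing = FALSE),
               "unreachable.*cycloartanol")
})

test_that("mozukulin gap-filling admits the documented three novel types", {
  gf <- gap_fill(mozukulin_kb(), aux_transformation_library(),
                 variant_alias_table())
  expect_identical(gf$admitted$name,
                   c("sterone-23-hydroxylation", "sterone-d1-2-desaturation",
                     "sterone-23-reduction"))
  expect_identical(gf$admitted$level, c(1L, 1L, 2L))
  expect_identical(
    gf$admitted$basis[gf$admitted$name == "sterone-23-reduction"],
    "sterone-3-reduction")
  # final step: the Delta24 reduction re-used on a sterone substrate,
  # a substrate class absent from the strict exemplars
  final <- gf$pathway$edges[gf$pathway$edges$product == "mozukulin-b", ]
  expect_identical(final$transformation, "sterol-d24-reduction")
  expect_identical(final$substrate, "mozukulin-a")
  kb <- mozukulin_kb()
  expect_false(any(kb$known_reactions$substrate == "mozukulin-a"))
})

test_that("gap filling is a no-op when targets are strictly reachable", {
  gf <- gap_fill(brown_algal_kb(), aux_transformation_library(),
                 variant_alias_table())
  expect_equal(nrow(gf$admitted), 0)
})

test_that("curation export is gated on strong support", {
  pw <- build_pathway(brown_algal_kb())
  strong <- export_gsmn_additions(pw, "strong")
  expect_equal(nrow(strong), nrow(pw$edges))
  weak <- export_gsmn_additions(pw, "weak",
                                rationale = "desmosterol not detected")
  expect_equal(nrow(weak), 0)
  expect_identical(attr(weak, "rationale"), "desmosterol not detected")
  kb1 <- brown_algal_kb(targets = "cholesterol")
  kb1$source <- "cholesterol"
  empty <- export_gsmn_additions(build_pathway(kb1), "strong")
  expect_equal(nrow(empty), 0)
})

test_that("deduction and pathway choice match brute force on random bases", {
  for (seed in 1:60) {
    g <- gen_knowledge_base(n_steps = sample(2:6, 1), n_branches = 1,
                            hide_fraction = 0, seed = seed)
    expect_lte(length(g$kb$registry$molecules), 8)
    ded <- deduce_reactions(g$kb)
    orc <- oracle_deduce(g$kb)
    expect_identical(ded[, c("transformation", "substrate", "product")],
                     orc, ignore_attr = TRUE, label = paste("seed", seed))
    # single-target query with only the endpoints observed, so the selection
    # rule reduces to (unobserved nodes, edge count, lexicographic order)
    tgt <- g$kb$targets[1]
    kb1 <- g$kb
    kb1$targets <- tgt
    kb1$detection$status[!kb1$detection$molecule %in% c(kb1$source, tgt)] <-
      "unknown"
    pw <- build_pathway(kb1, infer_missing = FALSE)
    edges <- candidate_edges(kb1)
    best <- oracle_best_path(edges, kb1$source, tgt, c(kb1$source, tgt))
    expect_identical(pathway_chain(pw, tgt), best,
                     label = paste("pathway seed", seed))
  }
})

test_that("adding a detected molecule never shrinks the reachable target set", {
  for (seed in 101:130) {
    g <- gen_knowledge_base(n_steps = 5, n_branches = 1, hide_fraction = 0.4,
                            seed = seed)
    reach <- function(kb) {
      edges <- candidate_edges(kb)
      tryCatch({
        pw <- build_pathway(kb)
        intersect(kb$targets, pw$nodes$molecule)
      }, error = function(e) character())
    }
    r_small <- reach(g$kb)
    kb_full <- g$kb
    kb_full$registry <- g$registry_full
    kb_full$detection <- data.frame(
      species = "synthetic-sp",
      molecule = names(g$registry_full$molecules), status = "detected")
    r_full <- reach(kb_full)
    expect_true(all(r_small %in% r_full), label = paste("seed", seed))
  }
})

test_that("pathway outputs are byte-identical across reruns", {
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_pathway_tsv(build_pathway(brown_algal_kb()), f1, all = TRUE)
  write_pathway_tsv(build_pathway(brown_algal_kb()), f2, all = TRUE)
  expect_identical(readLines(f1), readLines(f2))
  dot <- pathway_to_dot(build_pathway(brown_algal_kb()))
  expect_true(any(grepl("zymosterol", dot)))
})
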