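# Synthetic-data generators: random steroid knowledge bases with a known
# ground-truth pathway, linear-response chromatogram peak tables with known
# concentrations, and tip characters simulated under a known SYM CTMC.
# Every generator is a pure function of its configuration and seed.

#' Random steroid knowledge base with known ground truth
#'
#' Builds a random valid pathway (a chain with optional branches) over the
#' steroid grammar by repeatedly applying randomly chosen applicable
#' transformations to the cholestane scaffold, then hides a fraction of the
#' intermediates (marking them `not_detected`) and returns the observable
#' knowledge base plus the hidden truth.
#'
#' @param n_steps number of chain steps (default 5).
#' @param n_branches extra branch steps grafted on random chain nodes
#'   (default 0).
#' @param hide_fraction fraction of intermediate molecules hidden (default
#'   0).
#' @param seed integer seed (mandatory).
#' @return list with `kb` (a `knowledge_base`), `truth` (data frame of true
#'   reactions), `hidden` (character vector of hidden molecule names).
#' @export
gen_knowledge_base <- function(n_steps = 5, n_branches = 0,
                               hide_fraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_steps >= 1, hide_fraction >= 0, hide_fraction < 1)
  set.seed(seed)
  pool <- synthetic_transformation_pool()
  root <- cholestane_scaffold("syn-m001")
  mols <- list(root)
  names(mols) <- root$name
  truth <- list()
  ids <- canonical_id(root)
  counter <- 1L
  grow <- function(from_idx, n) {
    for (s in seq_len(n)) {
      g <- mols[[from_idx]]
      appl <- Filter(function(t) applicable(t, g), pool)
      if (!length(appl)) return(invisible(NULL))
      t <- appl[[sample.int(length(appl), 1)]]
      counter <<- counter + 1L
      nm <- sprintf("syn-m%03d", counter)
      res <- rename_molecule(apply_transformation(t, g), nm)
      id <- canonical_id(res)
      if (id %in% ids) { counter <<- counter - 1L; next }
      ids <<- c(ids, id)
      mols[[nm]] <<- res
      truth[[length(truth) + 1L]] <<- data.frame(
        transformation = t$name, substrate = g$name, product = nm,
        stringsAsFactors = FALSE)
      from_idx <- nm
    }
    invisible(NULL)
  }
  grow(root$name, n_steps)
  if (n_branches > 0) {
    for (b in seq_len(n_branches)) {
      at <- sample(names(mols), 1)
      grow(at, 1)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth)
  else data.frame(transformation = character(), substrate = character(),
                  product = character())
  # library derived from the truth reactions (one exemplar per name)
  reg <- structure(list(molecules = mols, aliases = character(),
                        tokens = character()),
                   class = "molecule_registry")
  inner <- setdiff(names(mols), c(root$name, leaves <- setdiff(
    truth_df$product, truth_df$substrate)))
  n_hide <- floor(hide_fraction * length(inner))
  hidden <- if (n_hide > 0) sort(sample(inner, n_hide)) else character()
  visible <- setdiff(names(mols), hidden)
  detection <- data.frame(species = "synthetic-sp",
                          molecule = names(mols),
                          status = ifelse(names(mols) %in% hidden,
                                          "not_detected", "detected"),
                          stringsAsFactors = FALSE)
  reg_vis <- reg
  reg_vis$molecules <- reg$molecules[visible]
  lib <- derive_library(reg, truth_df)
  kb <- knowledge_base(reg_vis,
                       detection[detection$molecule %in% visible, ],
                       known_reactions = truth_df[0, ],
                       source = root$name,
                       targets = if (length(leaves)) leaves else root$name,
                       library = lib)
  list(kb = kb, truth = truth_df, hidden = hidden, registry_full = reg)
}

# pool of strict transformations over the cholestane grammar used by the
# random generator: desaturations, their reductions, side-chain alkylations
# and hydroxylations at fixed skeletal positions
synthetic_transformation_pool <- function() {
  mk <- function(name, removed, added, context = character())
    transformation(name, removed, added, context)
  pool <- list(
    mk("syn-5-desaturation", "bond(c5,c6,single)", "bond(c5,c6,double)"),
    mk("syn-7-desaturation", "bond(c7,c8,single)", "bond(c7,c8,double)"),
    mk("syn-22-desaturation", "bond(c22,c23,single)", "bond(c22,c23,double)"),
    mk("syn-24-desaturation", "bond(c24,c25,single)", "bond(c24,c25,double)"),
    mk("syn-24-methylation", "bond(c24,c25,double)",
       c("atom(c28,carbon)", "bond(c24,c28,double)", "bond(c24,c25,single)")),
    mk("syn-d24-28-reduction", "bond(c24,c28,double)", "bond(c24,c28,single)"),
    mk("syn-6-hydroxylation", character(),
       c("atom(o2,oxygen)", "bond(c6,o2,single)"),
       context = "bond(c5,c6,single)"),
    mk("syn-11-hydroxylation", character(),
       c("atom(o3,oxygen)", "bond(c11,o3,single)")),
    mk("syn-3-oxidation", "bond(c3,o1,single)", "bond(c3,o1,double)"))
  names(pool) <- vapply(pool, function(t) t$name, "")
  pool
}

#' Synthetic peak tables with known concentrations
#'
#' Emulates the linear-response chromatograph: analyte area equals
#' `rrf * mass * (is_area / is_amount) * (1 + eps)` with
#' `eps ~ Normal(0, noise_sd)` (truncated at -0.9 to keep areas positive),
#' peaks placed at the standards' retention indices on a synthetic alkane
#' ladder, spectra copied from the standards registry. The generating truth
#' is returned alongside.
#'
#' @param true_mass_ug named numeric vector of true per-sterol masses
#'   (micrograms in the injected sample).
#' @param rrf_truth named numeric vector of true relative response factors
#'   (recycled from 1 if missing entries).
#' @param noise_sd multiplicative noise standard deviation (default 0).
#' @param sample id of the generated sample.
#' @param sample_mass_mg dry mass (default 60).
#' @param is_amount_ug internal-standard amount (default 5).
#' @param n_cal_levels calibration levels per mix (default 3).
#' @param seed integer seed (mandatory).
#' @return list with `peaks` (a `peak_table`), `calibration` (data frame),
#'   `standards`, `ladder`, `truth` (data frame `compound`, `mass_ug`,
#'   `conc_ug_mg`, `pct`).
#' @export
gen_peak_tables <- function(true_mass_ug, rrf_truth = NULL, noise_sd = 0,
                            sample = "synthetic-sample",
                            sample_mass_mg = DEFAULT_SAMPLE_MASS_MG,
                            is_amount_ug = DEFAULT_IS_AMOUNT_UG,
                            n_cal_levels = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(true_mass_ug > 0))
  set.seed(seed)
  ladder <- synthetic_alkane_ladder()
  standards <- synthetic_standards(names(true_mass_ug))
  if (is.null(rrf_truth)) rrf_truth <- stats::setNames(
    rep(1, length(true_mass_ug)), names(true_mass_ug))
  rrf_truth <- rrf_truth[names(true_mass_ug)]
  stopifnot(!anyNA(rrf_truth), all(rrf_truth > 0))
  is_area <- 1e6
  noise <- function(n) pmax(1 + stats::rnorm(n, 0, noise_sd), 0.1)
  area <- rrf_truth * true_mass_ug * (is_area / is_amount_ug) *
    noise(length(true_mass_ug))
  rows <- data.frame(
    name = c("5a-cholestane", names(true_mass_ug)),
    area = c(is_area, unname(area)), stringsAsFactors = FALSE)
  rows$ri <- standards$ri[match(rows$name, standards$name)]
  rows$spectrum <- standards$spectrum[match(rows$name, standards$name)]
  rows <- rows[order(rows$ri), ]
  pt <- peak_table(data.frame(rt_min = ri_to_rt(rows$ri, ladder),
                              area = rows$area, spectrum = rows$spectrum,
                              stringsAsFactors = FALSE),
                   sample = sample, sample_mass_mg = sample_mass_mg,
                   is_amount_ug = is_amount_ug)
  # calibration: two mixes, linear responses with the true RRFs (noise-free:
  # calibration error is not the property under test)
  cal <- do.call(rbind, lapply(names(true_mass_ug), function(st) {
    lev <- seq_len(n_cal_levels)
    do.call(rbind, lapply(1:2, function(mx) {
      conc <- lev * 10
      data.frame(sterol = st, mix = mx, level_conc = conc,
                 area = rrf_truth[[st]] * conc / 50 * 1e6,
                 is_area = 1e6, is_conc = 50, stringsAsFactors = FALSE)
    }))
  }))
  mass <- true_mass_ug
  truth <- data.frame(compound = names(mass), mass_ug = unname(mass),
                      conc_ug_mg = unname(mass) / sample_mass_mg,
                      pct = 100 * unname(mass) / sum(mass),
                      stringsAsFactors = FALSE)
  list(peaks = pt, calibration = cal, standards = standards, ladder = ladder,
       truth = truth)
}

#' Synthetic alkane ladder (C7-C40)
#'
#' Retention times follow a smooth concave ramp emulating a
#' temperature-programmed run of about 37 minutes.
#' @return data frame `n`, `rt`.
#' @export
synthetic_alkane_ladder <- function() {
  n <- 7:40
  rt <- 2 + 34 * (1 - exp(-(n - 6) / 14))
  data.frame(n = n, rt = rt)
}

#' Synthetic standards registry
#'
#' Reference retention indices and sparse electron-impact spectra for the
#' sterol panel plus the 5a-cholestane internal standard and squalene.
#' Retention indices are plausible HP-5-type values; spectra are synthetic
#' fingerprints (distinct dominant fragments per compound), adequate for
#' testing identification logic, not library-quality reference spectra.
#'
#' @param compounds optional subset of compound names to include (the
#'   internal standard is always included).
#' @return standards data frame (`name`, `ri`, `spectrum`, `alias_note`,
#'   `role`).
#' @export
synthetic_standards <- function(compounds = NULL) {
  base <- list(
    c("5a-cholestane", 2680, "internal_standard", ""),
    c("squalene", 2790, "precursor", ""),
    c("cholesterol", 3130, "sterol", ""),
    c("desmosterol", 3148, "sterol", ""),
    c("24-methylcholest-22-enol", 3162, "sterol", "brassicasterol proxy"),
    c("lathosterol", 3176, "sterol", ""),
    c("7-dehydrocholesterol", 3192, "sterol", ""),
    c("24-methylcholesterol", 3208, "sterol", "campesterol proxy"),
    c("zymosterol", 3224, "sterol", ""),
    c("24-ethylcholest-22-enol", 3244, "sterol", "stigmasterol proxy"),
    c("lanosterol", 3262, "sterol", ""),
    c("24-ethylcholesterol", 3282, "sterol", "sitosterol proxy"),
    c("fucosterol", 3306, "sterol", ""),
    c("cycloartanol", 3330, "sterol", ""),
    c("cycloartenol", 3352, "sterol", ""))
  df <- data.frame(name = vapply(base, `[`, "", 1),
                   ri = as.numeric(vapply(base, `[`, "", 2)),
                   role = vapply(base, `[`, "", 3),
                   alias_note = vapply(base, `[`, "", 4),
                   stringsAsFactors = FALSE)
  # deterministic synthetic spectra: three dominant fragments per compound
  # spread over m/z 50-500, plus shared steroid backbone ions
  df$spectrum <- vapply(seq_len(nrow(df)), function(i) {
    f1 <- 55 + (i * 37) %% 300
    f2 <- 95 + (i * 61) %% 350
    f3 <- 145 + (i * 83) %% 340
    spec <- c(stats::setNames(c(100, 80, 60), c(f1, f2, f3)),
              "129" = 30, "215" = 20, "69" = 25)
    spec <- tapply(spec, names(spec), max)
    format_spectrum(spec[order(as.numeric(names(spec)))])
  }, "")
  if (!is.null(compounds)) {
    missing <- setdiff(compounds, df$name)
    if (length(missing))
      stop("no synthetic standard for: ", paste(missing, collapse = ", "))
    df <- df[df$name %in% c(compounds, "5a-cholestane"), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Simulate a tree and tip characters under a known SYM model
#'
#' A pure-birth (Yule) tree of the requested size, rescaled to unit height,
#' with tip states simulated by exact CTMC transition sampling from a
#' uniform root state.
#'
#' @param n_tips number of tips.
#' @param rates true symmetric rates (scalar or per-pair vector).
#' @param states state set (default the support states).
#' @param seed integer seed (mandatory).
#' @return list with `tree` (a `support_tree`), `model` (the generating
#'   `sym_model`), `node_states` (true states at all nodes).
#' @export
gen_tree_characters <- function(n_tips, rates = 1,
                                states = c("none", "weak", "strong"), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_tips >= 2)
  set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  model <- with_eig(sym_model(states, rates))
  k <- length(states)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  st <- integer(nnode)
  root <- ntip + 1L
  st[root] <- sample.int(k, 1)
  edge_pre <- rev(seq_len(nrow(ape::reorder.phylo(phy, "postorder")$edge)))
  phy_post <- ape::reorder.phylo(phy, "postorder")
  for (i in edge_pre) {
    par <- phy_post$edge[i, 1]; ch <- phy_post$edge[i, 2]
    P <- sym_pmat(model, phy_post$edge.length[i])
    st[ch] <- sample.int(k, 1, prob = P[st[par], ])
  }
  tip_states <- stats::setNames(states[st[seq_len(ntip)]], phy$tip.label)
  tr <- read_support_tree(phy, tip_states)
  list(tree = tr, model = model,
       node_states = stats::setNames(
         states[st], c(phy$tip.label, paste0("node", (ntip + 1L):nnode))))
}

#' Write synthetic pipeline inputs to disk
#'
#' Writes the same file formats the real pipeline reads (peak table,
#' ladder, standards, calibration), with the generating truth alongside in
#' `*.truth.tsv` files.
#'
#' @param gen result of [gen_peak_tables()].
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_synthetic_inputs <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pt <- gen$peaks
  con <- file.path(dir, "peaks.tsv")
  writeLines(c(sprintf("# sample: %s", attr(pt, "sample")),
               sprintf("# sample_mass_mg: %g", attr(pt, "sample_mass_mg")),
               sprintf("# is_amount_ug: %g", attr(pt, "is_amount_ug"))), con)
  suppressWarnings(utils::write.table(
    as.data.frame(pt), con, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  utils::write.table(gen$ladder, file.path(dir, "ladder.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gen$standards, file.path(dir, "standards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$calibration, file.path(dir, "calibration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$truth, file.path(dir, "peaks.truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
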