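# Loaders for the packaged reference model: the brown-algal sterol
# biosynthesis knowledge base (cycloartenol -> cholesterol / fucosterol /
# 24-alkyl sterols) and the mozukulin specialized-metabolite knowledge base,
# both encoded as plain-text fact fixtures under extdata.

#' Path to a packaged data file
#' @param ... path components below `extdata`.
#' @return absolute file path.
#' @export
sterolpath_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "sterolpath", mustWork = TRUE)
  p
}

#' Brown algal species panel
#'
#' The seven brown algal species of the profiling panel (two Ectocarpus
#' genome species, two further Ectocarpus species, Pylaiella, and two
#' kelps), used as the default in-scope species set for the brown-algal
#' knowledge base.
#' @return character vector.
#' @export
brown_algae_species <- function() {
  c("Ectocarpus-siliculosus", "Ectocarpus-subulatus",
    "Ectocarpus-fasciculatus", "Ectocarpus-crouaniorum",
    "Pylaiella-littoralis", "Saccharina-latissima", "Laminaria-digitata")
}

#' Load the packaged detection table
#' @return data frame `species`, `molecule`, `status`.
#' @export
algae_detection <- function() {
  utils::read.delim(sterolpath_extdata("detection", "algae_detection.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' The brown-algal sterol knowledge base
#'
#' Molecule registry, known reactions (one exemplar per transformation,
#' spanning the demethylation series, the ring opening, the
#' isomerization/desaturation/reduction steps and the side-chain
#' alkylations), detection statuses aggregated over the brown algal panel,
#' source cycloartenol and the four end metabolites as targets.
#'
#' @param species in-scope species (default [brown_algae_species()]).
#' @param targets pathway targets (default the four GC-MS end metabolites).
#' @return a `knowledge_base`.
#' @export
brown_algal_kb <- function(species = brown_algae_species(),
                           targets = c("cholesterol", "fucosterol",
                                       "24-methylcholest-22-enol",
                                       "24-ethylcholest-22-enol")) {
  registry <- load_molecule_registry(c(
    sterolpath_extdata("molecules", "brown_sterols.facts"),
    sterolpath_extdata("molecules", "alkyl_sterols.facts")))
  reactions <- read_reaction_facts(
    sterolpath_extdata("reactions", "brown_reactions.facts"))
  knowledge_base(registry, algae_detection(), reactions,
                 source = "cycloartenol", targets = targets,
                 species = species)
}

#' The mozukulin knowledge base
#'
#' Extends the brown-algal registry with the sterone-derived mozukulin
#' branch of Cladosiphon okamuranus: source is the
#' cholesta-4,24-dien-3-one sterone (reached from desmosterol by the known
#' 3-dehydrogenation/isomerization), targets are mozukulins A and B. The
#' packaged mozukulin structures are synthetic stand-ins consistent with the
#' reaction chemistry (the isolated structures are not encoded here).
#'
#' @return a `knowledge_base` whose strict library is the late-SSR library
#'   plus the sterone boundary oxidation.
#' @export
mozukulin_kb <- function() {
  registry <- load_molecule_registry(c(
    sterolpath_extdata("molecules", "brown_sterols.facts"),
    sterolpath_extdata("molecules", "alkyl_sterols.facts"),
    sterolpath_extdata("molecules", "mozukulins_synthetic.facts")))
  reactions <- rbind(
    read_reaction_facts(sterolpath_extdata("reactions",
                                           "brown_reactions.facts")),
    read_reaction_facts(sterolpath_extdata("reactions",
                                           "mozukulin_reactions.facts")))
  detection <- rbind(
    algae_detection(),
    data.frame(species = "Cladosiphon-okamuranus",
               molecule = c("mozukulin-a", "mozukulin-b"),
               status = "detected", stringsAsFactors = FALSE))
  knowledge_base(registry, detection, reactions,
                 source = "cholesta-4-24-dien-3-one",
                 targets = c("mozukulin-a", "mozukulin-b"),
                 species = "Cladosiphon-okamuranus")
}

#' Auxiliary transformation library
#'
#' Transformations documented in other pathways and organisms, available
#' for level-1 gap-fill import: the sterone-Delta1(2)-desaturation of
#' bacterial/fungal/animal steroid catabolism, the sterone-23-hydroxylation
#' of land-plant brassinosteroid synthesis (encoded at the 23-oxo level),
#' and the animal/fungal sterone-3-reduction that brown algae lack.
#' @return named list of `transformation`s.
#' @export
aux_transformation_library <- function() {
  read_transformation_tsv(
    sterolpath_extdata("transformations", "aux_transformations.tsv"))
}

#' Curated names for positional gap-fill variants
#' @return named character vector (auto-generated name -> curated name).
#' @export
variant_alias_table <- function() {
  c("sterone-3-reduction-at-c23-o2" = "sterone-23-reduction")
}

#' Packaged reference edge list of the brown-algal model
#'
#' The expected pathway edges (chosen chains plus admissible optional
#' routes) of the packaged brown-algal model, used for regression checks
#' and by the acceptance script.
#' @return data frame `transformation`, `substrate`, `product`, `optional`.
#' @export
brown_model_edges <- function() {
  utils::read.delim(sterolpath_extdata("pathways", "brown_model_edges.tsv"),
                    stringsAsFactors = FALSE)
}

#' Packaged synthetic phylogeny of the brown algal panel
#'
#' A synthetic (hand-drawn, plausible-topology) tree of the seven panel
#' species with branch lengths, plus their support states derived from the
#' packaged detection table. A stand-in for a marker-gene tree, shipped so
#' the mapping stage runs end to end without downloads.
#' @return a `support_tree`.
#' @export
brown_support_tree_synthetic <- function() {
  states <- utils::read.delim(
    sterolpath_extdata("trees", "brown_support_states_synthetic.tsv"),
    comment.char = "#", stringsAsFactors = FALSE)
  read_support_tree(
    sterolpath_extdata("trees", "brown_cox3_synthetic.nwk"), states)
}
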