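# End-to-end orchestration: peak tables -> profiles -> detection -> pathway
# inference -> support mapping -> curation recommendation, with a manifest
# recording inputs and seeds for reproducibility.

read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = FALSE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    out[[key]] <- if (grepl(",", val)) trimws(strsplit(val, ",")[[1]]) else val
  }
  out
}

file_digest <- function(path) unname(tools::md5sum(path))

write_manifest <- function(outdir, inputs, params) {
  lines <- c("# run manifest",
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("sterolpath"))),
             "inputs:",
             unlist(lapply(names(inputs), function(n) {
               vapply(inputs[[n]], function(p)
                 sprintf("  %s: %s md5:%s", n, p,
                         tryCatch(file_digest(p),
                                  error = function(e) "NA")), "")
             })),
             "params:",
             vapply(names(params), function(n)
               sprintf("  %s: %s", n, paste(params[[n]], collapse = ",")), ""))
  writeLines(lines, file.path(outdir, "manifest.txt"))
}

#' Run the profiling stage
#'
#' Reads peak tables, identifies peaks against the standards registry,
#' calibrates relative response factors and writes per-sample profiles plus
#' the compounds-by-samples percent table and the detection table.
#'
#' @param peak_files character vector of peak-table TSVs.
#' @param ladder_file alkane ladder TSV.
#' @param standards_file standards registry TSV.
#' @param calibration_file calibration TSV.
#' @param outdir output directory (created).
#' @param ri_tol,s_min identification tolerances (see [identify_peaks()]).
#' @return invisibly, a list with `profiles`, `table`, `detection`.
#' @export
run_profile <- function(peak_files, ladder_file, standards_file,
                        calibration_file, outdir, ri_tol = 10, s_min = 0.8) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ladder <- read_alkane_ladder(ladder_file)
  standards <- read_standards(standards_file)
  rrf <- calibrate(read_calibration(calibration_file))
  profiles <- lapply(peak_files, function(f) {
    pt <- read_peak_table(f)
    ids <- identify_peaks(pt, standards, ladder, ri_tol = ri_tol,
                          s_min = s_min)
    quantify(pt, ids, rrf)
  })
  tab <- profile_table(profiles)
  det <- profiles_to_detection(profiles)
  utils::write.table(tab, file.path(outdir, "profile_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(det, file.path(outdir, "detection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  inputs <- c(stats::setNames(peak_files, paste0("peaks_", seq_along(peak_files))),
              ladder = ladder_file, standards = standards_file,
              calibration = calibration_file)
  write_manifest(outdir, as.list(inputs),
                 list(ri_tol = ri_tol, s_min = s_min))
  invisible(list(profiles = profiles, table = tab, detection = det))
}

#' Run pathway inference and support mapping
#'
#' Loads the molecule registry and known reactions, derives detection from a
#' detection table (e.g. from [run_profile()]), builds the source->target
#' pathway, classifies per-species support, optionally maps support states
#' on a phylogeny by stochastic character mapping, and emits the curation
#' recommendation table gated on strong support.
#'
#' @param molecule_dir directory of molecule fact files.
#' @param reaction_file reaction fact file (known reactions).
#' @param detection_file detection TSV (`species`, `molecule`, `status`).
#' @param source,targets pathway endpoints.
#' @param outdir output directory.
#' @param species optional in-scope species subset.
#' @param tree_file optional newick file; when given, support states are
#'   mapped along it.
#' @param focal_species species whose curation decision is reported
#'   (default: first species in the detection table).
#' @param n_histories histories to sample for the mapping (default 1000).
#' @param seed seed for mapping.
#' @return invisibly, list with `pathway`, `support` (per species),
#'   `frequencies` (or `NULL`), `additions`.
#' @export
run_infer <- function(molecule_dir, reaction_file, detection_file, source,
                      targets, outdir, species = NULL, tree_file = NULL,
                      focal_species = NULL, n_histories = 1000, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_molecule_registry(molecule_dir)
  reactions <- read_reaction_facts(reaction_file)
  detection <- utils::read.delim(detection_file, stringsAsFactors = FALSE,
                                 comment.char = "#")
  kb <- knowledge_base(registry, detection, reactions, source = source,
                       targets = targets, species = species)
  pw <- build_pathway(kb)
  write_pathway_tsv(pw, file.path(outdir, "pathway.tsv"), all = TRUE)
  writeLines(pathway_to_dot(pw), file.path(outdir, "pathway.dot"))

  sp_names <- unique(detection$species)
  support <- lapply(sp_names, function(sp) {
    d <- detection[detection$species == sp, ]
    support_state(stats::setNames(
      ifelse(d$status == "detected", "detected", "nd"), d$molecule),
      species = sp)
  })
  names(support) <- sp_names
  sup_df <- data.frame(species = sp_names,
                       state = vapply(support, function(s) s$state, ""),
                       stringsAsFactors = FALSE)
  utils::write.table(sup_df, file.path(outdir, "support.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  freqs <- NULL
  if (!is.null(tree_file)) {
    tr <- read_support_tree(tree_file,
                            stats::setNames(sup_df$state, sup_df$species))
    fit <- fit_sym_ml(tr, states = c("none", "weak", "strong"))
    hs <- sample_histories(tr, fit$model, n = n_histories, seed = seed)
    freqs <- node_state_frequencies(hs)
    # key each internal node by the tip set it spans, so rows are stable
    # across tools that renumber nodes
    ntip <- length(tr$phy$tip.label)
    tipset <- vapply(seq_len(nrow(freqs)), function(i) {
      tips <- ape::extract.clade(tr$phy, ntip + i)$tip.label
      paste(sort(tips), collapse = ",")
    }, "")
    utils::write.table(data.frame(node = rownames(freqs), tip_set = tipset,
                                  freqs),
                       file.path(outdir, "node_frequencies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  focal <- focal_species %||% sp_names[1]
  additions <- export_gsmn_additions(pw, support[[focal]])
  utils::write.table(additions, file.path(outdir, "gsmn_additions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("focal_species: %s\nsupport: %s\nrationale: %s",
                     focal, support[[focal]]$state,
                     attr(additions, "rationale")),
             file.path(outdir, "curation_decision.txt"))
  inputs <- list(molecules = molecule_dir, reactions = reaction_file,
                 detection = detection_file)
  if (!is.null(tree_file)) inputs$tree <- tree_file
  write_manifest(outdir, inputs,
                 list(source = source, targets = targets, seed = seed,
                      n_histories = n_histories))
  invisible(list(pathway = pw, support = support, frequencies = freqs,
                 additions = additions))
}
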