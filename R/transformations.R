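# Molecular transformations as signed fact-set diffs.
#
# A transformation stores: removed facts, added facts, and context facts --
# facts of the original substrate that touch the anchor positions but are
# unchanged. Context encodes cofactor-independent substrate requirements
# (e.g. side-chain alkylation at c28 requires the Delta24(28) bond) and is
# checked at application time; it is NOT part of transformation identity:
# two transformations with equal removed/added sets are the same type.

#' Construct a transformation
#'
#' @param name transformation name.
#' @param removed,added,context character vectors of fact strings; `removed`
#'   and `added` must be disjoint and not both empty.
#' @param relaxation `"strict"` or `"positional_variant"`.
#' @return object of class `transformation`.
#' @export
transformation <- function(name, removed, added, context = character(),
                           relaxation = "strict") {
  removed <- sort(unique(removed)); added <- sort(unique(added))
  if (length(intersect(removed, added)))
    stop("removed and added fact sets overlap")
  if (!length(removed) && !length(added))
    stop("empty transformation")
  relaxation <- match.arg(relaxation, c("strict", "positional_variant"))
  anchors <- fact_positions(c(removed, added))
  structure(list(name = name, removed = removed, added = added,
                 context = sort(unique(context)), anchors = anchors,
                 relaxation = relaxation),
            class = "transformation")
}

#' @export
print.transformation <- function(x, ...) {
  cat(sprintf("<transformation> %s [%s]\n", x$name, x$relaxation))
  if (length(x$removed)) cat("  - ", paste(x$removed, collapse = " "), "\n")
  if (length(x$added)) cat("  + ", paste(x$added, collapse = " "), "\n")
  invisible(x)
}

#' Derive the transformation between two molecules
#'
#' The signed fact-set diff: `removed = facts(a) \ facts(b)`,
#' `added = facts(b) \ facts(a)`. Because all molecules share the steroid
#' position numbering, no subgraph matching is needed; the same chemical
#' operation on different substrates yields the same diff. Context facts
#' (shared facts mentioning an anchor position) are captured from the
#' substrate.
#'
#' @param a,b substrate and product `steroid_graph`s.
#' @param name optional name; defaults to an automatic name built from the
#'   diff signature.
#' @return a `transformation` such that `apply_transformation(t, a)` has
#'   exactly the fact set of `b`.
#' @export
derive_transformation <- function(a, b, name = NULL) {
  fa <- molecule_facts(a); fb <- molecule_facts(b)
  removed <- setdiff(fa, fb); added <- setdiff(fb, fa)
  if (!length(removed) && !length(added))
    stop("empty transformation: '", a$name, "' and '", b$name,
         "' have identical fact sets")
  anchors <- fact_positions(c(removed, added))
  shared <- intersect(fa, fb)
  touches <- vapply(shared, function(f) any(fact_positions(f) %in% anchors), TRUE)
  tr <- transformation(name %||% auto_name(removed, added),
                       removed, added, context = shared[touches])
  tr
}

# classify a diff into an operation class + positions, for automatic naming
auto_name <- function(removed, added) {
  cls <- diff_shape(removed, added)
  pos <- fact_positions(c(removed, added))
  paste0(cls$class, "-", paste(pos, collapse = "-"))
}

# shape of a diff: counts of atom/bond facts by element/order, used both for
# naming and for the positional-variant compatibility pre-check
diff_shape <- function(removed, added) {
  part <- function(facts) {
    list(atom_c = sum(grepl("^atom\\(.*,carbon\\)$", facts)),
         atom_o = sum(grepl("^atom\\(.*,oxygen\\)$", facts)),
         bond_s = sum(grepl("^bond\\(.*,single\\)$", facts)),
         bond_d = sum(grepl("^bond\\(.*,double\\)$", facts)))
  }
  r <- part(removed); a <- part(added)
  class <- if (a$atom_c > r$atom_c) "alkylation"
  else if (r$atom_c > a$atom_c) "demethylation"
  else if (a$atom_o > r$atom_o) "oxygenation"
  else if (r$atom_o > a$atom_o) "deoxygenation"
  else if (a$bond_d > r$bond_d) "desaturation"
  else if (r$bond_d > a$bond_d) "reduction"
  else "isomerization"
  list(class = class, removed = r, added = a)
}

#' Apply a transformation to a molecule
#'
#' Preconditions: all removed and context facts are present in the substrate,
#' no added fact is already present, and the result passes
#' [validate_skeleton()]. Deterministic fact-set surgery; no search.
#'
#' @param t a `transformation`.
#' @param g substrate `steroid_graph`.
#' @param name product name (default: substrate name plus the transformation
#'   name).
#' @return product `steroid_graph`.
#' @export
apply_transformation <- function(t, g, name = NULL) {
  stopifnot(inherits(t, "transformation"), inherits(g, "steroid_graph"))
  fg <- molecule_facts(g)
  missing <- setdiff(c(t$removed, t$context), fg)
  if (length(missing))
    stop("transformation '", t$name, "' inapplicable to '", g$name,
         "': missing fact(s) ", paste(missing, collapse = ", "))
  clash <- intersect(t$added, fg)
  if (length(clash))
    stop("transformation '", t$name, "' inapplicable to '", g$name,
         "': fact(s) already present ", paste(clash, collapse = ", "))
  out <- union(setdiff(fg, t$removed), t$added)
  nm <- name %||% paste0(g$name, ">", t$name)
  res <- facts_to_graph(out, nm, annotations = g$annotations, validate = FALSE)
  # annotations may be invalidated by the diff (e.g. ring opening)
  if ("cyclopropane-9-19" %in% res$annotations &&
      !any(res$bonds$from == "c9" & res$bonds$to == "c19"))
    res$annotations <- setdiff(res$annotations, "cyclopropane-9-19")
  v <- validate_skeleton(res)
  if (length(v))
    stop("transformation '", t$name, "' on '", g$name,
         "' yields invalid structure: ", paste(v, collapse = "; "))
  res
}

#' Can a transformation be applied?
#' @param t a `transformation`.
#' @param g a `steroid_graph`.
#' @return `TRUE`/`FALSE` without raising.
#' @export
applicable <- function(t, g) {
  fg <- molecule_facts(g)
  if (length(setdiff(c(t$removed, t$context), fg))) return(FALSE)
  if (length(intersect(t$added, fg))) return(FALSE)
  res <- tryCatch(apply_transformation(t, g), error = function(e) NULL)
  !is.null(res)
}

# relabel position labels inside fact strings under a named mapping
relabel_facts <- function(facts, mapping) {
  vapply(facts, function(f) {
    m <- regmatches(f, regexec("^([a-z]+)\\((.*)\\)$", f))[[1]]
    args <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    npos <- if (m[2] == "atom") 1 else 2
    for (i in seq_len(npos))
      if (args[i] %in% names(mapping)) args[i] <- mapping[[args[i]]]
    if (m[2] == "bond") {
      e <- normalize_bond(args[1], args[2])
      args[1] <- e[1]; args[2] <- e[2]
    }
    paste0(m[2], "(", paste(args, collapse = ","), ")")
  }, "", USE.NAMES = FALSE)
}

permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

#' Similarity level between two transformations
#'
#' `identical` when the removed/added fact sets are equal; otherwise
#' `positional_variant` when a bijection between the anchor positions
#' (carbons to carbons, oxygens to oxygens) makes the diffs equal -- the same
#' chemical operation at a different skeletal position, the relaxed matching
#' historically called "type hIIc" homology; `unrelated` otherwise.
#' Symmetric, and invariant to fact-statement order.
#'
#' @param t1,t2 `transformation` objects.
#' @return one of `"identical"`, `"positional_variant"`, `"unrelated"`.
#' @export
match_level <- function(t1, t2) {
  if (setequal(t1$removed, t2$removed) && setequal(t1$added, t2$added))
    return("identical")
  s1 <- diff_shape(t1$removed, t1$added); s2 <- diff_shape(t2$removed, t2$added)
  if (!identical(s1$removed, s2$removed) || !identical(s1$added, s2$added))
    return("unrelated")
  map <- variant_mapping(t1, t2)
  if (!is.null(map)) "positional_variant" else "unrelated"
}

# find a label bijection from anchors(t2) onto anchors(t1) that equates the
# diffs, or NULL; brute force is exact (model diffs touch <= 5 labels)
variant_mapping <- function(t1, t2) {
  a1 <- t1$anchors; a2 <- t2$anchors
  if (length(a1) != length(a2)) return(NULL)
  c1 <- a1[position_element(a1) == "carbon"]; o1 <- a1[position_element(a1) == "oxygen"]
  c2 <- a2[position_element(a2) == "carbon"]; o2 <- a2[position_element(a2) == "oxygen"]
  if (length(c1) != length(c2) || length(o1) != length(o2)) return(NULL)
  for (pc in permutations(c1)) {
    for (po in if (length(o1)) permutations(o1) else list(character())) {
      mapping <- stats::setNames(c(pc, po), c(c2, o2))
      ok <- setequal(relabel_facts(t2$removed, mapping), t1$removed) &&
            setequal(relabel_facts(t2$added, mapping), t1$added)
      if (ok) return(mapping)
    }
  }
  NULL
}

#' Build a positional variant of a transformation
#'
#' Relabels the anchor positions of `t` under `mapping` (named vector,
#' old label -> new label), producing a concrete transformation at the new
#' position, flagged `positional_variant`. Context facts are relabelled where
#' they mention remapped anchors and dropped where the relabelled fact would
#' not make sense for an arbitrary substrate (non-anchor neighbours).
#'
#' @param t a `transformation`.
#' @param mapping named character vector.
#' @param name name for the variant.
#' @return a `transformation`.
#' @export
variant_at <- function(t, mapping, name = NULL) {
  removed <- relabel_facts(t$removed, mapping)
  added <- relabel_facts(t$added, mapping)
  transformation(name %||% paste0(t$name, "-variant-",
                                  paste(unname(mapping), collapse = "-")),
                 removed, added, context = character(),
                 relaxation = "positional_variant")
}

# ---- library I/O ------------------------------------------------------------

FACT_SEP <- " "

#' Write a transformation library to TSV
#'
#' Columns: name, removed, added, context (space-separated fact strings),
#' relaxation.
#' @param lib list of `transformation`s.
#' @param path output file.
#' @export
write_transformation_tsv <- function(lib, path) {
  df <- data.frame(
    name = vapply(lib, function(t) t$name, ""),
    removed = vapply(lib, function(t) paste(t$removed, collapse = FACT_SEP), ""),
    added = vapply(lib, function(t) paste(t$added, collapse = FACT_SEP), ""),
    context = vapply(lib, function(t) paste(t$context, collapse = FACT_SEP), ""),
    relaxation = vapply(lib, function(t) t$relaxation, ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transformation library from TSV
#' @param path file written by [write_transformation_tsv()].
#' @return named list of `transformation`s.
#' @export
read_transformation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  split_facts <- function(x) if (!nzchar(x)) character()
                             else strsplit(x, FACT_SEP, fixed = TRUE)[[1]]
  lib <- lapply(seq_len(nrow(df)), function(i)
    transformation(df$name[i], split_facts(df$removed[i]),
                   split_facts(df$added[i]), split_facts(df$context[i]),
                   df$relaxation[i]))
  names(lib) <- df$name
  lib
}

#' Parse a reaction fact file
#'
#' Grammar: `reaction(<transformation-name>, <substrate>, <product>).` lines,
#' `#` comments. Several reactions may share a transformation name -- the
#' same molecular transformation occurring on different substrates.
#'
#' @param path file path or character vector of lines (if no such file).
#' @return data frame with columns `transformation`, `substrate`, `product`.
#' @export
read_reaction_facts <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  pat <- "^\\s*reaction\\(([^,]+),([^,]+),([^)]+)\\)\\.\\s*$"
  rows <- lapply(keep, function(i) {
    m <- regmatches(lines[i], regexec(pat, lines[i]))[[1]]
    if (!length(m)) stop("syntax error in reaction file at line ", i, ": ",
                         trimws(lines[i]))
    trimws(m[2:4])
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("transformation", "substrate", "product")
  df
}

#' Derive a transformation library from known reactions
#'
#' For every distinct transformation name in a reaction table, derives the
#' diff from its first substrate/product exemplar (skipping reactions whose
#' substrate is an opaque token) and verifies that all other same-name
#' reactions carry an identical diff.
#'
#' @param registry a `molecule_registry`.
#' @param reactions data frame from [read_reaction_facts()].
#' @return named list of `transformation`s.
#' @export
derive_library <- function(registry, reactions) {
  lib <- list()
  for (nm in unique(reactions$transformation)) {
    rows <- reactions[reactions$transformation == nm, , drop = FALSE]
    first <- NULL
    for (i in seq_len(nrow(rows))) {
      sub <- resolve_name(registry, rows$substrate[i])
      if (sub %in% registry$tokens) next  # boundary reaction, no diff
      a <- registry_molecule(registry, rows$substrate[i])
      b <- registry_molecule(registry, rows$product[i])
      t <- derive_transformation(a, b, name = nm)
      if (is.null(first)) first <- t
      else if (match_level(first, t) != "identical")
        stop("reactions named '", nm, "' carry different diffs")
    }
    if (!is.null(first)) lib[[nm]] <- first
  }
  lib
}
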