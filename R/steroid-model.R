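#' @keywords internal
"_PACKAGE"

# Fact strings are the exchange currency of the whole package: a molecule is a
# set of strings "atom(<pos>,<element>)" and "bond(<pos1>,<pos2>,<order>)"
# with positions on the shared steroid numbering (c1..c27 core, c28/c29
# side-chain or 4,4-ring methyls, c30 the 14-methyl, o1.. oxygens).

BOND_ORDERS <- c(single = 1, double = 2)
MAX_VALENCE <- c(carbon = 4, oxygen = 2)

position_element <- function(pos) {
  ifelse(startsWith(pos, "o"), "oxygen", "carbon")
}

# natural sort for position labels: prefix letter, then number
order_positions <- function(pos) {
  prefix <- substr(pos, 1, 1)
  num <- suppressWarnings(as.integer(substring(pos, 2)))
  num[is.na(num)] <- 0L
  order(prefix, num, pos)
}

sort_positions <- function(pos) pos[order_positions(pos)]

normalize_bond <- function(p1, p2) {
  swap <- order_positions(c(p1, p2))[1] == 2
  if (swap) c(p2, p1) else c(p1, p2)
}

#' Construct a steroid graph
#'
#' A steroid molecule represented as a relational fact set on the standard
#' numbered carbon skeleton. Hydrogens are implicit; a 3-ketone is encoded as
#' a `c3=o1` double bond, the 9beta,19-cyclopropane ring of cyclosterols as an
#' explicit `c9-c19` single bond next to the usual `c10-c19` bond.
#'
#' @param name molecule identifier (lower-case, `[a-z0-9-]`).
#' @param atoms named character vector mapping position labels to elements
#'   (`"carbon"` or `"oxygen"`), e.g. `c(c1 = "carbon", o1 = "oxygen")`.
#' @param bonds data frame with columns `from`, `to`, `order`
#'   (`"single"`/`"double"`); bonds are unordered pairs.
#' @param annotations optional character vector of free-form flags.
#' @return an object of class `steroid_graph`.
#' @export
steroid_graph <- function(name, atoms, bonds, annotations = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(atoms)) || anyDuplicated(names(atoms)))
    stop("atom position labels must be unique and named")
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds)) {
    norm <- t(mapply(normalize_bond, bonds$from, bonds$to))
    bonds$from <- norm[, 1]
    bonds$to <- norm[, 2]
    key <- paste(bonds$from, bonds$to)
    if (anyDuplicated(key)) stop("duplicate bond between ", key[duplicated(key)][1])
    all_pos <- sort_positions(unique(c(bonds$from, bonds$to)))
    bonds <- bonds[order(match(bonds$from, all_pos), match(bonds$to, all_pos)), ,
                   drop = FALSE]
    rownames(bonds) <- NULL
  }
  g <- structure(
    list(name = name,
         atoms = atoms[sort_positions(names(atoms))],
         bonds = bonds,
         annotations = sort(unique(annotations))),
    class = "steroid_graph")
  g
}

#' @export
print.steroid_graph <- function(x, ...) {
  nc <- sum(position_element(names(x$atoms)) == "carbon")
  no <- sum(position_element(names(x$atoms)) == "oxygen")
  nd <- sum(x$bonds$order == "double")
  cat(sprintf("<steroid_graph> %s: C%d O%d, %d bonds (%d double)%s\n",
              x$name, nc, no, nrow(x$bonds), nd,
              if (length(x$annotations))
                paste0(" [", paste(x$annotations, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Fact set of a molecule
#'
#' Returns the molecule's atoms and bonds as a sorted character vector of
#' name-independent fact strings, the representation on which transformation
#' diffs operate.
#'
#' @param g a `steroid_graph`.
#' @return sorted character vector of `atom(pos,element)` and
#'   `bond(pos1,pos2,order)` strings.
#' @export
molecule_facts <- function(g) {
  stopifnot(inherits(g, "steroid_graph"))
  af <- sprintf("atom(%s,%s)", names(g$atoms), unname(g$atoms))
  bf <- if (nrow(g$bonds))
    sprintf("bond(%s,%s,%s)", g$bonds$from, g$bonds$to, g$bonds$order)
  else character()
  sort(c(af, bf))
}

fact_positions <- function(facts) {
  inner <- sub("^[a-z]+\\(", "", sub("\\)$", "", facts))
  parts <- strsplit(inner, ",", fixed = TRUE)
  labs <- unlist(lapply(parts, function(p) {
    if (length(p) == 2) p[1] else p[1:2]
  }))
  sort_positions(unique(labs))
}

#' Rebuild a steroid graph from a fact set
#'
#' Inverse of [molecule_facts()]: turns fact strings back into a validated
#' `steroid_graph`.
#'
#' @param facts character vector of fact strings.
#' @param name molecule name for the rebuilt graph.
#' @param annotations optional annotations to carry over.
#' @param validate check skeleton invariants (default `TRUE`).
#' @return a `steroid_graph`.
#' @export
facts_to_graph <- function(facts, name, annotations = character(), validate = TRUE) {
  facts <- sort(unique(facts))
  is_atom <- startsWith(facts, "atom(")
  is_bond <- startsWith(facts, "bond(")
  if (!all(is_atom | is_bond)) stop("unrecognized fact: ", facts[!(is_atom | is_bond)][1])
  strip <- function(x, head) strsplit(sub("\\)$", "", sub(head, "", x)), ",", fixed = TRUE)
  ap <- strip(facts[is_atom], "^atom\\(")
  atoms <- vapply(ap, `[`, "", 2)
  names(atoms) <- vapply(ap, `[`, "", 1)
  bp <- strip(facts[is_bond], "^bond\\(")
  bonds <- data.frame(
    from = vapply(bp, `[`, "", 1),
    to = vapply(bp, `[`, "", 2),
    order = vapply(bp, `[`, "", 3),
    stringsAsFactors = FALSE)
  g <- steroid_graph(name, atoms, bonds, annotations)
  if (validate) {
    v <- validate_skeleton(g)
    if (length(v)) stop("invalid molecule '", name, "': ", paste(v, collapse = "; "))
  }
  g
}

#' Validate steroid skeleton invariants
#'
#' Checks, without raising, that (i) every bond endpoint is a declared atom,
#' (ii) no atom exceeds its valence counting bond orders (4 for carbon, 2 for
#' oxygen, hydrogens implicit), (iii) declared bond orders are known, and
#' (iv) the carbon skeleton is connected through carbon-carbon bonds.
#'
#' @param g a `steroid_graph`.
#' @return character vector of violation messages; empty when all invariants
#'   hold.
#' @export
validate_skeleton <- function(g) {
  stopifnot(inherits(g, "steroid_graph"))
  bad <- character()
  atoms <- g$atoms
  b <- g$bonds
  if (!all(atoms %in% names(MAX_VALENCE)))
    bad <- c(bad, paste0("unknown element for ", names(atoms)[!atoms %in% names(MAX_VALENCE)]))
  if (nrow(b)) {
    dangling <- setdiff(c(b$from, b$to), names(atoms))
    if (length(dangling))
      bad <- c(bad, paste0("bond references undeclared atom ", sort(dangling)))
    badord <- setdiff(b$order, names(BOND_ORDERS))
    if (length(badord)) bad <- c(bad, paste0("unknown bond order ", badord))
    keep <- b$from %in% names(atoms) & b$to %in% names(atoms) & b$order %in% names(BOND_ORDERS)
    b2 <- b[keep, , drop = FALSE]
    if (nrow(b2)) {
      w <- BOND_ORDERS[b2$order]
      val <- tapply(c(w, w), c(b2$from, b2$to), sum)
      lim <- MAX_VALENCE[atoms[names(val)]]
      over <- !is.na(lim) & val > lim
      if (any(over))
        bad <- c(bad, sprintf("valence exceeded at %s (%d > %d)",
                              names(val)[over], as.integer(val[over]), as.integer(lim[over])))
    }
  }
  carb <- names(atoms)[atoms == "carbon"]
  if (length(carb) > 1) {
    cb <- b[b$from %in% carb & b$to %in% carb, , drop = FALSE]
    comp <- connected_components(carb, cb)
    if (max(comp) > 1) bad <- c(bad, "carbon skeleton is not connected")
  }
  bad
}

connected_components <- function(nodes, edges) {
  comp <- seq_along(nodes)
  names(comp) <- nodes
  if (nrow(edges)) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(edges))) {
        a <- comp[edges$from[i]]; bb <- comp[edges$to[i]]
        if (a != bb) {
          comp[comp == max(a, bb)] <- min(a, bb)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, sort(unique(comp)))
}

#' Canonical identifier of a molecule structure
#'
#' A function of the fact set only: statement order, molecule name and
#' annotations do not affect it, so structurally equal molecules always share
#' one id and (within a registry) structurally different molecules get
#' different ids.
#'
#' @param g a `steroid_graph` or a character vector of facts.
#' @return a single string.
#' @export
canonical_id <- function(g) {
  facts <- if (inherits(g, "steroid_graph")) molecule_facts(g) else sort(unique(g))
  paste(facts, collapse = ";")
}

#' Short digest of a canonical id
#'
#' Used to name machine-generated (inferred) structures.
#' @param g a `steroid_graph` or fact vector.
#' @return 10-character hex digest.
#' @export
short_id <- function(g) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canonical_id(g), tf)
  substr(unname(tools::md5sum(tf)), 1, 10)
}

# ---- fact-file grammar ------------------------------------------------------

#' Parse a molecule fact block
#'
#' Line-oriented grammar: `atom(<mol>, <pos>, <element>).`,
#' `bond(<mol>, <pos1>, <pos2>, <order>).`, `annotation(<mol>, <flag>).`,
#' `alias(<name>, <canonical>).`, `token(<name>).` (opaque precursor with no
#' structure, e.g. squalene); `#` starts a comment.
#'
#' @param text character vector of lines (or a single string with newlines).
#' @return named list with `molecules` (list of `steroid_graph`), `aliases`
#'   (named character vector alias -> canonical) and `tokens` (character).
#' @export
parse_molecule_block <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  pat <- "^\\s*([a-z_]+)\\(([^)]*)\\)\\.\\s*$"
  atoms <- list(); bonds <- list(); ann <- list()
  aliases <- character(); tokens <- character()
  for (i in keep) {
    ln <- lines[i]
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    if (!length(m)) stop("syntax error at line ", i, ": ", trimws(ln))
    head <- m[2]
    args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    add <- function(store, mol, row) {
      store[[mol]] <- c(store[[mol]], list(row)); store
    }
    if (head == "atom" && length(args) == 3) {
      atoms <- add(atoms, args[1], args[2:3])
    } else if (head == "bond" && length(args) == 4) {
      bonds <- add(bonds, args[1], args[2:4])
    } else if (head == "annotation" && length(args) == 2) {
      ann <- add(ann, args[1], args[2])
    } else if (head == "alias" && length(args) == 2) {
      aliases[args[1]] <- args[2]
    } else if (head == "token" && length(args) == 1) {
      tokens <- c(tokens, args[1])
    } else {
      stop("syntax error at line ", i, ": unknown statement '", head,
           "' with ", length(args), " arguments")
    }
  }
  mols <- lapply(sort(unique(c(names(atoms), names(bonds)))), function(mol) {
    am <- do.call(rbind, atoms[[mol]])
    if (is.null(am)) stop("molecule '", mol, "' has bonds but no atoms")
    a <- am[, 2]; names(a) <- am[, 1]
    if (anyDuplicated(names(a))) stop("duplicate atom position in '", mol, "'")
    bm <- do.call(rbind, bonds[[mol]])
    bdf <- if (is.null(bm)) data.frame(from = character(), to = character(),
                                       order = character())
           else data.frame(from = bm[, 1], to = bm[, 2], order = bm[, 3],
                           stringsAsFactors = FALSE)
    g <- steroid_graph(mol, a, bdf, unlist(ann[[mol]]) %||% character())
    v <- validate_skeleton(g)
    if (length(v)) stop("validation failure in '", mol, "': ",
                        paste(v, collapse = "; "))
    g
  })
  names(mols) <- vapply(mols, function(g) g$name, "")
  list(molecules = mols, aliases = aliases, tokens = sort(unique(tokens)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a single molecule from fact text
#'
#' Convenience wrapper around [parse_molecule_block()] for text describing one
#' molecule.
#' @param text fact lines.
#' @return a `steroid_graph`.
#' @export
parse_molecule <- function(text) {
  res <- parse_molecule_block(text)
  if (length(res$molecules) != 1)
    stop("expected exactly one molecule, found ", length(res$molecules))
  res$molecules[[1]]
}

#' Serialize a molecule to fact text
#'
#' Emits the grammar read by [parse_molecule()]; `parse(serialize(g))` equals
#' `g` on fact sets.
#' @param g a `steroid_graph`.
#' @return character vector of lines.
#' @export
serialize_molecule <- function(g) {
  stopifnot(inherits(g, "steroid_graph"))
  out <- c(
    sprintf("atom(%s, %s, %s).", g$name, names(g$atoms), unname(g$atoms)),
    if (nrow(g$bonds))
      sprintf("bond(%s, %s, %s, %s).", g$name, g$bonds$from, g$bonds$to, g$bonds$order),
    if (length(g$annotations))
      sprintf("annotation(%s, %s).", g$name, g$annotations))
  out
}

#' Load a molecule registry from fact files
#'
#' Reads every `*.facts` file in a directory (or an explicit file list) and
#' assembles the molecule registry: named list of graphs plus alias table and
#' opaque precursor tokens.
#'
#' @param path directory containing fact files, or character vector of files.
#' @return object of class `molecule_registry`: list with `molecules`,
#'   `aliases`, `tokens`.
#' @export
load_molecule_registry <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path))
    list.files(path, pattern = "\\.facts$", full.names = TRUE)
  else path
  if (!length(files)) stop("no .facts files found in ", path)
  mols <- list(); aliases <- character(); tokens <- character()
  for (f in sort(files)) {
    res <- parse_molecule_block(readLines(f, warn = FALSE))
    dup <- intersect(names(res$molecules), names(mols))
    if (length(dup)) stop("duplicate molecule name(s): ", paste(dup, collapse = ", "))
    mols <- c(mols, res$molecules)
    aliases <- c(aliases, res$aliases)
    tokens <- c(tokens, res$tokens)
  }
  structure(list(molecules = mols, aliases = aliases,
                 tokens = sort(unique(tokens))),
            class = "molecule_registry")
}

#' @export
print.molecule_registry <- function(x, ...) {
  cat(sprintf("<molecule_registry> %d molecules, %d aliases, %d tokens\n",
              length(x$molecules), length(x$aliases), length(x$tokens)))
  invisible(x)
}

#' Resolve a molecule name in a registry
#'
#' Follows proxy aliases (e.g. campesterol -> 24-methylcholesterol, the
#' commercial epimer proxy) and errors on unknown names.
#' @param registry a `molecule_registry`.
#' @param name molecule or alias or token name.
#' @return the canonical name (tokens resolve to themselves).
#' @export
resolve_name <- function(registry, name) {
  if (name %in% names(registry$molecules)) return(name)
  if (name %in% names(registry$aliases)) return(unname(registry$aliases[[name]]))
  if (name %in% registry$tokens) return(name)
  stop("molecule '", name, "' not found in registry")
}

#' Fetch a molecule from a registry
#' @param registry a `molecule_registry`.
#' @param name molecule or alias name.
#' @return a `steroid_graph`.
#' @export
registry_molecule <- function(registry, name) {
  nm <- resolve_name(registry, name)
  if (nm %in% registry$tokens)
    stop("'", nm, "' is an opaque precursor token with no structure")
  registry$molecules[[nm]]
}

# ---- scaffold builders (shared by fixtures and the synthetic generator) -----

#' Cholestane scaffold
#'
#' The saturated C27 sterol skeleton with a 3beta-hydroxyl: four fused rings
#' (A: c1-c2-c3-c4-c5-c10, B: c5-c6-c7-c8-c9-c10, C: c8-c9-c11-c12-c13-c14,
#' D: c13-c14-c15-c16-c17), angular methyls c18 (on c13) and c19 (on c10),
#' and the c17 side chain c20..c27. All bonds single; modify with
#' [with_double()], [with_methyl()], [with_cyclopropane_9_19()].
#'
#' @param name molecule name.
#' @return a `steroid_graph`.
#' @export
cholestane_scaffold <- function(name = "cholestanol") {
  pairs <- list(
    c("c1", "c2"), c("c2", "c3"), c("c3", "c4"), c("c4", "c5"), c("c5", "c10"),
    c("c1", "c10"), c("c5", "c6"), c("c6", "c7"), c("c7", "c8"), c("c8", "c9"),
    c("c9", "c10"), c("c9", "c11"), c("c11", "c12"), c("c12", "c13"),
    c("c13", "c14"), c("c8", "c14"), c("c13", "c17"), c("c16", "c17"),
    c("c15", "c16"), c("c14", "c15"), c("c13", "c18"), c("c10", "c19"),
    c("c17", "c20"), c("c20", "c21"), c("c20", "c22"), c("c22", "c23"),
    c("c23", "c24"), c("c24", "c25"), c("c25", "c26"), c("c25", "c27"),
    c("c3", "o1"))
  atoms <- c(stats::setNames(rep("carbon", 27), paste0("c", 1:27)),
             o1 = "oxygen")
  bonds <- data.frame(from = vapply(pairs, `[`, "", 1),
                      to = vapply(pairs, `[`, "", 2),
                      order = "single", stringsAsFactors = FALSE)
  steroid_graph(name, atoms, bonds)
}

#' Set a bond order on a molecule
#' @param g a `steroid_graph`.
#' @param p1,p2 bond endpoints.
#' @param order `"double"` or `"single"`.
#' @return modified `steroid_graph`.
#' @export
with_double <- function(g, p1, p2, order = "double") {
  e <- normalize_bond(p1, p2)
  i <- which(g$bonds$from == e[1] & g$bonds$to == e[2])
  if (!length(i)) stop("no bond ", p1, "-", p2, " in ", g$name)
  g$bonds$order[i] <- order
  g
}

#' Attach a methyl (or generic substituent) carbon
#' @param g a `steroid_graph`.
#' @param at position carrying the substituent.
#' @param label new position label.
#' @param element element of the new atom.
#' @param order bond order to the attachment point.
#' @return modified `steroid_graph`.
#' @export
with_methyl <- function(g, at, label, element = "carbon", order = "single") {
  if (label %in% names(g$atoms)) stop("position ", label, " already present")
  g$atoms <- c(g$atoms, stats::setNames(element, label))
  g$atoms <- g$atoms[sort_positions(names(g$atoms))]
  e <- normalize_bond(at, label)
  g$bonds <- rbind(g$bonds,
                   data.frame(from = e[1], to = e[2], order = order,
                              stringsAsFactors = FALSE))
  g
}

#' Close the 9beta,19-cyclopropane ring of cyclosterols
#' @param g a `steroid_graph` with a c10-c19 methyl.
#' @return modified `steroid_graph` with the extra c9-c19 single bond and a
#'   `cyclopropane-9-19` annotation.
#' @export
with_cyclopropane_9_19 <- function(g) {
  e <- normalize_bond("c9", "c19")
  g$bonds <- rbind(g$bonds, data.frame(from = e[1], to = e[2], order = "single",
                                       stringsAsFactors = FALSE))
  g$annotations <- sort(unique(c(g$annotations, "cyclopropane-9-19")))
  g
}

#' Rename a molecule
#' @param g a `steroid_graph`.
#' @param name new name.
#' @return renamed graph.
#' @export
rename_molecule <- function(g, name) { g$name <- name; g }
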