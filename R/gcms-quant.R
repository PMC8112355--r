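# Semi-quantitative GC-MS sterol profiling: linear retention indices against
# an n-alkane ladder, identification by retention index + spectral cosine
# similarity, internal-standard relative-response-factor calibration averaged
# over standard mixes, percent composition with the 0.01 % not-detectable
# rule, and pathway support-state classification.

ND_THRESHOLD_PCT <- 0.01   # relative abundance below this is reported "nd"
DEFAULT_IS_AMOUNT_UG <- 5  # 5 ul of 1 mg/ml internal standard
DEFAULT_SAMPLE_MASS_MG <- 60

#' Linear (temperature-programmed) retention index
#'
#' `RI = 100 * (n + (rt - t_n) / (t_{n+1} - t_n))` for the alkane bracket
#' `t_n <= rt <= t_{n+1}`; the linear index appropriate for a ramped oven
#' program.
#'
#' @param rt retention time (minutes), vectorised.
#' @param ladder data frame with columns `n` (alkane carbon number) and `rt`
#'   (retention time, strictly increasing with `n`).
#' @return numeric retention index (100 * carbon-number units).
#' @export
retention_index <- function(rt, ladder) {
  ladder <- ladder[order(ladder$n), , drop = FALSE]
  if (any(diff(ladder$rt) <= 0))
    stop("alkane ladder retention times must be strictly increasing")
  vapply(rt, function(x) {
    if (is.na(x) || x < min(ladder$rt) || x > max(ladder$rt))
      stop("retention time ", x, " outside alkane ladder span [",
           min(ladder$rt), ", ", max(ladder$rt), "]")
    i <- findInterval(x, ladder$rt, rightmost.closed = TRUE)
    100 * (ladder$n[i] + (x - ladder$rt[i]) /
             (ladder$rt[i + 1] - ladder$rt[i]))
  }, 0)
}

#' Inverse retention-index interpolation
#'
#' Maps a retention index back to a retention time on a ladder; used by the
#' synthetic peak-table generator.
#' @param ri retention index, vectorised.
#' @param ladder alkane ladder data frame (`n`, `rt`).
#' @return retention time in minutes.
#' @export
ri_to_rt <- function(ri, ladder) {
  ladder <- ladder[order(ladder$n), , drop = FALSE]
  vapply(ri, function(x) {
    n <- x / 100
    if (n < min(ladder$n) || n > max(ladder$n))
      stop("retention index ", x, " outside ladder span")
    i <- findInterval(n, ladder$n, rightmost.closed = TRUE)
    ladder$rt[i] + (n - ladder$n[i]) * (ladder$rt[i + 1] - ladder$rt[i])
  }, 0)
}

#' Parse a sparse spectrum string
#'
#' Format `mz:intensity;mz:intensity;...` over m/z 50-500.
#' @param s spectrum string.
#' @return named numeric vector (names = m/z).
#' @export
parse_spectrum <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(), character()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  mz <- vapply(parts, function(p) as.numeric(p[1]), 0)
  int <- vapply(parts, function(p) as.numeric(p[2]), 0)
  if (any(mz < 50 | mz > 500)) stop("spectrum m/z outside scanned range 50-500")
  stats::setNames(int, mz)
}

format_spectrum <- function(spec) {
  paste(sprintf("%s:%g", names(spec), unname(spec)), collapse = ";")
}

#' Cosine similarity between two sparse spectra
#' @param a,b named numeric vectors (names = m/z) or spectrum strings.
#' @return cosine similarity in `[0, 1]` (0 when either is empty).
#' @export
spectral_cosine <- function(a, b) {
  if (is.character(a)) a <- parse_spectrum(a)
  if (is.character(b)) b <- parse_spectrum(b)
  mz <- union(names(a), names(b))
  if (!length(mz)) return(0)
  va <- ifelse(mz %in% names(a), a[mz], 0)
  vb <- ifelse(mz %in% names(b), b[mz], 0)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Read a peak table TSV
#'
#' Columns: `rt_min`, `area`, `spectrum` (`mz:int;...`). Metadata lines at
#' the top of the file, `# sample: <id>`, `# sample_mass_mg: <x>`,
#' `# is_amount_ug: <x>`, set the sample id, dry mass and internal-standard
#' amount (defaults: 60 mg and 5 ug).
#'
#' @param path TSV file.
#' @return object of class `peak_table` (data frame with attributes
#'   `sample`, `sample_mass_mg`, `is_amount_ug`).
#' @export
read_peak_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE, na.strings = NULL)
  peak_table(df,
             sample = get_meta("sample", tools::file_path_sans_ext(basename(path))),
             sample_mass_mg = as.numeric(get_meta("sample_mass_mg",
                                                  DEFAULT_SAMPLE_MASS_MG)),
             is_amount_ug = as.numeric(get_meta("is_amount_ug",
                                                DEFAULT_IS_AMOUNT_UG)))
}

#' Construct and validate a peak table
#' @param df data frame with `rt_min`, `area`, `spectrum`.
#' @param sample sample id.
#' @param sample_mass_mg dry mass extracted (mg).
#' @param is_amount_ug internal-standard amount (micrograms).
#' @return a `peak_table`.
#' @export
peak_table <- function(df, sample, sample_mass_mg = DEFAULT_SAMPLE_MASS_MG,
                       is_amount_ug = DEFAULT_IS_AMOUNT_UG) {
  stopifnot(all(c("rt_min", "area", "spectrum") %in% names(df)))
  if (any(df$rt_min < 0)) stop("negative retention time")
  if (is.unsorted(df$rt_min, strictly = TRUE))
    stop("retention times must be strictly increasing down the table")
  if (any(df$area < 0)) stop("negative peak area")
  lapply(df$spectrum, parse_spectrum)  # validates m/z range
  structure(df, class = c("peak_table", "data.frame"), sample = sample,
            sample_mass_mg = sample_mass_mg, is_amount_ug = is_amount_ug)
}

#' Read an alkane ladder TSV
#' @param path TSV with columns `n`, `rt`.
#' @return validated ladder data frame.
#' @export
read_alkane_ladder <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("n", "rt") %in% names(df)))
  df <- df[order(df$n), , drop = FALSE]
  if (any(diff(df$rt) <= 0)) stop("ladder retention times not increasing")
  df
}

#' Read a standards registry TSV
#'
#' Columns: `name`, `ri` (reference retention index), `spectrum`
#' (`mz:int;...`), optional `alias_note` (epimer-proxy note reported with
#' identifications), optional `role` (`sterol` / `internal_standard` /
#' `precursor`).
#' @param path TSV file.
#' @return data frame.
#' @export
read_standards <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  stopifnot(all(c("name", "ri", "spectrum") %in% names(df)))
  if (!"alias_note" %in% names(df)) df$alias_note <- ""
  if (!"role" %in% names(df)) df$role <- "sterol"
  df
}

#' Identify peaks against a standards registry
#'
#' A peak matches a standard when the retention-index deviation is within
#' `ri_tol` AND the spectral cosine similarity is at least `s_min`; among
#' qualifying standards the highest spectral score wins, ties broken by the
#' smallest retention-index deviation. Unmatched peaks are reported as
#' `unidentified`.
#'
#' @param pt a `peak_table`.
#' @param standards standards registry data frame ([read_standards()]).
#' @param ladder alkane ladder for retention indexing.
#' @param ri_tol retention-index tolerance (default 10 index units).
#' @param s_min minimum spectral cosine similarity (default 0.8).
#' @return data frame with one row per peak: `rt_min`, `ri`, `area`,
#'   `compound` (`"unidentified"` when unmatched), `score`, `delta_ri`,
#'   `alias_note`.
#' @export
identify_peaks <- function(pt, standards, ladder, ri_tol = 10, s_min = 0.8) {
  ri <- retention_index(pt$rt_min, ladder)
  ref_spec <- lapply(standards$spectrum, parse_spectrum)
  out <- lapply(seq_len(nrow(pt)), function(i) {
    spec <- parse_spectrum(pt$spectrum[i])
    d_ri <- abs(standards$ri - ri[i])
    scores <- vapply(ref_spec, function(s) spectral_cosine(spec, s), 0)
    ok <- d_ri <= ri_tol & scores >= s_min
    if (!any(ok)) {
      return(data.frame(rt_min = pt$rt_min[i], ri = ri[i], area = pt$area[i],
                        compound = "unidentified", score = NA_real_,
                        delta_ri = NA_real_, alias_note = "",
                        stringsAsFactors = FALSE))
    }
    cand <- which(ok)
    cand <- cand[order(-scores[cand], d_ri[cand], standards$name[cand])]
    j <- cand[1]
    data.frame(rt_min = pt$rt_min[i], ri = ri[i], area = pt$area[i],
               compound = standards$name[j], score = scores[j],
               delta_ri = d_ri[j], alias_note = standards$alias_note[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a calibration TSV
#'
#' Columns: `sterol`, `mix` (1 or 2), `level_conc` (analyte concentration),
#' `area`, `is_area`, `is_conc` (internal-standard concentration at that
#' level).
#' @param path TSV file.
#' @return data frame.
#' @export
read_calibration <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sterol", "mix", "level_conc", "area", "is_area", "is_conc")
                %in% names(df)))
  df
}

#' Relative response factors from a calibration set
#'
#' The averaged-standard-curve method: for every sterol, the relative
#' response factor is the mean over all calibration levels of both standard
#' mixes of `(area / is_area) / (conc / is_conc)` -- a linear-through-origin
#' internal-standard calibration. Per-mix means and their relative spread
#' are reported alongside.
#'
#' @param cs calibration data frame ([read_calibration()]).
#' @return data frame with columns `sterol`, `rrf`, `rrf_mix1`, `rrf_mix2`,
#'   `rel_spread`, `n_levels`.
#' @export
calibrate <- function(cs) {
  if (any(cs$is_area <= 0)) stop("internal-standard area must be positive")
  mixes <- sort(unique(cs$mix))
  if (length(mixes) == 1)
    warning("single calibration mix present; proceeding without cross-mix averaging")
  out <- lapply(sort(unique(cs$sterol)), function(st) {
    rows <- cs[cs$sterol == st, , drop = FALSE]
    if (all(rows$area == 0))
      stop("all calibration areas are zero for sterol '", st, "'")
    resp <- (rows$area / rows$is_area) / (rows$level_conc / rows$is_conc)
    per_mix <- tapply(resp, rows$mix, mean)
    rrf <- mean(resp)
    if (rrf <= 0) stop("non-positive response factor for '", st, "'")
    data.frame(sterol = st, rrf = rrf,
               rrf_mix1 = if ("1" %in% names(per_mix)) per_mix[["1"]] else NA_real_,
               rrf_mix2 = if ("2" %in% names(per_mix)) per_mix[["2"]] else NA_real_,
               rel_spread = if (length(per_mix) > 1)
                 diff(range(per_mix)) / rrf else 0,
               n_levels = nrow(rows), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quantify identified peaks into a sterol profile
#'
#' Internal-standard semi-quantification:
#' `mass_x = (area_x / area_IS) * IS_amount / RRF_x` (micrograms), then
#' concentration per dry weight and relative abundance as percent of the
#' total; compounds below the 0.01 % threshold are flagged `nd`. The
#' precursor squalene is included in the total by default, as in the profile
#' tables this mirrors.
#'
#' @param pt a `peak_table`.
#' @param ids peak assignments from [identify_peaks()].
#' @param rrf calibration data frame from [calibrate()].
#' @param is_name internal-standard compound name (default
#'   `"5a-cholestane"`).
#' @param include_squalene_total include squalene in the percent denominator
#'   (default `TRUE`).
#' @return object of class `sterol_profile`: data frame `compound`,
#'   `mass_ug`, `conc_ug_mg`, `pct`, `status`; attributes `sample`,
#'   `total_conc_ug_mg`.
#' @export
quantify <- function(pt, ids, rrf, is_name = "5a-cholestane",
                     include_squalene_total = TRUE) {
  is_rows <- ids[ids$compound == is_name, , drop = FALSE]
  if (!nrow(is_rows))
    stop("internal standard '", is_name, "' not found among identified peaks")
  is_area <- sum(is_rows$area)
  hits <- ids[!ids$compound %in% c(is_name, "unidentified"), , drop = FALSE]
  if (!nrow(hits)) stop("no identified analyte peaks")
  area <- tapply(hits$area, hits$compound, sum)
  compounds <- names(area)
  rrf_x <- rrf$rrf[match(compounds, rrf$sterol)]
  if (anyNA(rrf_x))
    stop("no response factor for: ",
         paste(compounds[is.na(rrf_x)], collapse = ", "))
  mass <- as.numeric(area) / is_area * attr(pt, "is_amount_ug") / rrf_x
  conc <- mass / attr(pt, "sample_mass_mg")
  denom_mass <- if (include_squalene_total) sum(mass)
                else sum(mass[compounds != "squalene"])
  pct <- 100 * mass / denom_mass
  status <- ifelse(pct < ND_THRESHOLD_PCT, "nd", "detected")
  out <- data.frame(compound = compounds, mass_ug = mass, conc_ug_mg = conc,
                    pct = pct, status = status, stringsAsFactors = FALSE)
  out <- out[order(out$compound), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sterol_profile", "data.frame"),
            sample = attr(pt, "sample"),
            total_conc_ug_mg = sum(conc))
}

#' Pathway support state of a profile
#'
#' Classifies species-level evidence for the late side-chain-reductase
#' cholesterol pathway: `strong` when both cholesterol and desmosterol are
#' detected, `weak` when only cholesterol is, `none` otherwise.
#'
#' @param p a `sterol_profile`, or a named character vector of compound
#'   statuses (`detected`/`nd`).
#' @param species species label carried in the result.
#' @return object of class `support_state` (list with `species`, `state`).
#' @export
support_state <- function(p, species = NULL) {
  status <- if (inherits(p, "sterol_profile")) {
    stats::setNames(p$status, p$compound)
  } else p
  get <- function(nm) {
    if (!nm %in% names(status)) return("nd")
    unname(status[[nm]])
  }
  chol <- get("cholesterol") == "detected"
  desmo <- get("desmosterol") == "detected"
  state <- if (chol && desmo) "strong" else if (chol) "weak" else "none"
  structure(list(species = species %||% (attr(p, "sample") %||% NA_character_),
                 state = state),
            class = "support_state")
}

#' @export
print.support_state <- function(x, ...) {
  cat(sprintf("<support_state> %s: %s\n", x$species, x$state))
  invisible(x)
}

#' Profile table in the compounds-by-samples layout
#'
#' Rows are compounds (squalene alongside the sterols), columns are samples
#' holding percent relative abundance formatted with `nd` flags for values
#' below the 0.01 % threshold, and the final column `conc_ug_mg_dw` holds
#' the per-compound concentration relative to dry weight (averaged across
#' samples).
#'
#' @param profiles list of `sterol_profile`s.
#' @param digits digits for the percent values.
#' @return data frame with a `compound` column, one column per sample and a
#'   final `conc_ug_mg_dw` column.
#' @export
profile_table <- function(profiles, digits = 2) {
  samples <- vapply(profiles, function(p) attr(p, "sample"), "")
  compounds <- sort(unique(unlist(lapply(profiles, function(p) p$compound))))
  tab <- data.frame(compound = compounds, stringsAsFactors = FALSE)
  conc <- matrix(NA_real_, nrow = length(compounds), ncol = length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    pct <- p$pct[match(compounds, p$compound)]
    st <- p$status[match(compounds, p$compound)]
    col <- ifelse(is.na(pct) | st == "nd", "nd",
                  formatC(pct, digits = digits, format = "f"))
    tab[[samples[j]]] <- col
    conc[, j] <- p$conc_ug_mg[match(compounds, p$compound)]
  }
  tab$conc_ug_mg_dw <- rowMeans(conc, na.rm = TRUE)
  tab$conc_ug_mg_dw[is.nan(tab$conc_ug_mg_dw)] <- 0
  tab
}

#' Detection table from profiles
#'
#' Converts quantified profiles into the (species, molecule, status) table a
#' [knowledge_base()] consumes, applying the `nd` rule.
#' @param profiles list of `sterol_profile`s.
#' @return data frame `species`, `molecule`, `status`.
#' @export
profiles_to_detection <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(species = attr(p, "sample"), molecule = p$compound,
               status = ifelse(p$status == "detected", "detected",
                               "not_detected"),
               stringsAsFactors = FALSE)
  }))
}
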