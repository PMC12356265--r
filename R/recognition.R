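#' Build a recognition rule
#'
#' Target-class spectra are recognized by matching a set of diagnostic
#' product-ion formulas inside a max-min-normalized m/z window at a ppm
#' tolerance and requiring a minimum number of matched formulas. Peaks whose
#' normalized intensity falls below `noise_threshold` are treated as noise
#' and excluded from matching.
#'
#' @param formulas list of charged `element_count` objects (or formula
#'   strings, parsed with charge +1).
#' @param tol_ppm mass tolerance in ppm (default 5, closed window).
#' @param mz_range normalization window, default `c(200, 400)`.
#' @param noise_threshold minimum normalized intensity (default 0.1).
#' @param min_matching_ions matches required for a hit (default 2).
#' @return object of class `recognition_rule`.
#' @export
recognition_rule <- function(formulas, tol_ppm = 5, mz_range = c(200, 400),
                             noise_threshold = 0.1, min_matching_ions = 2L) {
  if (!length(formulas)) stop("diagnostic formula set must be non-empty")
  formulas <- lapply(formulas, function(f)
    if (inherits(f, "element_count")) f else parse_formula(f, charge = 1L))
  if (min_matching_ions < 1L) stop("min_matching_ions must be >= 1")
  if (noise_threshold < 0 || noise_threshold > 1)
    stop("noise_threshold must be in [0, 1]")
  structure(list(formulas = formulas, tol_ppm = tol_ppm,
                 mz_range = as.numeric(mz_range),
                 noise_threshold = noise_threshold,
                 min_matching_ions = as.integer(min_matching_ions)),
            class = "recognition_rule")
}

#' Derive a recognition rule from a pseudo-compound library
#'
#' Uses the union of all predicted product-ion formulas whose theoretical
#' m/z falls inside the normalization window as the diagnostic set.
#'
#' @param lib a `pseudo_library`.
#' @inheritParams recognition_rule
#' @return a `recognition_rule`.
#' @export
recognition_rule_from_library <- function(lib, tol_ppm = 5,
                                          mz_range = c(200, 400),
                                          noise_threshold = 0.1,
                                          min_matching_ions = 2L) {
  prod <- unique(lib$ions[lib$ions$kind == "product_ion",
                          c("formula", "charge")])
  fl <- lapply(seq_len(nrow(prod)), function(i)
    parse_formula(prod$formula[i], charge = prod$charge[i]))
  mz <- vapply(fl, monoisotopic_mass, numeric(1))
  fl <- fl[mz >= mz_range[1] & mz <= mz_range[2]]
  recognition_rule(fl, tol_ppm = tol_ppm, mz_range = mz_range,
                   noise_threshold = noise_threshold,
                   min_matching_ions = min_matching_ions)
}

#' Match diagnostic-ion formulas against a spectrum
#'
#' The spectrum is normalized over the rule's window; peaks below the noise
#' floor are discarded; each formula may claim at most one peak and each
#' peak at most one formula, assigned greedily by smallest absolute ppm
#' error (ties broken by higher intensity).
#'
#' @param s a [spectrum].
#' @param rule a [recognition_rule].
#' @return data.frame with one row per matched formula: `formula`,
#'   `mz_theo`, `mz_obs`, `ppm`, `norm`.
#' @export
match_diagnostic_ions <- function(s, rule) {
  stopifnot(inherits(s, "spectrum"), inherits(rule, "recognition_rule"))
  s <- normalize_range_quiet(s, rule$mz_range[1], rule$mz_range[2])
  pk <- s$peaks[!is.na(s$peaks$norm) &
                  s$peaks$norm >= rule$noise_threshold, , drop = FALSE]
  empty <- data.frame(formula = character(0), mz_theo = numeric(0),
                      mz_obs = numeric(0), ppm = numeric(0),
                      norm = numeric(0))
  if (!nrow(pk)) return(empty)
  theo <- vapply(rule$formulas, monoisotopic_mass, numeric(1))
  fstr <- vapply(rule$formulas, formula_string, character(1))
  # candidate (formula, peak) pairs inside the tolerance window
  cand <- list()
  for (i in seq_along(theo)) {
    w <- tolerance_window(theo[i], rule$tol_ppm)
    hit <- which(pk$mz >= w$low & pk$mz <= w$high)
    if (length(hit))
      cand[[length(cand) + 1L]] <- data.frame(
        fi = i, pi = hit, ppm = ppm_error(pk$mz[hit], theo[i]),
        intensity = pk$intensity[hit])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$ppm), -cand$intensity), , drop = FALSE]
  used_f <- logical(length(theo)); used_p <- logical(nrow(pk))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    fi <- cand$fi[k]; pi <- cand$pi[k]
    if (used_f[fi] || used_p[pi]) next
    used_f[fi] <- TRUE; used_p[pi] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      formula = fstr[fi], mz_theo = theo[fi], mz_obs = pk$mz[pi],
      ppm = cand$ppm[k], norm = pk$norm[pi], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$mz_theo), , drop = FALSE]
}

# normalize_range without the no-peaks warning (recognition treats an empty
# window as simply "no matches")
normalize_range_quiet <- function(s, mz_min, mz_max) {
  suppressWarnings(normalize_range(s, mz_min, mz_max))
}

#' Recognize a target-class spectrum
#'
#' @param s a [spectrum].
#' @param rule a [recognition_rule].
#' @return a `recognition_hit` (list with `feature_id`, `matches`,
#'   `n_matched`) when at least `min_matching_ions` formulas match, else
#'   `NULL`.
#' @export
recognize <- function(s, rule) {
  m <- match_diagnostic_ions(s, rule)
  if (nrow(m) < rule$min_matching_ions) return(NULL)
  structure(list(feature_id = s$feature_id, matches = m,
                 n_matched = nrow(m)),
            class = "recognition_hit")
}

#' MS1 adduct-pattern predicate over the feature table
#'
#' Some submodules are diagnosed in MS1 rather than MS/MS: a compound whose
#' \[M+H-H2O\]+ feature is more intense than its \[M+H\]+ feature (the
#' dehydration-dominant pattern typical of a 9,13,14-triol C ring) versus
#' the protonated-molecule-dominant pattern of an orthoester. The predicate
#' looks for a co-eluting companion feature at `mz - mass(H2O)` within an RT
#' tolerance and compares total areas.
#'
#' @param ft a `feature_table`.
#' @param feature_id id of the \[M+H\]+ feature to test.
#' @param rt_tol co-elution tolerance in minutes (default 0.1).
#' @param tol_ppm m/z tolerance for the companion (default 5).
#' @return `"dehydration_dominant"`, `"protonated_dominant"`, or `NA` if the
#'   feature id is unknown.
#' @export
precursor_pattern <- function(ft, feature_id, rt_tol = 0.1, tol_ppm = 5) {
  row <- ft[ft$feature_id == as.character(feature_id), , drop = FALSE]
  if (!nrow(row)) return(NA_character_)
  h2o <- sum(element_count(H = 2, O = 1)$counts * ELEMENT_MASSES)
  target <- row$mz[1] - h2o
  w <- tolerance_window(target, tol_ppm)
  area_cols <- setdiff(names(ft), c("feature_id", "mz", "rt"))
  comp <- ft[ft$mz >= w$low & ft$mz <= w$high &
               abs(ft$rt - row$rt[1]) <= rt_tol, , drop = FALSE]
  if (!nrow(comp)) return("protonated_dominant")
  a_self <- sum(unlist(row[area_cols]), na.rm = TRUE)
  a_comp <- max(rowSums(as.matrix(comp[area_cols]), na.rm = TRUE))
  if (a_comp > a_self) "dehydration_dominant" else "protonated_dominant"
}
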