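#' Label characteristic neutral losses between carbon-constrained ion pairs
#'
#' Peaks inside `mz_range` are max-min normalized and decomposed into CHON
#' compositions (singly charged cations) with [decompose_ion()]. Ordered
#' pairs (heavier, lighter) whose carbon counts equal `carbons = c(C_hi,
#' C_lo)` are formed; the elementwise difference of their compositions is
#' compared against `target_losses`. A matching pair is scored with
#' `IA = (I1 + I2)/2` (mean normalized intensity),
#' `IDF = 1 / (1 + |I1 - I2| / IA)` (intensity difference factor), and
#' `score = IA * IDF`. The within-count case of the carbon filter is the
#' pair `c(c, c)`; a precursor-to-core loss uses distinct counts, e.g.
#' `c(20, 17)` for the B-ring C3H4O2 elimination.
#'
#' @param s a [spectrum].
#' @param mz_range numeric length-2 normalization/labeling window.
#' @param carbons integer length-2 `c(C_heavier, C_lighter)` (a single value
#'   is recycled to both).
#' @param target_losses list of neutral `element_count`s (or formula
#'   strings) to match.
#' @param db a `formula_db` for peak decomposition.
#' @param tol_ppm decomposition tolerance (default 5).
#' @return data.frame with one row per labeled pair: `loss`, `formula_hi`,
#'   `formula_lo`, `mz_hi`, `mz_lo`, `I1`, `I2`, `IA`, `IDF`, `score`,
#'   `ppm` (mean absolute decomposition error of the pair).
#' @export
label_neutral_losses <- function(s, mz_range, carbons, target_losses, db,
                                 tol_ppm = 5) {
  stopifnot(inherits(s, "spectrum"))
  if (length(carbons) == 1L) carbons <- rep(carbons, 2L)
  target_losses <- lapply(target_losses, function(f)
    if (inherits(f, "element_count")) f else parse_formula(f, charge = 0))
  loss_str <- vapply(target_losses, formula_string, character(1))
  empty <- data.frame(loss = character(0), formula_hi = character(0),
                      formula_lo = character(0), mz_hi = numeric(0),
                      mz_lo = numeric(0), I1 = numeric(0), I2 = numeric(0),
                      IA = numeric(0), IDF = numeric(0), score = numeric(0),
                      ppm = numeric(0))
  s <- normalize_range_quiet(s, mz_range[1], mz_range[2])
  pk <- s$peaks[!is.na(s$peaks$norm), , drop = FALSE]
  if (!nrow(pk)) return(empty)
  dec <- decompose_ion(pk$mz, db, tol_ppm = tol_ppm)
  ok <- !is.na(dec$formula)
  pk <- pk[ok, , drop = FALSE]; dec <- dec[ok, , drop = FALSE]
  hi_idx <- which(dec$C == carbons[1])
  lo_idx <- which(dec$C == carbons[2])
  rows <- list()
  for (i in hi_idx) for (j in lo_idx) {
    if (pk$mz[i] <= pk$mz[j]) next   # heavier minus lighter
    dC <- dec$C[i] - dec$C[j]; dH <- dec$H[i] - dec$H[j]
    dO <- dec$O[i] - dec$O[j]; dN <- dec$N[i] - dec$N[j]
    if (any(c(dC, dH, dO, dN) < 0)) next
    hit <- which(vapply(target_losses, function(tl)
      tl$counts[["C"]] == dC && tl$counts[["H"]] == dH &&
        tl$counts[["O"]] == dO && tl$counts[["N"]] == dN, logical(1)))
    if (!length(hit)) next
    I1 <- pk$norm[i]; I2 <- pk$norm[j]
    IA <- (I1 + I2) / 2
    IDF <- if (IA > 0) 1 / (1 + abs(I1 - I2) / IA) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      loss = loss_str[hit[1]], formula_hi = dec$formula[i],
      formula_lo = dec$formula[j], mz_hi = pk$mz[i], mz_lo = pk$mz[j],
      I1 = I1, I2 = I2, IA = IA, IDF = IDF, score = IA * IDF,
      ppm = mean(abs(c(dec$ppm[i], dec$ppm[j]))),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}

#' Label diagnostic feature ions and rank them by relative intensity
#'
#' Peaks inside `mz_range` are normalized; those matching one of the
#' specified characteristic compositions (within `tol_ppm`) are ranked by
#' normalized intensity (descending; ties by smaller |ppm|) and the top `n`
#' returned with score `I_i / I_max`, where `I_max` is the maximum
#' normalized intensity in the range (1 by construction of max-min scaling,
#' so the score equals the normalized intensity).
#'
#' @param s a [spectrum].
#' @param mz_range numeric length-2 window.
#' @param features list of charged `element_count`s or formula strings
#'   (parsed with charge +1).
#' @param n maximum number of labels returned (default all).
#' @param tol_ppm match tolerance (default 5).
#' @return data.frame: `formula`, `mz_theo`, `mz_obs`, `ppm`, `rank`,
#'   `score`.
#' @export
label_feature_ions <- function(s, mz_range, features, n = Inf, tol_ppm = 5) {
  stopifnot(inherits(s, "spectrum"))
  features <- lapply(features, function(f)
    if (inherits(f, "element_count")) f else parse_formula(f, charge = 1L))
  empty <- data.frame(formula = character(0), mz_theo = numeric(0),
                      mz_obs = numeric(0), ppm = numeric(0),
                      rank = integer(0), score = numeric(0))
  s <- normalize_range_quiet(s, mz_range[1], mz_range[2])
  pk <- s$peaks[!is.na(s$peaks$norm), , drop = FALSE]
  if (!nrow(pk)) return(empty)
  imax <- max(pk$norm)
  theo <- vapply(features, monoisotopic_mass, numeric(1))
  fstr <- vapply(features, formula_string, character(1))
  rows <- list()
  for (i in seq_along(theo)) {
    w <- tolerance_window(theo[i], tol_ppm)
    hit <- which(pk$mz >= w$low & pk$mz <= w$high)
    if (!length(hit)) next
    pp <- ppm_error(pk$mz[hit], theo[i])
    j <- hit[order(abs(pp))[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      formula = fstr[i], mz_theo = theo[i], mz_obs = pk$mz[j],
      ppm = ppm_error(pk$mz[j], theo[i]),
      score = pk$norm[j] / imax, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, abs(out$ppm)), , drop = FALSE]
  out <- utils::head(out, n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("formula", "mz_theo", "mz_obs", "ppm", "rank", "score")]
}

#' Range-limited cosine similarity of two spectra
#'
#' Peaks inside `mz_range` are paired greedily by ascending m/z distance
#' within `match_tol_ppm`, each peak used at most once; the cosine is
#' computed over the matched pairs' intensities:
#' `sum(Qi * Si) / (sqrt(sum(Qi^2)) * sqrt(sum(Si^2)))`, and 0 when no pair
#' matches. Intensities are used as given (typically relative intensities
#' from an upstream normalization); the value is invariant under uniform
#' scaling of either spectrum.
#'
#' @param q,s [spectrum] objects (query and standard).
#' @param mz_range numeric length-2 window.
#' @param match_tol_ppm peak-pairing tolerance (default 10 ppm).
#' @return list with `value` (in \[0, 1\]), `n_matched`, `mz_range`.
#' @export
range_cosine <- function(q, s, mz_range, match_tol_ppm = 10) {
  in_range <- function(p)
    p$peaks[p$peaks$mz >= mz_range[1] & p$peaks$mz <= mz_range[2], ,
            drop = FALSE]
  qp <- in_range(q)
  sp <- in_range(s)
  if (!nrow(qp) || !nrow(sp))
    return(list(value = 0, n_matched = 0L, mz_range = mz_range))
  cand <- list()
  for (i in seq_len(nrow(qp))) {
    w <- tolerance_window(qp$mz[i], match_tol_ppm)
    hit <- which(sp$mz >= w$low & sp$mz <= w$high)
    if (length(hit))
      cand[[length(cand) + 1L]] <- data.frame(
        qi = i, si = hit, d = abs(sp$mz[hit] - qp$mz[i]))
  }
  if (!length(cand))
    return(list(value = 0, n_matched = 0L, mz_range = mz_range))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d), , drop = FALSE]
  used_q <- logical(nrow(qp)); used_s <- logical(nrow(sp))
  qv <- numeric(0); sv <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    qi <- cand$qi[k]; si <- cand$si[k]
    if (used_q[qi] || used_s[si]) next
    used_q[qi] <- TRUE; used_s[si] <- TRUE
    qv <- c(qv, qp$intensity[qi]); sv <- c(sv, sp$intensity[si])
  }
  denom <- sqrt(sum(qv^2)) * sqrt(sum(sv^2))
  val <- if (denom > 0) sum(qv * sv) / denom else 0
  list(value = val, n_matched = length(qv), mz_range = mz_range)
}
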