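#' Electrospray adduct specifications
#'
#' An adduct is described by the composition gained and lost relative to the
#' neutral molecule M and the resulting charge. The default table carries the
#' seven adducts routinely considered in positive and negative mode:
#' \[M+H\]+, \[M+NH4\]+, \[M+H-H2O\]+, \[M+CH3CN+H\]+, \[M+CH3NH2+H\]+,
#' \[M-H\]- and \[M+HCOO\]-.
#'
#' @param name display name, e.g. `"[M+H]+"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param gained,lost `element_count` compositions added to / removed from M.
#' @param charge ion charge (+1 or -1); must match polarity.
#' @return object of class `adduct_spec`.
#' @export
adduct_spec <- function(name, polarity, gained, lost = element_count(),
                        charge = if (polarity == "positive") 1L else -1L) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  if ((polarity == "positive") != (charge > 0))
    stop("adduct '", name, "': polarity inconsistent with charge sign")
  structure(list(name = name, polarity = polarity, gained = gained,
                 lost = lost, charge = as.integer(charge)),
            class = "adduct_spec")
}

#' @rdname adduct_spec
#' @export
default_adducts <- function() {
  list(
    adduct_spec("[M+H]+", "positive", element_count(H = 1)),
    adduct_spec("[M+NH4]+", "positive", element_count(N = 1, H = 4)),
    adduct_spec("[M+H-H2O]+", "positive", element_count(H = 1),
                element_count(H = 2, O = 1)),
    adduct_spec("[M+CH3CN+H]+", "positive", element_count(C = 2, H = 4, N = 1)),
    adduct_spec("[M+CH3NH2+H]+", "positive", element_count(C = 1, H = 6, N = 1)),
    adduct_spec("[M-H]-", "negative", element_count(), element_count(H = 1)),
    adduct_spec("[M+HCOO]-", "negative", element_count(C = 1, H = 1, O = 2))
  )
}

#' Read an adduct table from a JSON config
#'
#' Expected shape: an array of objects with fields `name`, `polarity`,
#' `gained`, `lost` (formula strings, possibly empty) and `charge`.
#'
#' @param path JSON file path.
#' @return list of [adduct_spec] objects.
#' @export
read_adducts <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    adduct_spec(a$name, a$polarity,
                gained = parse_formula(a$gained %||% "", charge = 0),
                lost = parse_formula(a$lost %||% "", charge = 0),
                charge = as.integer(a$charge))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mass shift of an adduct relative to the neutral mass
#'
#' `mass(gained) - mass(lost) - charge * electron mass`; the ion m/z of a
#' neutral M is `mass(M) + adduct_shift(adduct)`.
#'
#' @param adduct an [adduct_spec].
#' @return numeric shift in Da.
#' @export
adduct_shift <- function(adduct) {
  g <- adduct$gained; l <- adduct$lost
  sum(g$counts * ELEMENT_MASSES) - sum(l$counts * ELEMENT_MASSES) -
    adduct$charge * ELECTRON_MASS
}

#' m/z of an adduct ion of a neutral molecule
#'
#' @param neutral an `element_count` with charge 0.
#' @param adduct an [adduct_spec].
#' @return ion m/z (Th). Errors if the adduct's lost composition is not a
#'   sub-composition of `neutral + gained`.
#' @export
adduct_mz <- function(neutral, adduct) {
  stopifnot(inherits(neutral, "element_count"))
  if (neutral$charge != 0L) stop("adduct_mz() expects a neutral composition")
  ion <- ec_subtract(ec_add(neutral, adduct$gained), adduct$lost)
  ion$charge <- adduct$charge
  monoisotopic_mass(ion)
}

#' Exhaustive CHON formula database within element-count bounds
#'
#' Enumerates every composition `C_a H_b O_c N_d` with each count inside its
#' closed `[min, max]` bounds, exactly once, and returns them sorted by
#' neutral monoisotopic mass for binary search. A guard refuses bound boxes
#' with more than `cap` combinations.
#'
#' @param c_range,h_range,o_range,n_range integer length-2 vectors
#'   `c(min, max)`.
#' @param cap maximum number of combinations (default 5e6).
#' @return data.frame of class `formula_db` with integer columns
#'   `C`, `H`, `O`, `N` and numeric `mass` (neutral), ascending in `mass`.
#' @export
build_formula_db <- function(c_range = c(0L, 50L), h_range = c(0L, 70L),
                             o_range = c(0L, 15L), n_range = c(0L, 3L),
                             cap = 5e6) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2] || any(r < 0))
      stop("invalid ", nm, " bounds: need 0 <= min <= max")
    as.integer(r)
  }
  c_range <- chk(c_range, "C"); h_range <- chk(h_range, "H")
  o_range <- chk(o_range, "O"); n_range <- chk(n_range, "N")
  n_comb <- prod(diff(c_range) + 1, diff(h_range) + 1,
                 diff(o_range) + 1, diff(n_range) + 1)
  if (n_comb > cap)
    stop("formula space has ", format(n_comb, big.mark = ","),
         " combinations (> cap ", format(cap, big.mark = ","),
         "); narrow the element bounds")
  g <- expand.grid(C = c_range[1]:c_range[2], H = h_range[1]:h_range[2],
                   O = o_range[1]:o_range[2], N = n_range[1]:n_range[2],
                   KEEP.OUT.ATTRS = FALSE)
  g$mass <- g$C * ELEMENT_MASSES[["C"]] + g$H * ELEMENT_MASSES[["H"]] +
    g$O * ELEMENT_MASSES[["O"]] + g$N * ELEMENT_MASSES[["N"]]
  g <- g[order(g$mass, g$C, g$H, g$O, g$N), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("formula_db", "data.frame")
  g
}

#' RDBE column helper (vectorized over a formula_db slice)
#' @noRd
.db_rdbe <- function(db) db$C - db$H / 2 + db$N / 2 + 1

#' Assign a molecular formula and adduct to a precursor ion
#'
#' For each adduct of the requested polarity, searches the mass-sorted
#' formula database for neutral compositions whose adduct-ion m/z falls
#' within `tol_ppm` of the observed precursor and whose neutral RDBE lies in
#' `rdbe_range`. The assignment with the smallest absolute ppm error wins.
#' Ties at identical |ppm| are broken deterministically: RDBE closest to the
#' midpoint of `rdbe_range`, then fewer N, then lexicographic formula
#' string.
#'
#' @param precursor_mz observed precursor m/z (> 0).
#' @param polarity `"positive"` or `"negative"`.
#' @param db a `formula_db` from [build_formula_db()].
#' @param adducts list of [adduct_spec]; filtered to `polarity`.
#' @param tol_ppm match tolerance (default 5 ppm, closed window).
#' @param rdbe_range length-2 numeric plausibility range (default `c(0, 40)`).
#' @return data.frame of ranked candidates (best first) with columns
#'   `formula`, `adduct`, `mz_theo`, `ppm`, `rdbe`, `C`, `H`, `O`, `N`;
#'   zero rows when nothing matches.
#' @export
assign_precursor <- function(precursor_mz, polarity = "positive", db,
                             adducts = default_adducts(), tol_ppm = 5,
                             rdbe_range = c(0, 40)) {
  if (precursor_mz <= 0) stop("precursor_mz must be > 0")
  polarity <- match.arg(polarity, c("positive", "negative"))
  adducts <- Filter(function(a) a$polarity == polarity, adducts)
  if (!length(adducts)) stop("no adducts for polarity ", polarity)
  out <- list()
  w <- tolerance_window(precursor_mz, tol_ppm)
  for (a in adducts) {
    sh <- adduct_shift(a)
    # neutral masses whose ion m/z lies in [w$low, w$high]
    lo <- w$low - sh; hi <- w$high - sh
    i1 <- findInterval(lo, db$mass, left.open = TRUE) + 1L
    i2 <- findInterval(hi, db$mass)
    if (i2 < i1) next
    cand <- db[i1:i2, , drop = FALSE]
    # the adduct's lost composition must be removable from M + gained
    tot_h <- cand$H + a$gained$counts[["H"]] - a$lost$counts[["H"]]
    tot_o <- cand$O + a$gained$counts[["O"]] - a$lost$counts[["O"]]
    tot_c <- cand$C + a$gained$counts[["C"]] - a$lost$counts[["C"]]
    tot_n <- cand$N + a$gained$counts[["N"]] - a$lost$counts[["N"]]
    ok <- tot_h >= 0 & tot_o >= 0 & tot_c >= 0 & tot_n >= 0
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    mz_theo <- cand$mass + sh
    rd <- .db_rdbe(cand)
    keep <- rd >= rdbe_range[1] & rd <= rdbe_range[2]
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    mz_theo <- mz_theo[keep]; rd <- rd[keep]
    out[[a$name]] <- data.frame(
      formula = paste0(ifelse(cand$C > 0, paste0("C", ifelse(cand$C == 1, "", cand$C)), ""),
                       ifelse(cand$H > 0, paste0("H", ifelse(cand$H == 1, "", cand$H)), ""),
                       ifelse(cand$N > 0, paste0("N", ifelse(cand$N == 1, "", cand$N)), ""),
                       ifelse(cand$O > 0, paste0("O", ifelse(cand$O == 1, "", cand$O)), "")),
      adduct = a$name,
      mz_theo = mz_theo,
      ppm = ppm_error(precursor_mz, mz_theo),
      rdbe = rd,
      C = cand$C, H = cand$H, O = cand$O, N = cand$N,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(formula = character(0), adduct = character(0),
                      mz_theo = numeric(0), ppm = numeric(0),
                      rdbe = numeric(0), C = integer(0), H = integer(0),
                      O = integer(0), N = integer(0)))
  res <- do.call(rbind, out)
  mid <- mean(rdbe_range)
  # |ppm| rounded so that analytically degenerate assignments (e.g. [M+H]+
  # of M vs [M+H-H2O]+ of M+H2O) fall through to the documented tie-breaks
  ord <- order(round(abs(res$ppm), 3), abs(res$rdbe - mid), res$N,
               res$formula)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Decompose fragment-ion m/z values into CHON compositions
#'
#' Vectorized helper for spectrum annotation: each m/z is interpreted as a
#' singly charged even-electron cation (composition mass = m/z + electron
#' mass) and matched against the formula database within `tol_ppm`; the
#' smallest |ppm| candidate inside `rdbe_range` wins (RDBE evaluated on the
#' cation composition, hence typically half-integer). Peaks with no
#' candidate get NA.
#'
#' @param mz numeric vector of peak m/z values.
#' @param db a `formula_db`.
#' @param tol_ppm tolerance (default 5).
#' @param rdbe_range plausibility range on the cation composition RDBE
#'   (default `c(-0.5, 40)`).
#' @return data.frame with one row per input m/z: `formula`, `C`, `H`, `O`,
#'   `N`, `ppm` (NA when unassigned).
#' @export
decompose_ion <- function(mz, db, tol_ppm = 5, rdbe_range = c(-0.5, 40)) {
  n <- length(mz)
  res <- data.frame(formula = rep(NA_character_, n), C = NA_integer_,
                    H = NA_integer_, O = NA_integer_, N = NA_integer_,
                    ppm = NA_real_)
  if (!n) return(res)
  target <- mz + ELECTRON_MASS   # neutral-composition mass of the cation
  for (i in seq_len(n)) {
    w <- tolerance_window(target[i], tol_ppm)
    i1 <- findInterval(w$low, db$mass, left.open = TRUE) + 1L
    i2 <- findInterval(w$high, db$mass)
    if (i2 < i1) next
    cand <- db[i1:i2, , drop = FALSE]
    rd <- .db_rdbe(cand)  # on the cation composition: half-integer for even-electron ions
    keep <- rd >= rdbe_range[1] & rd <= rdbe_range[2]
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    pp <- ppm_error(target[i], cand$mass)
    j <- order(abs(pp), cand$N)[1]
    res$C[i] <- cand$C[j]; res$H[i] <- cand$H[j]
    res$O[i] <- cand$O[j]; res$N[i] <- cand$N[j]
    res$ppm[i] <- pp[j]
    ecf <- element_count(C = cand$C[j], H = cand$H[j],
                         O = cand$O[j], N = cand$N[j], charge = 1L)
    res$formula[i] <- formula_string(ecf)
  }
  res
}
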