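#' Monoisotopic element masses
#'
#' Single authoritative table of monoisotopic masses (Da) used everywhere in
#' the package, plus the electron rest mass. Carbon is exactly 12 by
#' definition of the unified atomic mass scale; the remaining values carry at
#' least 6 decimals.
#'
#' @format Named numeric vector, one entry per supported element symbol.
#' @export
ELEMENT_MASSES <- c(
  C  = 12,
  H  = 1.0078250319,
  O  = 15.9949146221,
  N  = 14.0030740052,
  S  = 31.97207069,
  P  = 30.97376151,
  Cl = 34.96885271
)

#' Electron rest mass in Da
#' @export
ELECTRON_MASS <- 0.0005485799

#' Construct an element-composition vector
#'
#' An `element_count` holds non-negative integer counts per element symbol
#' (C, H, O, N by default; any symbol in [ELEMENT_MASSES] is accepted) plus a
#' signed integer charge (0 for a neutral species, +1 for a singly charged
#' cation, ...).
#'
#' @param ... named integer element counts, e.g. `C = 17, H = 17, O = 2`.
#' @param charge signed integer charge (default 0).
#' @return An object of class `element_count`.
#' @examples
#' element_count(C = 17, H = 17, O = 2, charge = 1)
#' @export
element_count <- function(..., charge = 0L) {
  counts <- c(...)
  if (is.null(counts)) counts <- numeric(0)
  if (length(counts) && is.null(names(counts)))
    stop("element counts must be named, e.g. element_count(C = 17, H = 17)")
  unknown <- setdiff(names(counts), names(ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0))
    stop("element counts must be non-negative")
  if (any(counts != round(counts)))
    stop("element counts must be integers")
  full <- stats::setNames(integer(length(ELEMENT_MASSES)), names(ELEMENT_MASSES))
  full[names(counts)] <- as.integer(round(counts))
  structure(list(counts = full, charge = as.integer(charge)),
            class = "element_count")
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style formula strings such as `"C17H17O2"` or `"C3H4O2"`;
#' two-letter symbols (`Cl`) are recognized. An optional trailing `+`/`-`
#' sets charge +1/-1 when `charge` is not given.
#'
#' @param x formula string.
#' @param charge signed integer charge; overrides any trailing sign in `x`.
#' @return An `element_count`.
#' @examples
#' parse_formula("C17H17O2", charge = 1)
#' @export
parse_formula <- function(x, charge = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- trimws(x)
  sgn <- 0L
  if (grepl("[+-]$", s)) {
    sgn <- if (endsWith(s, "+")) 1L else -1L
    s <- sub("[+-]$", "", s)
  }
  if (is.null(charge)) charge <- sgn
  if (!nzchar(s)) return(element_count(charge = charge))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", x)
  counts <- stats::setNames(integer(length(ELEMENT_MASSES)), names(ELEMENT_MASSES))
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(ELEMENT_MASSES))
      stop("unknown element symbol: ", sym, " in formula ", x)
    counts[sym] <- counts[sym] + n
  }
  ec <- element_count(charge = as.integer(charge))
  ec$counts <- counts
  ec
}

#' @export
format.element_count <- function(x, ...) {
  nz <- x$counts[x$counts > 0L]
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(nz)),
           sort(setdiff(names(nz), c("C", "H"))))
  body <- paste0(ord, ifelse(nz[ord] == 1L, "", nz[ord]), collapse = "")
  if (!nzchar(body)) body <- "(empty)"
  chg <- if (x$charge == 0L) "" else if (x$charge > 0L)
    paste0(strrep("+", x$charge)) else paste0(strrep("-", -x$charge))
  paste0(body, chg)
}

#' @export
print.element_count <- function(x, ...) {
  cat("<element_count> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Format an element_count as a plain formula string (no charge sign)
#' @param x an `element_count`.
#' @return character scalar.
#' @export
formula_string <- function(x) {
  stopifnot(inherits(x, "element_count"))
  nz <- x$counts[x$counts > 0L]
  if (!length(nz)) return("")
  ord <- c(intersect(c("C", "H"), names(nz)),
           sort(setdiff(names(nz), c("C", "H"))))
  paste0(ord, ifelse(nz[ord] == 1L, "", nz[ord]), collapse = "")
}

#' Element-wise composition arithmetic
#'
#' Addition and subtraction of `element_count` objects are element-wise on
#' counts and additive on charge. Subtraction refuses to produce negative
#' counts.
#'
#' @param e1,e2 `element_count` objects.
#' @return An `element_count`.
#' @name element_count-arith
#' @export
ec_add <- function(e1, e2) {
  stopifnot(inherits(e1, "element_count"), inherits(e2, "element_count"))
  out <- e1
  out$counts <- e1$counts + e2$counts
  out$charge <- e1$charge + e2$charge
  out
}

#' @rdname element_count-arith
#' @export
ec_subtract <- function(e1, e2) {
  stopifnot(inherits(e1, "element_count"), inherits(e2, "element_count"))
  d <- e1$counts - e2$counts
  if (any(d < 0L))
    stop("subtraction would give negative count(s) for: ",
         paste(names(d)[d < 0L], collapse = ", "))
  out <- e1
  out$counts <- d
  out$charge <- e1$charge - e2$charge
  out
}

#' @export
`+.element_count` <- function(e1, e2) ec_add(e1, e2)

#' @export
`-.element_count` <- function(e1, e2) ec_subtract(e1, e2)

#' @export
`==.element_count` <- function(e1, e2) {
  all(e1$counts == e2$counts) && e1$charge == e2$charge
}

#' Monoisotopic mass / m-over-z of a composition
#'
#' Sum of per-element monoisotopic masses minus `charge` times the electron
#' mass. For `|charge| == 1` the returned value is the ion m/z; for charge 0
#' it is the neutral monoisotopic mass. Charge states beyond |1| are not
#' supported.
#'
#' @param f an `element_count`.
#' @return mass (Da) or m/z (Th) as a numeric scalar.
#' @examples
#' monoisotopic_mass(parse_formula("C17H17O2", charge = 1)) # 253.1223
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "element_count"))
  if (abs(f$charge) > 1L)
    stop("only |charge| <= 1 is supported")
  sum(f$counts * ELEMENT_MASSES[names(f$counts)]) - f$charge * ELECTRON_MASS
}

#' Signed mass error in parts per million
#'
#' `(exp - theo) / theo * 1e6`, sign preserved.
#'
#' @param mass_exp experimental mass (Da).
#' @param mass_theo theoretical mass (Da); must be > 0.
#' @return signed ppm error (vectorized).
#' @export
ppm_error <- function(mass_exp, mass_theo) {
  if (any(mass_theo <= 0)) stop("mass_theo must be > 0")
  (mass_exp - mass_theo) / mass_theo * 1e6
}

#' Closed ppm tolerance window around a theoretical mass
#'
#' @param mass_theo theoretical mass (Da), > 0.
#' @param tol_ppm tolerance in ppm, >= 0.
#' @return list with `low` and `high` (Da); the interval is closed, a value
#'   exactly at +/- `tol_ppm` is inside.
#' @export
tolerance_window <- function(mass_theo, tol_ppm) {
  if (any(mass_theo <= 0)) stop("mass_theo must be > 0")
  if (any(tol_ppm < 0)) stop("tol_ppm must be >= 0")
  list(low = mass_theo * (1 - tol_ppm / 1e6),
       high = mass_theo * (1 + tol_ppm / 1e6))
}

#' Ring-and-double-bond equivalents (hydrogen deficiency index)
#'
#' `C - H/2 + N/2 + 1`, evaluated on the composition as given. For a
#' protonated molecule pass `neutralize = TRUE` to remove one proton per
#' positive charge first (the conventional neutral-molecule RDBE).
#'
#' @param f an `element_count` (CHON-based; O does not enter the formula).
#' @param neutralize if TRUE and `f` is charged, remove `charge` hydrogens
#'   and the charge before evaluating.
#' @return numeric RDBE (can be half-integer for even-electron ions).
#' @examples
#' rdbe(parse_formula("C6H6")) # 4
#' @export
rdbe <- function(f, neutralize = FALSE) {
  stopifnot(inherits(f, "element_count"))
  cc <- f$counts
  if (neutralize && f$charge != 0L) {
    cc["H"] <- cc["H"] - f$charge
    if (cc["H"] < 0) stop("cannot neutralize: fewer H than charge")
  }
  unname(cc["C"] - cc["H"] / 2 + cc["N"] / 2 + 1)
}
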