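#' Locate the Python interpreter used for structure handling
#'
#' SMILES parsing, fragment merging, valence checking and canonicalization
#' are delegated to RDKit through a bundled helper script run with the
#' `python` found on the PATH (override with option `mfsa.python` or
#' environment variable `MFSA_PYTHON`).
#'
#' @return path to the interpreter.
#' @keywords internal
python_binary <- function() {
  p <- getOption("mfsa.python", Sys.getenv("MFSA_PYTHON", ""))
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no 'python' interpreter on PATH; RDKit is required for structure assembly")
  p
}

#' Merge labeled SMILES fragment sets into canonical structures (batch)
#'
#' Each element of `jobs` is a character vector of SMILES fragments whose
#' shared atoms carry equal atom-map labels (e.g. `[CH2:23]`). Atoms with
#' the same label are unified; hydrogens on merged atoms are re-derived from
#' standard valence; the merged molecule is sanitized and canonicalized by
#' RDKit. Empty strings are allowed and contribute nothing.
#'
#' @param jobs list of character vectors of fragment SMILES.
#' @return data.frame with one row per job: `smiles`, `formula`, `natoms`,
#'   `unmatched` (comma-separated label numbers seen only once), `error`
#'   (NA on success).
#' @export
merge_fragments <- function(jobs) {
  stopifnot(is.list(jobs), length(jobs) > 0)
  script <- system.file("python", "assemble.py", package = "mfsa")
  if (!nzchar(script) || !file.exists(script))
    stop("bundled helper assemble.py not found; is the package installed?")
  payload <- jsonlite::toJSON(list(jobs = lapply(jobs, function(j)
    as.list(unname(as.character(j))))), auto_unbox = FALSE)
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  writeLines(payload, infile)
  out <- suppressWarnings(
    system2(python_binary(), shQuote(script), stdout = TRUE, stderr = TRUE,
            stdin = infile))
  status <- attr(out, "status")
  txt <- paste(out, collapse = "\n")
  if (!is.null(status) && status != 0)
    stop("structure helper failed (exit ", status, "): ", txt)
  res <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  data.frame(
    smiles = vapply(res, function(r) chr1(r$smiles), character(1)),
    formula = vapply(res, function(r) chr1(r$formula), character(1)),
    natoms = vapply(res, function(r) int1(r$natoms), integer(1)),
    unmatched = vapply(res, function(r)
      paste(unlist(r$unmatched), collapse = ","), character(1)),
    error = vapply(res, function(r) chr1(r$error), character(1)),
    stringsAsFactors = FALSE)
}
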