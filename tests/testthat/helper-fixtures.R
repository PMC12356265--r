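# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

daphnane_module_set <- function() {
  memo("ms", read_module_set(
    system.file("extdata", "daphnane_modules.json", package = "mfsa")))
}

daphnane_library <- function() {
  memo("lib", enumerate_library(daphnane_module_set()))
}

daphnane_rules <- function() {
  memo("rules", read_rules(
    system.file("extdata", "daphnane_rules.json", package = "mfsa")))
}

small_formula_db <- function() {
  memo("small_db", build_formula_db(c(0L, 15L), c(0L, 25L), c(0L, 6L),
                                    c(0L, 2L)))
}

# a trivial 2x3x4 module set of disconnected alkane/amine fragments; no
# shared labels, so assembly is plain combination -- used for combinatorics
toy_module_set <- function() {
  memo("toy_ms", validate_module_set(list(
    name = "toy234",
    optional_labels = list(),
    modules = list(
      list(id = "s1", submodules = list(
        list(id = "a1", smiles = "C",
             deltas = list(fam = c(0, 0, 0, 0))),
        list(id = "a2", smiles = "CC",
             deltas = list(fam = c(1, 2, 0, 0))))),
      list(id = "s2", submodules = list(
        list(id = "b1", smiles = "CCC", deltas = list()),
        list(id = "b2", smiles = "CCCC",
             deltas = list(fam = c(0, 0, 1, 0))),
        list(id = "b3", smiles = "CCCCC",
             deltas = list(fam = c(0, 2, 0, 0))))),
      list(id = "s3", submodules = list(
        list(id = "c1", smiles = "N", deltas = list()),
        list(id = "c2", smiles = "NC", deltas = list()),
        list(id = "c3", smiles = "NCC",
             deltas = list(fam = c(0, 0, 0, 1))),
        list(id = "c4", smiles = "NCCC", deltas = list())))),
    templates = list(
      list(id = "fam", kind = "product_ion", m0 = "C5H5O2", charge = 1,
           slots = list("s1", "s2", "s3"))))))
}

toy_library <- function() {
  memo("toy_lib", enumerate_library(toy_module_set()))
}

# minimal spectrum constructor used across files
mk_spectrum <- function(mz, intensity, precursor_mz = 500, id = "S1",
                        rt = 5) {
  spectrum(feature_id = id, precursor_mz = precursor_mz,
           peaks = data.frame(mz = mz, intensity = intensity), rt = rt)
}
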