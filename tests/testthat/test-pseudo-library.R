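# Mass-shift prediction, labeled-fragment assembly, combinatorial
# enumeration and the single-file library store.

test_that("predict_ion_formula applies the mass-shift model element-wise", {
  ms <- daphnane_module_set()
  # identity combination: all-zero deltas reproduce m0
  f <- predict_ion_formula(ms, "core17", list(module_I = "I1"))
  expect_true(f == parse_formula("C17H17O2", charge = 1))
  # one-oxygen submodule shift: the 12-oxygenated analog's module-I ion
  f <- predict_ion_formula(ms, "core17", list(module_I = "I2"))
  expect_true(f == parse_formula("C17H17O3", charge = 1))
  expect_equal(round(monoisotopic_mass(f)), 269)
})

test_that("multi-slot deltas sum and commute", {
  toy <- toy_module_set()
  # a2: +C+2H, b3: +2H, c3: +N over m0 = C5H5O2
  f <- predict_ion_formula(toy, "fam",
                           list(s1 = "a2", s2 = "b3", s3 = "c3"))
  expect_true(f == parse_formula("C6H9NO2", charge = 1))
  # order of slots in the choice list is irrelevant
  f2 <- predict_ion_formula(toy, "fam",
                            list(s3 = "c3", s1 = "a2", s2 = "b3"))
  expect_true(f == f2)
  expect_error(predict_ion_formula(toy, "fam", list(s1 = "a2")),
               "needs a choice")
})

test_that("negative predicted counts are a hard error naming the family", {
  ms <- validate_module_set(list(
    name = "neg", modules = list(list(id = "m", submodules = list(
      list(id = "x", smiles = "C", deltas = list(f = c(-3, 0, 0, 0)))))),
    templates = list(list(id = "f", kind = "product_ion", m0 = "C2H2",
                          charge = 1, slots = list("m")))))
  expect_error(predict_ion_formula(ms, "f", list(m = "x")),
               "negative element")
})

test_that("shared-atom merging keeps merged atoms once and is deterministic", {
  # two cyclohexanes sharing two adjacent labeled atoms -> decalin
  r <- merge_fragments(list(c("C1CCC[CH:1][CH:2]1", "C1CC[CH:1][CH:2]C1")))
  expect_true(is.na(r$error[1]))
  expect_identical(r$natoms[1], 10L)          # 6 + 6 - 2
  expect_identical(r$formula[1], "C10H18")    # ring-fusion CH kept sane
  # determinism: identical input, identical canonical output
  r2 <- merge_fragments(list(c("C1CCC[CH:1][CH:2]1", "C1CC[CH:1][CH:2]C1")))
  expect_identical(r$smiles[1], r2$smiles[1])
  # single shared atom -> spiro center, atom count sum - 1
  r3 <- merge_fragments(list(c("C1CC[C:1]C1", "[C:1]1CCOC1")))
  expect_identical(r3$natoms[1], 9L)
})

test_that("assembly reports unmatched labels and valence violations", {
  bad <- validate_module_set(list(
    name = "bad", optional_labels = list(),
    modules = list(
      list(id = "m1", submodules = list(
        list(id = "x", smiles = "C[CH2:9]", deltas = list())))),
    templates = list(list(id = "f", kind = "product_ion", m0 = "CH3",
                          charge = 1, slots = list("m1")))))
  expect_error(assemble_structure(bad, list(m1 = "x")),
               "unmatched attachment label.*9")
  # five bonds on a merged carbon is rejected by sanitization
  r <- merge_fragments(list(c("[C:3](C)(C)C", "[C:3]1CCCC1")))
  expect_false(is.na(r$error[1]))
  expect_match(r$error[1], "invalid structure")
})

test_that("library size equals the product of slot sizes (oracle)", {
  toy <- toy_library()
  expect_identical(toy$n_combinations, 24L)   # 2 x 3 x 4
  expect_identical(nrow(toy$compounds), 24L)  # all distinct here
  # brute-force nested-loop oracle over the same fragments, each fragment
  # canonicalized independently so string forms are comparable
  ms <- toy_module_set()
  frags <- unique(unlist(lapply(ms$modules, function(m)
    vapply(m$submodules, `[[`, character(1), "smiles"))))
  canon <- merge_fragments(lapply(frags, identity))$smiles
  names(canon) <- frags
  oracle <- character(0)
  for (a in ms$modules[[1]]$submodules)
    for (b in ms$modules[[2]]$submodules)
      for (cc in ms$modules[[3]]$submodules)
        oracle <- c(oracle, paste(sort(canon[c(a$smiles, b$smiles,
                                               cc$smiles)]),
                                  collapse = "."))
  expect_identical(length(unique(oracle)), 24L)
  # every enumerated structure contains the same components as the oracle
  got <- vapply(toy$compounds$smiles, function(s)
    paste(sort(strsplit(s, ".", fixed = TRUE)[[1]]), collapse = "."),
    character(1))
  expect_setequal(unname(got), unique(oracle))
})

test_that("duplicated submodules are collapsed with provenance", {
  ms <- validate_module_set(list(
    name = "dup", optional_labels = list(),
    modules = list(
      list(id = "m1", submodules = list(
        list(id = "u", smiles = "CCO", deltas = list()),
        list(id = "v", smiles = "CCO", deltas = list()))),
      list(id = "m2", submodules = list(
        list(id = "w", smiles = "N", deltas = list())))),
    templates = list(list(id = "f", kind = "product_ion", m0 = "CH3",
                          charge = 1, slots = list("m1")))))
  expect_message(lib <- enumerate_library(ms), "duplicate")
  expect_identical(lib$n_combinations, 2L)
  expect_identical(nrow(lib$compounds), 1L)
  expect_length(lib$provenance, 1L)
})

test_that("every predicted formula differs from m0 by the summed deltas", {
  lib <- daphnane_library()
  ms <- daphnane_module_set()
  set.seed(3)
  idx <- sample(nrow(lib$compounds), 10)
  for (i in idx) {
    comp <- lib$compounds[i, ]
    choices <- as.list(comp[grep("^choice_", names(comp))])
    names(choices) <- sub("^choice_", "", names(choices))
    ions <- lib$ions[lib$ions$compound_id == comp$compound_id, ]
    for (j in seq_len(nrow(ions))) {
      f <- predict_ion_formula(ms, ions$family[j], choices)
      expect_identical(formula_string(f), ions$formula[j])
    }
  }
})

test_that("library persists and loads as an equal object with lookups", {
  lib <- daphnane_library()
  p <- tempfile(fileext = ".json")
  persist_library(lib, p)
  lib2 <- load_library(p)
  expect_identical(lib2$compounds, lib$compounds)
  expect_identical(lib2$ions, lib$ions)
  expect_identical(lib2$n_combinations, lib$n_combinations)
  # indexed lookups: by predicted formula and by module choice
  ids <- ions_by_formula(lib2, "C17H17O2", family = "core17")
  expect_identical(length(ids), 64L)  # I1 fixed, 2*4*2*4 free combinations
  sub <- compounds_matching(lib2, choices = list(module_I = "I2",
                                                 module_V = "V0"))
  expect_identical(nrow(sub), 16L)    # 2*4*2
})

test_that("schema mismatches and corrupted stores fail cleanly", {
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = "mfsa-library-99"), p,
                       auto_unbox = TRUE)
  expect_error(load_library(p), "schema version mismatch")
  p2 <- tempfile(fileext = ".json")
  writeLines("{ not json", p2)
  expect_error(load_library(p2), "corrupted")
  expect_error(load_library(tempfile()), "not found")
})

test_that("empty module slots are rejected", {
  expect_error(validate_module_set(list(
    modules = list(list(id = "m1", submodules = list())),
    templates = list())), "empty")
})
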