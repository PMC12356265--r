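# Rule application, candidate lookup and the full annotation pipeline.

test_that("rule validation enforces binary weights and evidence presence", {
  expect_error(validate_rule(list(id = "r", slot = "s", submodule = "x",
                                  evidence = list())), "no evidence")
  expect_error(validate_rule(list(
    id = "r", slot = "s", submodule = "x",
    evidence = list(list(type = "ion", formula = "C2H4", weight = 0.5)))),
    "binary")
  expect_error(validate_rules(list(settings = list(bogus = 1))),
               "unknown setting")
  r <- validate_rule(list(id = "r", slot = "s", submodule = "x",
                          evidence = list(list(type = "ion",
                                               formula = "C2H4"))))
  expect_identical(r$evidence[[1]]$weight, 1)
})

test_that("priority score sums weighted evidence scores", {
  rules <- list(
    validate_rule(list(id = "rI", slot = "module_I", submodule = "I1",
                       evidence = list(list(type = "ion", family = "core17",
                                            formula = "C17H17O2",
                                            weight = 1)))),
    validate_rule(list(id = "rII", slot = "module_II", submodule = "II1",
                       evidence = list(list(type = "loss", family = "bloss",
                                            formula = "C3H4O2",
                                            carbons = c(20L, 17L),
                                            weight = 1)))))
  evidence <- list()
  evidence[[evidence_key(rules[[1]]$evidence[[1]])]] <-
    list(score = 1.0, ppm = 0.1)
  evidence[[evidence_key(rules[[2]]$evidence[[1]])]] <-
    list(score = 0.36, ppm = 0.2)
  cands <- apply_rules(evidence, rules)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$score, 1.36, tolerance = 1e-12)
  expect_identical(cands[[1]]$choices,
                   list(module_I = "I1", module_II = "II1"))
})

test_that("unsatisfied rules yield no candidates; conflicts are kept ranked", {
  rules <- list(
    validate_rule(list(id = "a", slot = "m", submodule = "x",
                       evidence = list(list(type = "ion", formula = "C2H4",
                                            weight = 1)))),
    validate_rule(list(id = "b", slot = "m", submodule = "y",
                       evidence = list(list(type = "ion", formula = "C3H6",
                                            weight = 1)))))
  # nothing observed -> empty
  ev0 <- list()
  ev0[[evidence_key(rules[[1]]$evidence[[1]])]] <-
    list(score = NA_real_, ppm = NA_real_)
  ev0[[evidence_key(rules[[2]]$evidence[[1]])]] <-
    list(score = NA_real_, ppm = NA_real_)
  expect_length(apply_rules(ev0, rules), 0)
  # both observed: contradictory submodules for one slot -> two candidates,
  # higher score first
  ev <- list()
  ev[[evidence_key(rules[[1]]$evidence[[1]])]] <- list(score = 0.4, ppm = 1)
  ev[[evidence_key(rules[[2]]$evidence[[1]])]] <- list(score = 0.9, ppm = 1)
  cands <- apply_rules(ev, rules)
  expect_length(cands, 2)
  expect_identical(cands[[1]]$choices$m, "y")
  expect_true(cands[[1]]$score >= cands[[2]]$score)
})

test_that("rules assigning the same submodule pool distinct evidence", {
  rules <- list(
    validate_rule(list(id = "a", slot = "m", submodule = "x",
                       evidence = list(list(type = "ion", formula = "C2H4",
                                            weight = 1)))),
    validate_rule(list(id = "b", slot = "m", submodule = "x",
                       evidence = list(list(type = "ion", formula = "C2H4",
                                            weight = 1),
                                       list(type = "ion", formula = "C5H8",
                                            weight = 1)))))
  ev <- list()
  ev[[evidence_key(rules[[1]]$evidence[[1]])]] <- list(score = 0.5, ppm = 1)
  ev[[evidence_key(rules[[2]]$evidence[[2]])]] <- list(score = 0.25, ppm = 1)
  cands <- apply_rules(ev, rules)
  expect_length(cands, 1)
  # C2H4 counted once although required by both rules
  expect_equal(cands[[1]]$score, 0.75, tolerance = 1e-12)
  expect_identical(cands[[1]]$n_evidence, 2L)
})

test_that("derived rules cover every single-slot family submodule", {
  lib <- daphnane_library()
  rules <- derive_rules(lib)
  ids <- vapply(rules, `[[`, character(1), "id")
  # 3 core17 + 3 core20 + 4 acylium + 2 bloss + 3 macroloss (V0 absent)
  expect_identical(length(rules), 15L)
  expect_true("core17:I2" %in% ids)
  expect_false(any(grepl("macroloss:V0", ids)))
  r <- rules[[which(ids == "core17:I2")[1]]]
  expect_identical(r$evidence[[1]]$formula, "C17H17O3")
})

test_that("candidate lookup honors partial choices and formula constraints", {
  lib <- daphnane_library()
  full <- list(module_I = "I1", module_II = "II1", module_III = "III1",
               module_IV = "IV1", module_V = "V0")
  hit <- lookup_candidates(list(choices = full), lib)
  expect_identical(nrow(hit), 1L)
  partial <- full[c("module_I", "module_II", "module_III", "module_V")]
  hit2 <- lookup_candidates(list(choices = partial), lib)
  expect_identical(nrow(hit2), 2L)   # module_IV free
  # formula constraint selects among the two
  hit3 <- lookup_candidates(list(choices = partial), lib,
                            formula = hit$formula[1])
  expect_identical(nrow(hit3), 1L)
  expect_identical(hit3$compound_id, hit$compound_id)
  # a constraint excluding everything
  expect_identical(nrow(lookup_candidates(list(choices = partial), lib,
                                          formula = "C999")), 0L)
})

test_that("annotate recovers members, skips decoys and reports tiers", {
  lib <- daphnane_library()
  cfg <- simulation_config(seed = 41, n_members = 12, n_decoys = 12)
  ds <- simulate_dataset(lib, cfg)
  res <- annotate(ds$feature_table, ds$spectra, lib, daphnane_rules())
  expect_s3_class(res, "annotation_report")
  expect_identical(top1_recovery(res, ds$truth), 1)
  decoys <- ds$truth$feature_id[is.na(ds$truth$compound_id)]
  expect_identical(sum(res$hits$feature_id %in% decoys), 0L)
  r1 <- res$report[res$report$rank == 1, ]
  expect_true(all(r1$tier == "A"))
  # every recognized feature appears exactly once at rank 1 and candidate
  # counts respect top-N
  expect_setequal(r1$feature_id, res$hits$feature_id)
  per_feature <- table(res$report$feature_id)
  expect_true(all(per_feature <= res$settings$top_n))
})

test_that("adding evidence never lowers the priority score", {
  lib <- daphnane_library()
  cfg <- simulation_config(seed = 43, n_members = 6, n_decoys = 0)
  ds <- simulate_dataset(lib, cfg)
  rules_full <- c(daphnane_rules()$rules, derive_rules(lib))
  db <- build_formula_db(c(0L, 50L), c(0L, 80L), c(0L, 15L), c(0L, 0L))
  for (fid in names(ds$spectra)[1:3]) {
    s <- ds$spectra[[fid]]
    ev <- gather_evidence(s, rules_full, db, feature_table = ds$feature_table)
    full_c <- apply_rules(ev, rules_full, top_n = 1)
    # drop the loss rules: the best score cannot increase
    rules_ion <- Filter(function(r)
      all(vapply(r$evidence, function(e) e$type != "loss", logical(1))),
      rules_full)
    ion_c <- apply_rules(ev, rules_ion, top_n = 1)
    if (length(full_c) && length(ion_c))
      expect_lte(ion_c[[1]]$score, full_c[[1]]$score + 1e-12)
  }
})

test_that("annotate isolates per-feature failures and handles empty input", {
  lib <- daphnane_library()
  res <- annotate(
    structure(data.frame(feature_id = character(0), mz = numeric(0),
                         rt = numeric(0)),
              class = c("feature_table", "data.frame")),
    list(), lib, daphnane_rules())
  expect_identical(nrow(res$report), 0L)
  expect_identical(nrow(res$hits), 0L)
})

test_that("reports are byte-identical across reruns", {
  lib <- daphnane_library()
  cfg <- simulation_config(seed = 47, n_members = 8, n_decoys = 4)
  ds <- simulate_dataset(lib, cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(annotate(ds$feature_table, ds$spectra, lib,
                        daphnane_rules()), d1)
  write_report(annotate(ds$feature_table, ds$spectra, lib,
                        daphnane_rules()), d2)
  f1 <- file.path(d1, "report.csv"); f2 <- file.path(d2, "report.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
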