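# Neutral-loss scoring (IA x IDF), feature-ion scoring and range cosine.

loss_db <- function() memo("loss_db",
  build_formula_db(c(0L, 35L), c(0L, 60L), c(0L, 12L), c(0L, 0L)))

# a spectrum carrying the C20H21O4 / C17H17O2 pair realizing the C3H4O2
# loss, with raw intensities chosen to hit target normalized values
pair_spectrum <- function(i_hi, i_lo) {
  mz_hi <- monoisotopic_mass(parse_formula("C20H21O4", charge = 1))
  mz_lo <- monoisotopic_mass(parse_formula("C17H17O2", charge = 1))
  # anchors at norm 0 and 1 so that normalized intensities equal i_hi, i_lo
  mk_spectrum(c(mz_lo, mz_hi, 210.0, 390.0),
              c(i_lo * 1e6, i_hi * 1e6, 0, 1e6))
}

test_that("neutral-loss scores evaluate IA, IDF and their product", {
  s <- pair_spectrum(0.8, 0.8)
  lab <- label_neutral_losses(s, c(200, 400), c(20L, 17L), list("C3H4O2"),
                              loss_db())
  expect_identical(nrow(lab), 1L)
  expect_equal(lab$IA, 0.8, tolerance = 1e-12)
  expect_equal(lab$IDF, 1, tolerance = 1e-12)
  expect_equal(lab$score, 0.8, tolerance = 1e-12)
  s2 <- pair_spectrum(0.8, 0.4)
  lab2 <- label_neutral_losses(s2, c(200, 400), c(20L, 17L), list("C3H4O2"),
                               loss_db())
  expect_equal(lab2$IA, 0.6, tolerance = 1e-12)
  expect_equal(lab2$IDF, 0.6, tolerance = 1e-12)
  expect_equal(lab2$score, 0.36, tolerance = 1e-12)
})

test_that("score is symmetric in the pair intensities and bounded", {
  s_ab <- pair_spectrum(0.7, 0.3)
  s_ba <- pair_spectrum(0.3, 0.7)
  la <- label_neutral_losses(s_ab, c(200, 400), c(20L, 17L), list("C3H4O2"),
                             loss_db())
  lb <- label_neutral_losses(s_ba, c(200, 400), c(20L, 17L), list("C3H4O2"),
                             loss_db())
  expect_equal(la$score, lb$score, tolerance = 1e-12)
  # IDF = 1 iff equal; strictly decreasing in |I1 - I2| at fixed IA
  idf <- function(i1, i2) {
    ia <- (i1 + i2) / 2
    1 / (1 + abs(i1 - i2) / ia)
  }
  ds <- seq(0, 0.5, by = 0.05)
  vals <- vapply(ds, function(d) idf(0.5 + d, 0.5 - d), numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
  for (d in ds) {
    sc <- (0.5) * idf(0.5 + d, 0.5 - d)
    expect_true(sc >= 0 && sc <= 1)
  }
})

test_that("both pair members must carry the target carbon counts", {
  # same loss composition but between C19 and C16 ions: not labeled for
  # the (20, 17) constraint
  mz_hi <- monoisotopic_mass(parse_formula("C19H21O4", charge = 1))
  mz_lo <- monoisotopic_mass(parse_formula("C16H17O2", charge = 1))
  s <- mk_spectrum(c(mz_lo, mz_hi, 210, 390), c(4e5, 5e5, 0, 1e6))
  lab <- label_neutral_losses(s, c(200, 400), c(20L, 17L), list("C3H4O2"),
                              loss_db())
  expect_identical(nrow(lab), 0L)
  # the within-count case is the pair (c, c)
  lab2 <- label_neutral_losses(pair_spectrum(0.8, 0.6), c(200, 400),
                               c(20L, 20L), list("C3H4O2"), loss_db())
  expect_identical(nrow(lab2), 0L)  # members have 20 and 17 carbons
})

test_that("no in-range peaks yields an empty labeling", {
  s <- mk_spectrum(c(150, 600), c(1, 1))
  expect_identical(
    nrow(label_neutral_losses(s, c(200, 400), c(20L, 17L), list("C3H4O2"),
                              loss_db())), 0L)
})

test_that("feature ions are ranked by relative intensity with Ii/Imax score", {
  mz253 <- monoisotopic_mass(parse_formula("C17H17O2", charge = 1))
  mz361 <- monoisotopic_mass(parse_formula("C20H25O6", charge = 1))
  s <- mk_spectrum(c(mz253, mz361, 210, 390), c(1e6, 5e5, 0, 8e5))
  lab <- label_feature_ions(s, c(200, 400), list("C17H17O2", "C20H25O6"))
  expect_identical(lab$formula, c("C17H17O2", "C20H25O6"))
  expect_identical(lab$rank, 1:2)
  expect_equal(lab$score[1], 1, tolerance = 1e-12)  # the Imax peak itself
  expect_equal(lab$score[2], 0.5, tolerance = 1e-9)
  # top-N truncation
  lab1 <- label_feature_ions(s, c(200, 400), list("C17H17O2", "C20H25O6"),
                             n = 1)
  expect_identical(nrow(lab1), 1L)
  expect_identical(lab1$formula, "C17H17O2")
})

test_that("range cosine matches the worked example and its invariants", {
  q <- mk_spectrum(c(100, 200), c(1.0, 0.5))
  s <- mk_spectrum(c(100, 200), c(0.5, 1.0))
  expect_equal(range_cosine(q, s, c(50, 250))$value, 0.8,
               tolerance = 1e-12)
  # self-similarity is exactly 1, disjoint support exactly 0
  expect_equal(range_cosine(q, q, c(50, 250))$value, 1, tolerance = 1e-12)
  d <- mk_spectrum(c(150, 250), c(1, 1))
  expect_identical(range_cosine(q, d, c(50, 300))$value, 0)
  # symmetry and invariance under uniform scaling
  expect_equal(range_cosine(s, q, c(50, 250))$value,
               range_cosine(q, s, c(50, 250))$value, tolerance = 1e-12)
  q10 <- mk_spectrum(c(100, 200), c(10, 5))
  expect_equal(range_cosine(q10, s, c(50, 250))$value,
               range_cosine(q, s, c(50, 250))$value, tolerance = 1e-12)
  # range restriction drops out-of-window peaks
  q2 <- mk_spectrum(c(100, 200, 400), c(1, 0.5, 99))
  expect_equal(range_cosine(q2, s, c(50, 250))$value, 0.8,
               tolerance = 1e-12)
})

test_that("labels on noiseless fixtures match the generating families", {
  lib <- daphnane_library()
  cfg <- simulation_config(seed = 31, n_members = 5, n_decoys = 0,
                           jitter_ppm_sd = 0, noise_n_in = 3,
                           noise_n_out = 2)
  ds <- simulate_dataset(lib, cfg)
  ms <- daphnane_module_set()
  for (i in seq_len(nrow(ds$truth))) {
    fid <- ds$truth$feature_id[i]
    cid <- ds$truth$compound_id[i]
    ions <- lib$ions[lib$ions$compound_id == cid, ]
    s <- ds$spectra[[fid]]
    # every product-ion family inside the window is labeled at ~0 ppm
    prod <- ions[ions$kind == "product_ion", ]
    for (j in seq_len(nrow(prod))) {
      f <- parse_formula(prod$formula[j], charge = prod$charge[j])
      mzt <- monoisotopic_mass(f)
      rng <- if (mzt < 200) c(50, 200) else c(200, 400)
      lab <- label_feature_ions(s, rng, list(prod$formula[j]))
      expect_identical(nrow(lab), 1L)
      expect_lt(abs(lab$ppm[1]), 1e-6)
    }
    # every loss family is labeled with its carbon constraint
    loss <- ions[ions$kind == "neutral_loss", ]
    for (j in seq_len(nrow(loss))) {
      tp <- Filter(function(t) t$id == loss$family[j], ms$templates)[[1]]
      lab <- label_neutral_losses(s, as.numeric(unlist(tp$label_range)),
                                  as.integer(unlist(tp$carbons)),
                                  list(loss$formula[j]), loss_db())
      expect_gt(nrow(lab), 0)
    }
  }
})
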