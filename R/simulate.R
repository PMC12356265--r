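#' Configuration for the synthetic MZmine-style dataset generator
#'
#' The generator emulates the exports the workflow consumes: a quant CSV and
#' an MGF with class-member spectra built from a pseudo-compound library
#' (every predicted diagnostic family realized as peaks) plus decoy spectra
#' whose peaks avoid all diagnostic windows by construction.
#'
#' Intensity model: diagnostic ions uniform in `diag_range` of the range
#' maximum (default \[0.5, 1\]); noise uniform in \[0, `noise_ceiling`\]
#' (default 0.08, below the default 0.1 noise floor). m/z jitter is
#' multiplicative, `mz * (1 + eps/1e6)` with `eps ~ N(0, jitter_ppm_sd)`.
#'
#' @param seed integer RNG seed.
#' @param n_members,n_decoys number of class members / decoys (default 50/50).
#' @param jitter_ppm_sd m/z jitter sigma in ppm (default 1).
#' @param dropout per-diagnostic-ion dropout probability (default 0).
#' @param noise_n_in,noise_n_out noise peaks inside / outside the
#'   recognition window (defaults 8 / 4).
#' @param noise_ceiling noise intensity ceiling as a fraction of the range
#'   maximum (default 0.08).
#' @param diag_range diagnostic intensity range as fractions of the maximum.
#' @param mz_range recognition/normalization window (default `c(200, 400)`).
#' @param base_intensity raw counts of the strongest peak (default 1e6).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_members = 50L, n_decoys = 50L,
                              jitter_ppm_sd = 1, dropout = 0,
                              noise_n_in = 8L, noise_n_out = 4L,
                              noise_ceiling = 0.08,
                              diag_range = c(0.5, 1),
                              mz_range = c(200, 400),
                              base_intensity = 1e6) {
  stopifnot(dropout >= 0, dropout <= 1, noise_ceiling >= 0,
            noise_ceiling <= 1)
  structure(list(seed = as.integer(seed), n_members = as.integer(n_members),
                 n_decoys = as.integer(n_decoys),
                 jitter_ppm_sd = jitter_ppm_sd, dropout = dropout,
                 noise_n_in = as.integer(noise_n_in),
                 noise_n_out = as.integer(noise_n_out),
                 noise_ceiling = noise_ceiling, diag_range = diag_range,
                 mz_range = as.numeric(mz_range),
                 base_intensity = base_intensity),
            class = "simulation_config")
}

# theoretical m/z of every diagnostic peak a compound can show, including
# the heavy partner ion implied by each neutral-loss family (pair_base +
# loss); used both for spectrum construction and for decoy exclusion
.diagnostic_mzs <- function(lib) {
  ms <- validate_module_set(lib$module_set)
  ions <- unique(lib$ions[c("compound_id", "family", "kind", "formula",
                            "charge")])
  # distinct (family, formula) is tiny even for large libraries
  prod <- unique(ions[ions$kind == "product_ion", c("formula", "charge")])
  mz <- vapply(seq_len(nrow(prod)), function(i)
    monoisotopic_mass(parse_formula(prod$formula[i],
                                    charge = prod$charge[i])), numeric(1))
  loss <- ions[ions$kind == "neutral_loss", , drop = FALSE]
  if (nrow(loss)) {
    pair_keys <- unique(do.call(rbind, lapply(seq_len(nrow(loss)), function(i) {
      tp <- .get_template(ms, loss$family[i])
      base <- lib$ions[lib$ions$compound_id == loss$compound_id[i] &
                         lib$ions$family == (tp$pair_base %||% ""), ,
                       drop = FALSE]
      if (!nrow(base)) return(NULL)
      data.frame(loss_f = loss$formula[i], base_f = base$formula[1],
                 base_c = base$charge[1], stringsAsFactors = FALSE)
    })))
    if (!is.null(pair_keys) && nrow(pair_keys)) {
      mz <- c(mz, vapply(seq_len(nrow(pair_keys)), function(i) {
        lo <- parse_formula(pair_keys$base_f[i], charge = pair_keys$base_c[i])
        f0 <- parse_formula(pair_keys$loss_f[i], charge = 0)
        monoisotopic_mass(ec_add(lo, f0))
      }, numeric(1)))
    }
  }
  sort(unique(round(mz, 6)))
}

.jitter <- function(mz, sd_ppm) mz * (1 + stats::rnorm(length(mz), 0, sd_ppm) / 1e6)

# draw m/z values in [lo, hi] rejecting anything within `margin_ppm` of a
# forbidden position
.draw_clear_mz <- function(n, lo, hi, forbidden, margin_ppm = 50) {
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n && guard < 10000L) {
    x <- stats::runif(n - length(out), lo, hi)
    ok <- vapply(x, function(v)
      !any(abs((v - forbidden) / forbidden) * 1e6 <= margin_ppm), logical(1))
    out <- c(out, x[ok])
    guard <- guard + 1L
  }
  out
}

#' Simulate one member MS/MS spectrum from a pseudo-compound
#'
#' Realizes every predicted diagnostic family of the compound: product-ion
#' families as single peaks, neutral-loss families as the implied ion pair
#' (the `pair_base` family's ion plus the heavy partner), plus the
#' \[M+H\]+ precursor peak and noise. Deterministic given `(cfg$seed,
#' feature_index)`.
#'
#' @param lib a `pseudo_library`.
#' @param compound_id compound to simulate.
#' @param cfg a [simulation_config].
#' @param feature_index integer stream index making each feature's draw
#'   independent and reproducible.
#' @param all_diag optional precomputed vector of diagnostic m/z values to
#'   exclude from noise (default recomputed from the library).
#' @return a [spectrum] (feature_id = `sprintf("F%04d", feature_index)`).
#' @export
simulate_spectrum <- function(lib, compound_id, cfg, feature_index = 1L,
                              all_diag = NULL) {
  set.seed((cfg$seed * 1009L + feature_index) %% .Machine$integer.max)
  ms <- validate_module_set(lib$module_set)
  ions <- lib$ions[lib$ions$compound_id == compound_id, , drop = FALSE]
  if (!nrow(ions)) stop("compound ", compound_id, " has no predicted ions")
  comp <- lib$compounds[lib$compounds$compound_id == compound_id, ,
                        drop = FALSE]
  mz <- numeric(0)
  for (i in seq_len(nrow(ions))) {
    f <- parse_formula(ions$formula[i], charge = ions$charge[i])
    if (ions$kind[i] == "product_ion") {
      mz <- c(mz, monoisotopic_mass(f))
    } else {
      tp <- .get_template(ms, ions$family[i])
      base <- ions[ions$family == (tp$pair_base %||% ""), , drop = FALSE]
      if (!nrow(base))
        stop("loss family '", ions$family[i], "' has no pair_base ion for ",
             compound_id)
      lo <- parse_formula(base$formula[1], charge = base$charge[1])
      f0 <- f; f0$charge <- 0L
      mz <- c(mz, monoisotopic_mass(ec_add(lo, f0)))
    }
  }
  mz <- unique(mz)
  keep <- stats::runif(length(mz)) >= cfg$dropout
  mz <- mz[keep]
  neutral <- parse_formula(comp$formula[1], charge = 0)
  prec <- adduct_mz(neutral, default_adducts()[[1]])   # [M+H]+
  n_d <- length(mz)
  diag_int <- stats::runif(n_d, cfg$diag_range[1], cfg$diag_range[2]) *
    cfg$base_intensity
  if (is.null(all_diag)) all_diag <- .diagnostic_mzs(lib)
  noise_in <- .draw_clear_mz(cfg$noise_n_in, cfg$mz_range[1], cfg$mz_range[2],
                             c(all_diag, prec))
  noise_out <- .draw_clear_mz(cfg$noise_n_out, 100, max(600, prec - 50),
                              c(all_diag, prec))
  noise_mz <- c(noise_in, noise_out)
  noise_int <- stats::runif(length(noise_mz), 0, cfg$noise_ceiling) *
    cfg$base_intensity
  peaks <- data.frame(
    mz = c(.jitter(mz, cfg$jitter_ppm_sd), .jitter(prec, cfg$jitter_ppm_sd),
           noise_mz),
    intensity = c(diag_int,
                  stats::runif(1, cfg$diag_range[1], cfg$diag_range[2]) *
                    cfg$base_intensity,
                  noise_int))
  spectrum(feature_id = sprintf("F%04d", feature_index),
           precursor_mz = .jitter(prec, cfg$jitter_ppm_sd),
           peaks = peaks, charge = 1L,
           rt = stats::runif(1, 1, 15), polarity = "positive")
}

#' Simulate a complete fixture dataset (feature table + spectra + truth)
#'
#' Members are drawn (without replacement when possible) from the library;
#' decoy spectra carry random peaks excluded from every diagnostic window
#' (50 ppm margin), so recognition returns zero decoy hits at 5 ppm by
#' construction. Submodules declaring `"ms1_pattern":
#' "dehydration_dominant"` in the module set get a co-eluting companion
#' feature at \[M+H-H2O\]+ with twice the area, emulating the
#' dehydration-dominant MS1 pattern.
#'
#' @param lib a `pseudo_library`.
#' @param cfg a [simulation_config].
#' @return list with `feature_table`, `spectra` (named list), `truth`
#'   (data.frame feature_id -> compound_id; decoys have NA).
#' @export
simulate_dataset <- function(lib, cfg = simulation_config()) {
  set.seed(cfg$seed)
  n_comp <- nrow(lib$compounds)
  ids <- lib$compounds$compound_id[
    sample.int(n_comp, cfg$n_members, replace = cfg$n_members > n_comp)]
  ms <- validate_module_set(lib$module_set)
  dehydration_subs <- character(0)
  for (m in ms$modules) for (sm in m$submodules)
    if (identical(sm$ms1_pattern, "dehydration_dominant"))
      dehydration_subs <- c(dehydration_subs, paste0(m$id, "=", sm$id))
  spectra <- list()
  ft_rows <- list()
  truth <- list()
  slot_ids <- vapply(ms$modules, `[[`, character(1), "id")
  all_diag <- .diagnostic_mzs(lib)
  for (k in seq_len(cfg$n_members)) {
    sp <- simulate_spectrum(lib, ids[k], cfg, feature_index = k,
                            all_diag = all_diag)
    spectra[[sp$feature_id]] <- sp
    area <- stats::runif(1, 1e5, 1e7)
    ft_rows[[length(ft_rows) + 1L]] <- data.frame(
      feature_id = sp$feature_id, mz = sp$precursor_mz, rt = sp$rt,
      area_S1 = area, stringsAsFactors = FALSE)
    comp <- lib$compounds[lib$compounds$compound_id == ids[k], , drop = FALSE]
    tags <- paste0(slot_ids, "=",
                   unlist(comp[paste0("choice_", slot_ids)]))
    if (any(tags %in% dehydration_subs)) {
      h2o <- sum(element_count(H = 2, O = 1)$counts * ELEMENT_MASSES)
      ft_rows[[length(ft_rows) + 1L]] <- data.frame(
        feature_id = paste0(sp$feature_id, "d"), mz = sp$precursor_mz - h2o,
        rt = sp$rt, area_S1 = 2 * area, stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = sp$feature_id, compound_id = ids[k],
      formula = comp$formula[1], stringsAsFactors = FALSE)
  }
  all_diag <- .diagnostic_mzs(lib)
  for (k in seq_len(cfg$n_decoys)) {
    idx <- cfg$n_members + k
    set.seed((cfg$seed * 1009L + idx) %% .Machine$integer.max)
    prec <- stats::runif(1, 450, 750)
    pk_mz <- .draw_clear_mz(12L, 150, 600, all_diag)
    pk_int <- stats::runif(length(pk_mz), 0.1, 1) * cfg$base_intensity
    sp <- spectrum(feature_id = sprintf("F%04d", idx), precursor_mz = prec,
                   peaks = data.frame(mz = pk_mz, intensity = pk_int),
                   charge = 1L, rt = stats::runif(1, 1, 15),
                   polarity = "positive")
    spectra[[sp$feature_id]] <- sp
    ft_rows[[length(ft_rows) + 1L]] <- data.frame(
      feature_id = sp$feature_id, mz = prec, rt = sp$rt,
      area_S1 = stats::runif(1, 1e5, 1e7), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = sp$feature_id, compound_id = NA_character_,
      formula = NA_character_, stringsAsFactors = FALSE)
  }
  ft <- do.call(rbind, ft_rows)
  class(ft) <- c("feature_table", "data.frame")
  list(feature_table = ft, spectra = spectra,
       truth = do.call(rbind, truth))
}

#' Randomly degrade library coverage (sensitivity harness)
#'
#' Retains a uniform random subset of submodules at the given fraction of
#' the total count (rounding half up), keeping at least one submodule per
#' slot; compounds and predicted ions using dropped submodules are removed.
#'
#' @param lib a `pseudo_library`.
#' @param fraction retention fraction in (0, 1\].
#' @param seed integer seed for the random retention draw.
#' @return a reduced `pseudo_library`.
#' @export
degrade_library <- function(lib, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(lib)
  set.seed(as.integer(seed))
  ms <- validate_module_set(lib$module_set)
  all_subs <- do.call(rbind, lapply(ms$modules, function(m)
    data.frame(slot = m$id,
               sub = vapply(m$submodules, `[[`, character(1), "id"),
               stringsAsFactors = FALSE)))
  n <- nrow(all_subs)
  keep_n <- max(length(ms$modules), floor(fraction * n + 0.5))
  # guarantee one per slot, then fill the quota uniformly
  first <- vapply(split(seq_len(n), all_subs$slot), function(ix)
    if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
  rest <- setdiff(seq_len(n), first)
  extra <- if (keep_n > length(first))
    sample(rest, keep_n - length(first)) else integer(0)
  keep_idx <- sort(c(unname(first), extra))
  kept <- all_subs[keep_idx, , drop = FALSE]
  new_modules <- lapply(ms$modules, function(m) {
    m$submodules <- Filter(function(sm)
      sm$id %in% kept$sub[kept$slot == m$id], m$submodules)
    m
  })
  new_ms <- ms
  new_ms$modules <- new_modules
  ok <- rep(TRUE, nrow(lib$compounds))
  for (m in ms$modules) {
    col <- paste0("choice_", m$id)
    ok <- ok & lib$compounds[[col]] %in% kept$sub[kept$slot == m$id]
  }
  out <- lib
  out$module_set <- validate_module_set(unclass(new_ms))
  out$compounds <- lib$compounds[ok, , drop = FALSE]
  out$ions <- lib$ions[lib$ions$compound_id %in% out$compounds$compound_id, ,
                       drop = FALSE]
  rownames(out$compounds) <- rownames(out$ions) <- NULL
  out
}

#' Top-1 recovery of generating compounds from an annotation report
#'
#' @param report the `report` data.frame of an `annotation_report` (or the
#'   report object itself).
#' @param truth truth table from [simulate_dataset()].
#' @return fraction of members whose generating compound is the rank-1
#'   structure.
#' @export
top1_recovery <- function(report, truth) {
  if (inherits(report, "annotation_report")) report <- report$report
  members <- truth[!is.na(truth$compound_id), , drop = FALSE]
  hit <- vapply(seq_len(nrow(members)), function(i) {
    r1 <- report[report$feature_id == members$feature_id[i] &
                   report$rank == 1L, , drop = FALSE]
    nrow(r1) == 1L && !is.na(r1$compound_id) &&
      r1$compound_id == members$compound_id[i]
  }, logical(1))
  mean(hit)
}

#' Library-degradation sensitivity harness
#'
#' Simulates one dataset from the full library, then measures mean Top-1
#' recovery when annotating against libraries degraded to each retention
#' fraction (replicated with distinct seeds). Mirrors a coverage-reduction
#' experiment at 100/50/33/10 per cent retention with 10 replicates per
#' level.
#'
#' @param lib a `pseudo_library`.
#' @param cfg a [simulation_config].
#' @param fractions retention fractions (default `c(1, 0.5, 1/3, 0.1)`).
#' @param n_rep replicates per fraction (default 10; fraction 1 is
#'   deterministic and run once).
#' @param rules optional `rule_set`; defaults to auto-derived rules.
#' @return data.frame with `fraction`, `mean_top1`, `sd_top1`, `n_rep`.
#' @export
sensitivity_harness <- function(lib, cfg = simulation_config(),
                                fractions = c(1, 0.5, 1 / 3, 0.1),
                                n_rep = 10L, rules = NULL) {
  ds <- simulate_dataset(lib, cfg)
  rows <- lapply(fractions, function(fr) {
    reps <- if (fr == 1) 1L else n_rep
    rec <- vapply(seq_len(reps), function(r) {
      sub <- degrade_library(lib, fr,
                             seed = (cfg$seed * 7919L + round(fr * 1000) +
                                       r) %% .Machine$integer.max)
      rep_report <- annotate(ds$feature_table, ds$spectra, sub, rules)
      top1_recovery(rep_report, ds$truth)
    }, numeric(1))
    data.frame(fraction = fr, mean_top1 = mean(rec),
               sd_top1 = if (length(rec) > 1) stats::sd(rec) else 0,
               n_rep = reps)
  })
  do.call(rbind, rows)
}
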