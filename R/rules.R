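#' Read and validate an annotation rule set (JSON)
#'
#' A rule set couples workflow settings (tolerances, windows, thresholds)
#' with module-annotation rules. Each rule asserts: when all of its evidence
#' items are observed, a given slot is assigned a given submodule. Evidence
#' items are diagnostic feature ions, characteristic neutral losses, or an
#' MS1 adduct-intensity pattern; each carries a binary weight `w` in {0, 1}
#' deciding whether its score enters the priority score.
#'
#' Expected JSON shape:
#' \preformatted{
#' {"name": "...",
#'  "auto_from_library": true,
#'  "settings": {"tol_ppm": 5, "mz_range": [200, 400],
#'               "noise_threshold": 0.1, "min_matching_ions": 2,
#'               "top_n": 3, "polarity": "positive",
#'               "rt_tol": 0.1, "cosine_tol_ppm": 10,
#'               "db_bounds": {"C": [0, 45], "H": [0, 70],
#'                              "O": [0, 15], "N": [0, 3]}},
#'  "rules": [{"id": "...", "slot": "module_I", "submodule": "I2",
#'             "evidence": [{"type": "ion", "family": "core17",
#'                           "formula": "C17H17O3", "weight": 1,
#'                           "range": [200, 400]}]}]}
#' }
#' With `auto_from_library` true, per-submodule rules are derived from the
#' library's predicted formulas at load time ([derive_rules()]) and appended
#' to any explicitly listed rules.
#'
#' @param path JSON file path.
#' @return object of class `rule_set`: list with `name`, `settings`,
#'   `rules`, `auto_from_library`.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_rules(raw)
}

default_settings <- function() {
  list(tol_ppm = 5, mz_range = c(200, 400), noise_threshold = 0.1,
       min_matching_ions = 2L, top_n = 3L, polarity = "positive",
       rt_tol = 0.1, cosine_tol_ppm = 10,
       rdbe_range = c(0, 40),
       db_bounds = list(C = c(0L, 45L), H = c(0L, 70L),
                        O = c(0L, 15L), N = c(0L, 3L)))
}

#' @rdname read_rules
#' @param x list with the rule-set structure.
#' @export
validate_rules <- function(x) {
  st <- default_settings()
  for (k in names(x$settings)) {
    if (!k %in% names(st))
      stop("unknown setting: ", k)
    v <- x$settings[[k]]
    st[[k]] <- if (k == "db_bounds")
      lapply(v, function(b) as.integer(unlist(b))) else unlist(v)
  }
  rules <- lapply(x$rules %||% list(), validate_rule)
  structure(list(name = x$name %||% "(unnamed)", settings = st,
                 rules = rules,
                 auto_from_library = isTRUE(x$auto_from_library)),
            class = "rule_set")
}

validate_rule <- function(r) {
  if (is.null(r$id) || is.null(r$slot) || is.null(r$submodule))
    stop("rule needs id, slot and submodule")
  if (is.null(r$evidence) || !length(r$evidence))
    stop("rule '", r$id, "' has no evidence items")
  r$evidence <- lapply(r$evidence, function(ev) {
    ev$weight <- ev$weight %||% 1
    if (!ev$weight %in% c(0, 1))
      stop("rule '", r$id, "': evidence weight must be binary (0 or 1)")
    if (is.null(ev$type) ||
        !ev$type %in% c("ion", "loss", "ms1_pattern"))
      stop("rule '", r$id, "': evidence type must be ion, loss or ms1_pattern")
    if (ev$type %in% c("ion", "loss") && is.null(ev$formula))
      stop("rule '", r$id, "': ", ev$type, " evidence needs a formula")
    if (ev$type == "loss" && is.null(ev$carbons))
      stop("rule '", r$id, "': loss evidence needs a carbons pair")
    if (ev$type == "ms1_pattern" && is.null(ev$pattern))
      stop("rule '", r$id, "': ms1_pattern evidence needs a pattern")
    if (!is.null(ev$range)) ev$range <- as.numeric(unlist(ev$range))
    if (!is.null(ev$carbons)) ev$carbons <- as.integer(unlist(ev$carbons))
    ev
  })
  r
}

#' Derive per-submodule annotation rules from a pseudo-compound library
#'
#' For every ion-family template that depends on exactly one module slot,
#' one rule per submodule of that slot is generated: observing the family
#' formula predicted for that submodule assigns the submodule. Product-ion
#' families become `ion` evidence; neutral-loss families become `loss`
#' evidence with the template's carbon pair. Templates spanning several
#' slots are skipped (their evidence cannot be attributed to one slot) with
#' a message. The template's `label_range` (falling back to
#' `settings$mz_range` for ions and a wide default for losses) becomes the
#' evidence range.
#'
#' @param lib a `pseudo_library`.
#' @param settings settings list (see [read_rules()]).
#' @return list of validated rules.
#' @export
derive_rules <- function(lib, settings = default_settings()) {
  ms <- lib$module_set
  if (!inherits(ms, "module_set")) ms <- validate_module_set(ms)
  rules <- list()
  for (tp in ms$templates) {
    slots <- unlist(tp$slots)
    if (length(slots) != 1L) {
      message("derive_rules: skipping multi-slot family '", tp$id, "'")
      next
    }
    rng <- if (!is.null(tp$label_range)) as.numeric(unlist(tp$label_range))
      else if (tp$kind == "product_ion") as.numeric(settings$mz_range)
      else c(100, 1200)
    mod <- NULL
    for (m in ms$modules) if (m$id == slots) mod <- m
    for (sm in mod$submodules) {
      ch <- stats::setNames(list(sm$id), slots)
      f <- predict_ion_formula(ms, tp$id, ch)
      if (is.null(f)) next   # family absent for this submodule
      ev <- if (tp$kind == "neutral_loss") {
        list(type = "loss", family = tp$id, formula = formula_string(f),
             carbons = as.integer(unlist(tp$carbons %||% c(0L, 0L))),
             weight = 1, range = rng)
      } else {
        list(type = "ion", family = tp$id, formula = formula_string(f),
             weight = 1, range = rng)
      }
      rules[[length(rules) + 1L]] <- validate_rule(list(
        id = paste0(tp$id, ":", sm$id), slot = slots, submodule = sm$id,
        evidence = list(ev)))
    }
  }
  rules
}

evidence_key <- function(ev) {
  paste(ev$type, ev$family %||% "", ev$formula %||% "", ev$pattern %||% "",
        sep = "|")
}

#' Gather evidence scores for one spectrum
#'
#' Evaluates every distinct evidence item referenced by the rules against
#' the spectrum (and, for MS1 patterns, the feature table). Ion evidence is
#' scored by [label_feature_ions()] (relative intensity), loss evidence by
#' [label_neutral_losses()] (IA x IDF, best-scoring labeled pair),
#' ms1_pattern evidence by the [precursor_pattern()] predicate (score 1 when
#' the pattern holds).
#'
#' @param s a [spectrum].
#' @param rules list of validated rules.
#' @param db a `formula_db` for loss decomposition.
#' @param settings settings list.
#' @param feature_table optional `feature_table` for MS1 pattern evidence.
#' @return named list keyed by [evidence_key()]: each element a list with
#'   `score` and `ppm` (NA when the evidence is absent).
#' @export
gather_evidence <- function(s, rules, db, settings = default_settings(),
                            feature_table = NULL) {
  out <- list()
  for (r in rules) for (ev in r$evidence) {
    key <- evidence_key(ev)
    if (!is.null(out[[key]])) next
    if (ev$type == "ion") {
      rng <- ev$range %||% as.numeric(settings$mz_range)
      lab <- label_feature_ions(s, rng, list(ev$formula),
                                tol_ppm = settings$tol_ppm)
      out[[key]] <- if (nrow(lab))
        list(score = lab$score[1], ppm = lab$ppm[1])
      else list(score = NA_real_, ppm = NA_real_)
    } else if (ev$type == "loss") {
      rng <- ev$range %||% c(100, 1200)
      lab <- label_neutral_losses(s, rng, ev$carbons, list(ev$formula), db,
                                  tol_ppm = settings$tol_ppm)
      out[[key]] <- if (nrow(lab))
        list(score = lab$score[1], ppm = lab$ppm[1])
      else list(score = NA_real_, ppm = NA_real_)
    } else {
      pat <- if (is.null(feature_table)) NA_character_
        else precursor_pattern(feature_table, s$feature_id,
                               rt_tol = settings$rt_tol,
                               tol_ppm = settings$tol_ppm)
      out[[key]] <- if (!is.na(pat) && identical(pat, ev$pattern))
        list(score = 1, ppm = 0)
      else list(score = NA_real_, ppm = NA_real_)
    }
  }
  out
}

#' Convert evidence into ranked candidate module assignments
#'
#' A rule is satisfied when all of its evidence items were observed.
#' Satisfied rules contribute their slot assignment; one candidate is formed
#' for every combination of the (possibly conflicting) submodules assigned
#' per slot, so contradictory evidence yields several ranked candidates
#' rather than a silent drop. The priority score of a candidate is the sum
#' of `w * s` over the distinct evidence items of its supporting rules.
#' Candidates are ordered by score, then more evidence items, then smaller
#' mean |ppm| of the evidence, then a lexicographic key.
#'
#' @param evidence output of [gather_evidence()].
#' @param rules list of validated rules.
#' @param top_n maximum number of candidates returned.
#' @return list of candidates, each a list with `choices` (named list,
#'   possibly covering only some slots), `score`, `n_evidence`, `mean_ppm`,
#'   `rule_ids`.
#' @export
apply_rules <- function(evidence, rules, top_n = 3L) {
  satisfied <- Filter(function(r) {
    all(vapply(r$evidence, function(ev)
      !is.na(evidence[[evidence_key(ev)]]$score), logical(1)))
  }, rules)
  if (!length(satisfied)) return(list())
  slots <- unique(vapply(satisfied, `[[`, character(1), "slot"))
  per_slot <- lapply(slots, function(s)
    unique(vapply(Filter(function(r) r$slot == s, satisfied),
                  `[[`, character(1), "submodule")))
  names(per_slot) <- slots
  grid <- expand.grid(per_slot, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cands <- lapply(seq_len(nrow(grid)), function(i) {
    ch <- as.list(grid[i, , drop = FALSE])
    names(ch) <- slots
    sup <- Filter(function(r) identical(ch[[r$slot]], r$submodule), satisfied)
    items <- list()
    for (r in sup) for (ev in r$evidence) items[[evidence_key(ev)]] <- ev
    sc <- 0; pps <- numeric(0)
    for (key in names(items)) {
      e <- evidence[[key]]
      sc <- sc + items[[key]]$weight * e$score
      pps <- c(pps, abs(e$ppm))
    }
    list(choices = ch, score = sc, n_evidence = length(items),
         mean_ppm = if (length(pps)) mean(pps) else Inf,
         rule_ids = vapply(sup, `[[`, character(1), "id"),
         key = paste(unlist(ch), collapse = "/"))
  })
  ord <- order(-vapply(cands, `[[`, numeric(1), "score"),
               -vapply(cands, `[[`, numeric(1), "n_evidence"),
               vapply(cands, `[[`, numeric(1), "mean_ppm"),
               vapply(cands, `[[`, character(1), "key"))
  utils::head(cands[ord], top_n)
}

#' Retrieve library structures consistent with a candidate module set
#'
#' @param candidate a candidate from [apply_rules()] (or a named choice
#'   list).
#' @param lib a `pseudo_library`.
#' @param formula optional molecular-formula constraint.
#' @return matching rows of `lib$compounds`.
#' @export
lookup_candidates <- function(candidate, lib, formula = NULL) {
  ch <- if (!is.null(candidate$choices)) candidate$choices else candidate
  compounds_matching(lib, choices = ch, formula = formula)
}
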