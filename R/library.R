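#' Read a module-set definition (JSON)
#'
#' A module set divides the target class skeleton into ordered module slots,
#' each offering one or more submodules (structural variants). A submodule
#' carries a SMILES fragment whose shared atoms are labeled with atom maps,
#' plus per-ion-family element shift rows `(dC, dH, dO, dN)` of the
#' mass-shift matrix. Ion-family templates give the initial composition `m0`
#' of each diagnostic product ion or neutral loss and the slots whose shifts
#' apply to it.
#'
#' Expected JSON shape:
#' \preformatted{
#' {"name": "...",
#'  "optional_labels": [23, 24],
#'  "modules": [{"id": "module_I",
#'               "submodules": [{"id": "I1", "label": "...",
#'                               "smiles": "...",
#'                               "deltas": {"core17": [0,0,1,0]}}]}],
#'  "templates": [{"id": "core17", "kind": "product_ion",
#'                 "m0": "C17H17O2", "charge": 1,
#'                 "slots": ["module_I"], "carbons": [20, 17]}]}
#' }
#' A delta may also be the string `"absent"`, meaning the family is not
#' produced by combinations containing that submodule. A missing delta row
#' means no shift. `optional_labels` lists attachment labels that may stay
#' unmatched (hydrogen-capped) when a slot contributes an empty fragment.
#'
#' @param path JSON file path.
#' @return object of class `module_set`.
#' @export
read_module_set <- function(path) {
  if (!file.exists(path)) stop("module-set file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_module_set(raw)
}

#' @rdname read_module_set
#' @param x a list with the module-set structure (as parsed from JSON).
#' @export
validate_module_set <- function(x) {
  if (is.null(x$modules) || !length(x$modules))
    stop("module set has no modules")
  for (m in x$modules) {
    if (is.null(m$id)) stop("module without id")
    if (is.null(m$submodules) || !length(m$submodules))
      stop("module slot '", m$id, "' is empty")
    for (sm in m$submodules) {
      if (is.null(sm$id)) stop("submodule without id in slot '", m$id, "'")
      if (is.null(sm$smiles)) sm$smiles <- ""
    }
  }
  slot_ids <- vapply(x$modules, `[[`, character(1), "id")
  if (anyDuplicated(slot_ids))
    stop("duplicate module slot ids")
  if (is.null(x$templates) || !length(x$templates))
    stop("module set declares no ion-family templates")
  for (tp in x$templates) {
    if (is.null(tp$id) || is.null(tp$kind) || is.null(tp$m0))
      stop("template needs id, kind and m0")
    if (!tp$kind %in% c("product_ion", "neutral_loss", "insource"))
      stop("template '", tp$id, "': unknown kind '", tp$kind, "'")
    bad <- setdiff(unlist(tp$slots), slot_ids)
    if (length(bad))
      stop("template '", tp$id, "' references unknown slot(s): ",
           paste(bad, collapse = ", "))
  }
  structure(x, class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$submodules), integer(1))
  cat(sprintf("<module_set> %s: %d slots (%s), %d ion-family templates\n",
              x$name %||% "(unnamed)", length(x$modules),
              paste(sizes, collapse = "x"), length(x$templates)))
  invisible(x)
}

.get_submodule <- function(ms, slot_id, sub_id) {
  for (m in ms$modules) {
    if (m$id == slot_id) {
      for (sm in m$submodules) if (sm$id == sub_id) return(sm)
      stop("submodule '", sub_id, "' not found in slot '", slot_id, "'")
    }
  }
  stop("slot '", slot_id, "' not found")
}

.get_template <- function(ms, family) {
  for (tp in ms$templates) if (tp$id == family) return(tp)
  stop("ion-family template '", family, "' not found")
}

#' Predict a diagnostic ion/loss formula for a module combination
#'
#' Element-wise sum of the template's initial composition `m0` and the shift
#' rows of the chosen submodules in the slots the template lists:
#' the predicted composition is `m0` plus the sum of per-slot deltas.
#'
#' @param ms a `module_set`.
#' @param family template id.
#' @param choices named character vector or list mapping slot id to
#'   submodule id; must cover every slot the template lists.
#' @return an `element_count` (charged for product ions, neutral for
#'   losses), or `NULL` when a chosen submodule suppresses the family
#'   (delta `"absent"`).
#' @export
predict_ion_formula <- function(ms, family, choices) {
  stopifnot(inherits(ms, "module_set"))
  tp <- .get_template(ms, family)
  f <- parse_formula(tp$m0, charge = as.integer(tp$charge %||% 0))
  for (slot in unlist(tp$slots)) {
    if (is.null(choices[[slot]]))
      stop("template '", family, "' needs a choice for slot '", slot, "'")
    sm <- .get_submodule(ms, slot, choices[[slot]])
    d <- sm$deltas[[family]]
    if (is.null(d)) next
    if (identical(d, "absent")) return(NULL)
    d <- as.integer(unlist(d))
    if (length(d) != 4L)
      stop("delta for family '", family, "' in submodule '", sm$id,
           "' must be length 4 (dC, dH, dO, dN)")
    newc <- f$counts[c("C", "H", "O", "N")] + d
    if (any(newc < 0))
      stop("family '", family, "' with choices {",
           paste(names(choices), unlist(choices), sep = "=", collapse = ", "),
           "} yields negative element count(s)")
    f$counts[c("C", "H", "O", "N")] <- newc
  }
  f
}

#' Assemble labeled fragments for module choices into a canonical structure
#'
#' Collects the chosen submodules' SMILES fragments in slot order and merges
#' them on shared atom-map labels (see [merge_fragments()]). Labels seen
#' only once must be listed in the module set's `optional_labels`, otherwise
#' an error names them.
#'
#' @param ms a `module_set`.
#' @param choices named mapping slot id -> submodule id covering all slots.
#' @return list with `smiles` (canonical), `formula` (Hill string) and
#'   `natoms`.
#' @export
assemble_structure <- function(ms, choices) {
  res <- assemble_structures(ms, list(choices))
  if (!is.na(res$error[1])) stop(res$error[1])
  list(smiles = res$smiles[1], formula = res$formula[1],
       natoms = res$natoms[1])
}

#' Batch version of [assemble_structure()]
#' @param ms a `module_set`.
#' @param choice_list list of named choice mappings.
#' @return data.frame with columns `smiles`, `formula`, `natoms`, `error`.
#' @export
assemble_structures <- function(ms, choice_list) {
  stopifnot(inherits(ms, "module_set"))
  slot_ids <- vapply(ms$modules, `[[`, character(1), "id")
  jobs <- lapply(choice_list, function(ch) {
    missing <- setdiff(slot_ids, names(ch))
    if (length(missing))
      stop("choices missing for slot(s): ", paste(missing, collapse = ", "))
    vapply(slot_ids, function(s)
      .get_submodule(ms, s, ch[[s]])$smiles %||% "", character(1))
  })
  res <- merge_fragments(jobs)
  allowed <- as.character(unlist(ms$optional_labels))
  for (i in seq_len(nrow(res))) {
    if (!is.na(res$error[i])) next
    un <- setdiff(strsplit(res$unmatched[i], ",")[[1]], c("", allowed))
    if (length(un))
      res$error[i] <- paste0("unmatched attachment label(s): ",
                             paste(un, collapse = ", "))
  }
  res
}

#' Enumerate the combinatorial pseudo-compound library
#'
#' Builds every combination of one submodule per slot (the pre-deduplication
#' size is the product of slot sizes), assembles each combination's
#' structure, predicts every ion-family formula, and collapses duplicate
#' canonical structures (first-seen combination wins; the others are kept as
#' provenance).
#'
#' @param ms a `module_set`.
#' @return object of class `pseudo_library`: list with `module_set`,
#'   `compounds` (data.frame: `compound_id`, `smiles`, `formula`, one
#'   `choice_<slot>` column per slot), `ions` (data.frame: `compound_id`,
#'   `family`, `kind`, `formula`, `charge`), `provenance` (named list of
#'   duplicate choice vectors), and `n_combinations` (pre-dedup count).
#' @export
enumerate_library <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  slot_ids <- vapply(ms$modules, `[[`, character(1), "id")
  sub_ids <- lapply(ms$modules, function(m)
    vapply(m$submodules, `[[`, character(1), "id"))
  names(sub_ids) <- slot_ids
  grid <- expand.grid(sub_ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n_comb <- nrow(grid)
  choice_list <- lapply(seq_len(n_comb), function(i)
    as.list(grid[i, , drop = FALSE]))
  asm <- assemble_structures(ms, choice_list)
  bad <- which(!is.na(asm$error))
  if (length(bad))
    stop("assembly failed for combination ", bad[1], " (",
         paste(names(grid), unlist(grid[bad[1], ]), sep = "=", collapse = ", "),
         "): ", asm$error[bad[1]])
  keep <- !duplicated(asm$smiles)
  provenance <- list()
  if (any(!keep)) {
    first_idx <- match(asm$smiles[!keep], asm$smiles)
    for (k in which(!keep)) {
      fid <- sprintf("PC%04d", match(asm$smiles[k], asm$smiles[keep]))
      provenance[[fid]] <- c(provenance[[fid]], list(choice_list[[k]]))
    }
    message("collapsed ", sum(!keep), " duplicate structure(s)")
  }
  kept <- which(keep)
  compounds <- data.frame(compound_id = sprintf("PC%04d", seq_along(kept)),
                          smiles = asm$smiles[kept],
                          formula = asm$formula[kept],
                          stringsAsFactors = FALSE)
  for (s in slot_ids)
    compounds[[paste0("choice_", s)]] <- grid[kept, s]
  ion_rows <- list()
  fam_ids <- vapply(ms$templates, `[[`, character(1), "id")
  for (i in seq_along(kept)) {
    ch <- choice_list[[kept[i]]]
    for (fam in fam_ids) {
      f <- predict_ion_formula(ms, fam, ch)
      if (is.null(f)) next
      tp <- .get_template(ms, fam)
      ion_rows[[length(ion_rows) + 1L]] <- data.frame(
        compound_id = compounds$compound_id[i],
        family = fam, kind = tp$kind,
        formula = formula_string(f), charge = f$charge,
        stringsAsFactors = FALSE)
    }
  }
  ions <- do.call(rbind, ion_rows)
  structure(list(schema_version = "mfsa-library-1",
                 name = ms$name %||% "(unnamed)",
                 module_set = unclass(ms),
                 compounds = compounds,
                 ions = ions,
                 provenance = provenance,
                 n_combinations = n_comb),
            class = "pseudo_library")
}

#' @export
print.pseudo_library <- function(x, ...) {
  cat(sprintf(
    "<pseudo_library> %s: %d compounds (%d combinations), %d predicted ions\n",
    x$name, nrow(x$compounds), x$n_combinations, nrow(x$ions)))
  invisible(x)
}

#' Persist / load a pseudo-compound library (single JSON file)
#'
#' The store is a schema-versioned single-file relational layout (tables:
#' compounds, ions, provenance, plus the generating module set). Loading a
#' file with a different schema version, or a corrupted file, fails cleanly
#' without returning a partial library.
#'
#' @param lib a `pseudo_library`.
#' @param path file path (conventionally `.json`).
#' @return `persist_library` returns `path` invisibly; `load_library`
#'   returns the `pseudo_library`.
#' @export
persist_library <- function(lib, path) {
  stopifnot(inherits(lib, "pseudo_library"))
  jsonlite::write_json(unclass(lib), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname persist_library
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted library file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(raw$schema_version) ||
      !identical(raw$schema_version, "mfsa-library-1"))
    stop("library schema version mismatch: found '",
         raw$schema_version %||% "<none>", "', expected 'mfsa-library-1'")
  ms <- jsonlite::fromJSON(path, simplifyVector = FALSE)$module_set
  lib <- list(schema_version = raw$schema_version,
              name = raw$name,
              module_set = validate_module_set(ms),
              compounds = as.data.frame(raw$compounds,
                                        stringsAsFactors = FALSE),
              ions = as.data.frame(raw$ions, stringsAsFactors = FALSE),
              provenance = raw$provenance %||% list(),
              n_combinations = raw$n_combinations)
  class(lib) <- "pseudo_library"
  lib
}

#' Look up compounds by a predicted diagnostic-ion formula
#'
#' @param lib a `pseudo_library`.
#' @param formula formula string (as stored, e.g. `"C17H17O2"`).
#' @param family optional family id to restrict the match.
#' @return character vector of compound ids.
#' @export
ions_by_formula <- function(lib, formula, family = NULL) {
  sel <- lib$ions$formula == formula
  if (!is.null(family)) sel <- sel & lib$ions$family == family
  unique(lib$ions$compound_id[sel])
}

#' Look up compounds consistent with a (partial) module choice
#'
#' @param lib a `pseudo_library`.
#' @param choices named mapping slot id -> submodule id (or character vector
#'   of allowed submodule ids); slots not named are unconstrained.
#' @param formula optional molecular-formula constraint (Hill string).
#' @return the matching rows of `lib$compounds`.
#' @export
compounds_matching <- function(lib, choices = list(), formula = NULL) {
  df <- lib$compounds
  sel <- rep(TRUE, nrow(df))
  for (slot in names(choices)) {
    col <- paste0("choice_", slot)
    if (!col %in% names(df)) stop("unknown slot: ", slot)
    sel <- sel & df[[col]] %in% unlist(choices[[slot]])
  }
  if (!is.null(formula)) sel <- sel & df$formula == formula
  df[sel, , drop = FALSE]
}
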