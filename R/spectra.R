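#' Construct an MS/MS spectrum object
#'
#' @param feature_id feature identifier (coerced to character).
#' @param precursor_mz precursor m/z (Th).
#' @param peaks data.frame with columns `mz` and `intensity` (and optionally
#'   `norm`); rows are sorted ascending by m/z on construction.
#' @param charge precursor charge (default +1).
#' @param rt retention time in minutes (NA if unknown).
#' @param polarity `"positive"` or `"negative"`.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(feature_id, precursor_mz, peaks,
                     charge = 1L, rt = NA_real_, polarity = "positive") {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks)) {
    if (any(peaks$mz <= 0)) stop("peak m/z must be > 0")
    if (any(peaks$intensity < 0)) stop("peak intensity must be >= 0")
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  if (!"norm" %in% names(peaks)) peaks$norm <- rep(NA_real_, nrow(peaks))
  structure(list(feature_id = as.character(feature_id),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 rt = as.numeric(rt),
                 polarity = match.arg(polarity, c("positive", "negative")),
                 peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> id=%s precursor m/z=%.4f rt=%.3f min, %d peaks\n",
              x$feature_id, x$precursor_mz, x$rt, nrow(x$peaks)))
  invisible(x)
}

#' Read a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, and optionally
#' `CHARGE`, `RTINSECONDS`, `FEATURE_ID` (MZmine) or `SCANS`. Retention time
#' is converted to minutes. A block without `FEATURE_ID` takes its id from
#' `SCANS`. A block with an empty peak list is retained (and reported via a
#' warning) so that joins against the feature table stay complete.
#'
#' @param path path to an MGF file.
#' @param default_polarity polarity assumed when a block does not carry a
#'   signed charge (default positive, charge +1).
#' @return list of [spectrum] objects, named by feature id.
#' @export
read_mgf <- function(path, default_polarity = "positive") {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  hdr <- list()
  mzs <- NULL; ints <- NULL
  block_start <- 0L
  empty_ids <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("malformed MGF: nested BEGIN IONS at line ", i)
      in_block <- TRUE
      hdr <- list(); mzs <- numeric(0); ints <- numeric(0)
      block_start <- i
    } else if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF: END IONS without BEGIN at line ", i)
      in_block <- FALSE
      if (is.null(hdr$PEPMASS))
        stop("malformed MGF: block starting at line ", block_start,
             " has no PEPMASS")
      id <- hdr$FEATURE_ID
      if (is.null(id)) id <- hdr$SCANS
      if (is.null(id)) id <- as.character(length(spectra) + 1L)
      chg <- 1L
      polarity <- default_polarity
      if (!is.null(hdr$CHARGE)) {
        chg_s <- hdr$CHARGE
        polarity <- if (grepl("-", chg_s, fixed = TRUE)) "negative" else "positive"
        chg <- as.integer(gsub("[^0-9]", "", chg_s))
        if (polarity == "negative") chg <- -chg
      } else if (default_polarity == "negative") {
        chg <- -1L
      }
      rt <- if (!is.null(hdr$RTINSECONDS))
        as.numeric(hdr$RTINSECONDS) / 60 else NA_real_
      if (!length(mzs)) empty_ids <- c(empty_ids, id)
      sp <- spectrum(feature_id = id,
                     precursor_mz = as.numeric(strsplit(hdr$PEPMASS, "\\s+")[[1]][1]),
                     peaks = data.frame(mz = mzs, intensity = ints),
                     charge = chg, rt = rt, polarity = polarity)
      spectra[[id]] <- sp
    } else if (in_block) {
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        hdr[[toupper(kv[1])]] <- paste(kv[-1], collapse = "=")
      } else {
        parts <- strsplit(ln, "[ \t]+")[[1]]
        mz <- suppressWarnings(as.numeric(parts[1]))
        it <- suppressWarnings(as.numeric(parts[2]))
        if (is.na(mz) || is.na(it))
          stop("malformed MGF: unparseable peak line ", i, ": '", ln, "'")
        mzs <- c(mzs, mz); ints <- c(ints, it)
      }
    }
    # lines outside blocks (comments, headers) are ignored
  }
  if (in_block)
    stop("malformed MGF: unterminated block starting at line ", block_start)
  if (length(empty_ids))
    warning("MGF blocks with empty peak lists retained for feature id(s): ",
            paste(empty_ids, collapse = ", "))
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: m/z written to 1e-4, intensities to 1e-2.
#' Optional per-spectrum annotation headers (a named character vector in
#' `annotations[[feature_id]]`) are emitted as extra `KEY=value` lines.
#'
#' @param spectra list of [spectrum] objects.
#' @param path output path.
#' @param annotations optional named list of named character vectors.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, annotations = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("FEATURE_ID=%s", sp$feature_id), con)
    writeLines(sprintf("PEPMASS=%.4f", sp$precursor_mz), con)
    chg <- sp$charge
    writeLines(sprintf("CHARGE=%d%s", abs(chg), if (chg < 0) "-" else "+"), con)
    if (!is.na(sp$rt))
      writeLines(sprintf("RTINSECONDS=%.3f", sp$rt * 60), con)
    ann <- annotations[[sp$feature_id]]
    if (!is.null(ann))
      writeLines(sprintf("%s=%s", toupper(names(ann)), ann), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.4f %.2f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an MZmine-style quantification table (CSV)
#'
#' Recognizes MZmine's `row ID` / `row m/z` / `row retention time` headers
#' case-insensitively, as well as the plain `id` / `mz` / `rt` dialect used
#' by the fixture generator. Remaining numeric columns are treated as
#' per-sample peak areas; unknown non-numeric columns are ignored with a
#' message.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame of class `feature_table` with columns `feature_id`,
#'   `mz`, `rt` and one column per sample area.
#' @export
read_quant_csv <- function(path) {
  if (!file.exists(path)) stop("quant CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nms <- tolower(trimws(names(df)))
  find_col <- function(cands) {
    hit <- which(nms %in% cands)
    if (length(hit)) hit[1] else NA_integer_
  }
  id_col <- find_col(c("row id", "id", "feature_id", "row.id"))
  mz_col <- find_col(c("row m/z", "mz", "m/z", "row.m.z"))
  rt_col <- find_col(c("row retention time", "rt", "retention time",
                       "row.retention.time"))
  if (is.na(id_col) || is.na(mz_col) || is.na(rt_col))
    stop("quant CSV must contain id, m/z and retention-time columns; got: ",
         paste(names(df), collapse = ", "))
  ids <- as.character(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature_id(s) in quant CSV: ", paste(dup, collapse = ", "))
  rest <- setdiff(seq_along(df), c(id_col, mz_col, rt_col))
  is_num <- vapply(df[rest], is.numeric, logical(1))
  if (any(!is_num))
    message("ignoring non-numeric column(s): ",
            paste(names(df)[rest[!is_num]], collapse = ", "))
  areas <- df[rest[is_num]]
  if (length(areas) && any(unlist(areas) < 0, na.rm = TRUE))
    stop("peak areas must be >= 0")
  out <- cbind(data.frame(feature_id = ids,
                          mz = as.numeric(df[[mz_col]]),
                          rt = as.numeric(df[[rt_col]]),
                          stringsAsFactors = FALSE),
               areas)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write a feature table as an MZmine-style quant CSV
#' @param ft a `feature_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(ft, path) {
  df <- as.data.frame(ft)
  names(df)[names(df) == "feature_id"] <- "row ID"
  names(df)[names(df) == "mz"] <- "row m/z"
  names(df)[names(df) == "rt"] <- "row retention time"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Max-min normalization of peak intensities within an m/z range
#'
#' Applies `(I - Imin) / (Imax - Imin)` to all peaks with m/z inside the
#' closed interval `[mz_min, mz_max]`, where Imin/Imax are the minimum and
#' maximum raw intensities of the in-range peaks. Peaks outside the range
#' get `NA` in the `norm` column. When all in-range intensities are equal
#' (including a single in-range peak) every in-range peak normalizes to 1,
#' so a lone diagnostic peak stays visible.
#'
#' @param s a [spectrum].
#' @param mz_min,mz_max range bounds (Th), `mz_min < mz_max`.
#' @return the spectrum with `peaks$norm` filled for in-range peaks.
#' @export
normalize_range <- function(s, mz_min, mz_max) {
  stopifnot(inherits(s, "spectrum"))
  if (!(mz_min < mz_max)) stop("mz_min must be < mz_max")
  s$peaks$norm <- rep(NA_real_, nrow(s$peaks))
  sel <- s$peaks$mz >= mz_min & s$peaks$mz <= mz_max
  if (!any(sel)) {
    warning("no peaks in range [", mz_min, ", ", mz_max, "] for feature ",
            s$feature_id)
    return(s)
  }
  ii <- s$peaks$intensity[sel]
  lo <- min(ii); hi <- max(ii)
  s$peaks$norm[sel] <- if (hi > lo) (ii - lo) / (hi - lo) else 1
  s
}
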