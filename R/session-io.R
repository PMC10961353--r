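#' Subject-factor level dictionary
#'
#' Canonical category levels for the subject questionnaire factors. Ordinal
#' factors are listed in increasing order: hair_length from none to long,
#' hair_color ranked by lightness (lightest first, so higher index = darker),
#' hair_density from low to high.
#' @return named list of allowed levels per factor.
#' @export
factorLevels <- function() {
  list(
    sex = c("male", "female"),
    ethnicity = c("white", "east_asian", "south_asian", "hispanic", "black"),
    hair_length = c("none", "short", "medium", "long"),
    hair_color = c("gray", "blond", "red", "light_brown", "dark_brown", "black"),
    hair_density = c("low", "medium", "high")
  )
}

#' Read a subject-factors CSV
#'
#' Expected columns: subject_id, optionally session_number, age, sex,
#' ethnicity, hair_length, hair_color, hair_density, alertness (1-10). Empty
#' cells are kept as missing (never imputed). Categorical values are checked
#' against [factorLevels()]; 0-based ordinal index columns (`*_ord`) are
#' appended for the hair factors.
#'
#' @param path CSV file.
#' @return data.frame of per-subject (or per-session) factors.
#' @export
readFactorsTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopIfNot("subject_id" %in% names(df), "factors CSV must have subject_id")
  lv <- factorLevels()
  for (nm in names(lv)) {
    if (!nm %in% names(df)) next
    v <- df[[nm]]
    v[v == ""] <- NA
    bad <- !is.na(v) & !(v %in% lv[[nm]])
    if (any(bad)) {
      stop(sprintf("unknown %s level(s) %s; allowed: %s", nm,
                   paste(unique(v[bad]), collapse = ", "),
                   paste(lv[[nm]], collapse = ", ")), call. = FALSE)
    }
    df[[nm]] <- v
  }
  for (nm in c("hair_length", "hair_color", "hair_density")) {
    if (nm %in% names(df)) {
      df[[paste0(nm, "_ord")]] <- match(df[[nm]], lv[[nm]]) - 1L
    }
  }
  df
}

#' Hair-severity index
#'
#' Scalar in [0, 1] summarizing how strongly a subject's hair is expected to
#' occlude optode-scalp coupling: a weighted mean of normalized hair length,
#' darkness (lightness rank) and density ordinals. Missing components are
#' dropped with their weight.
#'
#' @param factors data.frame with `hair_length_ord`, `hair_color_ord`,
#'   `hair_density_ord` columns (see [readFactorsTable()]).
#' @param weights length/color/density weights.
#' @return numeric vector of severities.
#' @export
hairSeverity <- function(factors, weights = c(0.4, 0.35, 0.25)) {
  lv <- factorLevels()
  comp <- cbind(
    factors$hair_length_ord / (length(lv$hair_length) - 1),
    factors$hair_color_ord / (length(lv$hair_color) - 1),
    factors$hair_density_ord / (length(lv$hair_density) - 1)
  )
  out <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    ok <- !is.na(comp[i, ])
    out[i] <- if (any(ok)) sum(comp[i, ok] * weights[ok]) / sum(weights[ok]) else NA_real_
  }
  out
}

#' Write / read a session recording
#'
#' Sessions are stored in the package's own versioned container (an RDS file
#' with a documented schema), which round-trips the intensity matrix
#' bit-exactly and marker times losslessly. SNIRF (HDF5) input is recognized
#' by extension but not supported in this build and raises an explicit
#' unsupported-format error.
#'
#' @param session a [NirsSession-class].
#' @param path file path (conventionally `.nirs.rds`).
#' @return `writeSession` returns `path` invisibly; `readSession` returns the
#'   [NirsSession-class].
#' @export
writeSession <- function(session, path) {
  stopIfNot(is(session, "NirsSession"), "session must be a NirsSession")
  payload <- list(
    format = "hdnirs-session", version = 1L,
    fs = session@fs, intensity = session@intensity,
    markers = session@markers, channels = session@channels,
    subject_id = session@subjectId, session_number = session@sessionNumber,
    factors = session@factors, meta = session@meta
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  if (grepl("\\.snirf$", path, ignore.case = TRUE)) {
    stop("unsupported format: SNIRF (HDF5) reading is not available in this ",
         "build; use the package's native session container", call. = FALSE)
  }
  payload <- readRDS(path)
  if (!identical(payload$format, "hdnirs-session")) {
    stop("not an hdnirs session container: ", path, call. = FALSE)
  }
  if (!"wavelength" %in% names(payload$channels)) {
    stop("format error: channel table lacks wavelength metadata", call. = FALSE)
  }
  new("NirsSession",
      intensity = payload$intensity, fs = payload$fs,
      markers = payload$markers, channels = payload$channels,
      subjectId = payload$subject_id, sessionNumber = payload$session_number,
      factors = payload$factors, meta = payload$meta)
}

#' Read a cohort from a manifest
#'
#' The manifest CSV has columns subject_id, session_number, file (paths are
#' resolved relative to the manifest). Per-session subject factors are joined
#' from the factors CSV written alongside the manifest.
#'
#' @param manifestPath manifest CSV (as written by [generateCohort()]).
#' @param factorsPath factors CSV; defaults to `factors.csv` next to the
#'   manifest.
#' @return list of [NirsSession-class] objects.
#' @export
readCohort <- function(manifestPath,
                       factorsPath = file.path(dirname(manifestPath), "factors.csv")) {
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  fac <- if (file.exists(factorsPath)) readFactorsTable(factorsPath) else NULL
  lapply(seq_len(nrow(man)), function(i) {
    s <- readSession(file.path(dirname(manifestPath), man$file[i]))
    if (!is.null(fac)) {
      sel <- fac$subject_id == man$subject_id[i]
      if ("session_number" %in% names(fac)) {
        sel <- sel & fac$session_number == man$session_number[i]
      }
      row <- fac[sel, , drop = FALSE]
      if (nrow(row)) s@factors <- row[1, , drop = FALSE]
    }
    s
  })
}
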