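#' Montage: optode and channel geometry of a high-density fNIRS headset
#'
#' Geometry model of a tiled continuous-wave fNIRS montage in a flat
#' head-surface approximation (mm; x runs left to right, y posterior to
#' anterior, z away from the scalp). Each rigid tile holds 3 dual-wavelength
#' sources and 4 detectors; channels enumerate every source-detector pair at
#' every wavelength.
#'
#' @slot optodes data.frame with columns id, kind ("source"/"detector"),
#'   tile_id, x, y, z.
#' @slot tiles data.frame with columns id, hemisphere ("left"/"right"),
#'   cx, cy, cz (tile center, mm).
#' @slot channels data.frame: one row per wavelength-resolved channel, columns
#'   id, pair_id, source_id, detector_id, source_tile, detector_tile,
#'   wavelength (nm), length (mm), mid_x, mid_y, mid_z, depth_proxy
#'   (length/4, mm), hemisphere ("left"/"right"/"cross"), roi
#'   ("left_motor"/"right_motor"/"none").
#' @slot wavelengths numeric vector of source wavelengths (nm).
#' @slot roiCenters 2 x 3 matrix of left/right motor ROI centers (mm).
#' @slot geometry list recording the geometry configuration used.
#' @export
setClass("Montage", representation(
  optodes = "data.frame",
  tiles = "data.frame",
  channels = "data.frame",
  wavelengths = "numeric",
  roiCenters = "matrix",
  geometry = "list"
))

setValidity("Montage", function(object) {
  msgs <- character(0)
  op <- object@optodes
  if (anyDuplicated(op$id)) msgs <- c(msgs, "duplicate optode ids")
  if (!all(is.finite(c(op$x, op$y, op$z)))) {
    msgs <- c(msgs, "non-finite optode positions")
  }
  ns <- sum(op$kind == "source"); nd <- sum(op$kind == "detector")
  nch <- nrow(object@channels)
  if (nch != ns * nd * length(object@wavelengths)) {
    msgs <- c(msgs, "channel enumeration is not |S| x |D| x |wavelengths|")
  }
  if (any(object@channels$length < 0)) msgs <- c(msgs, "negative channel length")
  for (t in unique(object@tiles$id)) {
    sub <- op[op$tile_id == t, ]
    if (sum(sub$kind == "source") != 3 || sum(sub$kind == "detector") != 4) {
      msgs <- c(msgs, sprintf("tile %d does not hold 3 sources + 4 detectors", t))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' NirsSession: a continuous dual-wavelength fNIRS recording
#'
#' Continuous per-channel intensity at a fixed sampling rate together with
#' event markers, the channel table describing each row of the intensity
#' matrix, and subject/session metadata.
#'
#' @slot intensity numeric matrix [n_channels x n_samples], arbitrary
#'   intensity units; sample k covers time (k-1)/fs seconds.
#' @slot fs sampling rate in Hz.
#' @slot markers data.frame with columns time (s) and label; labels are
#'   "left", "right", "overt_left", "overt_right", "block_start",
#'   "block_end", "baseline_start", "baseline_end".
#' @slot channels channel table (same columns as the Montage channel table).
#' @slot subjectId character scalar.
#' @slot sessionNumber integer 1..3.
#' @slot factors single-row data.frame of subject factors (may have 0 rows).
#' @slot meta free-form list (generator ground truth, processing provenance).
#' @export
setClass("NirsSession", representation(
  intensity = "matrix",
  fs = "numeric",
  markers = "data.frame",
  channels = "data.frame",
  subjectId = "character",
  sessionNumber = "integer",
  factors = "data.frame",
  meta = "list"
))

setValidity("NirsSession", function(object) {
  msgs <- character(0)
  if (nrow(object@intensity) != nrow(object@channels)) {
    msgs <- c(msgs, "intensity rows do not match channel table")
  }
  if (any(object@intensity < 0)) msgs <- c(msgs, "negative intensity")
  if (nrow(object@markers)) {
    span <- ncol(object@intensity) / object@fs
    if (any(object@markers$time < 0 | object@markers$time > span)) {
      msgs <- c(msgs, "marker times outside recording span")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TrialFeatures: per-trial spatio-temporal decoder features
#'
#' @slot x numeric array [n_trials x n_rows x n_time]; rows are channel pairs
#'   (length <= L), HbO block first then HbR block, in channel-table order.
#' @slot labels character vector ("left"/"right") per trial.
#' @slot blocks integer task-block index per trial.
#' @slot rowInfo data.frame describing each feature row (pair_id, chromophore,
#'   mid_x, mid_y, mid_z, length, depth_proxy, hemisphere).
#' @slot time numeric vector of feature time points (s, relative to onset).
#' @slot scaler list with median/mad matrices fitted on training data, or
#'   empty if features are unscaled.
#' @export
setClass("TrialFeatures", representation(
  x = "array",
  labels = "character",
  blocks = "integer",
  rowInfo = "data.frame",
  time = "numeric",
  scaler = "list"
))

setValidity("TrialFeatures", function(object) {
  d <- dim(object@x)
  msgs <- character(0)
  if (length(d) != 3) msgs <- c(msgs, "feature array must be 3-dimensional")
  if (d[1] != length(object@labels)) msgs <- c(msgs, "labels do not match trials")
  if (d[2] != nrow(object@rowInfo)) msgs <- c(msgs, "rowInfo does not match rows")
  if (d[3] != length(object@time)) msgs <- c(msgs, "time does not match columns")
  if (length(object@scaler) && any(!is.finite(object@x))) {
    msgs <- c(msgs, "scaled features contain missing values")
  }
  if (length(msgs)) msgs else TRUE
})

#' DecoderModel: fitted spatio-temporally regularized logistic decoder
#'
#' @slot W weight matrix [n_rows x n_time] in feature-row order.
#' @slot b bias (unpenalized).
#' @slot alpha,beta,gamma regularization strengths (trace norm, spatial
#'   Tikhonov, temporal Tikhonov).
#' @slot operators list(Gs, Dt) of the spatial/temporal difference operators.
#' @slot scaler robust-scaling statistics from the training set.
#' @slot rowInfo feature-row table of the training features.
#' @slot time feature time axis (s).
#' @slot trace numeric vector, objective value per accepted iteration.
#' @slot converged logical.
#' @export
setClass("DecoderModel", representation(
  W = "matrix",
  b = "numeric",
  alpha = "numeric",
  beta = "numeric",
  gamma = "numeric",
  operators = "list",
  scaler = "list",
  rowInfo = "data.frame",
  time = "numeric",
  trace = "numeric",
  converged = "logical"
))

setMethod("show", "Montage", function(object) {
  op <- object@optodes
  cat(sprintf(
    "Montage: %d tiles, %d sources, %d detectors, %d channels (%s nm)\n",
    nrow(object@tiles), sum(op$kind == "source"), sum(op$kind == "detector"),
    nrow(object@channels), paste(object@wavelengths, collapse = "/")
  ))
})

setMethod("show", "NirsSession", function(object) {
  cat(sprintf(
    "NirsSession: subject %s session %d | %d channels x %d samples @ %g Hz | %d markers\n",
    object@subjectId, object@sessionNumber, nrow(object@intensity),
    ncol(object@intensity), object@fs, nrow(object@markers)
  ))
})

setMethod("show", "TrialFeatures", function(object) {
  d <- dim(object@x)
  cat(sprintf(
    "TrialFeatures: %d trials x %d rows x %d time points (%s)\n",
    d[1], d[2], d[3], if (length(object@scaler)) "scaled" else "unscaled"
  ))
})

setMethod("show", "DecoderModel", function(object) {
  cat(sprintf(
    "DecoderModel: %d x %d weights | alpha=%g beta=%g gamma=%g | %d iterations%s\n",
    nrow(object@W), ncol(object@W), object@alpha, object@beta, object@gamma,
    length(object@trace), if (object@converged) "" else " (not converged)"
  ))
})

#' Accessors
#'
#' `channels()` returns the wavelength-resolved channel table; `tiles()` the
#' tile table; `optodes()` the optode table; `markers()`, `intensity()`,
#' `samplingRate()`, `subjectId()`, `sessionNumber()`, `subjectFactors()`
#' access the corresponding `NirsSession` content; `trialLabels()` and
#' `featureArray()` access `TrialFeatures`; `weights()` the decoder weights.
#'
#' @param object a Montage, NirsSession, TrialFeatures or DecoderModel.
#' @return the corresponding slot content.
#' @name accessors
#' @aliases channels tiles optodes markers intensity samplingRate subjectId
#'   sessionNumber subjectFactors trialLabels featureArray decoderWeights
NULL

#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))
#' @rdname accessors
#' @export
setMethod("channels", "Montage", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channels", "NirsSession", function(object) object@channels)

#' @rdname accessors
#' @export
setGeneric("tiles", function(object) standardGeneric("tiles"))
#' @rdname accessors
#' @export
setMethod("tiles", "Montage", function(object) object@tiles)

#' @rdname accessors
#' @export
setGeneric("optodes", function(object) standardGeneric("optodes"))
#' @rdname accessors
#' @export
setMethod("optodes", "Montage", function(object) object@optodes)

#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))
#' @rdname accessors
#' @export
setMethod("markers", "NirsSession", function(object) object@markers)

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setMethod("intensity", "NirsSession", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "NirsSession", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "NirsSession", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("sessionNumber", function(object) standardGeneric("sessionNumber"))
#' @rdname accessors
#' @export
setMethod("sessionNumber", "NirsSession", function(object) object@sessionNumber)

#' @rdname accessors
#' @export
setGeneric("subjectFactors", function(object) standardGeneric("subjectFactors"))
#' @rdname accessors
#' @export
setMethod("subjectFactors", "NirsSession", function(object) object@factors)

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setMethod("trialLabels", "TrialFeatures", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("featureArray", function(object) standardGeneric("featureArray"))
#' @rdname accessors
#' @export
setMethod("featureArray", "TrialFeatures", function(object) object@x)

#' @rdname accessors
#' @export
setGeneric("decoderWeights", function(object) standardGeneric("decoderWeights"))
#' @rdname accessors
#' @export
setMethod("decoderWeights", "DecoderModel", function(object) object@W)
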