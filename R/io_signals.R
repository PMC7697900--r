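#' Construct a TriaxialRecording
#'
#' @param subjectId,recordingId identifiers.
#' @param kind `"fall"` or `"adl"`.
#' @param ax,ay,az numeric per-sample acceleration in g.
#' @param fs sampling frequency in Hz; only 100 Hz streams are accepted (all
#'   windowing constants are defined at 100 Hz; resampling is out of scope).
#' @param rangeG sensor full scale in g.
#' @param impactSample 0-based annotated impact sample (required for falls).
#' @return a validated [TriaxialRecording-class].
#' @export
triaxialRecording <- function(subjectId, recordingId, kind, ax, ay, az,
                              fs = 100, rangeG = 2, impactSample = NA) {
  if (!isTRUE(all.equal(fs, 100)))
    stop("only 100 Hz recordings are supported (got fs = ", fs, ")")
  new("TriaxialRecording",
      subjectId = as.character(subjectId),
      recordingId = as.character(recordingId),
      kind = as.character(kind), fs = as.numeric(fs),
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
      rangeG = as.numeric(rangeG), impactSample = as.integer(impactSample))
}

#' @rdname TriaxialRecording-class
#' @export
setMethod("subjectId", "TriaxialRecording", function(x) x@subjectId)
#' @rdname TriaxialRecording-class
#' @export
setMethod("recordingId", "TriaxialRecording", function(x) x@recordingId)
#' @rdname TriaxialRecording-class
#' @export
setMethod("recordingKind", "TriaxialRecording", function(x) x@kind)
#' @rdname TriaxialRecording-class
#' @export
setMethod("samplingRate", "TriaxialRecording", function(x) x@fs)
#' @rdname TriaxialRecording-class
#' @export
setMethod("nSamples", "TriaxialRecording", function(x) length(x@ax))
#' @rdname TriaxialRecording-class
#' @export
setMethod("impactSample", "TriaxialRecording", function(x) x@impactSample)

#' @rdname TriaxialRecording-class
#' @export
setMethod("axisMatrix", "TriaxialRecording", function(x)
  cbind(ax = x@ax, ay = x@ay, az = x@az))

setMethod("show", "TriaxialRecording", function(object) {
  cat(sprintf(
    "TriaxialRecording '%s' (subject %s, %s): %d samples @ %g Hz (%.1f s), range +/-%g g\n",
    object@recordingId, object@subjectId, object@kind, length(object@ax),
    object@fs, length(object@ax) / object@fs, object@rangeG))
  if (identical(object@kind, "fall"))
    cat(sprintf("  annotated impact sample: %d (t = %.2f s)\n",
                object@impactSample, object@impactSample / object@fs))
})

#' @rdname NormSignal-class
#' @export
setMethod("normValues", "NormSignal", function(x) x@values)
#' @rdname NormSignal-class
#' @export
setMethod("samplingRate", "NormSignal", function(x) x@fs)
#' @rdname NormSignal-class
#' @export
setMethod("recordingId", "NormSignal", function(x) x@recordingId)

setMethod("show", "NormSignal", function(object) {
  cat(sprintf("NormSignal of '%s': %d samples @ %g Hz, range [%.3f, %.3f] g\n",
              object@recordingId, length(object@values), object@fs,
              min(object@values), max(object@values)))
})

#' @rdname clipToRange
#' @export
setMethod("clipToRange", "TriaxialRecording", function(rec, limit = 2) {
  stopifnot(limit > 0)
  if (rec@rangeG <= limit) return(rec)
  rec@ax <- pmin(pmax(rec@ax, -limit), limit)
  rec@ay <- pmin(pmax(rec@ay, -limit), limit)
  rec@az <- pmin(pmax(rec@az, -limit), limit)
  rec@rangeG <- as.numeric(limit)
  validObject(rec)
  rec
})

#' @rdname computeNorm
#' @export
setMethod("computeNorm", "TriaxialRecording", function(rec) {
  # squares are summed in ascending order so the result is bit-identical
  # under any axis permutation or sign flip (IEEE addition is not
  # associative), in addition to being slightly more accurate
  x <- rec@ax^2; y <- rec@ay^2; z <- rec@az^2
  lo <- pmin(x, y); hi <- pmax(x, y)
  mn <- pmin(lo, z); mx <- pmax(hi, z)
  mid <- pmax(lo, pmin(hi, z))
  new("NormSignal", values = sqrt((mn + mid) + mx),
      fs = rec@fs, recordingId = rec@recordingId)
})

sidecarPath <- function(path) sub("\\.csv$", ".json", path)

#' Read a recording from a CSV file with a JSON sidecar
#'
#' The CSV holds the samples (header `ax,ay,az`, one row per sample, units g).
#' The sidecar `<stem>.json` holds the metadata: `subject_id`, `recording_id`,
#' `kind`, `fs`, `range_g` and, for fall recordings, `impact_sample`
#' (0-based). A fall sidecar without an impact sample is an error, as is any
#' non-finite sample.
#'
#' @param path path to the recording CSV.
#' @return a validated [TriaxialRecording-class].
#' @seealso [writeRecording()], [readManifest()]
#' @export
readRecording <- function(path) {
  meta_path <- sidecarPath(path)
  if (!file.exists(path)) stop("recording CSV not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("subject_id", "recording_id", "kind", "fs", "range_g"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "'")
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("ax", "ay", "az") %in% names(df)))
    stop("recording CSV must have columns ax, ay, az")
  if (!is.null(meta$n_samples) && meta$n_samples != nrow(df))
    stop("sidecar n_samples (", meta$n_samples,
         ") does not match CSV rows (", nrow(df), ")")
  is_ <- meta$impact_sample
  if (identical(meta$kind, "fall") && is.null(is_))
    stop("fall recording '", meta$recording_id, "' lacks impact_sample")
  triaxialRecording(meta$subject_id, meta$recording_id, meta$kind,
                    ax = df$ax, ay = df$ay, az = df$az, fs = meta$fs,
                    rangeG = meta$range_g,
                    impactSample = if (is.null(is_)) NA else is_)
}

#' Write a recording as CSV + JSON sidecar
#'
#' @param rec a [TriaxialRecording-class].
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  # 17 significant digits make the CSV round-trip bit-exact for doubles
  df <- data.frame(ax = sprintf("%.17g", rec@ax),
                   ay = sprintf("%.17g", rec@ay),
                   az = sprintf("%.17g", rec@az))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = rec@subjectId, recording_id = rec@recordingId,
               kind = rec@kind, fs = rec@fs, range_g = rec@rangeG,
               n_samples = nSamples(rec))
  if (identical(rec@kind, "fall")) meta$impact_sample <- rec@impactSample
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a JSON file listing a dataset's recording CSVs (paths are
#' relative to the manifest's directory).
#'
#' @param path path to `manifest.json`.
#' @return a list of [TriaxialRecording-class] objects.
#' @seealso [writeDataset()]
#' @export
readManifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  lapply(man$recordings, function(p) readRecording(file.path(base, p)))
}

#' Write a dataset (recordings + manifest) to a directory
#'
#' @param recordings list of [TriaxialRecording-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(recordings, function(r) {
    f <- paste0(r@recordingId, ".csv")
    writeRecording(r, file.path(dir, f))
    f
  }, character(1))
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(recordings = files), man, auto_unbox = TRUE)
  invisible(man)
}
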