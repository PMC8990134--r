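# ---------------------------------------------------------------------------
# Session container and persistence. The on-disk format is a single JSON file
# mirroring a hierarchical layout (neural/data, neural/fs, kinematics/data,
# kinematics/fs, channel_map, meta), with doubles written at 17 significant
# digits so a write -> read round trip reproduces arrays bitwise.
# ---------------------------------------------------------------------------

#' Validate a session container
#'
#' Checks the structural invariants: arrays present, channel map consistent
#' with the neural array, positive sampling rates, and both arrays spanning
#' the same wall-clock duration to within one sample.
#'
#' @param session An `lfp_session` (list with `neural`, `neural_fs`,
#'   `kinematics`, `kin_fs`, `channel_map`, `meta`).
#' @return The session, invisibly; errors name the offending element.
#' @export
validate_session <- function(session) {
  for (el in c("neural", "neural_fs", "kinematics", "kin_fs", "channel_map"))
    if (is.null(session[[el]]))
      stop(sprintf("session is missing required element '%s'", el))
  if (!is.matrix(session$neural) || !is.matrix(session$kinematics))
    stop("neural and kinematics must be channels/joints x samples matrices")
  if (session$neural_fs <= 0 || session$kin_fs <= 0)
    stop("sampling rates must be positive")
  if (nrow(session$channel_map) != nrow(session$neural))
    stop(sprintf("channel_map has %d entries for %d neural channels",
                 nrow(session$channel_map), nrow(session$neural)))
  dur_n <- ncol(session$neural) / session$neural_fs
  dur_k <- ncol(session$kinematics) / session$kin_fs
  if (abs(dur_n - dur_k) > 1 / min(session$neural_fs, session$kin_fs) + 1e-9)
    stop("neural and kinematic arrays span different durations")
  invisible(session)
}

#' Construct a session container from raw arrays
#'
#' @param neural Channels x samples LFP matrix.
#' @param neural_fs Neural sampling rate (Hz).
#' @param kinematics Joints x samples angle matrix (degrees).
#' @param kin_fs Kinematic sampling rate (Hz).
#' @param channel_map Data frame with columns `electrode`, `column`
#'   (`dorsal`/`lateral`), `side` (`left`/`right`).
#' @param meta Metadata list (cadence, seed, notes, ...).
#' @return A validated `lfp_session`.
#' @export
as_session <- function(neural, neural_fs, kinematics, kin_fs,
                       channel_map = default_channel_map(), meta = list()) {
  s <- structure(list(neural = neural, neural_fs = neural_fs,
                      kinematics = kinematics, kin_fs = kin_fs,
                      channel_map = channel_map, meta = meta),
                 class = "lfp_session")
  validate_session(s)
  s
}

# drop S3 classes (e.g. coupling_spec, gait_model) before JSON serialization
strip_classes <- function(x) {
  if (is.object(x) && !is.data.frame(x)) x <- unclass(x)
  if (is.list(x) && !is.data.frame(x)) x[] <- lapply(x, strip_classes)
  x
}

#' Write a session container to disk
#'
#' @param session An `lfp_session`.
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  payload <- list(
    schema = "lfpdecode-session/1",
    neural = list(data = session$neural, fs = session$neural_fs,
                  joints = rownames(session$neural)),
    kinematics = list(data = session$kinematics, fs = session$kin_fs,
                      joints = rownames(session$kinematics)),
    channel_map = session$channel_map,
    meta = strip_classes(session$meta)
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

restore_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Read a session container from disk
#'
#' @param path File written by [write_session()].
#' @return A validated `lfp_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such session file: %s", path))
  raw <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  for (el in c("neural", "kinematics", "channel_map"))
    if (is.null(raw[[el]]))
      stop(sprintf("session file is missing the '%s' group", el))
  for (grp in c("neural", "kinematics")) {
    if (is.null(raw[[grp]]$data) || is.null(raw[[grp]]$fs))
      stop(sprintf("session file group '%s' lacks data/fs", grp))
    if (raw[[grp]]$fs <= 0)
      stop(sprintf("'%s' sampling rate must be positive", grp))
  }
  kin <- restore_matrix(raw$kinematics$data)
  if (!is.null(raw$kinematics$joints) && length(raw$kinematics$joints) == nrow(kin))
    rownames(kin) <- raw$kinematics$joints
  meta <- raw$meta
  if (!is.null(meta$ground_truth)) {
    gt <- meta$ground_truth
    if (!is.null(gt$coupling)) {
      gt$coupling <- coupling_spec(
        n_channels = gt$coupling$n_channels,
        m = restore_matrix(gt$coupling$m),
        psi = restore_matrix(gt$coupling$psi),
        amp = restore_matrix(gt$coupling$amp))
    }
    if (!is.null(gt$band_amp)) gt$band_amp <- restore_matrix(gt$band_amp)
    meta$ground_truth <- gt
  }
  as_session(
    neural = restore_matrix(raw$neural$data),
    neural_fs = as.numeric(raw$neural$fs),
    kinematics = kin,
    kin_fs = as.numeric(raw$kinematics$fs),
    channel_map = as.data.frame(raw$channel_map, stringsAsFactors = FALSE),
    meta = meta
  )
}
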