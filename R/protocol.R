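#' Wire protocol and session logs
#'
#' Every component of a session — simulated trackers, game clients and the
#' coordinator — talks through a small closed vocabulary of messages,
#' serialized one per line as UTF-8 JSON, and through three flat CSV logs
#' per session (gaze, events, behavior). Timestamps are integer
#' milliseconds from a per-session epoch distributed by the server at
#' registration; clients never write wall-clock times.
#'
#' @name protocol
NULL

MSG_TYPES <- c(
  "register", "ack", "gaze", "event", "start_recording", "stop_recording",
  "show_screen", "submit_contribution", "feedback", "barrier_wait",
  "barrier_release", "calibrate", "calibration_outcome", "session_end"
)

EVENT_KINDS <- c(
  "click", "keypress", "screen_shown", "recording_on", "recording_off",
  "barrier_release", "calibration_result"
)

canonical_body <- function(body) {
  if (length(body) == 0L) return(structure(list(), names = character(0)))
  if (is.null(names(body)) || any(!nzchar(names(body))))
    stop("message body must be a fully named list", call. = FALSE)
  lapply(body, function(v) {
    if (is.numeric(v)) as.double(v)
    else if (is.character(v) || is.logical(v)) v
    else stop("unserializable body value of class ", class(v)[1], call. = FALSE)
  })
}

#' Construct a wire message
#'
#' @param msg_type One of the closed message vocabulary (see `MSG_TYPES`).
#' @param sender Sender identifier (participant id or `"server"`).
#' @param t_ms Integer milliseconds since the session epoch.
#' @param body Named list of atomic payload values.
#' @return An object of class `wire_message`.
#' @export
#' @examples
#' m <- wire_message("register", "p01", 0)
#' identical(decode_message(encode_message(m)), m)
wire_message <- function(msg_type, sender, t_ms, body = list()) {
  if (!is.character(msg_type) || length(msg_type) != 1L || !msg_type %in% MSG_TYPES)
    stop("unknown msg_type: ", paste(msg_type, collapse = ","), call. = FALSE)
  if (!is.character(sender) || length(sender) != 1L || is.na(sender))
    stop("`sender` must be a single string", call. = FALSE)
  stop_if_not_scalar_number(t_ms, "t_ms", min = 0)
  structure(
    list(msg_type = msg_type, sender = sender, t_ms = as.integer(t_ms),
         body = canonical_body(body)),
    class = "wire_message"
  )
}

#' Encode a message as one newline-terminated JSON line
#'
#' @param m A `wire_message`.
#' @return A single character string ending in `"\n"`;
#'   `decode_message(encode_message(m))` is identical to `m`.
#' @export
encode_message <- function(m) {
  if (!inherits(m, "wire_message")) stop("`m` must be a wire_message", call. = FALSE)
  paste0(jsonlite::toJSON(unclass(m), auto_unbox = TRUE, digits = NA, null = "null"),
         "\n")
}

#' Decode one wire line back into a message
#'
#' @param raw One complete newline-delimited record (with or without the
#'   trailing newline).
#' @return A `wire_message`.
#' @export
decode_message <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L)
    stop("`raw` must be a single string", call. = FALSE)
  line <- sub("\n$", "", raw)
  parsed <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                     error = function(e) stop("malformed record: ",
                                              conditionMessage(e), call. = FALSE))
  for (f in c("msg_type", "sender", "t_ms")) {
    if (is.null(parsed[[f]]))
      stop("malformed record: missing field `", f, "`", call. = FALSE)
  }
  if (is.null(parsed$body)) parsed$body <- list()
  wire_message(parsed$msg_type, parsed$sender, parsed$t_ms, as.list(parsed$body))
}

#' @export
print.wire_message <- function(x, ...) {
  cat(sprintf("<%s> from %s @ %d ms", x$msg_type, x$sender, x$t_ms))
  if (length(x$body))
    cat("  {", paste(names(x$body), unlist(lapply(x$body, paste, collapse = "|")),
                     sep = "=", collapse = ", "), "}")
  cat("\n")
  invisible(x)
}

GAZE_COLS <- c("participant_id", "t_ms", "x_px", "y_px", "pupil", "valid")
EVENT_COLS <- c("participant_id", "t_ms", "kind", "payload_json")
BEHAVIOR_COLS <- c("pair_id", "game", "round", "participant_id",
                   "contribution", "sum", "average", "payoff")

empty_gaze <- function() {
  data.frame(participant_id = character(0), t_ms = integer(0),
             x_px = numeric(0), y_px = numeric(0), pupil = numeric(0),
             valid = logical(0), stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(participant_id = character(0), t_ms = integer(0),
             kind = character(0), payload_json = character(0),
             stringsAsFactors = FALSE)
}

check_sorted_per_participant <- function(df, what) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- vapply(split(df$t_ms, df$participant_id),
                function(t) is.unsorted(t), logical(1))
  if (any(bad))
    stop(what, " records must be sorted by t_ms within participant (",
         paste(names(bad)[bad], collapse = ", "), ")", call. = FALSE)
  invisible(df)
}

#' Build an event record row
#'
#' @param participant_id Participant the event belongs to.
#' @param t_ms Session time in ms.
#' @param kind One of the closed event vocabulary (see `EVENT_KINDS`).
#' @param payload Named list serialized to the `payload_json` column.
#' @return One-row data frame in event-log layout.
#' @export
event_record <- function(participant_id, t_ms, kind, payload = list()) {
  if (!kind %in% EVENT_KINDS) stop("unknown event kind: ", kind, call. = FALSE)
  stop_if_not_scalar_number(t_ms, "t_ms", min = 0)
  data.frame(
    participant_id = participant_id, t_ms = as.integer(t_ms), kind = kind,
    payload_json = as.character(jsonlite::toJSON(canonical_body(payload),
                                                 auto_unbox = TRUE, digits = NA)),
    stringsAsFactors = FALSE
  )
}

#' Read and write session logs
#'
#' Gaze, event and behavior logs are plain CSV with fixed headers
#' (`participant_id,t_ms,x_px,y_px,pupil,valid`;
#' `participant_id,t_ms,kind,payload_json`;
#' `pair_id,game,round,participant_id,contribution,sum,average,payoff`).
#' Writing validates the column set and that records are time-sorted within
#' participant; `read_*(write_*(x))` returns `x` unchanged.
#'
#' @param df Data frame of records.
#' @param path File path.
#' @return `write_*` returns `path` invisibly; `read_*` returns a data frame.
#' @name session_logs
NULL

write_log_impl <- function(df, path, cols, sorted = TRUE, what = "log") {
  if (!all(cols %in% names(df)))
    stop(what, " is missing columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  df <- df[, cols, drop = FALSE]
  if (sorted) check_sorted_per_participant(df, what)
  data.table::fwrite(df, path)
  invisible(path)
}

read_log_impl <- function(path, classes) {
  if (!file.exists(path)) stop("cannot read log: ", path, call. = FALSE)
  df <- data.table::fread(path, colClasses = classes, data.table = FALSE)
  if (!identical(names(df), names(classes)))
    stop("unexpected header in ", path, call. = FALSE)
  df
}

#' @rdname session_logs
#' @export
write_gaze_log <- function(df, path)
  write_log_impl(df, path, GAZE_COLS, what = "gaze log")

#' @rdname session_logs
#' @export
read_gaze_log <- function(path)
  read_log_impl(path, c(participant_id = "character", t_ms = "integer",
                        x_px = "numeric", y_px = "numeric",
                        pupil = "numeric", valid = "logical"))

#' @rdname session_logs
#' @export
write_event_log <- function(df, path)
  write_log_impl(df, path, EVENT_COLS, what = "event log")

#' @rdname session_logs
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("cannot read log: ", path, call. = FALSE)
  # base read.csv: the payload column embeds CSV-escaped JSON quotes
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       t_ms = "integer", kind = "character",
                                       payload_json = "character"))
  if (!identical(names(df), EVENT_COLS))
    stop("unexpected header in ", path, call. = FALSE)
  df
}

#' @rdname session_logs
#' @export
write_behavior_log <- function(df, path)
  write_log_impl(df, path, BEHAVIOR_COLS, sorted = FALSE, what = "behavior log")

#' @rdname session_logs
#' @export
read_behavior_log <- function(path)
  read_log_impl(path, c(pair_id = "character", game = "integer",
                        round = "integer", participant_id = "character",
                        contribution = "integer", sum = "integer",
                        average = "numeric", payoff = "numeric"))
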