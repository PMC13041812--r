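#' Behavioral event table
#'
#' Holds timestamped annotations: `risk_assessment` point events plus
#' optional `sequence_start`, `center_cross`, `sequence_stop` markers.
#'
#' @param time Event times in seconds (non-decreasing after sorting).
#' @param behavior Labels, each one of `risk_assessment`, `sequence_start`,
#'   `center_cross`, `sequence_stop`.
#' @param source `"manual"` or `"simulated"` per row (recycled).
#' @return data.frame of class `event_table`, sorted by time.
#' @export
event_table <- function(time = numeric(), behavior = character(),
                        source = "manual") {
  ok <- c("risk_assessment", "sequence_start", "center_cross",
          "sequence_stop")
  if (length(time) != length(behavior))
    stop("time and behavior must have equal length")
  if (!all(behavior %in% ok))
    stop("unknown behavior label(s): ",
         paste(setdiff(behavior, ok), collapse = ", "))
  out <- data.frame(time = as.numeric(time),
                    behavior = as.character(behavior),
                    source = rep_len(as.character(source),
                                     length(time)))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Read a BORIS-style annotation CSV
#'
#' Expects columns `Time` (s), `Subject`, `Behavior`, `Status`
#' (`START` / `STOP` / `POINT`). POINT rows whose behavior matches
#' `risk_label` map to `risk_assessment`; START rows of
#' `sequence`/`sequence_start` map to `sequence_start`, STOP rows to
#' `sequence_stop`; `center_cross` POINT rows pass through. Other rows are
#' dropped with a message.
#'
#' @param path CSV path.
#' @param risk_label Behavior label used for risk-assessment point events
#'   (default `"risk_assessment"`).
#' @return An [event_table()] with an `subject` attribute when present.
#' @export
read_boris_csv <- function(path, risk_label = "risk_assessment") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("Time", "Behavior", "Status")
  if (!all(need %in% names(df)))
    stop("BORIS export must contain columns Time, Behavior, Status")
  st <- toupper(df$Status)
  beh <- rep(NA_character_, nrow(df))
  beh[st == "POINT" & df$Behavior == risk_label] <- "risk_assessment"
  beh[st == "POINT" & df$Behavior == "center_cross"] <- "center_cross"
  beh[st == "START" & df$Behavior %in% c("sequence", "sequence_start")] <-
    "sequence_start"
  beh[st == "STOP" & df$Behavior %in% c("sequence", "sequence_stop")] <-
    "sequence_stop"
  keep <- !is.na(beh)
  if (any(!keep))
    message(sprintf("read_boris_csv: dropped %d unrecognized rows", sum(!keep)))
  ev <- event_table(df$Time[keep], beh[keep], source = "manual")
  if ("Subject" %in% names(df))
    attr(ev, "subject") <- unique(df$Subject[keep])
  ev
}

#' Write an event table as a BORIS-style CSV
#' @param events An [event_table()].
#' @param path Output path.
#' @param subject Subject id written to the `Subject` column.
#' @return `path`, invisibly.
#' @export
write_boris_csv <- function(events, path, subject = "subject1") {
  status <- c(risk_assessment = "POINT", center_cross = "POINT",
              sequence_start = "START", sequence_stop = "STOP")[events$behavior]
  behavior <- ifelse(events$behavior %in% c("sequence_start", "sequence_stop"),
                     "sequence", events$behavior)
  utils::write.csv(data.frame(Time = events$time, Subject = subject,
                              Behavior = behavior, Status = unname(status)),
                   path, row.names = FALSE)
  invisible(path)
}
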