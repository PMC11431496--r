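#' @title EDF and NSRR-style XML input/output
#' @name hstarousal-io
#' @description
#' Recordings travel as European Data Format (EDF) files with a sidecar
#' annotation file in the NSRR XML dialect (scored events with a concept
#' name, start seconds and duration seconds, plus 30 s sleep-staging
#' events).  The EDF support implemented here covers the continuous,
#' 16-bit-integer subset of the format that the pipeline needs; annotation
#' files are handled with `xml2`.
NULL

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

fmt_num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Uses 1 s data records and 16-bit sample encoding; per-channel physical
#' scaling is chosen from the data range.  The duration is truncated to
#' whole seconds (EDF data records are integer-duration).
#'
#' @param rec A `recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  chans <- rec$channels
  ns <- length(chans)
  n_rec <- floor(rec$duration_s)
  spr <- vapply(chans, function(tr) {
    s <- tr$rate_hz
    if (abs(s - round(s)) > 1e-9) {
      stop("write_edf requires integer samples per 1 s record")
    }
    as.integer(round(s))
  }, integer(1))

  pmin_ <- pmax_ <- numeric(ns)
  digmin <- -32768L; digmax <- 32767L
  digital <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- chans[[i]]$samples[seq_len(n_rec * spr[i])]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-9) { lo <- lo - 1; hi <- hi + 1 }
    # widen slightly so rounding never exceeds digital bounds, then snap to
    # the precision the 8-character header field can carry so that encoding
    # and decoding use identical scale factors
    span <- hi - lo
    lo <- lo - 1e-3 * span; hi <- hi + 1e-3 * span
    lo <- as.numeric(trimws(fmt_num_field(lo, 8)))
    hi <- as.numeric(trimws(fmt_num_field(hi, 8)))
    pmin_[i] <- lo; pmax_[i] <- hi
    digital[[i]] <- pmin.int(pmax.int(as.integer(round(
      (x - lo) / (hi - lo) * (digmax - digmin) + digmin)), digmin), digmax)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field(rec$record_id, 80),
    pad_field("Startdate 01-JAN-2000", 80),
    "01.01.00", "00.00.00",
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  ), con, eos = NULL)
  field <- function(get, width) {
    writeChar(paste0(vapply(seq_len(ns), get, character(1)), collapse = ""),
              con, eos = NULL)
  }
  field(function(i) pad_field(names(chans)[i], 16), 16)
  field(function(i) pad_field("synthetic", 80), 80)
  field(function(i) pad_field(if (names(chans)[i] == "DHR") "bpm" else "au", 8), 8)
  field(function(i) fmt_num_field(pmin_[i], 8), 8)
  field(function(i) fmt_num_field(pmax_[i], 8), 8)
  field(function(i) pad_field(digmin, 8), 8)
  field(function(i) pad_field(digmax, 8), 8)
  field(function(i) pad_field("", 80), 80)
  field(function(i) pad_field(spr[i], 8), 8)
  field(function(i) pad_field("", 32), 32)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(digital[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with 16-bit samples (the subset [write_edf()]
#' produces and polysomnography exports commonly use).
#'
#' @param path Path to an EDF file.
#' @return A `recording`.  Channel kinds are inferred from channel names
#'   (`WS`/`Pos_chg` binary, `Pos` categorical, others continuous).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) readChar(con, nchars, useBytes = TRUE)
  rd(8)                                   # version
  record_id <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)           # reserved

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2L,
                               signed = TRUE, endian = "little")
    }
  }
  channels <- list()
  for (i in seq_len(ns)) {
    dig <- unlist(raw[[i]])
    phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
      pmin_[i]
    nm <- labels[i]
    kind <- if (nm %in% BINARY_CHANNELS) "binary"
      else if (nm %in% CATEGORICAL_CHANNELS) "categorical"
      else "continuous"
    if (kind != "continuous") phys <- round(phys)
    channels[[nm]] <- signal_trace(phys, spr[i] / rec_dur, nm, kind)
  }
  recording(record_id, channels, n_rec * rec_dur)
}

stage_concepts <- c(
  W = "Wake|0", N1 = "Stage 1 sleep|1", N2 = "Stage 2 sleep|2",
  N3 = "Stage 3 sleep|3", R = "REM sleep|5"
)

#' Write arousal events and a hypnogram to an NSRR-style XML file
#'
#' Produces a `PSGAnnotation` document with one `ScoredEvent` per arousal
#' (`EventType` `Arousals|Arousals`, start and duration in seconds) and one
#' per 30 s staging epoch (`EventType` `Stages|Stages`).
#'
#' @param events An `event_list` of arousals.
#' @param hyp A `hypnogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nsrr_xml <- function(events, hyp, path) {
  doc <- xml2::xml_new_root("PSGAnnotation")
  xml2::xml_add_child(doc, "SoftwareVersion", "hstarousal")
  xml2::xml_add_child(doc, "EpochLength", "30")
  se <- xml2::xml_add_child(doc, "ScoredEvents")
  add_event <- function(type, concept, start, duration) {
    ev <- xml2::xml_add_child(se, "ScoredEvent")
    xml2::xml_add_child(ev, "EventType", type)
    xml2::xml_add_child(ev, "EventConcept", concept)
    xml2::xml_add_child(ev, "Start", format(start, digits = 12))
    xml2::xml_add_child(ev, "Duration", format(duration, digits = 12))
  }
  for (i in seq_len(nrow(events))) {
    add_event("Arousals|Arousals", "Arousal|Arousal ()",
              events$onset[i], events$offset[i] - events$onset[i])
  }
  for (i in seq_along(hyp$stages)) {
    add_event("Stages|Stages", stage_concepts[[hyp$stages[i]]],
              (i - 1) * 30, 30)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read arousal events and a hypnogram from an NSRR-style XML file
#'
#' @param path Path to an annotation XML file as written by
#'   [write_nsrr_xml()] (or the matching NSRR dialect).
#' @return A list with `events` (`event_list`) and `hypnogram`.
#' @export
read_nsrr_xml <- function(path) {
  doc <- xml2::read_xml(path)
  evs <- xml2::xml_find_all(doc, ".//ScoredEvent")
  type <- xml2::xml_text(xml2::xml_find_first(evs, "./EventType"))
  concept <- xml2::xml_text(xml2::xml_find_first(evs, "./EventConcept"))
  start <- as.numeric(xml2::xml_text(xml2::xml_find_first(evs, "./Start")))
  duration <- as.numeric(xml2::xml_text(xml2::xml_find_first(evs, "./Duration")))

  is_arousal <- grepl("^Arousal", type) | grepl("^Arousal", concept)
  o <- order(start[is_arousal])
  events <- event_list(start[is_arousal][o],
                       (start[is_arousal] + duration[is_arousal])[o])

  is_stage <- grepl("^Stages", type)
  stage_start <- start[is_stage]
  stage_concept <- concept[is_stage]
  code_of <- stats::setNames(names(stage_concepts), unname(stage_concepts))
  o <- order(stage_start)
  stages <- unname(code_of[stage_concept[o]])
  if (anyNA(stages)) stop("unknown stage concept in annotation file")
  list(events = events, hypnogram = hypnogram(stages))
}
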