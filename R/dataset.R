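#' Read a pharmacokinetic event dataset
#'
#' Reads the package's CSV event format: one row per event with columns
#' `id, time, evid, amt, dur, obs`. `evid = 1` marks a dose row (`amt` in
#' mg, `dur` in h, `obs` empty) and `evid = 0` an observation row (`obs`
#' in mg/L, `amt`/`dur` empty). Rows must be grouped by subject and sorted
#' by time within subject.
#'
#' @param path Path to the CSV file.
#' @return A list of [subject_record()] objects, one per subject, in
#'   order of first appearance.
#' @export
read_pk_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  required <- c("id", "time", "evid", "amt", "dur", "obs")
  if (!all(required %in% names(df)))
    stop("dataset must have columns: ", paste(required, collapse = ", "))
  if (!all(df$evid %in% c(0L, 1L)))
    stop("evid must be 0 (observation) or 1 (dose)")
  ids <- unique(df$id)
  lapply(ids, function(sid) {
    rows <- df[df$id == sid, , drop = FALSE]
    if (is.unsorted(rows$time))
      stop("events for subject ", sid, " are not sorted by time")
    doses <- list(); obs <- list()
    for (r in seq_len(nrow(rows))) {
      if (rows$evid[r] == 1L) {
        doses[[length(doses) + 1L]] <-
          dose_event(rows$time[r], rows$amt[r],
                     if (is.na(rows$dur[r])) 0 else rows$dur[r])
      } else {
        obs[[length(obs) + 1L]] <- observation(rows$time[r], rows$obs[r])
      }
    }
    subject_record(sid, doses, obs)
  })
}

subjects_to_frame <- function(subjects) {
  rows <- lapply(subjects, function(s) {
    d <- do.call(rbind, lapply(s$doses, function(x)
      data.frame(id = s$subject_id, time = x$start_time, evid = 1L,
                 amt = x$amount, dur = x$duration, obs = NA_real_)))
    o <- do.call(rbind, lapply(s$observations, function(x)
      data.frame(id = s$subject_id, time = x$time, evid = 0L,
                 amt = NA_real_, dur = NA_real_, obs = x$value)))
    out <- rbind(d, o)
    out[order(out$time, -out$evid), , drop = FALSE]
  })
  do.call(rbind, rows)
}

#' Write a pharmacokinetic event dataset
#'
#' Inverse of [read_pk_dataset()]: serializes subject records to the CSV
#' event format. Writing then reading yields an identical list of
#' subjects, and re-writing reproduces the file byte for byte.
#'
#' @param subjects List of [subject_record()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(subjects, path) {
  df <- subjects_to_frame(subjects)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  lines <- c("id,time,evid,amt,dur,obs",
             sprintf("%s,%s,%d,%s,%s,%s", df$id, fmt(df$time), df$evid,
                     fmt(df$amt), fmt(df$dur), fmt(df$obs)))
  writeLines(lines, path)
  invisible(path)
}
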