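# Event-record dataset reading/writing and validation. The on-disk format
# is a NONMEM-compatible CSV: ID, TIME, TAD, AMT, DV, EVID, MDV, SS, II,
# BLQ plus covariate columns (upper-case on disk, lower-case in R).

DATASET_CORE <- c("id", "time", "tad", "amt", "dv", "evid", "mdv", "ss",
                  "ii", "blq")

#' Write an event-record dataset to CSV
#'
#' @param data dataset from [simulate_pk_dataset()] (or the same shape).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  out <- data
  names(out) <- toupper(names(out))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}

#' Read and validate an event-record dataset
#'
#' Checks the schema (ID/TIME/DV/AMT/EVID/MDV at minimum), per-subject time
#' ordering, and that every observation is preceded by a dosing record.
#' Quantification flags are recomputed from `lloq` when given.
#'
#' @param path CSV file written by [write_pk_dataset()] or equivalent.
#' @param lloq optional quantification limit (ug/mL) used to (re)derive the
#'   `blq` column from DV on observation rows.
#' @return validated data.frame with lower-case column names.
#' @export
read_pk_dataset <- function(path, lloq = NULL) {
  raw <- utils::read.csv(path, na.strings = c("NA", "."))
  names(raw) <- tolower(names(raw))
  need <- c("id", "time", "dv", "amt", "evid", "mdv")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"tad" %in% names(raw)) raw$tad <- raw$time
  if (!"blq" %in% names(raw)) raw$blq <- 0L
  for (id in unique(raw$id)) {
    b <- raw[raw$id == id, ]
    if (is.unsorted(b$time))
      stop("times are not non-decreasing within subject ", id)
    obs_t <- b$time[b$evid == 0]
    dose_t <- b$time[b$evid == 1]
    if (length(obs_t) && (!length(dose_t) || min(obs_t) < min(dose_t)))
      stop("subject ", id, " has an observation before any dose")
  }
  if (!is.null(lloq)) {
    o <- raw$evid == 0
    raw$blq[o] <- as.integer(!is.na(raw$dv[o]) & raw$dv[o] < lloq)
    raw$mdv[o] <- pmax(raw$mdv[o], raw$blq[o])
  }
  raw
}
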