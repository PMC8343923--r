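## Event-record dataset I/O (NONMEM-style conventions): one row per dose or
## observation event. Columns:
##   ID       subject identifier
##   TIME     h since the subject's first dose
##   EVID     1 = dose, 0 = observation
##   AMT      dose amount, mg (dose rows only)
##   DUR      infusion duration, h (dose rows only)
##   DV       observed concentration, mg/L (observation rows only)
##   OBSCLASS "peak" | "trough" (observation rows; NA on dose rows)
##   WT, AGE, SEX, SCR   covariates (kg, months, 0/1 male, mg/dL)

DATASET_COLUMNS <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "OBSCLASS",
                     "WT", "AGE", "SEX", "SCR")

#' Validate an event-record dataset
#'
#' Checks the dataset contract: required columns, non-negative and
#' within-subject non-decreasing times, dose rows with `AMT > 0`, `DUR > 0`
#' and no `DV`, observation rows with `DV >= 0` and no `AMT`, and at least
#' one observation per subject. All violations are collected and reported
#' together with their row numbers.
#'
#' @param data A data.frame in event-record form.
#' @return The dataset, invisibly, with class `event_record` attached.
#' @export
validate_dataset <- function(data) {
  missing_cols <- setdiff(DATASET_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop_validation("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  probs <- character(0)
  bad <- function(rows, msg) {
    if (length(rows)) {
      probs <<- c(probs, paste0("rows ", paste(rows, collapse = ","), ": ", msg))
    }
  }
  rn <- seq_len(nrow(data))
  bad(rn[!data$EVID %in% c(0, 1)], "EVID must be 0 (observation) or 1 (dose)")
  bad(rn[!is.finite(data$TIME) | data$TIME < 0], "TIME must be finite and >= 0")
  dose <- data$EVID == 1
  obs <- data$EVID == 0
  bad(rn[dose & (!is.finite(data$AMT) | data$AMT <= 0)], "dose rows need AMT > 0")
  bad(rn[dose & (!is.finite(data$DUR) | data$DUR <= 0)], "dose rows need DUR > 0")
  bad(rn[dose & !is.na(data$DV)], "dose rows must not carry DV")
  bad(rn[obs & !is.na(data$AMT)], "observation rows must not carry AMT")
  bad(rn[obs & (!is.finite(data$DV) | data$DV < 0)], "observation rows need DV >= 0")
  bad(rn[obs & !(data$OBSCLASS %in% c("peak", "trough"))],
      "observation rows need OBSCLASS 'peak' or 'trough'")
  for (id in unique(data$ID)) {
    rows <- which(data$ID == id)
    if (is.unsorted(data$TIME[rows])) {
      bad(rows[1], paste0("subject ", id, ": TIME not non-decreasing"))
    }
    if (!any(data$EVID[rows] == 0)) {
      bad(rows[1], paste0("subject ", id, ": no observation rows"))
    }
  }
  if (length(probs)) {
    stop_validation("invalid event-record dataset:\n  ", paste(probs, collapse = "\n  "))
  }
  if (!inherits(data, "event_record")) class(data) <- c("event_record", class(data))
  invisible(data)
}

#' Read an event-record dataset from CSV
#'
#' Comma-separated, '.' decimal, UTF-8, header required; column order in the
#' file is irrelevant. The dataset is validated on read (see
#' [validate_dataset]); violations are reported with row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated `event_record` data.frame in canonical column order.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop_validation("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, DATASET_COLUMNS]
  raw$ID <- as.character(raw$ID)
  for (col in c("TIME", "AMT", "DUR", "DV", "WT", "AGE", "SEX", "SCR")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  raw$OBSCLASS <- as.character(raw$OBSCLASS)
  raw$OBSCLASS[raw$OBSCLASS == ""] <- NA_character_
  validate_dataset(raw)
  class(raw) <- c("event_record", "data.frame")
  raw
}

#' Write an event-record dataset to CSV
#'
#' Deterministic canonical form: fixed column order, `%.15g` float
#' formatting, empty string for missing values. Re-serializing a file read
#' with [read_dataset] is byte-identical.
#'
#' @param data A validated event-record dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  if (nrow(data) > 0) validate_dataset(data)
  out <- data.frame(ID = as.character(data$ID), stringsAsFactors = FALSE)
  for (col in c("TIME", "EVID", "AMT", "DUR", "DV")) out[[col]] <- fmt_num(data[[col]])
  out$OBSCLASS <- ifelse(is.na(data$OBSCLASS), "", data$OBSCLASS)
  for (col in c("WT", "AGE", "SEX", "SCR")) out[[col]] <- fmt_num(data[[col]])
  if (nrow(data) == 0) out <- out[0, , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(DATASET_COLUMNS, collapse = ","), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out[DATASET_COLUMNS])), sep = ","))
    writeLines(lines, con)
  }
  invisible(path)
}
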