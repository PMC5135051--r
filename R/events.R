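## Event-table input and validation.
##
## One row per observed interaction event: the same plant-ant pair seen
## feeding in a different encounter counts as a new event, so interaction
## frequency is the row count for that pair.

EVENT_COLUMNS <- c("site_id", "plot_id", "season", "plant_sp", "ant_sp",
                   "resource", "workers")

#' Read an interaction-event table from CSV
#'
#' Expects a header with the seven columns `site_id, plot_id, season,
#' plant_sp, ant_sp, resource, workers`. Each row is one observed
#' interaction event; `workers` is the number of recruited workers seen at
#' the resource (metadata; it never enters the count matrices).
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame` of events (possibly zero rows).
#' @seealso [validate_events()], [build_layer()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("event file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_events(df)
}

#' Validate an event table
#'
#' Checks the seven-column schema, the closed resource vocabulary
#' (see [resource_types()]), and that worker counts are non-negative
#' integers. Rows are returned unchanged on success.
#'
#' @param events A data.frame of interaction events.
#' @return The validated data.frame.
#' @export
validate_events <- function(events) {
  if (!is.data.frame(events)) stop_schema("events must be a data.frame")
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing)) {
    stop_schema(paste0("event table is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  events <- events[, EVENT_COLUMNS, drop = FALSE]
  if (nrow(events) == 0L) return(events)
  bad_res <- !(events$resource %in% resource_types())
  if (any(bad_res)) {
    stop_schema(paste0(
      "unknown resource label(s): ",
      paste(unique(events$resource[bad_res]), collapse = ", "),
      " (allowed: ", paste(resource_types(), collapse = ", "), ")"
    ))
  }
  w <- events$workers
  if (any(is.na(w)) || any(w < 0) || any(w != floor(w))) {
    bad <- which(is.na(w) | w < 0 | w != floor(w))[1L]
    stop_validation(paste0("workers must be a non-negative integer; row ",
                           bad, " has workers = ", w[bad]))
  }
  events
}

#' Write an event table to CSV
#'
#' @param events Validated event data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
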