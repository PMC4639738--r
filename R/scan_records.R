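#' Scan record sets
#'
#' A `scan_record_set` holds every scan of one group over one observation
#' period. Internally events are kept in a tidy table with one row per
#' event: `scan` (1-based index), `behaviour` (`"proximity"` or
#' `"grooming"`), `actor`, `recipient`. Proximity is a symmetric dyadic
#' state ("within an arm's reach"), so proximity rows are stored with the
#' lexicographically smaller id as `actor` and deduplicated; grooming events
#' are ordered groomer -> groomee and deduplicated within a scan.
#'
#' @param group_id,period_id identifiers of the group and observation period.
#' @param n_scans total number of scans conducted (including scans in which
#'   no event was recorded); must be at least the largest scan index.
#' @param events data frame with columns `scan`, `behaviour`, `actor`,
#'   `recipient`.
#' @param normalize orient/deduplicate rows (default). Set to `FALSE` only
#'   to construct deliberately invalid sets for [validate_records()].
#' @return An object of class `scan_record_set`.
#' @export
scan_record_set <- function(group_id, period_id, n_scans, events,
                            normalize = TRUE) {
  events <- tibble::as_tibble(events)
  needed <- c("scan", "behaviour", "actor", "recipient")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    stop("scan record format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  events <- events[needed]
  events$scan <- as.integer(events$scan)
  events$behaviour <- as.character(events$behaviour)
  events$actor <- as.character(events$actor)
  events$recipient <- as.character(events$recipient)
  bad <- setdiff(unique(events$behaviour), c("proximity", "grooming"))
  if (length(bad) > 0) {
    stop("scan record format error: unknown behaviour label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_scans <- as.integer(n_scans)
  if (is.na(n_scans) || n_scans < 1) {
    stop("scan record validation error: n_scans must be a positive integer",
         call. = FALSE)
  }
  if (nrow(events) > 0 && max(events$scan) > n_scans) {
    stop("scan record validation error: scan index exceeds n_scans",
         call. = FALSE)
  }
  if (normalize) {
    self <- events$actor == events$recipient
    if (any(self)) {
      stop("scan record validation error: self-pair for id ",
           events$actor[which(self)[1]], call. = FALSE)
    }
    prox <- events$behaviour == "proximity"
    a <- pmin(events$actor[prox], events$recipient[prox])
    b <- pmax(events$actor[prox], events$recipient[prox])
    events$actor[prox] <- a
    events$recipient[prox] <- b
    events <- dplyr::distinct(events)
    events <- dplyr::arrange(events, .data$scan, .data$behaviour,
                             .data$actor, .data$recipient)
  }
  structure(
    list(group_id = as.character(group_id),
         period_id = as.character(period_id),
         n_scans = n_scans,
         events = events),
    class = "scan_record_set"
  )
}

#' @export
print.scan_record_set <- function(x, ...) {
  counts <- table(factor(x$events$behaviour,
                         levels = c("proximity", "grooming")))
  cat(sprintf(
    "<scan_record_set> group %s, period %s: %d scans, %d proximity pairs, %d grooming events\n",
    x$group_id, x$period_id, x$n_scans,
    counts[["proximity"]], counts[["grooming"]]))
  invisible(x)
}

scan_table_columns <- function() {
  c("group", "period", "scan", "behaviour", "actor", "recipient")
}

#' Read scan-sampling tables
#'
#' The long (tidy) input format has one row per recorded event and columns
#' `group, period, scan, behaviour, actor, recipient`, with `behaviour` one
#' of `proximity`, `grooming` or `none` (a placeholder marking a scan with
#' no recorded events, so that the scan still counts in the denominator).
#' Proximity rows may be given in either orientation; duplicates within a
#' scan are collapsed. Every id must appear in `roster` under the stated
#' group.
#'
#' @param path CSV file path.
#' @param roster the study [roster()].
#' @return A named list of [scan_record_set()] objects, one per
#'   group-period, named `"<group>:<period>"`.
#' @export
read_scan_table <- function(path, roster) {
  stopifnot(inherits(roster, "roster"))
  if (!file.exists(path)) {
    stop("scan table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(scan_table_columns(), names(df))
  if (length(missing) > 0) {
    stop("scan table format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[scan_table_columns()])
  df$scan <- as.integer(df$scan)
  is_event <- df$behaviour != "none"
  ev <- df[is_event, ]
  self <- ev$actor == ev$recipient
  if (any(self)) {
    stop("scan table validation error: actor equals recipient (row ",
         which(is_event)[which(self)[1]], ")", call. = FALSE)
  }
  for (col in c("actor", "recipient")) {
    member_of <- roster$group_id[match(ev[[col]], roster$id)]
    bad <- is.na(member_of) | member_of != ev$group
    if (any(bad)) {
      i <- which(bad)[1]
      stop("scan table validation error: id \"", ev[[col]][i],
           "\" not in roster for group ", ev$group[i],
           " (row ", which(is_event)[i], ")", call. = FALSE)
    }
  }
  keys <- unique(df[c("group", "period")])
  out <- vector("list", nrow(keys))
  names(out) <- paste(keys$group, keys$period, sep = ":")
  for (i in seq_len(nrow(keys))) {
    sel <- df$group == keys$group[i] & df$period == keys$period[i]
    sub <- df[sel & df$behaviour != "none", ]
    out[[i]] <- scan_record_set(
      group_id = keys$group[i], period_id = keys$period[i],
      n_scans = max(df$scan[sel]),
      events = sub[c("scan", "behaviour", "actor", "recipient")]
    )
  }
  out
}

#' Write scan record sets to the long CSV dialect
#'
#' Inverse of [read_scan_table()]: scans with no events are written as a
#' single `none` placeholder row so that the scan count round-trips.
#'
#' @param records a [scan_record_set()] or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(records, path) {
  if (inherits(records, "scan_record_set")) records <- list(records)
  rows <- lapply(records, function(r) {
    ev <- r$events
    used <- unique(ev$scan)
    empty <- setdiff(seq_len(r$n_scans), used)
    filler <- tibble::tibble(scan = as.integer(empty), behaviour = "none",
                             actor = "", recipient = "")
    out <- dplyr::bind_rows(ev, filler)
    out$group <- r$group_id
    out$period <- r$period_id
    dplyr::arrange(out[scan_table_columns()], .data$scan)
  })
  utils::write.csv(as.data.frame(dplyr::bind_rows(rows)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate scan records against a roster
#'
#' Report-only companion to the strict reader: checks every
#' `scan_record_set` invariant and returns a tally instead of raising.
#' Violation kinds: `self_pair`, `unknown_id`, `duplicate_event`,
#' `scan_index_out_of_range`, `bad_behaviour`.
#'
#' @param records a [scan_record_set()] (possibly built with
#'   `normalize = FALSE`).
#' @param roster the study [roster()].
#' @return A `validation_report`: list with `n_scans`, `n_proximity_events`,
#'   `n_grooming_events`, `n_violations` and a `violations` tibble
#'   (`kind`, `scan`, `detail`).
#' @export
validate_records <- function(records, roster) {
  stopifnot(inherits(records, "scan_record_set"), inherits(roster, "roster"))
  ev <- records$events
  v <- list()
  add <- function(kind, scan, detail) {
    tibble::tibble(kind = kind, scan = as.integer(scan), detail = detail)
  }
  bad_beh <- !ev$behaviour %in% c("proximity", "grooming")
  if (any(bad_beh)) {
    v <- c(v, list(add("bad_behaviour", ev$scan[bad_beh], ev$behaviour[bad_beh])))
  }
  self <- ev$actor == ev$recipient
  if (any(self)) {
    v <- c(v, list(add("self_pair", ev$scan[self], ev$actor[self])))
  }
  members <- roster$id[roster$group_id == records$group_id]
  for (col in c("actor", "recipient")) {
    bad <- !ev[[col]] %in% members
    if (any(bad)) {
      v <- c(v, list(add("unknown_id", ev$scan[bad], ev[[col]][bad])))
    }
  }
  norm <- ev
  prox <- norm$behaviour == "proximity"
  a <- pmin(norm$actor[prox], norm$recipient[prox])
  b <- pmax(norm$actor[prox], norm$recipient[prox])
  norm$actor[prox] <- a
  norm$recipient[prox] <- b
  dup <- duplicated(norm)
  if (any(dup)) {
    v <- c(v, list(add("duplicate_event", ev$scan[dup],
                       paste(ev$actor[dup], ev$recipient[dup], sep = "-"))))
  }
  oob <- ev$scan < 1 | ev$scan > records$n_scans
  if (any(oob)) {
    v <- c(v, list(add("scan_index_out_of_range", ev$scan[oob], "")))
  }
  violations <- if (length(v) > 0) dplyr::bind_rows(v) else
    tibble::tibble(kind = character(), scan = integer(), detail = character())
  structure(
    list(group_id = records$group_id, period_id = records$period_id,
         n_scans = records$n_scans,
         n_proximity_events = sum(ev$behaviour == "proximity"),
         n_grooming_events = sum(ev$behaviour == "grooming"),
         n_violations = nrow(violations),
         violations = violations),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> group %s, period %s: %d scans, %d proximity, %d grooming, %d violation(s)\n",
    x$group_id, x$period_id, x$n_scans, x$n_proximity_events,
    x$n_grooming_events, x$n_violations))
  if (x$n_violations > 0) print(x$violations, n = 10)
  invisible(x)
}
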