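#' Weighted scan-sampling networks
#'
#' A `scan_network` stores the vertex set (all roster members of the group,
#' including isolates), the integer matrix of scan counts per directed or
#' undirected dyad, and the number of scans. Edge weights are expressed in
#' percent-of-scans units, \eqn{w_{ij} = 100\,c_{ij}/n_{scans}}, so
#' \eqn{0 \le w_{ij} \le 100} and \eqn{w_{ij} n_{scans}/100} is always an
#' integer count. Measures are computed from the exact counts and divided
#' late, which keeps identities such as the equal-distribution disparity
#' \eqn{1/(N-1)} exact.
#'
#' @param ids ordered vertex ids.
#' @param counts integer matrix of scan counts (symmetric if undirected).
#' @param n_scans positive scan count (the weight denominator).
#' @param directed logical.
#' @param behaviour `"proximity"` or `"grooming"`.
#' @param group_id,period_id identifiers.
#' @return An object of class `scan_network`.
#' @export
scan_network <- function(ids, counts, n_scans, directed, behaviour,
                         group_id = NA_character_, period_id = NA_character_) {
  counts <- as.matrix(counts)
  n <- length(ids)
  stopifnot(nrow(counts) == n, ncol(counts) == n)
  dimnames(counts) <- list(ids, ids)
  n_scans <- as.integer(n_scans)
  if (is.na(n_scans) || n_scans < 1) {
    stop("network error: n_scans must be a positive integer", call. = FALSE)
  }
  if (any(diag(counts) != 0)) {
    stop("network error: nonzero diagonal", call. = FALSE)
  }
  if (any(counts < 0) || any(counts > n_scans)) {
    stop("network error: counts outside [0, n_scans]", call. = FALSE)
  }
  if (!directed && !isTRUE(all.equal(counts, t(counts)))) {
    stop("network error: undirected network must be symmetric", call. = FALSE)
  }
  structure(
    list(ids = as.character(ids), counts = counts, n_scans = n_scans,
         directed = isTRUE(directed), behaviour = behaviour,
         group_id = as.character(group_id),
         period_id = as.character(period_id)),
    class = "scan_network"
  )
}

#' @export
print.scan_network <- function(x, ...) {
  cat(sprintf(
    "<scan_network> %s %s network: %d vertices, %d scans (group %s, period %s)\n",
    if (x$directed) "directed" else "undirected", x$behaviour,
    length(x$ids), x$n_scans, x$group_id, x$period_id))
  invisible(x)
}

#' Edge weights in percent-of-scans units
#' @param network a [scan_network()].
#' @return Numeric matrix, \eqn{100 \cdot counts / n_{scans}}.
#' @export
network_weights <- function(network) {
  stopifnot(inherits(network, "scan_network"))
  100 * network$counts / network$n_scans
}

group_members <- function(roster, group_id) {
  ids <- roster$id[roster$group_id == group_id]
  if (length(ids) == 0) {
    stop("no roster members for group ", group_id, call. = FALSE)
  }
  ids
}

tally_counts <- function(events, ids) {
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(events) > 0) {
    tab <- table(factor(events$actor, levels = ids),
                 factor(events$recipient, levels = ids))
    counts <- counts + unclass(tab)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Build the undirected proximity network
#'
#' Edge weight between two individuals is the percent of scans the pair
#' spent within an arm's reach of each other:
#' \eqn{w_{ij} = 100 \cdot \#\{scans\ with\ pair\ (i,j)\}/n_{scans}}.
#'
#' @param records a validated [scan_record_set()].
#' @param roster the study [roster()].
#' @return An undirected [scan_network()].
#' @export
build_proximity_network <- function(records, roster) {
  stopifnot(inherits(records, "scan_record_set"), inherits(roster, "roster"))
  ids <- group_members(roster, records$group_id)
  ev <- records$events[records$events$behaviour == "proximity", ]
  counts <- tally_counts(ev, ids)
  counts <- counts + t(counts)
  scan_network(ids, counts, records$n_scans, directed = FALSE,
               behaviour = "proximity", group_id = records$group_id,
               period_id = records$period_id)
}

#' Build the directed grooming-given network
#'
#' Out-edge weight from groomer i to groomee j is the percent of scans i
#' spent grooming j; mutual grooming within one scan yields two directed
#' events.
#'
#' @inheritParams build_proximity_network
#' @return A directed [scan_network()].
#' @export
build_grooming_network <- function(records, roster) {
  stopifnot(inherits(records, "scan_record_set"), inherits(roster, "roster"))
  ids <- group_members(roster, records$group_id)
  ev <- records$events[records$events$behaviour == "grooming", ]
  scan_network(ids, tally_counts(ev, ids), records$n_scans, directed = TRUE,
               behaviour = "grooming", group_id = records$group_id,
               period_id = records$period_id)
}

#' Convert a scan network to an igraph graph
#' @param network a [scan_network()].
#' @return An igraph object with vertex `name`, edge `weight` (percent) and
#'   graph attributes `n_scans`, `behaviour`, `group_id`, `period_id`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "scan_network"))
  g <- igraph::graph_from_adjacency_matrix(
    network_weights(network),
    mode = if (network$directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE
  )
  igraph::graph_attr(g, "n_scans") <- network$n_scans
  igraph::graph_attr(g, "behaviour") <- network$behaviour
  igraph::graph_attr(g, "group_id") <- network$group_id
  igraph::graph_attr(g, "period_id") <- network$period_id
  g
}

#' Export / import a network
#'
#' `edgelist` writes a CSV with columns `source, target, weight, directed`
#' (zero-weight edges omitted, one row per undirected dyad); `graphml`
#' writes GraphML via igraph, preserving isolates and metadata. Both
#' round-trip losslessly through [import_network()].
#'
#' @param network a [scan_network()].
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly (`import_network()` returns a
#'   [scan_network()]).
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(network, "scan_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    w <- network_weights(network)
    keep <- if (network$directed) w > 0 else upper.tri(w) & w > 0
    idx <- which(keep, arr.ind = TRUE)
    df <- data.frame(
      source = network$ids[idx[, 1]], target = network$ids[idx[, 2]],
      weight = w[keep], directed = network$directed
    )
    # header comment row carries the metadata needed for lossless re-import
    meta <- sprintf("# n_scans=%d behaviour=%s group_id=%s period_id=%s ids=%s",
                    network$n_scans, network$behaviour, network$group_id,
                    network$period_id, paste(network$ids, collapse = "|"))
    writeLines(c(meta, paste(names(df), collapse = ",")), path)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE, append = TRUE)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    meta <- sub("^# ", "", readLines(path, n = 1))
    fields <- strsplit(meta, " ")[[1]]
    kv <- strsplit(fields, "=")
    vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    ids <- strsplit(vals[["ids"]], "\\|")[[1]]
    n_scans <- as.integer(vals[["n_scans"]])
    df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
    directed <- nrow(df) > 0 && isTRUE(df$directed[1])
    if (nrow(df) == 0) directed <- vals[["behaviour"]] == "grooming"
    counts <- matrix(0L, length(ids), length(ids),
                     dimnames = list(ids, ids))
    if (nrow(df) > 0) {
      counts[cbind(df$source, df$target)] <-
        as.integer(round(df$weight * n_scans / 100))
      if (!directed) counts <- counts + t(counts) - diag(diag(counts))
    }
    scan_network(ids, counts, n_scans, directed = directed,
                 behaviour = vals[["behaviour"]],
                 group_id = vals[["group_id"]],
                 period_id = vals[["period_id"]])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    directed <- igraph::is_directed(g)
    w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    ids <- igraph::V(g)$name
    dimnames(w) <- list(ids, ids)
    n_scans <- as.integer(igraph::graph_attr(g, "n_scans"))
    scan_network(ids, round(w * n_scans / 100), n_scans,
                 directed = directed,
                 behaviour = igraph::graph_attr(g, "behaviour"),
                 group_id = igraph::graph_attr(g, "group_id"),
                 period_id = igraph::graph_attr(g, "period_id"))
  }
}
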