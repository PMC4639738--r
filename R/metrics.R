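#' Vertex strength centrality
#'
#' The vertex strength \eqn{s_i} is the sum of the weights of the edges
#' incident to vertex i (outgoing edges in the directed grooming-given
#' network). Dividing by the number of potential partners, N - 1,
#' standardizes for group size:
#' \deqn{C_s(v_i) = s_i / (N - 1)}
#' and reads as the mean percent of scans spent within arm's reach of (or
#' grooming) an individual group member, so it is bounded by
#' \eqn{[0, 100]}.
#'
#' @param network a [scan_network()].
#' @param vertex vertex id(s); default all vertices.
#' @return Named numeric vector.
#' @export
#' @examples
#' net <- scan_network(c("A", "B", "C"),
#'                     rbind(c(0, 4, 2), c(4, 0, 0), c(2, 0, 0)),
#'                     n_scans = 10, directed = FALSE, behaviour = "proximity")
#' vertex_strength_centrality(net)
vertex_strength_centrality <- function(network, vertex = NULL) {
  stopifnot(inherits(network, "scan_network"))
  vertex <- check_vertices(network, vertex)
  n <- length(network$ids)
  if (n < 2) stop("strength centrality undefined for N < 2", call. = FALSE)
  s_counts <- rowSums(network$counts)[vertex]
  100 * s_counts / network$n_scans / (n - 1)
}

check_vertices <- function(network, vertex) {
  if (is.null(vertex)) return(network$ids)
  bad <- setdiff(vertex, network$ids)
  if (length(bad) > 0) {
    stop("vertex not in network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  vertex
}

#' Edge weight disparity and its deviation from the equal-distribution value
#'
#' The edge weight disparity
#' \deqn{Y_2(v_i) = \sum_j (w_{ij} / s_i)^2}
#' measures how unevenly an individual spreads its association or grooming
#' over its N - 1 groupmates: it equals \eqn{1/(N-1)} under a perfectly
#' even spread and 1 when all weight falls on a single partner. For
#' individuals with \eqn{s_i = 0} (e.g. non-groomers) the disparity is
#' undefined and `NA` is returned; such individuals are excluded from
#' disparity analyses downstream.
#'
#' `deviation_from_disparity()` subtracts the group-specific
#' equal-distribution disparity, \eqn{\Delta Y_2 = Y_2(v_i) - 1/(N-1)},
#' making the score comparable across groups of different size: 0 means an
#' even spread; the higher the value, the more restricted the individual is
#' in its association or grooming partners.
#'
#' Both are computed from the integer scan counts (the common denominator
#' cancels), so the equal-distribution identity holds exactly.
#'
#' @inheritParams vertex_strength_centrality
#' @return Named numeric vector (`NA` where undefined).
#' @export
edge_weight_disparity <- function(network, vertex = NULL) {
  stopifnot(inherits(network, "scan_network"))
  vertex <- check_vertices(network, vertex)
  if (length(network$ids) < 2) {
    stop("disparity undefined for N < 2", call. = FALSE)
  }
  vapply(vertex, function(v) {
    c_out <- network$counts[v, ]
    s <- sum(c_out)
    if (s == 0) return(NA_real_)
    sum((c_out / s)^2)
  }, numeric(1))
}

#' @rdname edge_weight_disparity
#' @export
deviation_from_disparity <- function(network, vertex = NULL) {
  y2 <- edge_weight_disparity(network, vertex)
  y2 - 1 / (length(network$ids) - 1)
}

#' Per-individual measure table across networks
#'
#' Assembles the analysis table: one row per individual per behaviour per
#' group-period, holding vertex strength (percent), strength centrality,
#' disparity Y2, deviation dY2, a `defined` flag (FALSE where strength is
#' zero, in which case Y2/dY2 are `NA` but strength centrality is kept at
#' 0), and the individual's covariates from the roster.
#'
#' @param networks a [scan_network()] or list of them (typically both
#'   behaviours for every group-period).
#' @param roster the study [roster()].
#' @return A tibble (`measure_table`).
#' @export
metrics_table <- function(networks, roster) {
  if (inherits(networks, "scan_network")) networks <- list(networks)
  stopifnot(inherits(roster, "roster"))
  rows <- lapply(networks, function(net) {
    if (!all(net$ids %in% roster$id)) {
      stop("network vertex absent from roster: ",
           paste(setdiff(net$ids, roster$id), collapse = ", "),
           call. = FALSE)
    }
    n <- length(net$ids)
    strength <- 100 * rowSums(net$counts) / net$n_scans
    y2 <- edge_weight_disparity(net)
    tibble::tibble(
      id = net$ids,
      group_id = net$group_id,
      period_id = net$period_id,
      behaviour = net$behaviour,
      n_group = n,
      n_scans = net$n_scans,
      strength = unname(strength),
      strength_centrality = unname(strength) / (n - 1),
      y2 = unname(y2),
      dy2 = unname(y2) - 1 / (n - 1),
      defined = !is.na(unname(y2))
    )
  })
  out <- dplyr::bind_rows(rows)
  covars <- c("id", "sex", "age_class", "deprivation_class")
  out <- dplyr::left_join(out, tibble::as_tibble(roster)[covars], by = "id")
  class(out) <- c("measure_table", class(out))
  out
}

#' Write a measure table to CSV
#' @param table a [metrics_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
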