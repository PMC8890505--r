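## Plain-CSV readers/writers for the two input tables and the stage
## outputs. Column names are part of the contract and documented on the
## corresponding generators.

#' Read / write ethogram event and dyad-summary tables
#'
#' Events CSV contract: `dyad_id, sex, fish_id, behavior, t_seconds`.
#' Dyad-summary CSV contract: the columns of [summarize_dyads()].
#' Activation CSV contract: `fish_id, sex, condition`, then one count
#' column per region.
#'
#' @param path File path.
#' @param x Data.frame to write.
#' @param regions Region columns expected in an activation table.
#' @return The data.frame read, or (for writers) `path` invisibly.
#' @name sdmnet_io
NULL

#' @rdname sdmnet_io
#' @export
read_ethogram_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "sex", "fish_id", "behavior", "t_seconds")
  if (!all(need %in% names(ev)))
    stop(path, " lacks event columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  ev
}

#' @rdname sdmnet_io
#' @export
write_ethogram_events <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sdmnet_io
#' @export
read_dyad_summaries <- function(path) {
  sm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "sex", "latency", "resolution_time")
  if (!all(need %in% names(sm)))
    stop(path, " lacks dyad-summary columns: ",
         paste(setdiff(need, names(sm)), collapse = ", "))
  sm
}

#' @rdname sdmnet_io
#' @export
write_dyad_summaries <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname sdmnet_io
#' @export
read_activation_table <- function(path, regions = sdmn_regions()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_activation_table(tab, regions)
  tab
}

#' @rdname sdmnet_io
#' @export
write_activation_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a treatment network as edge list and dense matrix CSVs
#'
#' @param network A `treatment_network`.
#' @param edge_path,matrix_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, a list of the written paths.
#' @export
write_network_csv <- function(network, edge_path = NULL, matrix_path = NULL) {
  stopifnot(inherits(network, "treatment_network"))
  if (!is.null(edge_path)) {
    ei <- edge_index(network$regions)
    w <- network$weights[cbind(ei$i, ei$j)]
    edges <- data.frame(region_i = ei$region_i, region_j = ei$region_j,
                        weight = w)
    utils::write.csv(edges[edges$weight != 0, ], edge_path,
                     row.names = FALSE)
  }
  if (!is.null(matrix_path)) {
    m <- as.data.frame(network$weights)
    m <- cbind(region = network$regions, m)
    utils::write.csv(m, matrix_path, row.names = FALSE)
  }
  invisible(list(edges = edge_path, matrix = matrix_path))
}
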