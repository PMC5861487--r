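# Cross-condition comparison of refined networks: core proteins, induced core
# networks, condition-specific proteins and hub rankings.

network_nodes <- function(x) {
  if (inherits(x, c("refined_network", "candidate_network"))) return(x$nodes)
  if (inherits(x, "edge_list")) return(sort(unique(c(x$edges[, "a"], x$edges[, "b"]))))
  stop_regennet("unsupported network object", "regennet_type_error")
}

network_edges <- function(x) {
  if (inherits(x, "refined_network")) {
    return(cbind(a = x$edges$a, b = x$edges$b))
  }
  if (inherits(x, c("candidate_network", "edge_list"))) {
    return(x$edges[, c("a", "b"), drop = FALSE])
  }
  stop_regennet("unsupported network object", "regennet_type_error")
}

#' Core proteins across conditions
#'
#' The intersection of the node sets of all supplied networks: proteins whose
#' interactions survived model pruning in every condition.
#'
#' @param networks List (>= 2) of `refined_network` (or compatible) objects.
#' @return Sorted character vector of core protein ids.
#' @export
core_proteins <- function(networks) {
  if (!is.list(networks) || length(networks) < 2) {
    stop_regennet("core_proteins needs at least two networks",
                  "regennet_parameter_error")
  }
  sets <- lapply(networks, network_nodes)
  sort(Reduce(intersect, sets))
}

#' Edges of one condition's network induced on the core proteins
#'
#' Same node set across conditions, different edges: the subgraph of one
#' refined network induced on the core proteins.
#'
#' @param network A `refined_network` (or compatible).
#' @param core Character vector of core protein ids.
#' @return Two-column character matrix of edges (columns `a`, `b`).
#' @export
core_network <- function(network, core) {
  ed <- network_edges(network)
  keep <- ed[, "a"] %in% core & ed[, "b"] %in% core
  ed[keep, , drop = FALSE]
}

#' Condition-specific proteins
#'
#' The relative complement of one condition's node set with respect to all
#' other conditions: proteins appearing only in the focal network.
#'
#' @param networks Named list (>= 2) of networks.
#' @param focal Name of the focal condition.
#' @return Sorted character vector of focal-only protein ids.
#' @export
specific_proteins <- function(networks, focal) {
  if (!is.list(networks) || length(networks) < 2) {
    stop_regennet("specific_proteins needs at least two networks",
                  "regennet_parameter_error")
  }
  if (!focal %in% names(networks)) {
    stop_regennet(paste0("unknown focal condition: ", focal),
                  "regennet_lookup_error")
  }
  focal_nodes <- network_nodes(networks[[focal]])
  others <- unlist(lapply(networks[names(networks) != focal], network_nodes),
                   use.names = FALSE)
  sort(setdiff(focal_nodes, others))
}

#' Hub proteins ranked by interaction count
#'
#' Degree is the number of incident undirected edges; ties rank
#' alphabetically.
#'
#' @param network A `refined_network` (or compatible).
#' @param top_k Number of top hubs to return.
#' @return A data.frame with columns `protein` and `ppis`, at most `top_k`
#'   rows, ordered by decreasing degree then id.
#' @export
hub_ranking <- function(network, top_k = 10) {
  if (top_k < 1) {
    stop_regennet("top_k must be a positive integer", "regennet_parameter_error")
  }
  nodes <- network_nodes(network)
  ed <- network_edges(network)
  deg <- table(factor(c(ed[, "a"], ed[, "b"]), levels = nodes))
  ord <- order(-as.integer(deg), names(deg), method = "radix")
  out <- data.frame(protein = names(deg)[ord], ppis = as.integer(deg)[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Compare refined networks across conditions
#'
#' Runs the full cross-condition comparison: core proteins (node-set
#' intersection), per-condition core networks (induced subgraphs),
#' condition-specific proteins (relative complements) and hub rankings.
#'
#' @param networks Named list (>= 2) of `refined_network` objects.
#' @param top_k Hub list length per condition.
#' @return An object of class `network_comparison`: list with `core_proteins`,
#'   `core_networks` (named list of edge matrices), `specific_proteins` (named
#'   list), `hub_tables` (named list of data.frames) and `counts` (summary
#'   data.frame).
#' @export
compare_networks <- function(networks, top_k = 10) {
  if (!is.list(networks) || length(networks) < 2) {
    stop_regennet("compare_networks needs at least two networks",
                  "regennet_parameter_error")
  }
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop_regennet("networks must be a named list", "regennet_parameter_error")
  }
  core <- core_proteins(networks)
  core_nets <- lapply(networks, core_network, core = core)
  sp_sets <- lapply(stats::setNames(names(networks), names(networks)),
                    function(nm) specific_proteins(networks, nm))
  hubs <- lapply(networks, hub_ranking, top_k = top_k)
  counts <- data.frame(
    condition = names(networks),
    nodes = vapply(networks, function(n) length(network_nodes(n)), integer(1)),
    edges = vapply(networks, function(n) nrow(network_edges(n)), integer(1)),
    core_edges = vapply(core_nets, nrow, integer(1)),
    specific_proteins = vapply(sp_sets, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(core_proteins = core, core_networks = core_nets,
         specific_proteins = sp_sets, hub_tables = hubs, counts = counts),
    class = "network_comparison"
  )
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network comparison across %d conditions\n", nrow(x$counts)))
  cat(sprintf("Core proteins: %d\n", length(x$core_proteins)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
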