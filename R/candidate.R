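# Candidate interactome construction: project the human interactome onto
# zebrafish identifiers through orthologs, then keep only interactions whose
# endpoints are differentially expressed.

#' Candidate PPI network
#'
#' @param a,b Character vectors of paired endpoint ids (one pair per edge).
#' @param provenance Optional list (one element per input pair) of originating
#'   human edges, kept for reporting only.
#' @return An object of class `candidate_network` with `nodes` (sorted
#'   character vector), `edges` (two-column character matrix, `a` <= `b`) and
#'   `provenance` (named list keyed by "a|b", possibly empty).
#' @export
candidate_network <- function(a = character(), b = character(),
                              provenance = NULL) {
  pairs <- normalize_pairs(a, b)
  prov <- list()
  if (!is.null(provenance) && length(a) > 0) {
    keys_in <- pair_key(as.character(a), as.character(b))
    for (i in seq_along(keys_in)) {
      if (as.character(a)[i] == as.character(b)[i]) next
      k <- keys_in[i]
      prov[[k]] <- unique(c(prov[[k]], provenance[[i]]))
    }
  }
  nodes <- sort(unique(c(pairs[, "a"], pairs[, "b"])))
  structure(
    list(nodes = nodes, edges = pairs[, , drop = FALSE], provenance = prov),
    class = "candidate_network"
  )
}

#' @export
print.candidate_network <- function(x, ...) {
  cat(sprintf("Candidate PPI network: %d proteins, %d candidate interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Project human interactions onto zebrafish identifiers
#'
#' Each human edge (H1, H2) expands to every zebrafish pair (z_a, z_b) with
#' (z_a, H1) and (z_b, H2) in the ortholog map (both orientations). Many-to-many
#' orthology expands to all pairs: no disambiguation is attempted, since
#' spurious expansions are exactly what the downstream AIC pruning is for.
#' Pairs collapsing to a self-loop are dropped; human edges with no mapped
#' endpoint are dropped with a message.
#'
#' @param human_edges An [edge_list()] in human identifier space.
#' @param orthologs An [ortholog_map()].
#' @return An [edge_list()] in zebrafish identifier space.
#' @export
map_orthologs <- function(human_edges, orthologs) {
  stopifnot(inherits(human_edges, "edge_list"), inherits(orthologs, "ortholog_map"))
  if (nrow(orthologs$pairs) == 0) {
    warning("empty ortholog map: projected edge list is empty")
    return(edge_list(id_space = "zebrafish"))
  }
  # human id -> character vector of zebrafish ids
  zmap <- split(orthologs$pairs[, "zebrafish"], orthologs$pairs[, "human"])
  ha <- human_edges$edges[, "a"]
  hb <- human_edges$edges[, "b"]
  out_a <- character(0)
  out_b <- character(0)
  n_unmapped <- 0L
  for (e in seq_along(ha)) {
    za <- zmap[[ha[e]]]
    zb <- zmap[[hb[e]]]
    if (is.null(za) || is.null(zb)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    grid <- expand.grid(za = za, zb = zb, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    out_a <- c(out_a, grid$za)
    out_b <- c(out_b, grid$zb)
  }
  if (n_unmapped > 0) {
    message(sprintf("map_orthologs: dropped %d human edge(s) with no ortholog",
                    n_unmapped))
  }
  edge_list(out_a, out_b, id_space = "zebrafish")
}

#' Restrict an edge list to a differentially expressed protein pool
#'
#' Keeps edges whose BOTH endpoints are in the pool; network nodes are the
#' endpoints of surviving edges (pool proteins without any surviving
#' interaction are not nodes).
#'
#' @param edges An [edge_list()] (zebrafish space).
#' @param pool A `protein_pool` from [anova_filter()], or a character vector of
#'   ids.
#' @return A [candidate_network()].
#' @export
restrict_to_pool <- function(edges, pool) {
  stopifnot(inherits(edges, "edge_list"))
  ids <- if (inherits(pool, "protein_pool")) pool$protein_ids else as.character(pool)
  keep <- edges$edges[, "a"] %in% ids & edges$edges[, "b"] %in% ids
  candidate_network(edges$edges[keep, "a"], edges$edges[keep, "b"])
}

#' Interactors of a protein in a candidate network
#'
#' Returns the lexicographically sorted unique neighbors; the length of this
#' list is the candidate interaction count N_i that sizes the target's dynamic
#' regression.
#'
#' @param network A [candidate_network()] (or `refined_network`).
#' @param protein A node identifier.
#' @return Sorted character vector of neighbors.
#' @export
neighborhood <- function(network, protein) {
  if (inherits(network, "refined_network")) {
    ea <- network$edges$a
    eb <- network$edges$b
    nodes <- network$nodes
  } else if (inherits(network, "candidate_network")) {
    ea <- network$edges[, "a"]
    eb <- network$edges[, "b"]
    nodes <- network$nodes
  } else {
    stop_regennet("neighborhood: unsupported network object", "regennet_type_error")
  }
  if (!protein %in% nodes) {
    stop_regennet(paste0("unknown protein: ", protein), "regennet_lookup_error")
  }
  sort(unique(c(eb[ea == protein], ea[eb == protein])))
}

#' Read a network TSV written by [write_network()] as a candidate network
#' @param path Path to the TSV.
#' @return A [candidate_network()].
#' @export
read_candidate_network <- function(path) {
  el <- read_ppi_edges(path, dialect = "simple_tsv", id_space = "zebrafish")
  candidate_network(el$edges[, "a"], el$edges[, "b"])
}
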