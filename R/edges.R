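#' Undirected edge list
#'
#' A deduplicated, orientation-insensitive set of protein id pairs with no
#' self-loops. Identifiers are opaque case-sensitive strings.
#'
#' @param a,b Character vectors of interactor identifiers (pairwise).
#' @param id_space Label for the identifier namespace, e.g. `"human"` or
#'   `"zebrafish"`.
#' @return An object of class `edge_list`: a list with `edges` (two-column
#'   character matrix, columns `a` <= `b` lexicographically) and `id_space`.
#'   The number of self-loops dropped during normalization is kept in
#'   attribute `n_self_dropped`.
#' @export
edge_list <- function(a = character(), b = character(), id_space = "") {
  pairs <- normalize_pairs(a, b)
  structure(
    list(edges = pairs[, , drop = FALSE], id_space = as.character(id_space)),
    n_self_dropped = attr(pairs, "n_self"),
    class = "edge_list"
  )
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("Edge list (%s): %d undirected edges\n",
              if (nzchar(x$id_space)) x$id_space else "unlabelled",
              nrow(x$edges)))
  invisible(x)
}

#' Number of edges in an edge-bearing object
#' @param x An `edge_list`, `candidate_network` or `refined_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(x) {
  if (inherits(x, "edge_list")) return(nrow(x$edges))
  if (inherits(x, c("candidate_network", "refined_network"))) return(nrow(x$edges))
  stop_regennet("n_edges: unsupported object", "regennet_type_error")
}

#' Read a PPI edge list
#'
#' Two dialects are supported. `simple_tsv` takes the first two columns of a
#' tab-separated file (header required, extra columns ignored). `biogrid_tab`
#' is the BioGRID tab-delimited export: a header naming, among others, the
#' official-symbol columns of interactors A and B; which columns to use is
#' configurable because BioGRID releases also carry Entrez and systematic
#' identifiers.
#'
#' Edges are deduplicated ignoring orientation and self-loops are dropped (the
#' dynamic model already carries a self term, so a self-interaction would be
#' unidentifiable from it).
#'
#' @param path Path to the file.
#' @param dialect `"simple_tsv"` or `"biogrid_tab"`.
#' @param col_a,col_b Column names of the two interactor symbols
#'   (`biogrid_tab` only).
#' @param id_space Identifier namespace label stored on the result.
#' @return An [edge_list()].
#' @export
read_ppi_edges <- function(path, dialect = c("simple_tsv", "biogrid_tab"),
                           col_a = "Official Symbol Interactor A",
                           col_b = "Official Symbol Interactor B",
                           id_space = "human") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) return(edge_list(id_space = id_space))
  if (dialect == "simple_tsv") {
    if (ncol(df) < 2) {
      stop_regennet("simple_tsv edge files need at least two columns",
                    "regennet_format_error")
    }
    a <- df[[1]]
    b <- df[[2]]
  } else {
    missing_cols <- setdiff(c(col_a, col_b), colnames(df))
    if (length(missing_cols) > 0) {
      stop_regennet(paste0("biogrid_tab file lacks column(s): ",
                           paste(missing_cols, collapse = ", ")),
                    "regennet_format_error")
    }
    a <- df[[col_a]]
    b <- df[[col_b]]
  }
  out <- edge_list(a, b, id_space = id_space)
  n_self <- attr(out, "n_self_dropped")
  if (n_self > 0) {
    message(sprintf("read_ppi_edges: dropped %d self-loop(s)", n_self))
  }
  out
}

#' Zebrafish-human ortholog table
#'
#' @param zebrafish,human Character vectors of paired identifiers. Many-to-many
#'   correspondences are allowed; duplicate tuples are collapsed.
#' @return An object of class `ortholog_map` holding a two-column character
#'   matrix `pairs` (columns `zebrafish`, `human`).
#' @export
ortholog_map <- function(zebrafish = character(), human = character()) {
  zebrafish <- as.character(zebrafish)
  human <- as.character(human)
  stopifnot(length(zebrafish) == length(human))
  key <- paste(zebrafish, human, sep = "\r")
  keep <- !duplicated(key)
  structure(
    list(pairs = cbind(zebrafish = zebrafish[keep], human = human[keep])),
    class = "ortholog_map"
  )
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("Ortholog map: %d zebrafish-human pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' Read a ZFIN-style ortholog TSV
#'
#' @param path Path to a tab-separated file with a header.
#' @param col_zebrafish,col_human Names of the zebrafish and human identifier
#'   columns.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path, col_zebrafish = "zebrafish_id",
                              col_human = "human_id") {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(c(col_zebrafish, col_human), colnames(df))
  if (length(missing_cols) > 0) {
    stop_regennet(paste0("ortholog table lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "regennet_format_error")
  }
  ortholog_map(df[[col_zebrafish]], df[[col_human]])
}

#' Write an ortholog map as a TSV readable by [read_ortholog_map()]
#' @param map An [ortholog_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  lines <- c("zebrafish_id\thuman_id",
             paste(map$pairs[, "zebrafish"], map$pairs[, "human"], sep = "\t"))
  writeLines(lines, con = path)
  invisible(path)
}

#' Write a network to disk
#'
#' TSV output has one edge per line with lexicographically sorted endpoints and
#' sorted lines, plus per-direction interaction-ability columns (`a_ab` is the
#' fitted effect of protein b on protein a's next-step change; empty for
#' candidate networks or unretained directions). Output bytes are deterministic
#' for identical input. GraphML output carries the same annotations as edge
#' attributes.
#'
#' @param network A `candidate_network`, `refined_network` or [edge_list()].
#' @param path Output path.
#' @param fmt `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, fmt = c("tsv", "graphml")) {
  fmt <- match.arg(fmt)
  ed <- network_edge_table(network)
  ord <- order(ed$a, ed$b, method = "radix")
  ed <- ed[ord, , drop = FALSE]
  if (fmt == "tsv") {
    lines <- c("protein_a\tprotein_b\ta_ab\ta_ba",
               paste(ed$a, ed$b, fmt_num(ed$a_ab), fmt_num(ed$a_ba), sep = "\t"))
    writeLines(lines, con = path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$a, to = ed$b,
                 a_ab = ed$a_ab, a_ba = ed$a_ba,
                 stringsAsFactors = FALSE),
      directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Edge table (a, b, a_ab, a_ba) of any network-like object
#' @noRd
network_edge_table <- function(network) {
  if (inherits(network, "edge_list")) {
    data.frame(a = network$edges[, "a"], b = network$edges[, "b"],
               a_ab = NA_real_, a_ba = NA_real_, stringsAsFactors = FALSE)
  } else if (inherits(network, "candidate_network")) {
    data.frame(a = network$edges[, "a"], b = network$edges[, "b"],
               a_ab = NA_real_, a_ba = NA_real_, stringsAsFactors = FALSE)
  } else if (inherits(network, "refined_network")) {
    data.frame(a = network$edges$a, b = network$edges$b,
               a_ab = network$edges$a_ab, a_ba = network$edges$a_ba,
               stringsAsFactors = FALSE)
  } else {
    stop_regennet("write_network: unsupported network object",
                  "regennet_type_error")
  }
}
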