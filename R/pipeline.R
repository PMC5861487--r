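# End-to-end orchestration: preprocess -> candidate -> infer per condition,
# then cross-condition comparison, with a JSON run manifest.

#' Build a run configuration
#'
#' Collects every stage parameter of [run_pipeline()] in one validated list. A
#' configuration can also be loaded from a YAML document with
#' [read_run_config()]; values passed here override nothing (there is no
#' implicit global state).
#'
#' @param conditions Named list; each element describes one condition with
#'   elements `expr` (path to an expression TSV, or an [expression_matrix()])
#'   and optionally `design` (a [time_design()] or list with `time_points`,
#'   `replicates`; required when `expr` is a path).
#' @param ppi Path to the human PPI file, or an [edge_list()].
#' @param ppi_dialect Dialect for [read_ppi_edges()] when `ppi` is a path.
#' @param orthologs Path to the ortholog TSV, or an [ortholog_map()].
#' @param alpha,percentile,log2 Preprocessing parameters (see [anova_filter()],
#'   [percentile_normalize()], [log2_transform()]). `log2 = FALSE` by default:
#'   the dynamic model is fitted on the normalized scale. Set
#'   `percentile = NULL` for matrices that already share a common scale
#'   (platform-normalized uploads, simulator output): re-scaling such data only
#'   injects per-array error.
#' @param m_points,merge Inference parameters (see [infer_control()]).
#' @param top_k Hub list length for the comparison stage.
#' @param out_dir Optional output directory; when set, per-stage TSVs and the
#'   manifest are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(conditions, ppi, orthologs,
                       ppi_dialect = "simple_tsv",
                       alpha = 0.05, percentile = 75, log2 = FALSE,
                       m_points = "auto", merge = "union", top_k = 10,
                       out_dir = NULL) {
  if (!is.list(conditions) || length(conditions) < 1 ||
      is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop_regennet("conditions must be a non-empty named list",
                  "regennet_config_error")
  }
  cfg <- list(conditions = conditions, ppi = ppi, orthologs = orthologs,
              ppi_dialect = ppi_dialect, alpha = alpha,
              percentile = percentile, log2 = log2, m_points = m_points,
              merge = merge, top_k = top_k, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML document mirrors the arguments of [run_config()]; condition
#' designs are given as `time_points` / `replicates` lists.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$conditions)) {
    stop_regennet("config lacks a 'conditions' section", "regennet_config_error")
  }
  args <- doc[intersect(names(doc),
                        c("conditions", "ppi", "orthologs", "ppi_dialect",
                          "alpha", "percentile", "log2", "m_points", "merge",
                          "top_k", "out_dir"))]
  do.call(run_config, args)
}

resolve_condition <- function(cond, name) {
  expr <- cond$expr
  if (inherits(expr, "expression_matrix")) return(expr)
  design <- cond$design
  if (is.list(design) && !inherits(design, "time_design")) {
    design <- time_design(as.numeric(design$time_points),
                          as.integer(design$replicates))
  }
  if (!inherits(design, "time_design")) {
    stop_regennet(paste0("condition '", name, "' needs a design"),
                  "regennet_config_error")
  }
  read_expression_table(expr, design, condition = name)
}

#' Run the full inference pipeline across conditions
#'
#' Per condition: percentile normalization (optionally a shifted log2),
#' the ANOVA/Bonferroni differential-expression screen, candidate-network
#' construction from the ortholog-projected interactome, and dynamic-model
#' inference with AIC pruning. Refined networks are then compared across
#' conditions. Identical configuration and inputs give identical outputs: no
#' stage uses randomness.
#'
#' @param config A [run_config()] (or a path to a YAML file).
#' @param verbose Print one progress line per stage.
#' @return A list of class `pipeline_result` with `networks` (named list of
#'   `refined_network`), `pools`, `candidates`, `comparison` (a
#'   [compare_networks()] result) and `manifest` (per-stage counts and the
#'   configuration echo). When `out_dir` is configured, networks, comparison
#'   outputs and `manifest.json` are written there.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  ppi <- if (inherits(config$ppi, "edge_list")) config$ppi else
    read_ppi_edges(config$ppi, dialect = config$ppi_dialect)
  orth <- if (inherits(config$orthologs, "ortholog_map")) config$orthologs else
    read_ortholog_map(config$orthologs)
  projected <- map_orthologs(ppi, orth)
  say("candidate projection: %d human edges -> %d projected edges",
      n_edges(ppi), n_edges(projected))

  networks <- list()
  pools <- list()
  candidates <- list()
  stage_counts <- list()
  for (nm in names(config$conditions)) {
    mat <- resolve_condition(config$conditions[[nm]], nm)
    if (!is.null(config$percentile)) {
      mat <- percentile_normalize(mat, q = config$percentile)
    }
    if (isTRUE(config$log2)) mat <- log2_transform(mat)
    pool <- anova_filter(mat, alpha = config$alpha)
    cand <- restrict_to_pool(projected, pool)
    say("[%s] pool %d/%d proteins; candidate %d nodes / %d edges",
        nm, length(pool$protein_ids), length(pool$p_values),
        length(cand$nodes), nrow(cand$edges))
    refined <- infer_network(cand, mat,
                             control = infer_control(m_points = config$m_points,
                                                     merge = config$merge))
    say("[%s] refined %d nodes / %d edges",
        nm, length(refined$nodes), nrow(refined$edges))
    pools[[nm]] <- pool
    candidates[[nm]] <- cand
    networks[[nm]] <- refined
    stage_counts[[nm]] <- list(
      proteins_tested = length(pool$p_values),
      pool_size = length(pool$protein_ids),
      candidate_nodes = length(cand$nodes),
      candidate_edges = nrow(cand$edges),
      refined_nodes = length(refined$nodes),
      refined_edges = nrow(refined$edges))
  }
  comparison <- compare_networks(networks, top_k = config$top_k)
  manifest <- list(
    package = "regennet",
    version = as.character(utils::packageVersion("regennet")),
    config = config_echo(config),
    stages = stage_counts,
    core_proteins = length(comparison$core_proteins),
    core_edges = stats::setNames(
      as.list(vapply(comparison$core_networks, nrow, integer(1))),
      names(comparison$core_networks)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(networks)) {
      write_network(networks[[nm]],
                    file.path(config$out_dir, paste0("refined_", nm, ".tsv")))
      write_protein_pool(pools[[nm]],
                         file.path(config$out_dir, paste0("pool_", nm, ".tsv")))
    }
    writeLines(comparison$core_proteins,
               file.path(config$out_dir, "core_proteins.txt"))
    for (nm in names(comparison$specific_proteins)) {
      writeLines(comparison$specific_proteins[[nm]],
                 file.path(config$out_dir, paste0("specific_", nm, ".txt")))
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(
    list(networks = networks, pools = pools, candidates = candidates,
         comparison = comparison, manifest = manifest),
    class = "pipeline_result"
  )
}

# configuration echo for the manifest: paths stay, in-memory objects are
# summarized so the manifest is always JSON-serializable
config_echo <- function(config) {
  desc_obj <- function(x) {
    if (is.character(x)) x
    else if (inherits(x, "edge_list")) sprintf("<edge_list: %d edges>", n_edges(x))
    else if (inherits(x, "ortholog_map")) sprintf("<ortholog_map: %d pairs>", nrow(x$pairs))
    else class(x)[1]
  }
  list(
    conditions = lapply(config$conditions, function(cond) {
      if (inherits(cond$expr, "expression_matrix")) {
        list(expr = sprintf("<expression_matrix: %d x %d>",
                            nrow(cond$expr$values), ncol(cond$expr$values)))
      } else {
        list(expr = as.character(cond$expr))
      }
    }),
    ppi = desc_obj(config$ppi),
    orthologs = desc_obj(config$orthologs),
    alpha = config$alpha,
    percentile = if (is.null(config$percentile)) "none" else config$percentile,
    log2 = isTRUE(config$log2),
    m_points = config$m_points, merge = config$merge, top_k = config$top_k)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$comparison)
  invisible(x)
}
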