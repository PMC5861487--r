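# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Orientation-insensitive normalization of id pairs
#'
#' Sorts each pair lexicographically (first <= second), drops self-loops and
#' duplicates. Returns a two-column character matrix with columns a, b plus an
#' attribute `n_self` counting dropped self-loops.
#' @noRd
normalize_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  self <- a == b
  a2 <- a[!self]
  b2 <- b[!self]
  swap <- a2 > b2
  tmp <- a2[swap]
  a2[swap] <- b2[swap]
  b2[swap] <- tmp
  key <- paste(a2, b2, sep = "\r")
  keep <- !duplicated(key)
  out <- cbind(a = a2[keep], b = b2[keep])
  attr(out, "n_self") <- sum(self)
  out
}

#' Key used to index undirected edges in named lookups
#' @noRd
pair_key <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "\r")
}

#' Stop with a classed condition, keeping error classes greppable in tests
#' @noRd
stop_regennet <- function(msg, class) {
  stop(structure(
    class = c(class, "regennet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fmt_num <- function(x) {
  # %.17g round-trips IEEE doubles exactly
  ifelse(is.na(x), "", sprintf("%.17g", x))
}
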