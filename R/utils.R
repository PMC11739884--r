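# internal helpers shared across modules

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stop_seg2fem <- function(msg, class, ...) {
  stop(structure(class = c(class, "seg2fem_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric edge key for vertex index pairs (valid while n < 2^26)
edge_key <- function(a, b, n) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo * (n + 1) + hi
}

as_matrix3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  x
}
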