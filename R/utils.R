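# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

pls_error <- function(msg, class = "plsassay_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "plsassay_error", "error", "condition")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded internals (permutation nulls, simulators) never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  code
}

# geometric mean; values must be positive
geo_mean <- function(x) exp(mean(log(x)))

# row-wise sample sd (n-1 denominator) without apply() overhead
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) pls_error("at least 2 columns required for a sample standard deviation")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

is_count_scale <- function(x) all(is.finite(x)) && all(x >= 0)

# comma-join a character vector for TSV output
join_genes <- function(x) paste(x, collapse = ",")
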