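## Internal helpers shared across the pipeline.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards.  All stochastic entry points route through
## this so no function touches the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Population standard deviation (divide by N, not N-1).
pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

## Check that `x` is a numeric matrix with unique row and column names.
check_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop(sprintf("`%s` must have unique row names (gene ids)", what),
         call. = FALSE)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop(sprintf("`%s` must have unique column names (condition ids)", what),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` contains missing or non-finite values", what),
         call. = FALSE)
  invisible(x)
}

## Positive conditions of indicator `indicator` in a labels matrix
## (conditions x indicators, entries +1/0).
positive_conditions <- function(labels, indicator) {
  if (!indicator %in% colnames(labels))
    stop(sprintf("unknown indicator '%s'", indicator), call. = FALSE)
  rownames(labels)[labels[, indicator] == 1]
}

## Indicators with at least one positive condition (the scoreable ones).
scoreable_indicators <- function(labels) {
  colnames(labels)[colSums(labels == 1) >= 1L]
}
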