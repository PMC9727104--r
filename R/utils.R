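#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rbeta runif dist cophenetic kmeans prcomp median
#'   quantile dbinom dhyper setNames complete.cases
#' @importFrom utils write.table read.table head
NULL

# stopifnot with a formatted message
.check <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
  invisible(TRUE)
}

# draw a sub-seed stream deterministically from a master seed; keeps every
# stage's RNG independent of the others while remaining a pure function of
# the master seed (values stay below 2^31)
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483399) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
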