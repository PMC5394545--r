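#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dbinom dhyper dnbinom median phyper pnorm quantile
#'   rbinom rnbinom rnorm rpois runif sd setNames hclust dist p.adjust
#'   aggregate dnorm
#' @importFrom utils head read.delim write.table modifyList
#' @importFrom graphics hist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Round half-up to `digits` decimals (Table-style reporting; R's round()
## uses banker's rounding which would turn e.g. 96.735 into 96.73/96.74
## platform-dependently).
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

## Largest-remainder integer apportionment of `total` among weights `w`.
apportion <- function(total, w) {
  stopifnot(total >= 0, all(w >= 0), sum(w) > 0)
  exact <- total * w / sum(w)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

## Round values preserving their (rounded) sum: largest-remainder.
round_preserve_sum <- function(x) {
  target <- round(sum(x))
  base <- floor(x)
  rem <- target - sum(base)
  if (rem > 0) {
    idx <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  } else if (rem < 0) {
    idx <- order(x - base)[seq_len(-rem)]
    base[idx] <- base[idx] - 1
  }
  base
}

stop_domain <- function(...) stop(..., call. = FALSE)
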