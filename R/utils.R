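#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm runif rpois sd fft kruskal.test wilcox.test
#' @importFrom utils write.table read.delim modifyList packageVersion combn
#' @importFrom Rcpp sourceCpp
#' @useDynLib ecogrms, .registration = TRUE
NULL

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a deterministic child seed from a master seed and labels
#'
#' Polynomial string hash over `paste(master, ..., sep = ":")`, reduced
#' modulo 2^31 - 1 so the result is a valid 32-bit seed on any platform.
#' Used to give every mouse in a cohort an independent, reproducible RNG
#' stream.
#'
#' @param master integer master seed.
#' @param ... labels (cohort name, mouse index, ...) mixed into the hash.
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character, "")),
             collapse = ":")
  h <- 0
  m <- 2147483647
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Merge possibly overlapping [start, end] spans into a disjoint union.
merge_spans <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  spans <- spans[order(spans$start_s), c("start_s", "end_s")]
  out_s <- spans$start_s[1]
  out_e <- spans$end_s[1]
  if (nrow(spans) > 1) for (i in 2:nrow(spans)) {
    if (spans$start_s[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], spans$end_s[i])
    } else {
      out_s <- c(out_s, spans$start_s[i])
      out_e <- c(out_e, spans$end_s[i])
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

# Total overlap (seconds) between interval [a, b] and a set of disjoint spans.
span_overlap <- function(a, b, spans) {
  if (is.null(spans) || nrow(spans) == 0) return(0)
  sum(pmax(0, pmin(b, spans$end_s) - pmax(a, spans$start_s)))
}
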