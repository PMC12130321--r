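#' @keywords internal
"_PACKAGE"

#' @useDynLib nnpgs, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn inform .data
#' @importFrom stats cor cor.test pt qnorm rnorm runif rbinom sd var
#' @importFrom utils head
NULL

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# standardize with population sd; constant vectors -> error unless allow_zero
z_score <- function(x, center = mean(x), scale = pop_sd(x)) {
  (x - center) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
}

# deterministic tie-break ordering used by clumping and distance filtering:
# ascending p, then position, then lexicographic snp id
order_by_p <- function(p, pos, id) {
  order(p, pos, id, method = "radix")
}
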