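#' @keywords internal
"_PACKAGE"

#' @useDynLib pollinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.formula coef logLik median pchisq pnorm quantile
#'   rbinom rlnorm rmultinom rnbinom rpois runif sd setNames simulate update
#'   vcov aggregate anova formula model.matrix qnorm rgamma
#' @importFrom utils read.csv write.csv
NULL

#' Derive a reproducible substream seed from a master seed and a key
#'
#' Streams for independent pipeline stages (and for per-site-week null
#' ensembles) are derived by hashing the master seed together with a string
#' key, so that evaluation order and parallelism do not change results.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream, e.g. `"community"` or
#'   `"null/LANSING/7"`.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(17, "community")
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (code in utf8ToInt(paste0("s:", key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

#' Round a non-negative vector to integers preserving a target total
#'
#' Largest-remainder (Hamilton) apportionment: floors every value, then
#' distributes the remaining units to the largest fractional parts. Used to
#' discretize continuous marginal totals before integer table sampling.
#'
#' @param x non-negative numeric vector.
#' @param total target integer sum; defaults to `round(sum(x))`.
#' @return Integer vector with `sum == total`, each entry within 1 of `x`.
#' @export
largest_remainder_round <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem < 0) {
    # target below the floor sum (can happen when total is externally imposed):
    # take units back from the smallest fractional parts
    ord <- order(x - fl, x, decreasing = FALSE)
    take <- ord[fl[ord] > 0][seq_len(-rem)]
    fl[take] <- fl[take] - 1
  } else if (rem > 0) {
    ord <- order(x - fl, x, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent condition signalling with package class
pn_stop <- function(..., class = "pollinet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

pn_warn <- function(...) warning(paste0(...), call. = FALSE)
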