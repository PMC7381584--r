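#' Enumerate all integer tables with given marginal totals
#'
#' Exhaustive recursion over cells; intended for small problems (grand total
#' up to ~12, dimensions up to ~4x4) where it serves as an exact reference
#' for the table sampler.
#'
#' @param row_sums,col_sums non-negative integer marginals with equal sums.
#' @return List of integer matrices.
#' @export
enumerate_tables <- function(row_sums, col_sums) {
  r <- length(row_sums); s <- length(col_sums)
  stopifnot(sum(row_sums) == sum(col_sums))
  out <- list()
  tab <- matrix(0L, r, s)
  recurse2 <- function(i, j, rowrem, colrem) {
    if (i > r) {
      out[[length(out) + 1L]] <<- tab
      return(invisible())
    }
    if (j == s) {
      if (rowrem <= colrem[s]) {
        tab[i, s] <<- rowrem
        cr <- colrem; cr[s] <- cr[s] - rowrem
        recurse2(i + 1L, 1L, if (i < r) row_sums[i + 1L] else 0L, cr)
        tab[i, s] <<- 0L
      }
      return(invisible())
    }
    for (v in 0:min(rowrem, colrem[j])) {
      tab[i, j] <<- v
      cr <- colrem; cr[j] <- cr[j] - v
      recurse2(i, j + 1L, rowrem - v, cr)
      tab[i, j] <<- 0L
    }
    invisible()
  }
  recurse2(1L, 1L, row_sums[1L], as.integer(col_sums))
  out
}

#' Multiple-hypergeometric probability of an integer table
#'
#' The conditional probability of a table of independent counts given its
#' marginal totals: `prod(r_i!) prod(c_j!) / (N! prod(n_ij!))`. Computed in
#' log space for stability.
#'
#' @param tab integer matrix.
#' @return Probability of `tab` under fixed-margins randomization.
#' @export
table_probability <- function(tab) {
  exp(sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
        lfactorial(sum(tab)) - sum(lfactorial(tab)))
}
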