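# Fisher-Z conditional-independence testing.
#
# The partial correlation of x and y given a conditioning set S is obtained
# by inverting the correlation submatrix of (x, y, S); the test statistic
# is z = sqrt(n - |S| - 3) * atanh(r), referred to the standard normal.

# Partial correlation from a correlation matrix over columns (x, y, S).
partial_cor_from_corr <- function(R) {
  P <- tryCatch(solve(R), error = function(e) {
    stopf("rank-deficiency error: conditioning submatrix is singular")
  })
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Fisher-Z conditional-independence test
#'
#' Tests whether `x` and `y` are conditionally independent given the
#' variables in `S`, assuming joint Gaussianity. The partial correlation is
#' clamped to +/-(1 - 1e-12) before the atanh transform.
#'
#' @param data data.frame of numeric columns (code binary variables 0/1).
#' @param x,y column names of the two variables under test.
#' @param S character vector of conditioning column names (may be empty).
#' @param alpha significance level (default 0.05).
#' @return object of class `ci_test` with fields `var_x`, `var_y`,
#'   `conditioning_set`, `partial_corr`, `z_stat`, `p_value`,
#'   `independent` (`p_value > alpha`), `n`, `alpha`.
#' @export
#' @examples
#' d <- data.frame(a = rnorm(100), b = rnorm(100))
#' fisher_z_test(d, "a", "b")$independent
fisher_z_test <- function(data, x, y, S = character(), alpha = 0.05) {
  vars <- c(x, y, S)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stopf("unknown variable(s): %s", paste(miss, collapse = ", "))
  n <- nrow(data)
  k <- length(S)
  if (n <= k + 3) {
    stopf("sample-size error: need n > |S| + 3 (n = %d, |S| = %d)", n, k)
  }
  M <- as.matrix(data[, vars, drop = FALSE])
  storage.mode(M) <- "double"
  R <- stats::cor(M)
  r <- if (k == 0) R[1, 2] else partial_cor_from_corr(R)
  r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
  z <- sqrt(n - k - 3) * atanh(r)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(var_x = x, var_y = y, conditioning_set = S,
                 partial_corr = r, z_stat = z, p_value = p,
                 independent = p > alpha, n = n, alpha = alpha),
            class = "ci_test")
}
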