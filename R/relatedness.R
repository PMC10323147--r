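#' Additive genetic relationship structures
#'
#' A relatedness object bundles the `n` x `n` additive genetic relationship
#' matrix `A` with its symmetric matrix square root `A_M` (satisfying
#' `A_M %*% A_M = A`), which is used to induce relatedness among sampled
#' additive deviations. `identity_relatedness()` represents an unrelated
#' (randomly mating, unbred) population without materialising the identity
#' matrix, which keeps very large populations cheap. `band_relatedness()`
#' builds the highly related banded structure with 1 on the diagonal, 1/2
#' on the first off-diagonals and 1/4 everywhere else.
#' `relatedness_matrix()` wraps an arbitrary user-supplied matrix.
#'
#' `A_M` is computed by symmetric eigendecomposition with any (numerically)
#' negative eigenvalues clipped at zero; unlike a Cholesky factor it is
#' itself symmetric, so `A_M A_M = A` holds in the symmetric sense.
#'
#' @param n Number of individuals.
#' @return An object of class `rel_matrix` with elements `kind`
#'   (`"identity"`, `"band"` or `"custom"`), `n`, `A`, `A_M` (the latter two
#'   `NULL` for the identity kind).
#' @export
#' @examples
#' band_relatedness(6)$A
identity_relatedness <- function(n) {
  if (n < 1) abort("`n` must be >= 1.")
  structure(list(kind = "identity", n = n, A = NULL, A_M = NULL),
            class = "rel_matrix")
}

#' @rdname identity_relatedness
#' @export
band_relatedness <- function(n) {
  if (n < 1) abort("`n` must be >= 1.")
  A <- matrix(1 / 4, n, n)
  A[abs(row(A) - col(A)) == 1] <- 1 / 2
  diag(A) <- 1
  structure(list(kind = "band", n = n, A = A, A_M = sym_sqrt(A)),
            class = "rel_matrix")
}

#' @rdname identity_relatedness
#' @param A An `n` x `n` symmetric positive semidefinite matrix. A warning
#'   (not an error) is raised when the diagonal is not 1, to allow inbred
#'   conventions.
#' @export
relatedness_matrix <- function(A) {
  A <- as.matrix(A)
  check_psd(A, "A")
  if (any(abs(diag(A) - 1) > 1e-8)) {
    warn("relatedness matrix diagonal is not 1; proceeding anyway.")
  }
  structure(list(kind = "custom", n = nrow(A), A = A, A_M = sym_sqrt(A)),
            class = "rel_matrix")
}

# dense A (materialises the identity when needed; avoid for huge n)
rel_A <- function(rel) {
  if (rel$kind == "identity") diag(rel$n) else rel$A
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix> kind = %s, n = %d\n", x$kind, x$n))
  invisible(x)
}

#' Read / write a relatedness matrix as CSV
#'
#' Dense CSV, no header, one row per individual. On reading, the matrix is
#' validated for symmetry and positive semidefiniteness; a non-unit
#' diagonal raises a warning only.
#'
#' @param rel A `rel_matrix` (identity kind is materialised on write).
#' @param path File path.
#' @return `read_relatedness_csv()` returns a `rel_matrix`;
#'   `write_relatedness_csv()` returns `rel` invisibly.
#' @export
write_relatedness_csv <- function(rel, path) {
  utils::write.table(rel_A(rel), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(rel)
}

#' @rdname write_relatedness_csv
#' @export
read_relatedness_csv <- function(path) {
  A <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(A) <- NULL
  relatedness_matrix(A)
}
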