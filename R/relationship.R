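#' Tabular numerator relationship matrix (oracle-scale)
#'
#' Builds `A` by the textbook tabular recursion. Dense and quadratic in the
#' number of animals, so intentionally capped: it serves as the independent
#' cross-check for [a_inverse()] and [compute_inbreeding()] on small
#' pedigrees.
#'
#' @param ped pedigree (ids `1..n`, parents before offspring).
#' @param max_animals refuse above this size (default 2000).
#' @return dense symmetric matrix `A` with `diag(A) = 1 + F`.
#' @export
tabular_A <- function(ped, max_animals = 2000) {
  .check_pedigree(ped)
  n <- nrow(ped)
  if (n > max_animals)
    stop("tabular_A is an oracle for small pedigrees (n <= ", max_animals, ")")
  A <- matrix(0, n, n)
  sire <- ped$sire; dam <- ped$dam
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        aij <- 0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
        A[i, j] <- A[j, i] <- aij
      }
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) 0.5 * A[s, d] else 0)
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding. For animal i with Mendelian-sampling
#' variance `d_i` (`1` with no known parent, `0.75 - 0.25 F_p` with one,
#' `0.5 - 0.25 (F_s + F_d)` with both), add `1/d_i` at (i, i), `-0.5/d_i`
#' between i and each known parent, and `0.25/d_i` among the known parents.
#' Unknown parents are treated as unrelated founders (closed population, no
#' genetic groups).
#'
#' @param ped pedigree.
#' @param F inbreeding coefficients; computed when missing.
#' @return a symmetric sparse [Matrix::dsCMatrix] with
#'   `attr(, "logdet_A") = log|A| = sum(log d_i)`.
#' @export
a_inverse <- function(ped, F = NULL) {
  .check_pedigree(ped)
  if (is.null(F)) F <- compute_inbreeding(ped)
  n <- nrow(ped)
  s <- as.integer(ped$sire); d <- as.integer(ped$dam)
  Fs <- ifelse(s > 0, F[pmax(s, 1)], 0)
  Fd <- ifelse(d > 0, F[pmax(d, 1)], 0)
  di <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
        ifelse(s > 0, 0.75 - 0.25 * Fs,
        ifelse(d > 0, 0.75 - 0.25 * Fd, 1)))
  w <- 1 / di
  has_s <- which(s > 0)
  has_d <- which(d > 0)
  both <- which(s > 0 & d > 0)
  ## triplets with duplicates summed by sparseMatrix(); both triangles emitted
  ti <- c(seq_len(n),
          has_s, s[has_s], s[has_s],
          has_d, d[has_d], d[has_d],
          s[both], d[both])
  tj <- c(seq_len(n),
          s[has_s], has_s, s[has_s],
          d[has_d], has_d, d[has_d],
          d[both], s[both])
  tx <- c(w,
          -0.5 * w[has_s], -0.5 * w[has_s], 0.25 * w[has_s],
          -0.5 * w[has_d], -0.5 * w[has_d], 0.25 * w[has_d],
          0.25 * w[both], 0.25 * w[both])
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  Ainv <- Matrix::forceSymmetric(Ainv)
  structure(Ainv, logdet_A = sum(log(di)))
}
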