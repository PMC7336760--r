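# Independent oracles used to validate the package's computations.
# Each is implemented from first principles, separately from the code path
# it checks.

blosum62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# Brute-force enumeration of every global alignment (affine gaps: a gap run
# of length L costs open + L * extend), maximizing the score. Exponential;
# for tiny sequences only.
enum_align_score <- function(a, b, mat = blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, "d"))
    if (i <= length(A))
      best <- max(best, -(if (prev == "u") ext else open + ext) +
                    rec(i + 1L, j, "u"))
    if (j <= length(B))
      best <- max(best, -(if (prev == "l") ext else open + ext) +
                    rec(i, j + 1L, "l"))
    best
  }
  rec(1L, 1L, "s")
}

# Plain-R Gotoh three-state dynamic programme for the same scoring model;
# independent of the C implementation under test.
gotoh_score <- function(a, b, mat = blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  if (m > 0) for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Horn quaternion method for optimal superposition RMSD: the maximal
# eigenvalue of the 4x4 key matrix gives the residual in closed form.
quaternion_rmsd <- function(A, B) {
  P <- sweep(as.matrix(A), 2, colMeans(A))
  Q <- sweep(as.matrix(B), 2, colMeans(B))
  R <- t(Q) %*% P
  K <- matrix(c(
    R[1, 1] + R[2, 2] + R[3, 3], R[2, 3] - R[3, 2], R[3, 1] - R[1, 3], R[1, 2] - R[2, 1],
    R[2, 3] - R[3, 2], R[1, 1] - R[2, 2] - R[3, 3], R[1, 2] + R[2, 1], R[3, 1] + R[1, 3],
    R[3, 1] - R[1, 3], R[1, 2] + R[2, 1], -R[1, 1] + R[2, 2] - R[3, 3], R[2, 3] + R[3, 2],
    R[1, 2] - R[2, 1], R[3, 1] + R[1, 3], R[2, 3] + R[3, 2], -R[1, 1] - R[2, 2] + R[3, 3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max((sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P), 0))
}

# Closed-form survival function of the chi-square distribution with 3
# degrees of freedom: S(x) = erfc(sqrt(x/2)) + sqrt(2x/pi) * exp(-x/2).
chisq3_sf <- function(x) {
  erfc <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
  erfc(sqrt(x / 2)) + sqrt(2 * x / pi) * exp(-x / 2)
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
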