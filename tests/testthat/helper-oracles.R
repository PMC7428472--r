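# independent brute-force distance correlation: explicit double loops,
# no shared code with the package internals
dcor_brute <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j]); b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- 0; dvx <- 0; dvy <- 0
  for (i in 1:n) for (j in 1:n) {
    dcov2 <- dcov2 + A[i, j] * B[i, j]
    dvx <- dvx + A[i, j]^2; dvy <- dvy + B[i, j]^2
  }
  dcov2 <- dcov2 / n^2; dvx <- dvx / n^2; dvy <- dvy / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}
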