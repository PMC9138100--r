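# shared helpers: small in-code fixtures for the unit tests

# random fully-numeric measurement matrix
rand_mm <- function(n = 6, p = 4, seed = 1) {
  set.seed(seed)
  v <- matrix(abs(rnorm(n * p, 10, 3)), n, p,
              dimnames = list(paste0("e", seq_len(n)),
                              paste0("v", seq_len(p))))
  measurement_matrix(v)
}

# write CSV lines to a temp file, return path
csv_file <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# brute-force Yoon importance by explicit path enumeration
yoon_bruteforce <- function(W1, W2) {
  m <- nrow(W1); o <- ncol(W2); n <- ncol(W1)
  P <- matrix(0, m, o)
  for (i in seq_len(m)) for (j in seq_len(o)) {
    s <- 0
    for (k in seq_len(n)) s <- s + W1[i, k] * W2[k, j]
    P[i, j] <- s
  }
  for (j in seq_len(o)) P[, j] <- 100 * P[, j] / sum(abs(P[, j]))
  P
}
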