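#' Principal component analysis of an assay matrix
#'
#' Eigendecomposition of the correlation (default) or covariance matrix of
#' the ND-resolved data. Correlation scaling is the right default for
#' mixed-unit assay panels: the variables here span five orders of magnitude
#' (ABTS in the thousands, caffeic acid around 0.01-0.07 mg/g), so a
#' covariance PCA would be dominated by the largest-scale assay.
#'
#' Component signs are made deterministic by flipping each component so its
#' largest-magnitude loading is positive.
#'
#' @param m a [measurement_matrix()] (or plain numeric matrix with dimnames).
#' @param nd ND policy (see [apply_nd_policy()]); `"zero"` keeps all rows,
#'   `"drop_rows"` restricts to complete profiles.
#' @param scale `"correlation"` (standardized variables) or `"covariance"`
#'   (centred only).
#' @return an object of class `chemo_pca`: list with `eigenvalues`
#'   (non-increasing), `explained_pct` (summing to 100), `loadings`
#'   (variables x components, orthonormal), `scores` (extracts x
#'   components) and `contributions_pct` from [variable_contributions()].
#' @examples
#' p <- fit_pca(fixture("merged17"), nd = "zero")
#' p$explained_pct[1:3]
#' @export
fit_pca <- function(m, nd = "zero", scale = c("correlation", "covariance")) {
  scale <- match.arg(scale)
  if (inherits(m, "measurement_matrix")) {
    m <- apply_nd_policy(m, nd)
    x <- m$values
  } else {
    x <- as.matrix(m)
  }
  if (nrow(x) < 3L) stop("need >= 3 extracts for PCA", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (scale == "correlation" && any(sds == 0))
    stop("constant column under correlation scaling: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  xs <- base::scale(x, center = TRUE, scale = (scale == "correlation"))
  S <- if (scale == "correlation") stats::cor(x) else stats::cov(x)
  ee <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ee$values, 0)  # clip eigenvalue noise at 0
  V <- ee$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(x), paste0("PC", seq_len(ncol(V))))
  scores <- xs %*% V
  res <- structure(list(eigenvalues = lambda,
                        explained_pct = 100 * lambda / sum(lambda),
                        loadings = V, scores = scores, scale = scale),
                   class = "chemo_pca")
  res$contributions_pct <- variable_contributions(res)
  res
}

#' @export
print.chemo_pca <- function(x, ...) {
  cat(sprintf("chemo_pca (%s): %d components\n", x$scale,
              length(x$eigenvalues)))
  cat("explained %:", paste(sprintf("%.2f", utils::head(x$explained_pct, 5L)),
                            collapse = ", "),
      if (length(x$explained_pct) > 5L) "...", "\n")
  invisible(x)
}

#' Per-variable contributions to each principal component
#'
#' The contribution of variable `i` to component `k` is the squared loading
#' as a share of the component's squared-loading total:
#' \deqn{100 \cdot v_{ik}^2 / \sum_i v_{ik}^2.} Contributions are magnitudes
#' summing to 100 per component; the loading sign (score direction) is
#' reported separately in `loadings`.
#'
#' @param p a [fit_pca()] result.
#' @return matrix (variables x components) of percentages.
#' @export
variable_contributions <- function(p) {
  stopifnot(inherits(p, "chemo_pca"))
  L2 <- p$loadings^2
  sweep(L2, 2L, colSums(L2), "/") * 100
}
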