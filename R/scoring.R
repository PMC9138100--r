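#' Min-max normalization of an assay matrix
#'
#' Maps every column onto `[0, 1]` with the affine transform
#' \deqn{\bar{x}_i = (x_i - \min_i x_i) / (\max_i x_i - \min_i x_i)}
#' where the extremes are taken over all retained extracts. Not-detected
#' cells are resolved first (by default to 0, the convention under which the
#' published ranking of the packaged tables is reproduced, with extremes
#' computed over all rows including the resolved zeros).
#'
#' @param m a [measurement_matrix()].
#' @param nd ND policy passed to [apply_nd_policy()] (`"zero"`,
#'   `"drop_rows"` or `"error"`).
#' @param constant_policy what to do with a constant column: `"error"`
#'   (default) or `"zero"` (normalize it to all zeros).
#' @return an object of class `normalized_matrix`: list with `values`
#'   (normalized matrix), `min` and `max` (per-column extremes used).
#' @examples
#' m <- fixture("table1")
#' nm <- minmax_normalize(m, nd = "zero")
#' range(nm$values)
#' @export
minmax_normalize <- function(m, nd = "zero",
                             constant_policy = c("error", "zero")) {
  stopifnot(inherits(m, "measurement_matrix"))
  constant_policy <- match.arg(constant_policy)
  m <- apply_nd_policy(m, nd)
  x <- m$values
  if (nrow(x) < 2L) stop("need >= 2 extracts to normalize", call. = FALSE)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  rng <- maxs - mins
  if (any(rng == 0)) {
    if (constant_policy == "error")
      stop("constant column: ",
           paste(colnames(x)[rng == 0], collapse = ", "), call. = FALSE)
    rng[rng == 0] <- 1  # constant columns map to 0
  }
  vals <- sweep(sweep(x, 2L, mins), 2L, rng, "/")
  structure(list(values = vals, min = mins, max = maxs),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d extracts x %d variables, values in [0, 1]\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Weighted standard scores of extracts
#'
#' The standard score of an extract is the weighted sum of its min-max
#' normalized assay values,
#' \deqn{SS_e = \sum_i w_i \bar{x}_{ei},}
#' with non-negative weights normalized to sum to 1 (equal weights by
#' default). An SS close to 1 marks an extract near the per-assay optimum on
#' every criterion; the maximum identifies the preparation with the best
#' overall profile.
#'
#' @param nm a [minmax_normalize()] result.
#' @param weights optional numeric weights, one per column of `nm` (named
#'   vectors are matched by column name); default equal. Rescaled to sum
#'   to 1.
#' @return an object of class `standard_score_result`: data.frame with
#'   columns `extract`, `ss` and `rank` (1 = best; ties keep input order),
#'   plus attributes `weights` and `contributions` (extract x variable matrix
#'   of \eqn{w_i \bar{x}_{ei}}).
#' @examples
#' ss <- standard_score(minmax_normalize(score_fixture9()))
#' head(ss[order(ss$rank), ])
#' @export
standard_score <- function(nm, weights = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- nm$values
  p <- ncol(x)
  if (is.null(weights)) weights <- rep(1 / p, p)
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), colnames(x)))
      stop("weight names do not match matrix columns", call. = FALSE)
    weights <- weights[colnames(x)]
  }
  if (length(weights) != p)
    stop("need exactly one weight per variable (", p, ")", call. = FALSE)
  if (any(weights < 0) || any(!is.finite(weights)) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  weights <- weights / sum(weights)
  names(weights) <- colnames(x)
  contrib <- sweep(x, 2L, weights, "*")
  ss <- rowSums(contrib)
  # stable: ties broken by input row order
  rk <- integer(length(ss))
  rk[order(-ss, seq_along(ss))] <- seq_along(ss)
  out <- data.frame(extract = rownames(x), ss = ss, rank = rk,
                    row.names = NULL)
  attr(out, "weights") <- weights
  attr(out, "contributions") <- contrib
  class(out) <- c("standard_score_result", "data.frame")
  out
}

#' Rank extracts by standard score
#'
#' @param ssr a [standard_score()] result.
#' @return character vector of extract labels in descending SS order
#'   (ties keep input order).
#' @export
rank_extracts <- function(ssr) {
  stopifnot(inherits(ssr, "standard_score_result"))
  ssr$extract[order(ssr$rank)]
}

#' The nine-variable ranking table of the packaged study
#'
#' Joins the packaged `table1` (TPh, TBc, TBx) and `table3` (DPPH, ABTS, RP,
#' BCB, AIA, AHgA) fixtures into the 20-extract x 9-variable matrix on which
#' the published standard-score ranking is computed. SFE rows carry ND for
#' the three phytochemical variables.
#'
#' @return a [measurement_matrix()] with 20 rows and 9 columns.
#' @export
score_fixture9 <- function() {
  m <- fixture("merged17")
  vars <- c("TPh", "TBc", "TBx", "DPPH", "ABTS", "RP", "BCB", "AIA", "AHgA")
  m[, vars]
}
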