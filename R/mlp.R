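# Single-hidden-layer perceptron surrogate and weight-path sensitivity.
#
# The network is Y = f1(W2 . f2(W1 . X + B1) + B2) on min-max normalized
# inputs and outputs; training minimises the sum of squared residuals (SOS)
# by multi-restart quasi-Newton (BFGS) with analytic gradients.

mlp_activations <- list(
  identity = list(f = function(x) x, df = function(x, fx) rep(1, length(x))),
  logistic = list(f = function(x) 1 / (1 + exp(-x)),
                  df = function(x, fx) fx * (1 - fx)),
  tanh = list(f = tanh, df = function(x, fx) 1 - fx^2),
  exponential = list(f = exp, df = function(x, fx) fx)
)

minmax_bounds <- function(x) {
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  if (any(maxs <= mins))
    stop("constant column cannot be min-max normalized: ",
         paste(colnames(x)[maxs <= mins], collapse = ", "), call. = FALSE)
  list(min = mins, max = maxs)
}

minmax_apply <- function(x, b) sweep(sweep(x, 2L, b$min), 2L, b$max - b$min, "/")
minmax_invert <- function(x, b) sweep(sweep(x, 2L, b$max - b$min, "*"), 2L, b$min, "+")

#' Construct a perceptron parameter set
#'
#' Holds the weight matrices and bias vectors of a one-hidden-layer network
#' together with the activation names and the per-channel min-max
#' normalization bounds under which the weights were trained.
#'
#' @param W1 input-to-hidden weight matrix (inputs x hidden).
#' @param B1 hidden bias vector.
#' @param W2 hidden-to-output weight matrix (hidden x outputs).
#' @param B2 output bias vector.
#' @param hidden_activation,output_activation one of `"identity"`,
#'   `"logistic"`, `"tanh"`, `"exponential"`.
#' @param x_bounds,y_bounds lists with `min`/`max` vectors per input/output
#'   channel (as produced during training); identity bounds (0/1) mean the
#'   network operates on raw values.
#' @return an object of class `mlp_parameters`.
#' @export
mlp_parameters <- function(W1, B1, W2, B2,
                           hidden_activation = "tanh",
                           output_activation = "identity",
                           x_bounds = NULL, y_bounds = NULL) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  B1 <- as.numeric(B1); B2 <- as.numeric(B2)
  if (ncol(W1) != length(B1) || nrow(W2) != ncol(W1) ||
      ncol(W2) != length(B2))
    stop("inconsistent layer dimensions", call. = FALSE)
  if (!hidden_activation %in% names(mlp_activations) ||
      !output_activation %in% names(mlp_activations))
    stop("unknown activation; use one of: ",
         paste(names(mlp_activations), collapse = ", "), call. = FALSE)
  ident <- function(p) list(min = rep(0, p), max = rep(1, p))
  if (is.null(x_bounds)) x_bounds <- ident(nrow(W1))
  if (is.null(y_bounds)) y_bounds <- ident(ncol(W2))
  if (any(x_bounds$max <= x_bounds$min) || any(y_bounds$max <= y_bounds$min))
    stop("normalization bounds need max > min per channel", call. = FALSE)
  structure(list(W1 = W1, B1 = B1, W2 = W2, B2 = B2,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 x_bounds = x_bounds, y_bounds = y_bounds),
            class = "mlp_parameters")
}

#' @export
print.mlp_parameters <- function(x, ...) {
  cat(sprintf("mlp_parameters: %d-%d-%d (%s hidden, %s output), %d weights+biases\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2),
              x$hidden_activation, x$output_activation,
              length(x$W1) + length(x$B1) + length(x$W2) + length(x$B2)))
  invisible(x)
}

# forward pass on the normalized scale
mlp_forward <- function(p, Xn) {
  f2 <- mlp_activations[[p$hidden_activation]]
  f1 <- mlp_activations[[p$output_activation]]
  A1 <- sweep(Xn %*% p$W1, 2L, p$B1, "+")
  H <- f2$f(A1)
  A2 <- sweep(H %*% p$W2, 2L, p$B2, "+")
  f1$f(A2)
}

#' Predict from a fitted perceptron
#'
#' @param object an [mlp_parameters()] object.
#' @param newdata matrix of inputs on the original (unnormalized) scale,
#'   one column per input channel.
#' @param ... unused.
#' @return matrix of predictions on the original output scale.
#' @export
predict.mlp_parameters <- function(object, newdata, ...) {
  Xn <- minmax_apply(as.matrix(newdata), object$x_bounds)
  minmax_invert(mlp_forward(object, Xn), object$y_bounds)
}

# pack/unpack the parameter vector for the optimizer
mlp_unpack <- function(theta, m, n, o) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(m * n)], m, n); i <- i + m * n
  B1 <- theta[i + seq_len(n)]; i <- i + n
  W2 <- matrix(theta[i + seq_len(n * o)], n, o); i <- i + n * o
  B2 <- theta[i + seq_len(o)]
  list(W1 = W1, B1 = B1, W2 = W2, B2 = B2)
}

#' Training configuration for the perceptron surrogate
#'
#' @param hidden integer vector of hidden-layer sizes to consider (1..64).
#' @param activations character vector of hidden-activation candidates.
#' @param restarts random initialisations per candidate (>= 1).
#' @param maxit BFGS iteration cap per restart.
#' @param tol relative convergence tolerance for the optimizer.
#' @param validation_fraction fraction of rows held out for topology
#'   selection (0 selects on training SOS).
#' @param seed integer seed controlling initialisation and the validation
#'   split.
#' @return a list of class `mlp_training_config`.
#' @export
training_config <- function(hidden = 5:20, activations = "tanh",
                            restarts = 20L, maxit = 2000L, tol = 1e-12,
                            validation_fraction = 0, seed = 1L) {
  hidden <- as.integer(hidden)
  if (any(hidden < 1L) || any(hidden > 64L))
    stop("hidden sizes must be in [1, 64]", call. = FALSE)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must be in [0, 1)", call. = FALSE)
  if (!all(activations %in% names(mlp_activations)))
    stop("unknown activation candidate", call. = FALSE)
  structure(list(hidden = hidden, activations = activations,
                 restarts = as.integer(restarts), maxit = as.integer(maxit),
                 tol = tol, validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "mlp_training_config")
}

#' Fit a one-hidden-layer perceptron by multi-restart quasi-Newton
#'
#' Inputs and outputs are min-max normalized to `[0, 1]`; the network
#' `Y = f1(W2 . f2(W1 . X + B1) + B2)` is then fitted by BFGS minimisation of
#' the sum of squared residuals (SOS) with analytic gradients, restarted from
#' `restarts` random initialisations; the restart with the lowest SOS wins.
#' The result is fully reproducible given `seed`.
#'
#' With few samples and many parameters the network interpolates the
#' training data; it is a surrogate for sensitivity analysis, not a
#' generalizing predictor.
#'
#' @param X,Y numeric matrices (rows = samples) of inputs and outputs on the
#'   original scale; fully numeric (resolve ND first).
#' @param hidden number of hidden neurons (>= 1).
#' @param hidden_activation,output_activation activation names (default
#'   tanh/identity).
#' @param restarts,maxit,tol,seed see [training_config()].
#' @param init_scale half-width of the uniform weight initialisation.
#' @param normalize min-max normalize inputs and outputs (default `TRUE`);
#'   set `FALSE` for data already on the unit scale, in which case identity
#'   bounds are stored and the weights act on the raw values.
#' @return list with `params` ([mlp_parameters()]) and `metrics`
#'   (list `pooled_r2`, `per_output_r2`, `sos` on the normalized scale,
#'   see [pooled_r2()]).
#' @examples
#' \donttest{
#' tch <- gen_teacher_network(3, 4, 2, n_samples = 30, seed = 1)
#' fit <- fit_mlp(tch$X, tch$Y, hidden = 4, restarts = 5, seed = 2)
#' fit$metrics$pooled_r2
#' }
#' @export
fit_mlp <- function(X, Y, hidden = 8L,
                    hidden_activation = "tanh",
                    output_activation = "identity",
                    restarts = 20L, maxit = 2000L, tol = 1e-12,
                    seed = 1L, init_scale = 0.5, normalize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || nrow(X) < 2L)
    stop("X and Y need the same row count >= 2", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite training data (resolve ND first)", call. = FALSE)
  hidden <- as.integer(hidden)
  if (hidden < 1L) stop("hidden must be >= 1", call. = FALSE)
  if (normalize) {
    xb <- minmax_bounds(X); yb <- minmax_bounds(Y)
  } else {
    xb <- list(min = rep(0, ncol(X)), max = rep(1, ncol(X)))
    yb <- list(min = rep(0, ncol(Y)), max = rep(1, ncol(Y)))
  }
  Xn <- minmax_apply(X, xb); Yn <- minmax_apply(Y, yb)
  m <- ncol(X); n <- hidden; o <- ncol(Y)
  f2 <- mlp_activations[[hidden_activation]]
  f1 <- mlp_activations[[output_activation]]
  npar <- m * n + n + n * o + o

  sos_fn <- function(theta) {
    p <- mlp_unpack(theta, m, n, o)
    A1 <- sweep(Xn %*% p$W1, 2L, p$B1, "+")
    H <- f2$f(A1)
    A2 <- sweep(H %*% p$W2, 2L, p$B2, "+")
    sum((f1$f(A2) - Yn)^2)
  }
  sos_gr <- function(theta) {
    p <- mlp_unpack(theta, m, n, o)
    A1 <- sweep(Xn %*% p$W1, 2L, p$B1, "+")
    H <- f2$f(A1)
    A2 <- sweep(H %*% p$W2, 2L, p$B2, "+")
    Yh <- f1$f(A2)
    D2 <- 2 * (Yh - Yn) * f1$df(A2, Yh)
    D1 <- (D2 %*% t(p$W2)) * f2$df(A1, H)
    c(as.vector(t(Xn) %*% D1), colSums(D1),
      as.vector(t(H) %*% D2), colSums(D2))
  }

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    theta0 <- stats::runif(npar, -init_scale, init_scale)
    opt <- stats::optim(theta0, sos_fn, sos_gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = tol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  pl <- mlp_unpack(best$par, m, n, o)
  rownames(pl$W1) <- colnames(X); colnames(pl$W2) <- colnames(Y)
  params <- mlp_parameters(pl$W1, pl$B1, pl$W2, pl$B2,
                           hidden_activation, output_activation,
                           x_bounds = xb, y_bounds = yb)
  metrics <- pooled_r2(Yn, mlp_forward(params, Xn))
  list(params = params, metrics = metrics)
}

#' Screen perceptron topologies
#'
#' Trains every (hidden size, hidden activation) candidate in the
#' configuration and selects the one with the smallest validation SOS (or
#' training SOS when `validation_fraction` is 0). The full screening table
#' is returned for audit, and the selection is exactly its row-wise minimum.
#'
#' @param X,Y training matrices as in [fit_mlp()].
#' @param cfg a [training_config()].
#' @return list with `best` (the selected `fit_mlp` result refitted on all
#'   rows), `table` (data.frame: hidden, activation, sos_train, sos_val,
#'   pooled_r2) and `selected` (row index of the winner).
#' @export
screen_topologies <- function(X, Y, cfg = training_config()) {
  stopifnot(inherits(cfg, "mlp_training_config"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  grid <- expand.grid(hidden = cfg$hidden, activation = cfg$activations,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty candidate set", call. = FALSE)
  set.seed(cfg$seed)
  n_val <- floor(cfg$validation_fraction * nrow(X))
  val_idx <- if (n_val > 0) sample(nrow(X), n_val) else integer(0)
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  tab <- grid
  tab$sos_train <- tab$sos_val <- tab$pooled_r2 <- NA_real_
  fits <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    fit <- fit_mlp(X[tr_idx, , drop = FALSE], Y[tr_idx, , drop = FALSE],
                   hidden = grid$hidden[k],
                   hidden_activation = grid$activation[k],
                   restarts = cfg$restarts, maxit = cfg$maxit,
                   tol = cfg$tol, seed = cfg$seed + k)
    fits[[k]] <- fit
    tab$sos_train[k] <- fit$metrics$sos
    tab$pooled_r2[k] <- fit$metrics$pooled_r2
    tab$sos_val[k] <- if (n_val > 0) {
      Yv <- minmax_apply(Y[val_idx, , drop = FALSE], fit$params$y_bounds)
      Xv <- minmax_apply(X[val_idx, , drop = FALSE], fit$params$x_bounds)
      sum((mlp_forward(fit$params, Xv) - Yv)^2)
    } else fit$metrics$sos
  }
  sel <- which.min(tab$sos_val)
  list(best = fits[[sel]], table = tab, selected = sel)
}

#' Pooled coefficient of determination
#'
#' \deqn{R^2 = 1 - SS_{res} / SS_{tot}} computed jointly over all output
#' channels (residuals and per-channel-mean deviations pooled), plus a
#' per-output breakdown and the raw SOS. Callers comparing networks should
#' pass values on the normalized scale.
#'
#' @param y_true,y_pred numeric matrices of equal shape (vectors accepted).
#' @return list of class `fit_metrics` with `pooled_r2`, `per_output_r2`
#'   and `sos`.
#' @export
pooled_r2 <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!identical(dim(y_true), dim(y_pred)))
    stop("y_true and y_pred must have the same shape", call. = FALSE)
  centred <- sweep(y_true, 2L, colMeans(y_true))
  ss_tot <- sum(centred^2)
  if (ss_tot == 0) stop("zero total variance in y_true", call. = FALSE)
  ss_res <- sum((y_true - y_pred)^2)
  per <- vapply(seq_len(ncol(y_true)), function(j) {
    st <- sum(centred[, j]^2)
    if (st == 0) NA_real_ else 1 - sum((y_true[, j] - y_pred[, j])^2) / st
  }, numeric(1))
  names(per) <- colnames(y_true)
  structure(list(pooled_r2 = 1 - ss_res / ss_tot, per_output_r2 = per,
                 sos = ss_res), class = "fit_metrics")
}

#' Yoon weight-path relative importance
#'
#' Decomposes the influence of each input on each output of a fitted
#' one-hidden-layer perceptron from its weights alone. The path sum of input
#' `i` to output `j` is \eqn{P_{ij} = \sum_k w^{(1)}_{ik} w^{(2)}_{kj}}
#' (biases excluded); the signed relative importance is
#' \deqn{RI_{ij} = 100 \cdot P_{ij} / \sum_i |P_{ij}|,}
#' so that per output the magnitudes sum to exactly 100%. Setting
#' `literal = TRUE` drops the absolute value in the denominator (plain sum
#' of signed path sums), an alternative reading under which magnitudes no
#' longer sum to 100 when path sums disagree in sign.
#'
#' @param p an [mlp_parameters()] object.
#' @param literal use the signed-sum denominator instead of the
#'   absolute-value one (default `FALSE`).
#' @return matrix (inputs x outputs) of signed percentages.
#' @examples
#' p <- mlp_parameters(W1 = matrix(c(1, -1), 2, 1), B1 = 0,
#'                     W2 = matrix(1), B2 = 0)
#' yoon_ri(p)  # +50 / -50
#' @export
yoon_ri <- function(p, literal = FALSE) {
  stopifnot(inherits(p, "mlp_parameters"))
  P <- p$W1 %*% p$W2
  denom <- if (literal) colSums(P) else colSums(abs(P))
  bad <- denom == 0
  if (any(bad))
    stop("undefined importance: all path sums zero for output ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  sweep(P, 2L, denom, "/") * 100
}
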