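# Synthetic-data generators: correlated assay matrices with not-detected
# blocks, absorbance panels with known pigment truth, and teacher networks.
# All generators are pure functions of (configuration, seed).

#' Configuration for a simulated extract-by-variable matrix
#'
#' Describes marginal means/sds per variable, a block correlation structure
#' (within-block correlation `rho`, zero between blocks), and an optional
#' rectangular block of cells forced to not-detected — the missingness
#' pattern of a study where one instrument sees only a subset of
#' preparations.
#'
#' @param n_extracts number of rows (extract preparations).
#' @param variables data.frame with columns `name`, `mean`, `sd` (and
#'   optionally `unit`); sds must be >= 0.
#' @param blocks list of `list(vars = <names>, rho = <within-block r>)`;
#'   variables not listed are uncorrelated. The implied correlation matrix
#'   must be positive semi-definite (validated here).
#' @param nd_block optional `list(rows = <indices>, cols = <names or
#'   indices>)` stamped ND after simulation.
#' @param seed integer seed.
#' @return a list of class `matrix_sim_config` (with the full correlation
#'   matrix in `$corr`).
#' @export
matrix_sim_config <- function(n_extracts, variables, blocks = list(),
                              nd_block = NULL, seed = 1L) {
  stopifnot(is.data.frame(variables),
            all(c("name", "mean", "sd") %in% colnames(variables)))
  if (any(variables$sd < 0)) stop("sds must be >= 0", call. = FALSE)
  if (anyDuplicated(variables$name)) stop("duplicate variable name", call. = FALSE)
  p <- nrow(variables)
  corr <- diag(p)
  dimnames(corr) <- list(variables$name, variables$name)
  for (b in blocks) {
    idx <- match(b$vars, variables$name)
    if (anyNA(idx)) stop("unknown variable in block: ",
                         paste(b$vars[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    if (b$rho < -1 || b$rho > 1) stop("rho must be in [-1, 1]", call. = FALSE)
    corr[idx, idx] <- b$rho
    diag(corr)[idx] <- 1
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("block specification implies a non-PSD correlation matrix",
         call. = FALSE)
  if (!is.null(nd_block)) {
    rows <- nd_block$rows
    cols <- nd_block$cols
    if (is.character(cols)) cols <- match(cols, variables$name)
    if (any(rows < 1 | rows > n_extracts) || anyNA(cols) ||
        any(cols < 1 | cols > p))
      stop("nd_block indices out of range", call. = FALSE)
    nd_block <- list(rows = as.integer(rows), cols = as.integer(cols))
  }
  structure(list(n_extracts = as.integer(n_extracts), variables = variables,
                 corr = corr, nd_block = nd_block, seed = as.integer(seed)),
            class = "matrix_sim_config")
}

#' Simulate a measurement matrix
#'
#' Draws rows from a multivariate normal with the configured correlation
#' structure, applies the per-variable means and sds, truncates at 0 (assay
#' values are non-negative; the induced bias is negligible when
#' mean >= 3 sd), and stamps the ND block. Identical seeds give identical
#' matrices.
#'
#' @param cfg a [matrix_sim_config()].
#' @return a [measurement_matrix()].
#' @examples
#' cfg <- matrix_sim_config(10,
#'   data.frame(name = c("a", "b"), mean = c(10, 5), sd = c(1, 1)),
#'   blocks = list(list(vars = c("a", "b"), rho = 0.8)))
#' gen_extract_matrix(cfg)
#' @export
gen_extract_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "matrix_sim_config"))
  set.seed(cfg$seed)
  p <- nrow(cfg$variables)
  Z <- MASS::mvrnorm(cfg$n_extracts, mu = rep(0, p), Sigma = cfg$corr)
  Z <- matrix(Z, cfg$n_extracts, p)
  X <- sweep(sweep(Z, 2L, cfg$variables$sd, "*"), 2L, cfg$variables$mean, "+")
  X <- pmax(X, 0)
  dimnames(X) <- list(sprintf("extract_%02d", seq_len(cfg$n_extracts)),
                      cfg$variables$name)
  nd <- matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X))
  if (!is.null(cfg$nd_block)) {
    nd[cfg$nd_block$rows, cfg$nd_block$cols] <- TRUE
    X[nd] <- NA_real_
  }
  units <- if ("unit" %in% colnames(cfg$variables))
    stats::setNames(cfg$variables$unit, cfg$variables$name)
  measurement_matrix(X, nd = nd, units = units)
}

#' A study-shaped default simulation configuration
#'
#' 20 extracts x 17 variables on the scales of the packaged beetroot tables
#' (e.g. ABTS in the thousands, caffeic acid in hundredths of mg/g), with a
#' positively correlated phenolic block, a positively correlated antioxidant
#' block, and an 8-row x 11-column ND block mimicking preparations whose
#' phytochemical panel is below detection. Values are scale-alike only; they
#' are not the study's numbers.
#'
#' @param seed integer seed.
#' @return a [matrix_sim_config()].
#' @export
sim_config_beetroot <- function(seed = 1L) {
  vars <- data.frame(
    name = c("TPh", "TBc", "TBx", "Gal", "pCat", "eCat", "Van", "Chl",
             "Cum", "Gen", "Caff", "DPPH", "ABTS", "RP", "BCB", "AIA",
             "AHgA"),
    mean = c(170, 3.2, 3.0, 1.2, 11.8, 0.7, 0.37, 0.1,
             0.025, 0.2, 0.025, 13, 3700, 170, 135, 24, 53),
    sd = c(45, 0.5, 0.45, 0.3, 1.3, 0.2, 0.1, 0.03,
           0.008, 0.04, 0.008, 4, 900, 50, 28, 8, 15),
    stringsAsFactors = FALSE)
  matrix_sim_config(
    20L, vars,
    blocks = list(
      list(vars = c("TPh", "Gal", "pCat", "eCat", "Van", "Chl", "Cum",
                    "Gen", "Caff"), rho = 0.6),
      list(vars = c("DPPH", "ABTS", "RP", "BCB"), rho = 0.5)),
    nd_block = list(rows = 13:20, cols = c("TPh", "TBc", "TBx", "Gal",
                                           "pCat", "eCat", "Van", "Chl",
                                           "Cum", "Gen", "Caff")),
    seed = seed)
}

#' Simulate absorbance panels from known pigment concentrations
#'
#' Inverts the betalain reduction: from target betacyanin/betaxanthin
#' concentrations (mg/100 mL) it computes the corrected absorbances
#' `X = C_bc A1pct_bet / (1000 F)` and `Y = C_bx A1pct_vul / (1000 F)`, adds
#' the chosen impurity absorbance `c`, solves the correction equations
#' backwards for the raw readings (`a = X/1.095 + c`, `Z = a - X`,
#' `b = Y + Z + X/3.1`) and finally adds Gaussian read noise. The generating
#' truth is returned alongside, so reduction accuracy can be measured.
#'
#' @param conc_bc,conc_bx true betacyanin and betaxanthin concentrations
#'   (mg/100 mL); recycled to a common length.
#' @param impurity impurity absorbance level `c` (AU).
#' @param F_dilution dilution factor, > 0.
#' @param noise_sd Gaussian noise sd (AU) added to each of a, b, c.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `panel` (data.frame `a538`, `a476`, `a600`, `F`) and
#'   `truth` (data.frame `betacyanin`, `betaxanthin`).
#' @examples
#' sim <- gen_absorbance_panel(9.5, 3.2, impurity = 0.05)
#' reduce_absorbance_panel(sim$panel)[, c("betacyanin", "betaxanthin")]
#' @export
gen_absorbance_panel <- function(conc_bc, conc_bx, impurity = 0.05,
                                 F_dilution = 25, noise_sd = 0, seed = 1L) {
  if (any(conc_bc < 0) || any(conc_bx < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (F_dilution <= 0) stop("dilution factor must be > 0", call. = FALSE)
  n <- max(length(conc_bc), length(conc_bx), length(impurity))
  conc_bc <- rep_len(conc_bc, n); conc_bx <- rep_len(conc_bx, n)
  impurity <- rep_len(impurity, n)
  k <- pigment_constants()
  X <- conc_bc * k[["betanin"]] / (F_dilution * 1000)
  Y <- conc_bx * k[["vulgaxanthin"]] / (F_dilution * 1000)
  a <- X / 1.095 + impurity
  Z <- a - X
  b <- Y + Z + X / 3.1
  if (any(a < 0) || any(b < 0) || any(impurity < 0))
    stop("negative implied absorbance", call. = FALSE)
  if (noise_sd > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(n, 0, noise_sd)
    b <- b + stats::rnorm(n, 0, noise_sd)
    impurity <- impurity + stats::rnorm(n, 0, noise_sd)
  }
  list(panel = data.frame(a538 = a, a476 = b, a600 = impurity,
                          F = rep(F_dilution, n)),
       truth = data.frame(betacyanin = conc_bc, betaxanthin = conc_bx))
}

#' Generate a teacher network and its noise-free dataset
#'
#' Draws a random one-hidden-layer perceptron and evaluates it on uniformly
#' sampled inputs. The returned dataset is exactly the teacher's forward
#' pass, so refitting it provides a ground-truth recovery test for both the
#' trainer and the weight-path sensitivity.
#'
#' @param n_inputs,n_hidden,n_outputs layer sizes (>= 1).
#' @param n_samples rows of the sampled dataset.
#' @param weight_scale half-width of the uniform weight distribution.
#' @param hidden_activation,output_activation activation names.
#' @param seed integer seed.
#' @return list with `params` ([mlp_parameters()]), `X` (samples x inputs,
#'   uniform on `[0, 1]`) and `Y` (the teacher's outputs).
#' @export
gen_teacher_network <- function(n_inputs, n_hidden, n_outputs,
                                n_samples = 50L, weight_scale = 1,
                                hidden_activation = "tanh",
                                output_activation = "identity",
                                seed = 1L) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, n_outputs >= 1)
  set.seed(seed)
  r <- function(k) stats::runif(k, -weight_scale, weight_scale)
  params <- mlp_parameters(
    W1 = matrix(r(n_inputs * n_hidden), n_inputs, n_hidden),
    B1 = r(n_hidden),
    W2 = matrix(r(n_hidden * n_outputs), n_hidden, n_outputs),
    B2 = r(n_outputs),
    hidden_activation = hidden_activation,
    output_activation = output_activation)
  X <- matrix(stats::runif(n_samples * n_inputs), n_samples, n_inputs,
              dimnames = list(NULL, paste0("x", seq_len(n_inputs))))
  Y <- mlp_forward(params, X)
  colnames(Y) <- paste0("y", seq_len(n_outputs))
  list(params = params, X = X, Y = Y)
}
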