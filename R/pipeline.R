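#' Run the full extract-screening pipeline
#'
#' Orchestrates the analysis end to end: load or simulate the measurement
#' matrix, rank the extracts by weighted standard scores, run a
#' correlation-matrix PCA, fit the perceptron surrogate on the extracts with
#' complete phytochemical profiles, and decompose its input influence with
#' the Yoon weight-path method. Per-stage artifacts (CSV/JSON) plus a
#' versioned summary JSON are written when `out_dir` is given; the summary
#' is also returned. Re-running with the same inputs and seed writes
#' identical artifacts.
#'
#' @param input a fixture name (see [fixture()]), a path to a CSV readable
#'   by [load_matrix()], a [matrix_sim_config()] to simulate from, or a
#'   [measurement_matrix()].
#' @param out_dir optional output directory (created if needed).
#' @param stages subset of `c("score", "pca", "ann", "sensitivity")`;
#'   `"sensitivity"` requires `"ann"`.
#' @param nd_score,nd_pca ND policies for the ranking and PCA stages
#'   (default `"zero"`); the perceptron stage always drops incomplete rows.
#' @param score_variables columns to rank on (default: the nine ranking
#'   variables when present, otherwise all columns).
#' @param weights optional weight vector for [standard_score()].
#' @param ann_inputs,ann_outputs column names for the surrogate (defaults:
#'   the phytochemical panel as inputs, the bioactivity assays as outputs,
#'   intersected with the matrix).
#' @param hidden,restarts,maxit perceptron settings (see [fit_mlp()]).
#' @param pca_scale `"correlation"` or `"covariance"`.
#' @param seed integer seed for every stochastic stage.
#' @param verbose log stage progress to the console.
#' @return the summary list, invisibly: `schema_version`, `seed`, ND
#'   policies, `ranking` (extract/ss/rank with units), `pca`
#'   (explained %, contributions), `ann` (fit metrics) and `ri` (signed %
#'   importance, inputs x outputs).
#' @examples
#' \donttest{
#' s <- run_pipeline("merged17", stages = "score")
#' s$ranking[1, ]
#' }
#' @export
run_pipeline <- function(input = "merged17", out_dir = NULL,
                         stages = c("score", "pca", "ann", "sensitivity"),
                         nd_score = "zero", nd_pca = "zero",
                         score_variables = NULL, weights = NULL,
                         ann_inputs = NULL, ann_outputs = NULL,
                         hidden = 8L, restarts = 20L, maxit = 2000L,
                         pca_scale = "correlation", seed = 1L,
                         verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("sensitivity" %in% stages && !"ann" %in% stages)
    stop("stage 'sensitivity' requires stage 'ann'", call. = FALSE)
  say <- function(...) if (verbose) message("[chemoscore] ", ...)

  # fail-fast input validation before any stage runs
  m <- if (inherits(input, "measurement_matrix")) {
    input
  } else if (inherits(input, "matrix_sim_config")) {
    say("simulating matrix (seed ", input$seed, ")")
    gen_extract_matrix(input)
  } else if (is.character(input) && length(input) == 1L) {
    if (input %in% c("table1", "table2", "table3", "merged17")) {
      say("loading fixture ", input)
      fixture(input)
    } else {
      if (!file.exists(input))
        stop("input CSV not found: ", input, call. = FALSE)
      say("loading ", input)
      load_matrix(input)
    }
  } else stop("unsupported input", call. = FALSE)

  bioactivity <- c("DPPH", "ABTS", "RP", "BCB", "AIA", "AHgA")
  nine <- c("TPh", "TBc", "TBx", bioactivity)
  summary <- list(schema_version = "1.0",
                  input = if (is.character(input)) input else class(input)[1L],
                  seed = as.integer(seed),
                  nd_policy = list(score = nd_score, pca = nd_pca,
                                   ann = "drop_rows"),
                  n_extracts = nrow(m$values),
                  variables = colnames(m$values),
                  units = as.list(if (is.null(m$units)) character() else m$units))
  artifacts <- character()
  emit_csv <- function(df, name) {
    if (is.null(out_dir)) return()
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    artifacts <<- c(artifacts, p)
  }

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if ("score" %in% stages) {
    sv <- score_variables
    if (is.null(sv)) sv <- if (all(nine %in% colnames(m$values))) nine
                           else colnames(m$values)
    say("scoring on ", length(sv), " variables (nd = ", nd_score, ")")
    nm <- minmax_normalize(m[, sv], nd = nd_score)
    ssr <- standard_score(nm, weights = weights)
    ord <- ssr[order(ssr$rank), ]
    summary$ranking <- ord
    summary$score_weights <- as.list(attr(ssr, "weights"))
    emit_csv(ord, "scores.csv")
  }

  if ("pca" %in% stages) {
    say("PCA (", pca_scale, " scaling, nd = ", nd_pca, ")")
    p <- fit_pca(m, nd = nd_pca, scale = pca_scale)
    summary$pca <- list(explained_pct = p$explained_pct,
                        eigenvalues = p$eigenvalues)
    emit_csv(data.frame(variable = rownames(p$loadings), p$loadings,
                        check.names = FALSE), "pca_loadings.csv")
    emit_csv(data.frame(extract = rownames(p$scores), p$scores,
                        check.names = FALSE), "pca_scores.csv")
    emit_csv(data.frame(variable = rownames(p$contributions_pct),
                        p$contributions_pct, check.names = FALSE),
             "pca_contributions.csv")
  }

  if ("ann" %in% stages) {
    mm <- apply_nd_policy(m, "drop_rows")
    xi <- ann_inputs
    yi <- ann_outputs
    if (is.null(xi)) xi <- setdiff(colnames(mm$values), bioactivity)
    if (is.null(yi)) yi <- intersect(bioactivity, colnames(mm$values))
    if (length(xi) == 0L || length(yi) == 0L)
      stop("cannot infer surrogate inputs/outputs; set ann_inputs/ann_outputs",
           call. = FALSE)
    say("fitting ", length(xi), "-", hidden, "-", length(yi),
        " perceptron on ", nrow(mm$values), " complete extracts")
    fit <- fit_mlp(mm$values[, xi, drop = FALSE],
                   mm$values[, yi, drop = FALSE],
                   hidden = hidden, restarts = restarts, maxit = maxit,
                   seed = seed)
    summary$ann <- list(topology = c(length(xi), hidden, length(yi)),
                        inputs = xi, outputs = yi,
                        pooled_r2 = fit$metrics$pooled_r2,
                        per_output_r2 = as.list(fit$metrics$per_output_r2),
                        sos = fit$metrics$sos)
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "ann_model.json")
      jsonlite::write_json(
        list(W1 = fit$params$W1, B1 = fit$params$B1, W2 = fit$params$W2,
             B2 = fit$params$B2,
             hidden_activation = fit$params$hidden_activation,
             output_activation = fit$params$output_activation,
             x_bounds = fit$params$x_bounds, y_bounds = fit$params$y_bounds),
        p, digits = NA, auto_unbox = TRUE)
      artifacts <- c(artifacts, p)
    }
    if ("sensitivity" %in% stages) {
      say("Yoon weight-path sensitivity")
      ri <- yoon_ri(fit$params)
      summary$ri <- ri
      emit_csv(data.frame(input = rownames(ri), ri, check.names = FALSE),
               "relative_importance.csv")
    }
  }

  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, p, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows", matrix = "rowmajor")
    artifacts <- c(artifacts, p)
    say("wrote ", length(artifacts), " artifacts to ", out_dir)
  }
  invisible(summary)
}
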