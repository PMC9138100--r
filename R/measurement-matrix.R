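#' Extract-by-variable measurement matrix
#'
#' The central container of the package: a rectangular table of non-negative
#' assay means, one row per extract preparation and one column per assay
#' variable. Cells may carry an optional standard deviation and may be marked
#' "not detected" (ND). ND is a first-class state, distinct from both zero and
#' missing: a compound that an instrument could not detect is resolved
#' differently depending on the downstream stage (see [apply_nd_policy()]).
#'
#' @param values numeric matrix with extract row names and variable column
#'   names; ND cells hold `NA` and must be flagged in `nd`.
#' @param nd logical matrix of the same shape marking ND cells; defaults to
#'   all-`FALSE` (in which case `values` must be fully numeric).
#' @param sd optional numeric matrix of per-cell standard deviations (`NA`
#'   where no replicate spread was recorded); must be non-negative.
#' @param units optional named character vector of unit strings per variable.
#'
#' @return An object of class `measurement_matrix`: a list with elements
#'   `values`, `nd`, `sd` and `units`.
#' @examples
#' m <- measurement_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("e1", "e2"), c("v1", "v2"))))
#' n_nd(m)
#' @export
measurement_matrix <- function(values, nd = NULL, sd = NULL, units = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  storage.mode(values) <- "double"
  rn <- rownames(values); cn <- colnames(values)
  if (is.null(rn) || is.null(cn))
    stop("`values` must have extract row names and variable column names",
         call. = FALSE)
  if (anyDuplicated(rn))
    stop("duplicate extract label: ", rn[duplicated(rn)][1L], call. = FALSE)
  if (anyDuplicated(cn))
    stop("duplicate variable name: ", cn[duplicated(cn)][1L], call. = FALSE)
  if (is.null(nd)) nd <- is.na(values) & FALSE
  if (!is.matrix(nd) || !is.logical(nd) || !identical(dim(nd), dim(values)))
    stop("`nd` must be a logical matrix matching `values`", call. = FALSE)
  dimnames(nd) <- dimnames(values)
  if (any(nd & !is.na(values)))
    stop("ND cells must hold NA in `values`", call. = FALSE)
  if (any(is.na(values) & !nd))
    stop("missing (non-ND) cells are not allowed", call. = FALSE)
  num <- values[!nd]
  if (any(!is.finite(num)))
    stop("non-finite measurement value", call. = FALSE)
  if (any(num < 0))
    stop("negative measurement value", call. = FALSE)
  if (!is.null(sd)) {
    if (!is.matrix(sd) || !identical(dim(sd), dim(values)))
      stop("`sd` must be a numeric matrix matching `values`", call. = FALSE)
    storage.mode(sd) <- "double"
    dimnames(sd) <- dimnames(values)
    if (any(sd[!is.na(sd)] < 0)) stop("negative sd", call. = FALSE)
  }
  if (!is.null(units)) {
    units <- units[cn]
    names(units) <- cn
  }
  structure(list(values = values, nd = nd, sd = sd, units = units),
            class = "measurement_matrix")
}

#' @export
dim.measurement_matrix <- function(x) dim(x$values)

#' @export
dimnames.measurement_matrix <- function(x) dimnames(x$values)

#' Number of not-detected cells
#' @param m a [measurement_matrix()]
#' @return integer count of ND cells.
#' @export
n_nd <- function(m) {
  stopifnot(inherits(m, "measurement_matrix"))
  sum(m$nd)
}

#' @export
print.measurement_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("measurement_matrix: %d extracts x %d variables (%d ND cells)\n",
              d[1L], d[2L], sum(x$nd)))
  cat("variables:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.measurement_matrix <- function(x, ...) x$values

#' @export
as.data.frame.measurement_matrix <- function(x, ...) {
  data.frame(extract = rownames(x$values), x$values,
             check.names = FALSE, row.names = NULL)
}

#' Row/column subsetting keeps the class and the cell flags aligned
#' @param x a [measurement_matrix()]
#' @param i,j row and column indices (extract labels, variable names or
#'   positions)
#' @return a [measurement_matrix()] restricted to the selected cells.
#' @export
`[.measurement_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  measurement_matrix(x$values[i, j, drop = FALSE],
                     nd = x$nd[i, j, drop = FALSE],
                     sd = if (!is.null(x$sd)) x$sd[i, j, drop = FALSE],
                     units = if (!is.null(x$units)) x$units[colnames(x$values)[j]])
}

# Parse one CSV cell: a plain number, "nd", or "mean ± sd" (also "+/-").
# Returns list(mean, sd, nd). Decimal commas are rejected rather than
# silently reinterpreted.
parse_cell <- function(cell, row, col) {
  s <- trimws(cell)
  fail <- function(why) {
    stop(sprintf("malformed cell at row '%s', column '%s': %s (%s)",
                 row, col, encodeString(cell), why), call. = FALSE)
  }
  if (!nzchar(s)) fail("empty cell")
  if (tolower(s) == "nd") return(list(mean = NA_real_, sd = NA_real_, nd = TRUE))
  if (grepl(",", s, fixed = TRUE)) fail("decimal comma not supported")
  parts <- strsplit(s, "±|\\+/-")[[1L]]
  parts <- trimws(parts)
  if (length(parts) < 1L || length(parts) > 2L || any(!nzchar(parts)))
    fail("expected number, 'nd', or 'mean ± sd'")
  num <- suppressWarnings(as.numeric(parts))
  if (any(is.na(num))) fail("not a number")
  if (num[1L] < 0) fail("negative value")
  if (length(num) == 2L && num[2L] < 0) fail("negative sd")
  list(mean = num[1L], sd = if (length(num) == 2L) num[2L] else NA_real_,
       nd = FALSE)
}

#' Read a measurement matrix from CSV
#'
#' Expects a UTF-8 CSV with a header row whose first column holds the extract
#' label; every other column is an assay variable. Cells are decimal numbers,
#' the token `nd` (not detected), or `mean ± sd` strings (the ASCII dialect
#' `mean +/- sd` is also accepted). Decimal commas are rejected to avoid
#' silent locale bugs.
#'
#' @param path path to the CSV file.
#' @param schema either `"infer"` (take variables from the header) or a
#'   character vector of expected variable names, enforced in order.
#' @return a [measurement_matrix()] preserving the file's row and column
#'   order.
#' @seealso [write_matrix()] for the inverse operation.
#' @export
load_matrix <- function(path, schema = "infer") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8", strip.white = TRUE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("parse error: no data rows/columns in ", path, call. = FALSE)
  labels <- df[[1L]]
  if (anyDuplicated(labels))
    stop("duplicate extract label: ", labels[duplicated(labels)][1L],
         call. = FALSE)
  vars <- colnames(df)[-1L]
  if (!identical(schema, "infer") && !identical(vars, as.character(schema)))
    stop("column schema mismatch: expected ",
         paste(schema, collapse = ", "), call. = FALSE)
  nr <- nrow(df); nc <- length(vars)
  vals <- matrix(NA_real_, nr, nc, dimnames = list(labels, vars))
  sds <- vals
  nds <- matrix(FALSE, nr, nc, dimnames = list(labels, vars))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cell <- parse_cell(df[i, j + 1L], labels[i], vars[j])
      vals[i, j] <- cell$mean
      sds[i, j] <- cell$sd
      nds[i, j] <- cell$nd
    }
  }
  if (all(is.na(sds))) sds <- NULL
  measurement_matrix(vals, nd = nds, sd = sds)
}

#' Write a measurement matrix to CSV or JSON
#'
#' The CSV form round-trips through [load_matrix()] exactly, including ND
#' cells and standard deviations. The JSON form mirrors the same schema
#' (one record per extract) for consumption outside R.
#'
#' @param m a [measurement_matrix()].
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("csv", "json")) {
  stopifnot(inherits(m, "measurement_matrix"))
  format <- match.arg(format)
  num <- function(x) sprintf("%.15g", x)
  cells <- matrix("", nrow(m$values), ncol(m$values))
  for (j in seq_len(ncol(m$values))) {
    for (i in seq_len(nrow(m$values))) {
      cells[i, j] <- if (m$nd[i, j]) "nd"
      else if (!is.null(m$sd) && !is.na(m$sd[i, j]))
        paste0(num(m$values[i, j]), " ± ", num(m$sd[i, j]))
      else num(m$values[i, j])
    }
  }
  if (format == "csv") {
    df <- data.frame(extract = rownames(m$values), cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("extract", colnames(m$values))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    recs <- lapply(seq_len(nrow(m$values)), function(i) {
      row <- as.list(cells[i, ])
      names(row) <- colnames(m$values)
      c(list(extract = rownames(m$values)[i]), row)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Packaged beetroot extract assay tables
#'
#' Transcriptions of the published assay tables for the 20 beetroot extract
#' preparations (ultrasound, Soxhlet, cold and supercritical-CO2 extraction
#' with various solvents), shipped with the package:
#' \describe{
#'   \item{`table1`}{20 extracts x total phenolics (TPh, mg GAE/g), total
#'     betacyanins (TBc, mg BE/100 g) and total betaxanthins (TBx,
#'     mg VE/100 g); the 8 supercritical (SFE) rows are all ND.}
#'   \item{`table2`}{12 non-SFE extracts x 8 HPLC phenolic compounds
#'     (Gal, pCat, eCat, Van, Chl, Cum, Gen, Caff, mg/g) plus their printed
#'     `Total`.}
#'   \item{`table3`}{20 extracts x antioxidant and pharmacological assays
#'     (DPPH, ABTS, RP, BCB in umol TE/100 g; AIA, AHgA in percent
#'     inhibition).}
#'   \item{`merged17`}{the 20 x 17 join of the three (the `Total` column is
#'     dropped); SFE rows are ND for the 11 phytochemical variables.}
#' }
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"merged17"`.
#' @return a [measurement_matrix()].
#' @examples
#' fixture("table1")$values["SE 50% EtOH", "TPh"]
#' @export
fixture <- function(name = c("table1", "table2", "table3", "merged17")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "chemoscore",
                                  mustWork = TRUE)
  units1 <- c(TPh = "mg GAE/g", TBc = "mg BE/100 g", TBx = "mg VE/100 g")
  units2 <- c(Gal = "mg/g", pCat = "mg/g", eCat = "mg/g", Van = "mg/g",
              Chl = "mg/g", Cum = "mg/g", Gen = "mg/g", Caff = "mg/g",
              Total = "mg/g")
  units3 <- c(DPPH = "umol TE/100 g", ABTS = "umol TE/100 g",
              RP = "umol TE/100 g", BCB = "umol TE/100 g",
              AIA = "% inhibition", AHgA = "% inhibition")
  with_units <- function(m, u) {
    m$units <- u[colnames(m$values)]
    m
  }
  if (name == "table1") return(with_units(load_matrix(path("table1.csv")), units1))
  if (name == "table2") return(with_units(load_matrix(path("table2.csv")), units2))
  if (name == "table3") return(with_units(load_matrix(path("table3.csv")), units3))
  t1 <- fixture("table1"); t2 <- fixture("table2"); t3 <- fixture("table3")
  ext <- rownames(t1$values)
  comp <- setdiff(colnames(t2$values), "Total")
  vars <- c(colnames(t1$values), comp, colnames(t3$values))
  vals <- matrix(NA_real_, length(ext), length(vars),
                 dimnames = list(ext, vars))
  nds <- matrix(FALSE, length(ext), length(vars), dimnames = dimnames(vals))
  sds <- vals
  put <- function(m, cols) {
    for (e in rownames(m$values)) {
      vals[e, cols] <<- m$values[e, cols]
      nds[e, cols] <<- m$nd[e, cols]
      if (!is.null(m$sd)) sds[e, cols] <<- m$sd[e, cols]
    }
  }
  put(t1, colnames(t1$values))
  put(t2, comp)
  put(t3, colnames(t3$values))
  # extracts absent from the HPLC table carry ND for the compound columns
  miss <- setdiff(ext, rownames(t2$values))
  nds[miss, comp] <- TRUE
  vals[miss, comp] <- NA_real_
  measurement_matrix(vals, nd = nds, sd = sds,
                     units = c(units1, units2[comp], units3))
}

#' Resolve not-detected cells before a numeric stage
#'
#' Three policies are supported, because different stages of the analysis
#' want different resolutions: the ranking stage treats "below detection" as
#' a zero contribution (`"zero"`), model fitting on complete profiles drops
#' extracts with any ND cell (`"drop_rows"`), and strict stages refuse ND
#' input altogether (`"error"`).
#'
#' @param m a [measurement_matrix()].
#' @param policy `"zero"`, `"drop_rows"` or `"error"`.
#' @return a [measurement_matrix()] with no ND cells. Numeric cells are
#'   never altered.
#' @export
apply_nd_policy <- function(m, policy = c("zero", "drop_rows", "error")) {
  stopifnot(inherits(m, "measurement_matrix"))
  policy <- match.arg(policy)
  if (!any(m$nd)) return(m)
  if (policy == "error") {
    idx <- which(m$nd, arr.ind = TRUE)
    cells <- paste0("(", rownames(m$values)[idx[, 1L]], ", ",
                    colnames(m$values)[idx[, 2L]], ")")
    stop("ND cells present: ", paste(utils::head(cells, 10L), collapse = ", "),
         if (length(cells) > 10L) ", ...", call. = FALSE)
  }
  if (policy == "zero") {
    vals <- m$values
    vals[m$nd] <- 0
    return(measurement_matrix(vals, sd = m$sd, units = m$units))
  }
  keep <- rowSums(m$nd) == 0L
  if (!any(keep)) stop("drop_rows removed every extract", call. = FALSE)
  m[which(keep), ]
}
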