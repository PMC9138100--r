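test_that("CSV cells parse as numbers, nd markers and mean ± sd pairs", {
  path <- csv_file(c(
    "extract,TPh,TBc,TBx",
    "UE 30% MeOH,135.80,2.67 ± 0.09,2.59 +/- 0.08",
    "SFE A,nd,nd,0.5"))
  m <- load_matrix(path)
  expect_equal(m$values["UE 30% MeOH", "TPh"], 135.80)
  expect_equal(m$values["UE 30% MeOH", "TBc"], 2.67)
  expect_equal(m$sd["UE 30% MeOH", "TBc"], 0.09)
  expect_equal(m$sd["UE 30% MeOH", "TBx"], 0.08)  # ASCII +/- dialect
  # nd is a marker, not zero and not missing
  expect_true(m$nd["SFE A", "TPh"])
  expect_true(is.na(m$values["SFE A", "TPh"]))
  expect_false(m$nd["SFE A", "TBx"])
  expect_equal(n_nd(m), 2L)
})

test_that("malformed input is rejected with the offending cell named", {
  expect_error(load_matrix(csv_file(c("extract,a", "e1,abc"))),
               "row 'e1', column 'a'")
  expect_error(load_matrix(csv_file(c("extract,a", "e1,\"1,5\""))),
               "decimal comma")
  expect_error(load_matrix(csv_file(c("extract,a", "e1,-3"))), "negative")
  expect_error(load_matrix(csv_file(c("extract,a", "e1,1", "e1,2"))),
               "duplicate extract label")
  expect_error(load_matrix(csv_file(character())), "parse error|no data|empty")
  expect_error(load_matrix(tempfile()), "not found")
})

test_that("write_matrix/load_matrix round-trips values, sds and ND cells", {
  m <- rand_mm(5, 3, seed = 42)
  sd <- m$values * 0.05
  sd[1, 1] <- NA  # one cell without replicate spread
  vals <- m$values
  vals[2, 3] <- NA
  nd <- matrix(FALSE, 5, 3, dimnames = dimnames(vals))
  nd[2, 3] <- TRUE
  sd[2, 3] <- NA
  m <- measurement_matrix(vals, nd = nd, sd = sd)
  path <- tempfile(fileext = ".csv")
  write_matrix(m, path)
  m2 <- load_matrix(path)
  expect_equal(m2$values, m$values)
  expect_equal(m2$nd, m$nd)
  expect_equal(m2$sd, m$sd)
  # JSON export mirrors the same schema
  pj <- tempfile(fileext = ".json")
  write_matrix(m, pj, format = "json")
  rec <- jsonlite::read_json(pj)
  expect_length(rec, 5L)
  expect_equal(rec[[2]]$v3, "nd")
})

test_that("packaged tables hold the transcribed assay values", {
  t1 <- fixture("table1")
  expect_equal(dim(t1), c(20L, 3L))
  expect_equal(t1$values["SE 50% EtOH", "TPh"], 226.80)
  expect_equal(t1$values["SE 30% MeOH", "TBc"], 4.17)
  expect_equal(t1$sd["UE 30% MeOH", "TBc"], 0.09)
  expect_true(all(t1$nd[13:20, ]))  # SFE rows all ND
  expect_equal(n_nd(t1), 24L)

  t3 <- fixture("table3")
  expect_equal(dim(t3), c(20L, 6L))
  expect_equal(t3$values["SFE PrOH 40 °C 300 bar", "DPPH"], 20.39)
  expect_equal(t3$values["CE 50% MeOH", "AIA"], 42.86)
  expect_equal(n_nd(t3), 0L)

  m17 <- fixture("merged17")
  expect_equal(dim(m17), c(20L, 17L))
  expect_equal(n_nd(m17), 88L)  # 8 SFE rows x 11 phytochemical variables
  expect_equal(m17$units[["ABTS"]], "umol TE/100 g")
  expect_error(fixture("table9"))
})

test_that("per-compound sums reproduce the printed HPLC totals", {
  t2 <- fixture("table2")
  expect_equal(dim(t2), c(12L, 9L))
  comp <- setdiff(colnames(t2$values), "Total")
  sums <- rowSums(t2$values[, comp])
  expect_true(all(abs(sums - t2$values[, "Total"]) <= 0.01))
  expect_equal(t2$values["UE 30% MeOH", "Total"], 12.09)
  expect_equal(t2$values["SE 50% EtOH", "Total"], 18.60)
})

test_that("ND policies resolve not-detected cells as documented", {
  t1 <- fixture("table1")
  z <- apply_nd_policy(t1, "zero")
  expect_equal(n_nd(z), 0L)
  expect_true(all(z$values[13:20, ] == 0))
  # numeric cells are never changed
  expect_equal(z$values[1:12, ], t1$values[1:12, ])

  d <- apply_nd_policy(fixture("merged17"), "drop_rows")
  expect_equal(nrow(d$values), 12L)
  expect_equal(n_nd(d), 0L)

  expect_error(apply_nd_policy(t1, "error"), "ND cells present")

  full <- rand_mm()
  for (p in c("zero", "drop_rows", "error"))
    expect_equal(apply_nd_policy(full, p)$values, full$values)
})

test_that("the container enforces its invariants", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(measurement_matrix(v), "measurement_matrix")
  v2 <- v; v2[1, 1] <- -1
  expect_error(measurement_matrix(v2), "negative")
  expect_error(measurement_matrix(matrix(1:4, 2, 2)), "row names")
  v3 <- v; rownames(v3) <- c("a", "a")
  expect_error(measurement_matrix(v3), "duplicate")
  # subsetting keeps flags aligned
  m <- fixture("table1")[13:14, c("TPh", "TBc")]
  expect_equal(n_nd(m), 4L)
})
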