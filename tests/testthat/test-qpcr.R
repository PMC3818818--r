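make_ct <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], pathway = "x", condition = r[[2]],
               time_min = r[[3]], replicate = 1, ct = r[[4]])
  }))
  ct_table(df)
}

test_that("ct_table validates ranges and uniqueness", {
  expect_error(make_ct(list(list("A", "control", 0, 45))), "\\(0, 40\\]")
  df <- rbind(data.frame(gene = "A", pathway = "x", condition = "control",
                         time_min = 0, replicate = 1, ct = 20),
              data.frame(gene = "A", pathway = "x", condition = "control",
                         time_min = 0, replicate = 1, ct = 21))
  expect_error(ct_table(df), "duplicate")
})

test_that("one-cycle difference doubles the fold change", {
  ct <- make_ct(list(
    list("G", "control", 0, 25), list("G", "EMT", 0, 24),
    list("POLB", "control", 0, 20), list("POLB", "EMT", 0, 20)))
  fc <- ddct_fold_change(ct)
  expect_equal(unname(fc["G", "control_t0"]), 1)
  expect_equal(unname(fc["G", "EMT_t0"]), 2)
})

test_that("equal shifts of gene and reference cancel (fold change 1)", {
  ct <- make_ct(list(
    list("G", "control", 0, 25), list("G", "EMT", 0, 28),
    list("POLB", "control", 0, 20), list("POLB", "EMT", 0, 23)))
  fc <- ddct_fold_change(ct)
  expect_equal(unname(fc["G", "EMT_t0"]), 1)
})

test_that("adding a constant to every Ct of a column leaves fold changes unchanged", {
  base <- list(
    list("G", "control", 0, 25), list("G", "control", 60, 23),
    list("H", "control", 0, 28), list("H", "control", 60, 29),
    list("POLB", "control", 0, 20), list("POLB", "control", 60, 20))
  fc1 <- ddct_fold_change(make_ct(base))
  shifted <- lapply(base, function(r) {
    if (r[[3]] == 60) r[[4]] <- r[[4]] + 3.7
    r
  })
  fc2 <- ddct_fold_change(make_ct(shifted))
  expect_equal(fc1, fc2, tolerance = 1e-12)
})

test_that("replicates are averaged on the Ct scale before quantification", {
  df <- rbind(
    data.frame(gene = "G", pathway = "x", condition = "control", time_min = 0,
               replicate = 1:2, ct = c(24, 26)),
    data.frame(gene = "POLB", pathway = "x", condition = "control",
               time_min = 0, replicate = 1, ct = 20),
    data.frame(gene = "G", pathway = "x", condition = "EMT", time_min = 0,
               replicate = 1, ct = 24),
    data.frame(gene = "POLB", pathway = "x", condition = "EMT", time_min = 0,
               replicate = 1, ct = 20))
  fc <- ddct_fold_change(ct_table(df))
  expect_equal(unname(fc["G", "EMT_t0"]), 2)   # 25 -> 24 is one cycle
})

test_that("missing inputs propagate and missing reference blanks the column", {
  ct <- make_ct(list(
    list("G", "control", 0, 25), list("G", "EMT", 0, NA),
    list("H", "control", 0, 24), list("H", "EMT", 0, 23),
    list("POLB", "control", 0, 20), list("POLB", "EMT", 0, 20)))
  fc <- ddct_fold_change(ct)
  expect_true(is.na(fc["G", "EMT_t0"]))
  expect_false(is.na(fc["H", "EMT_t0"]))

  ct2 <- make_ct(list(
    list("G", "control", 0, 25), list("G", "EMT", 0, 23),
    list("POLB", "control", 0, 20), list("POLB", "EMT", 0, NA)))
  expect_warning(fc2 <- ddct_fold_change(ct2), "reference gene Ct missing")
  expect_true(is.na(fc2["G", "EMT_t0"]))
})

test_that("Z-score transform matches hand-computed rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(1, NA, 3))
  z <- zscore_transform(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(unname(z["c", ]), c(-1 / sqrt(2), NA, 1 / sqrt(2)),
               tolerance = 1e-4)
})

test_that("rows with fewer than two observations become entirely missing", {
  m <- rbind(a = c(1, NA, NA), b = c(1, 2, 4))
  z <- zscore_transform(m)
  expect_true(all(is.na(z["a", ])))
  expect_false(anyNA(z["b", ]))
})

test_that("observed entries of every Z-scored row have mean 0 and sample SD 1", {
  set.seed(5)
  m <- matrix(rlnorm(120), 10, 12)
  m[sample(length(m), 15)] <- NA
  z <- zscore_transform(m)
  for (i in seq_len(nrow(z))) {
    obs <- z[i, !is.na(z[i, ])]
    expect_lt(abs(mean(obs)), 1e-9)
    expect_equal(sd(obs), 1, tolerance = 1e-9)
  }
})

test_that("Z-scoring is idempotent", {
  set.seed(6)
  m <- matrix(rlnorm(60), 6, 10)
  z1 <- zscore_transform(m)
  z2 <- zscore_transform(structure(unclass(z1), value_kind = "fold_change"))
  expect_equal(unclass(z2), unclass(z1), tolerance = 1e-9)
})

test_that("empty matrices and wrong kinds are rejected", {
  expect_error(zscore_transform(matrix(numeric(0), 0, 0)), "non-empty")
  z <- zscore_transform(rbind(c(1, 2, 3)))
  expect_error(zscore_transform(z), "fold changes")
})

test_that("expression matrices round-trip through TSV with NA markers", {
  m <- rbind(a = c(1.5, NA), b = c(0.25, 4))
  colnames(m) <- c("control_t0", "EMT_t0")
  tmp <- tempfile(fileext = ".tsv")
  write_expr_matrix(m, tmp)
  expect_identical(sum(grepl("NA", readLines(tmp))), 1L)
  back <- read_expr_matrix(tmp)
  expect_equal(unclass(back), m, ignore_attr = TRUE)
})
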