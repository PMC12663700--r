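test_that("codebook parses from JSON and YAML with branch rules intact", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"variables": [
    {"id": "Q1", "section": "s1", "vtype": "categorical",
     "categories": ["yes", "no"]},
    {"id": "Q2", "section": "s1", "vtype": "continuous",
     "branch": {"parent": "Q1", "values": ["yes"]}},
    {"id": "Q3", "section": "s1", "vtype": "text"}]}', tmp)
  cb <- load_codebook(tmp)
  expect_s3_class(cb, "codebook")
  expect_length(cb, 3L)
  expect_equal(cb[["Q2"]]$branch$parent, "Q1")
  expect_equal(cb[["Q2"]]$branch$values, "yes")

  tmpy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("variables:",
               "  - id: Q1", "    section: s1", "    vtype: categorical",
               "    categories: [yes2, no2]",
               "  - id: Q2", "    section: s1", "    vtype: continuous",
               "    branch: {parent: Q1, values: [yes2]}"), tmpy)
  cby <- load_codebook(tmpy)
  expect_equal(cby[["Q2"]]$branch$parent, "Q1")

  # write_codebook round-trips
  out <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb, out)
  expect_equal(load_codebook(out), cb)
})

test_that("malformed codebooks raise typed validation errors", {
  v <- function(...) variable_spec(...)
  expect_error(codebook(list(v("Q5", "s", "continuous"),
                             v("Q5", "s", "continuous"))),
               "duplicate.*Q5", class = "msvdq_codebook_error")
  expect_error(codebook(list(v("Q1", "s", "continuous",
                               branch = list(parent = "Q99", values = "x")))),
               "Q99", class = "msvdq_codebook_error")
  # cyclic chain A -> B -> A
  expect_error(codebook(list(
    v("A", "s", "categorical", c("x", "y"),
      branch = list(parent = "B", values = "x")),
    v("B", "s", "categorical", c("x", "y"),
      branch = list(parent = "A", values = "x")))),
    "cyclic", class = "msvdq_codebook_error")
  # parent must be categorical/ordinal
  expect_error(codebook(list(
    v("A", "s", "continuous"),
    v("B", "s", "continuous", branch = list(parent = "A", values = "1")))),
    "not categorical", class = "msvdq_codebook_error")
  expect_error(v("Q1", "s", "categorical", "only_one"),
               ">= 2 distinct", class = "msvdq_codebook_error")
  expect_error(v("Q1", "s", "continuous", c("a", "b")),
               "must not declare", class = "msvdq_codebook_error")
})

test_that("dataset loading validates cells and preserves blanks", {
  cb <- toy_codebook()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(toy_dataset(), tmp)
  ds <- load_dataset(tmp, cb)
  expect_s3_class(ds, "msv_dataset")
  expect_equal(nrow(ds), 4L)
  expect_setequal(unique(dataset_sites(ds)), c("A", "B"))
  expect_true(is.na(ds$Q2[2L]))

  # invalid category names its coordinates
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,Q1", "A,yes", "A,maybe"), bad)
  cb2 <- codebook(list(variable_spec("Q1", "s", "categorical",
                                     c("yes", "no"))))
  expect_error(load_dataset(bad, cb2), "maybe.*row 2.*Q1",
               class = "msvdq_dataset_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("site,Q1", empty)
  expect_error(load_dataset(empty, cb2), "no records",
               class = "msvdq_dataset_error")

  unk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,Q1,Q77", "A,yes,1"), unk)
  expect_error(load_dataset(unk, cb2), "Q77",
               class = "msvdq_dataset_error")
})

test_that("write/load round-trip reproduces cells and blank positions", {
  sim <- generate(sim_config(
    sites = data.frame(label = c("A", "B"), n = c(12, 9)),
    sections = list(list(name = "s1", n_vars = 6L, n_gated = 2L)),
    missing_rate = 0.2, seed = 42))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$dataset, tmp)
  back <- load_dataset(tmp, sim$codebook)
  expect_identical(as.data.frame(back), as.data.frame(sim$dataset))
})

test_that("demographic summary reproduces cohort-table arithmetic", {
  cb <- codebook(list(
    variable_spec("age", "s", "continuous"),
    variable_spec("sex", "s", "categorical", c("female", "male"))))
  mk <- function(ns) {
    df <- data.frame(
      site = rep(paste0("S", seq_along(ns)), ns),
      age = as.character(rep(45, sum(ns))),
      sex = rep(c("female", "male"), length.out = sum(ns)),
      stringsAsFactors = FALSE)
    msv_dataset(df, cb)
  }
  dem <- summarize_demographics(mk(c(142, 158, 197, 155)), "age", "sex")
  expect_equal(dem$share[1:4], c(21.8, 24.2, 30.2, 23.8))
  expect_equal(dem$share[dem$site == "Total"], 100.0)
  # shares sum to 100 within rounding slack
  expect_lt(abs(sum(dem$share[1:4]) - 100), 0.2)

  dem1 <- summarize_demographics(mk(10), "age", "sex")
  expect_equal(dem1$share[1L], 100.0)

  # sample-SD convention
  df <- data.frame(site = c("S1", "S1"), age = c("40", "50"),
                   sex = c("female", "male"), stringsAsFactors = FALSE)
  dem2 <- summarize_demographics(msv_dataset(df, cb), "age", "sex")
  expect_equal(dem2$age_mean[1L], 45.0)
  expect_equal(dem2$age_sd[1L], 7.0710678, tolerance = 1e-7)

  # a site with no non-missing ages reports NA, not an error
  df$age <- NA_character_
  dem3 <- summarize_demographics(msv_dataset(df, cb), "age", "sex")
  expect_true(is.na(dem3$age_mean[1L]))
})
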