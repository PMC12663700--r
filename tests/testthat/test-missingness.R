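test_that("blank cells split into ordinary vs not-applicable by skip logic", {
  cb <- codebook(list(
    variable_spec("smoker", "risk", "categorical", c("no", "yes")),
    variable_spec("cigs", "risk", "continuous",
                  branch = list(parent = "smoker", values = "yes")),
    variable_spec("age", "socio", "continuous")))
  df <- data.frame(site = rep("A", 4),
                   smoker = c("no", "yes", "yes", NA),
                   cigs = c(NA, NA, "10", NA),
                   age = c("40", "50", "60", "70"),
                   stringsAsFactors = FALSE)
  m <- categorize(msv_dataset(df, cb))
  expect_equal(unname(m[, "cigs"]), c(1L, 0L, 2L, 0L))
  expect_equal(unname(m[, "smoker"]), c(2L, 2L, 2L, 0L))
  expect_equal(unname(m[, "age"]), rep(2L, 4))
  # codes partition the cells
  expect_equal(sum(m == 0) + sum(m == 1) + sum(m == 2), length(m))
  # code 1 only in branch-gated columns
  expect_false(any(m[, c("smoker", "age")] == 1L))
})

test_that("blank-parent cascades follow the inherit rule", {
  cb <- codebook(list(
    variable_spec("p", "s", "categorical", c("no", "yes")),
    variable_spec("c1", "s", "categorical", c("a", "b"),
                  branch = list(parent = "p", values = "yes")),
    variable_spec("c2", "s", "continuous",
                  branch = list(parent = "c1", values = "a"))))
  df <- data.frame(site = rep("A", 3),
                   p = c("no", NA, "yes"),
                   c1 = c(NA, NA, NA),
                   c2 = c(NA, NA, NA), stringsAsFactors = FALSE)
  ds <- msv_dataset(df, cb)
  m <- categorize(ds)
  # row 1: c1 not applicable (p = no); its child inherits code 1
  expect_equal(unname(m[1L, ]), c(2L, 1L, 1L))
  # row 2: p itself ordinarily blank -> children unknowable -> ordinary
  expect_equal(unname(m[2L, ]), c(0L, 0L, 0L))
  # row 3: p = yes, c1 ordinarily blank, c2's applicability unknowable
  expect_equal(unname(m[3L, ]), c(2L, 0L, 0L))
  # the all-ordinary mode never cascades 1s through blank parents: c1
  # keeps its direct not-applicable code but its blank child stays 0
  m2 <- categorize(ds, cascade = "ordinary")
  expect_equal(unname(m2[1L, ]), c(2L, 1L, 0L))
})

test_that("categorization is independent of row order", {
  sim <- generate(sim_config(
    sites = data.frame(label = c("A", "B"), n = c(25, 25)),
    sections = list(list(name = "s1", n_vars = 8L, n_gated = 3L)),
    missing_rate = 0.2, seed = 44))
  m <- categorize(sim$dataset)
  perm <- sample(nrow(sim$dataset))
  dfp <- as.data.frame(sim$dataset)[perm, ]
  mp <- categorize(msv_dataset(dfp, sim$codebook))
  expect_equal(unclass(mp), unclass(m)[perm, ], ignore_attr = TRUE)
})

test_that("code-1 cells match the generator's structural blanks when parents are observed", {
  for (s in 1:10) {
    sim <- generate(sim_config(
      sites = data.frame(label = c("A", "B"), n = c(30, 30)),
      sections = list(list(name = "s1", n_vars = 12L, n_gated = 4L)),
      missing_rate = 0.15, seed = s))
    m <- categorize(sim$dataset)
    cb <- sim$codebook
    for (id in names(cb)) {
      br <- cb[[id]]$branch
      if (is.null(br)) next
      p_obs <- !is.na(sim$dataset[[br$parent]])
      expect_identical(m[p_obs, id] == 1L,
                       sim$truth$structural[p_obs, id])
    }
  }
})

test_that("completeness summary reproduces the printed cohort arithmetic", {
  # build a 652 x 130 category matrix with the study's exact counts:
  # 8116 ordinary, 6260 not-applicable, 70384 observed
  specs <- lapply(1:130, function(j) {
    if (j <= 20)
      variable_spec(paste0("Q", j), if (j <= 10) "quality of life" else "other",
                    "continuous",
                    branch = list(parent = "G", values = "yes"))
    else if (j == 130)
      variable_spec("G", "other", "categorical", c("no", "yes"))
    else
      variable_spec(paste0("Q", j), "other", "continuous")
  })
  cb <- codebook(specs)
  codes <- rep(2L, 84760L)
  codes[seq_len(8116L)] <- 0L
  codes[8117L:(8116L + 6260L)] <- 1L
  m <- matrix(2L, 652L, 130L,
              dimnames = list(NULL, vapply(specs, `[[`, "", "id")))
  # place code-1 only inside the 20 gated columns, code-0 anywhere else
  m[, 1:20] <- 1L             # 13040 cells; trim back to 6260
  excess <- which(m == 1L)[-seq_len(6260L)]
  m[excess] <- 2L
  zero_slots <- which(m == 2L)[seq_len(8116L)]
  m[zero_slots] <- 0L
  mm <- structure(m, site = rep(c("A", "B", "C", "D"),
                                c(142L, 158L, 197L, 155L)),
                  codebook = cb, class = c("missing_matrix", "matrix"))
  cs <- completeness_summary(mm)
  expect_equal(cs$overall$total, 84760L)
  expect_equal(cs$overall$n_observed, 70384L)
  expect_equal(cs$overall$pct_observed_whole, 83)
  expect_equal(cs$overall$pct_not_applicable, 7.4)
  expect_equal(cs$overall$pct_ordinary, 9.6)

  # quality-of-life style slices through the same summary path:
  # 100 blanks of 1576 cells -> 6.3%; 10 of 3640 -> 0.3%
  slice_pct <- function(n_missing, n_cells, n_rows) {
    p <- n_cells / n_rows
    cbs <- codebook(lapply(seq_len(p), function(j)
      variable_spec(paste0("V", j), "quality of life", "continuous")))
    ms <- matrix(2L, n_rows, p, dimnames = list(NULL, names(cbs)))
    ms[seq_len(n_missing)] <- 0L
    mms <- structure(ms, site = rep("S", n_rows), codebook = cbs,
                     class = c("missing_matrix", "matrix"))
    completeness_summary(mms)$overall$pct_ordinary
  }
  expect_equal(slice_pct(100L, 1576L, 197L), 6.3)
  expect_equal(slice_pct(10L, 3640L, 455L), 0.3)
})

test_that("categorical table keeps levels and flags constants", {
  sim <- generate(sim_config(
    sites = data.frame(label = c("A", "B"), n = c(15, 15)),
    sections = list(list(name = "s1", n_vars = 6L, n_gated = 2L)),
    missing_rate = 0.3, seed = 77))
  m <- categorize(sim$dataset)
  tab <- to_categorical_table(m)
  expect_true(all(unlist(tab) %in% c("ordinary", "not_applicable",
                                     "observed")))
  expect_equal(unname(as.matrix(tab) == "observed"), unname(m == 2L))

  all2 <- structure(matrix(2L, 5, 3, dimnames = list(NULL, c("a", "b", "c"))),
                    site = rep("A", 5), codebook = NULL,
                    class = c("missing_matrix", "matrix"))
  t2 <- to_categorical_table(all2)
  expect_true(all(attr(t2, "constant")))
})

test_that("replica not-applicable share sits near the study's 7.4%", {
  sim <- reference_cohort()
  m <- categorize(sim$dataset)
  frac1 <- 100 * mean(m == 1L)
  expect_lt(abs(frac1 - 7.4), 1.5)
})
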