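test_that("parental frequencies follow the Balding-Nichols parametrisation", {
  model <- sample_parental_frequencies(4, 195, 0.25, seed = 11)
  expect_equal(dim(model$p), c(4, 195))
  expect_true(all(model$p >= 0 & model$p <= 1))
  # Beta(a, b) with a = p_anc (1-F)/F has mean p_anc and variance
  # F p_anc (1 - p_anc); check moments across many markers
  big <- sample_parental_frequencies(1, 20000, 0.25, seed = 5)
  z <- (big$p[1, ] - big$p_ancestral) /
    sqrt(0.25 * big$p_ancestral * (1 - big$p_ancestral))
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(stats::sd(z) - 1), 0.02)
  # divergence -> 0: populations collapse onto the ancestral frequency
  low <- sample_parental_frequencies(4, 500, 0.001, seed = 7)
  expect_lt(max(abs(sweep(low$p, 2, low$p_ancestral))), 0.15)
  expect_error(sample_parental_frequencies(4, 10, 1.2, seed = 1),
               "divergence")
  expect_error(sample_parental_frequencies(0, 10, 0.2, seed = 1), ">= 1")
})

test_that("simulated bands follow the dominant diploid observation model", {
  # degenerate frequencies pin the band state
  m1 <- sample_parental_frequencies(2, 50, 0.2, seed = 1)
  m1$p[, ] <- 1
  anc <- true_ancestry(matrix(c(1, 0), 1, 2))
  expect_true(all(unclass(simulate_matrix(m1, anc, seed = 2)) == 1L))
  m1$p[, ] <- 0
  expect_true(all(unclass(simulate_matrix(m1, anc, seed = 2)) == 0L))
  # band frequency for a pure diploid individual is 1 - (1 - p)^2
  mk <- sample_parental_frequencies(1, 50000, 0.2, seed = 3)
  mk$p[1, ] <- 0.3
  mat <- simulate_matrix(mk, true_ancestry(matrix(1, 1, 1)), seed = 4)
  f <- mean(unclass(mat) == 1L)
  expect_lt(abs(f - (1 - 0.49)), 3 * sqrt(0.51 * 0.49 / 50000))
  # copy-number-aware banding: tetraploid scoring uses 1 - (1 - p)^4
  anc4 <- true_ancestry(matrix(1, 1, 1), copy_number = 4L)
  mat4 <- simulate_matrix(mk, anc4, seed = 5)
  f4 <- mean(unclass(mat4) == 1L)
  expect_lt(abs(f4 - (1 - 0.7^4)), 3 * sqrt(0.76 * 0.24 / 50000))
  expect_error(simulate_matrix(mk, true_ancestry(matrix(c(.5, .5), 1, 2)),
                               seed = 1), "does not match")
})

test_that("fragment elimination zeroes one parent at the right markers", {
  model <- sample_parental_frequencies(4, 100, 0.25, seed = 9)
  before <- model$p
  mod <- apply_fragment_elimination(model, 0.14, 2, seed = 10)
  zeroed <- which(mod$p[2, ] == 0)
  expect_equal(length(mod$eliminated_markers), 14L)  # round(0.14 * 100)
  expect_true(all(colnames(mod$p)[zeroed] %in% mod$eliminated_markers))
  # other parents untouched
  expect_equal(mod$p[-2, ], before[-2, ])
  expect_equal(apply_fragment_elimination(model, 0, 1, seed = 1)$p, before)
  all_gone <- apply_fragment_elimination(model, 1, 3, seed = 2)
  expect_true(all(all_gone$p[3, ] == 0))
  expect_error(apply_fragment_elimination(model, 0.1, 9, seed = 1),
               "parent index")
})

test_that("missing-data injection is calibrated and reproducible", {
  model <- sample_parental_frequencies(4, 195, 0.25, seed = 20)
  anc <- pure_ancestry(4, 7)                    # 28 individuals
  mat <- simulate_matrix(model, anc, seed = 21)
  expect_identical(inject_missing(mat, 0, seed = 1), mat)
  wm <- inject_missing(mat, 0.04, seed = 22)
  n <- length(wm)
  frac <- mean(is.na(wm))
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.04) / n
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  expect_identical(inject_missing(mat, 0.5, seed = 7),
                   inject_missing(mat, 0.5, seed = 7))
  expect_error(inject_missing(mat, 1, seed = 1), "rate")
})

test_that("the marker filter drops strictly-more-than-threshold missing", {
  vals <- matrix(1L, 20, 3, dimnames = list(NULL, c("keep0", "keep5", "drop10")))
  vals[1, 2] <- NA          # 1/20 = 5% missing: retained (not "more than")
  vals[1:2, 3] <- NA        # 2/20 = 10% missing: removed
  filtered <- filter_markers(aflp_matrix(vals))
  expect_equal(colnames(filtered), c("keep0", "keep5"))
  # max_missing = 1 is the identity; the filter is idempotent
  m <- aflp_matrix(vals)
  expect_equal(dim(filter_markers(m, 1)), dim(m))
  expect_identical(filter_markers(filter_markers(m)), filter_markers(m))
})

test_that("csv and STRUCTURE files round-trip including missing cells", {
  syn <- synth_aflp_preset(n_pure = 2, n_hybrid = 2, L = 30, seed = 3)
  mat <- syn$raw
  expect_gt(sum(is.na(mat)), 0)
  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  write_matrix(mat, tmp_csv, "csv")
  back <- read_matrix(tmp_csv, "csv")
  expect_equal(unclass(back), unclass(mat))
  tmp_str <- withr::local_tempfile(fileext = ".str")
  write_matrix(mat, tmp_str, "structure", pop = syn$pop)
  back2 <- read_matrix(tmp_str, "structure")
  expect_equal(attr(back2, "pop"), syn$pop)
  attr(back2, "pop") <- NULL
  expect_equal(unclass(back2), unclass(mat))
  # -9 encodes missing on disk
  expect_true(any(grepl("-9", readLines(tmp_str))))
  # ragged files fail loudly, naming the row
  lines <- readLines(tmp_str)
  lines[3] <- paste(lines[3], "0")
  writeLines(lines, tmp_str)
  expect_error(read_matrix(tmp_str, "structure"), "row 3")
})

test_that("the default preset has the study dimensions", {
  syn <- synth_aflp_preset(seed = 3)
  expect_equal(nrow(syn$matrix), 27)            # 20 pure + 7 admixed
  expect_equal(syn$model$K, 4)
  expect_true(ncol(syn$matrix) <= 200 && ncol(syn$matrix) >= 150)
  expect_true(all(colMeans(is.na(syn$matrix)) <= 0.05))
  expect_true(all(unclass(syn$matrix) %in% c(0L, 1L, NA)))
  expect_equal(rowSums(syn$ancestry$Q_true), rep(1, 27),
               ignore_attr = TRUE)
})
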