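test_that("symmetry index matches hand-computed values and guards", {
  expect_equal(symmetry_index(0.7, 0.7), 0)
  expect_equal(symmetry_index(3, 1), 25)
  expect_equal(symmetry_index(1, 0), 50)
  expect_equal(symmetry_index(0, 0), 0)  # symmetric absence of motion
  expect_equal(symmetry_index(1, 3, signed = TRUE), -25)
  expect_error(symmetry_index(-1, 2), "non-negative")
})

test_that("symmetry index properties hold over randomized non-negative pairs", {
  set.seed(20)
  f_l <- rexp(2000, rate = 0.5)
  f_r <- rexp(2000, rate = 0.5)
  k <- runif(2000, 0.01, 100)
  c_val <- symmetry_index(f_l, f_r)
  expect_true(all(c_val >= 0 & c_val <= 50))
  expect_equal(symmetry_index(k * f_l, k * f_r), c_val, tolerance = 1e-9)
  expect_equal(symmetry_index(f_r, f_l), c_val)
  expect_equal(symmetry_index(f_l, f_l), rep(0, 2000))
})

test_that("global criterion reduces to the index and averages features", {
  # one feature, one pair
  fset1 <- list(P = matrix(c(3, 1), 1, 2, dimnames = list("std", NULL)),
                feature_names = "std", T = rbind(L = c(1, 0), R = c(0, 1)),
                bands = list(), M = 1L, Q = 2L, side = c("L", "R"),
                pair_index = c(1L, 1L), fs = 100)
  class(fset1) <- "feature_set"
  res <- global_criterion(fset1, psi = "std")
  expect_equal(res$C, 25)
  expect_equal(dim(res$c), c(1L, 1L))

  # two features with per-feature mean indices 10 and 20 average to 15
  pm <- rbind(a = c(3, 6, 9, 2, 4, 6),          # every pair scores 10
              b = c(7, 14, 3.5, 3, 6, 1.5))     # every pair scores 20
  fset2 <- list(P = pm, feature_names = c("a", "b"),
                T = rbind(L = c(1, 1, 1, 0, 0, 0), R = c(0, 0, 0, 1, 1, 1)),
                bands = list(), M = 3L, Q = 6L,
                side = rep(c("L", "R"), each = 3), pair_index = rep(1:3, 2),
                fs = 100)
  class(fset2) <- "feature_set"
  res2 <- global_criterion(fset2, psi = c("a", "b"))
  expect_equal(unname(colMeans(res2$c)), c(10, 20))
  expect_equal(res2$C, 15)
  expect_error(global_criterion(fset2, psi = "zzz"), "zzz")
  expect_error(global_criterion(fset2, psi = character(0)), "psi")
})

test_that("perfectly mirrored synthetic pairs score C = 0 end to end", {
  expect_equal(synth_criterion(asym_amp = 0, asym_freq = 0, noise_sd = 0), 0)
})

test_that("noise-free criterion responds monotonically to amplitude asymmetry", {
  cs <- vapply(c(0, 0.1, 0.2, 0.4), function(d) {
    synth_criterion(asym_amp = d, noise_sd = 0)
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("feature presets split frequency-domain and mixed-domain sets", {
  fset <- synth_fs(noise_sd = 0.1, seed = 2, M = 4)
  expect_equal(psi_preset(fset, "frequency"),
               grep("^bandpower", fset$feature_names, value = TRUE))
  expect_true("std" %in% psi_preset(fset, "mixed"))
  expect_false("mean" %in% psi_preset(fset, "mixed"))
})

test_that("aggregation reproduces the published reference summaries", {
  tab <- reference_symmetry()
  expect_equal(round(tab$row_means[["15"]], 1), 1.1)
  expect_equal(round(tab$row_means[["6"]], 1), 4.3)
  expect_equal(round(tab$col_means[["E6"]], 1), 3.4)
  expect_equal(round(tab$col_stds[["E6"]], 1), 2.4)
})

test_that("aggregate_table handles duplicates, gaps, and single cells", {
  mk <- function(ind, ex, C) {
    structure(list(c = matrix(C, 1, 1), C = C, psi = "std",
                   exercise_id = ex, individual_id = ind, degenerate = 0L),
              class = "symmetry_result")
  }
  tab <- aggregate_table(list(mk("a", "E1", 1), mk("a", "E2", 3), mk("b", "E1", 5)))
  expect_equal(unname(tab$row_means["a"]), 2)
  expect_true(is.na(tab$values["b", "E2"]))
  expect_equal(unname(tab$col_means["E1"]), 3)  # NA cells excluded
  expect_error(aggregate_table(list(mk("a", "E1", 1), mk("a", "E1", 2))),
               "duplicate")
  single <- aggregate_table(list(mk("a", "E1", 2.5)))
  expect_equal(unname(single$row_means), 2.5)
  expect_true(is.na(single$col_stds[["E1"]]))  # sample std undefined for n = 1
})

test_that("symmetry tables render and serialize with summaries attached", {
  tab <- reference_symmetry()
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_symmetry_table(tab, csv)
  write_symmetry_table(tab, js, provenance = list(config_hash = "abc"))
  lines <- readLines(csv)
  expect_match(lines[1], "^individual,E1")
  expect_match(lines[1], ",Mean$")
  expect_length(lines, 1 + 16 + 2)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$provenance$config_hash, "abc")
  expect_equal(round(parsed$col_means[["E6"]], 1), 3.4)
})
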