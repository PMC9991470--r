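# Generator: class-conditional marginals, censoring, reproducibility,
# planted-outlier mechanics.

test_that("generation is reproducible and respects basic invariants", {
  cfg <- generator_config(c("free-range" = 20, "caged" = 15), seed = 7)
  a <- generate_profiles(cfg = cfg)
  b <- generate_profiles(cfg = cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(generate_profiles(cfg = generator_config(c("free-range" = 20, "caged" = 15), seed = 8))),
    as.data.frame(a)))

  expect_equal(nrow(a), 35L)
  expect_equal(unname(table(as.character(a$class))["free-range"]), 20L)
  expect_true(all(conc_matrix(a) >= 0))
  expect_true(all(a$weight_g > 0.5))
  expect_equal(attr(a, "provenance")$seed, 7)
})

test_that("marginal distributions match the reference table at n = 10,000", {
  n <- 10000
  cfg <- generator_config(c("free-range" = n, "caged" = n), seed = 101)
  tab <- generate_profiles(cfg = cfg)
  X <- conc_matrix(tab)
  dists <- class_distributions()
  for (cls in c("free-range", "caged")) {
    d <- dists[[cls]]
    Xc <- X[as.character(tab$class) == cls, , drop = FALSE]
    for (j in seq_len(nrow(d))) {
      if (d$nondetect[j]) next
      # channels with mean < 2.5 SD are visibly truncation-biased; the
      # others must sit within 3 standard errors of the nominal mean
      if (d$mean[j] < 2.5 * d$sd[j]) next
      expect_lt(abs(mean(Xc[, j]) - d$mean[j]), 3 * d$sd[j] / sqrt(n),
                label = sprintf("%s %s mean", cls, d$element[j]))
    }
  }
  # headline example: free-range Se ~ 4.22 (1.68)
  se <- X[as.character(tab$class) == "free-range", "Se"]
  expect_lt(abs(mean(se) - 4.22), 0.07)  # 4 SE + truncation allowance
  expect_lt(abs(stats::sd(se) - 1.68), 0.06)
})

test_that("nondetect and degenerate channels behave exactly", {
  tab <- generate_profiles(cfg = generator_config(c("free-range" = 500, "caged" = 500), seed = 3))
  cd_free <- tab$Cd[as.character(tab$class) == "free-range"]
  expect_true(all(cd_free == 0))          # structurally nondetect: exact zeros
  expect_true(all(tab$Cd[as.character(tab$class) == "caged"] > 0))

  # SD = 0 with mean above DL and no replicate noise -> every value equals m
  dists <- class_distributions()
  dists[["free-range"]]$mean[dists[["free-range"]]$element == "Zn"] <- 5
  dists[["free-range"]]$sd[dists[["free-range"]]$element == "Zn"] <- 0
  tab2 <- generate_profiles(dists = dists,
                            cfg = generator_config(c("free-range" = 50, "caged" = 10),
                                                   seed = 3, replicate_cv = 0))
  expect_true(all(tab2$Zn[as.character(tab2$class) == "free-range"] == 5))
})

test_that("generator rejects inconsistent inputs", {
  expect_error(generator_config(c("free-range" = 1, "caged" = 10)), "n per class")
  dists <- class_distributions()
  dists[["caged"]] <- dists[["caged"]][-3, ]
  expect_error(generate_profiles(dists = dists), "does not match the panel")
})

test_that("plant_outliers is an identity at k = 0 and shifts exactly k rows", {
  tab <- tiny_profile_table(10, seed = 9)
  none <- plant_outliers(tab, k = 0, seed = 1)
  expect_identical(as.data.frame(none$table), as.data.frame(tab))
  expect_false(any(none$truth))

  one <- plant_outliers(tab, k = c("free-range" = 1, "caged" = 0),
                        displacement = 10, seed = 1)
  diff_rows <- unname(which(rowSums(conc_matrix(one$table) != conc_matrix(tab)) > 0))
  expect_length(diff_rows, 1L)
  expect_identical(which(one$truth), diff_rows)
  expect_true(all(conc_matrix(one$table) >= 0))

  expect_error(plant_outliers(tab, k = 99, seed = 1), "exceeds class")
})
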