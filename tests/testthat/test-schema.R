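test_that("the default schema carries 13 variables with the right log flags", {
  sch <- solvent_schema()
  expect_equal(nrow(sch), 13L)
  expect_setequal(sch$name[sch$log_transform],
                  c("henry_law_constant", "oral_ld50", "inhalation_lc50",
                    "fish_lc50", "bod_half_life"))
  expect_false(any(sch$log_transform[sch$name %in%
                                       c("log_kow", "log_koa", "log_bcf")]))
  sen <- attr(sch, "sentinel")
  expect_equal(sen$column, "inhalation_lc50")
  expect_equal(sen$value, 5001)
})

test_that("read_prop_table builds the mask and rejects malformed input", {
  sch <- endpoint_schema()
  df <- data.frame(id = c("a", "b", "c"), oral_ld50 = c(10, NA, 30),
                   inhalation_lc50 = c(100, 200, 300),
                   fish_lc50 = c(1, 2, 3), bod_half_life = c(4, 5, 6),
                   log_bcf = c(0.1, 0.2, 0.3))
  pt <- read_prop_table(write_endpoint_csv(df), sch)
  expect_s3_class(pt, "prop_table")
  expect_equal(dim(pt), c(3L, 5L))
  expect_equal(sum(!pt$mask), 1L)
  expect_false(pt$mask["b", "oral_ld50"])
  expect_identical(rownames(pt$values), c("a", "b", "c"))

  # complete table -> all-true mask
  df2 <- df; df2$oral_ld50[2] <- 99
  expect_true(all(read_prop_table(write_endpoint_csv(df2), sch)$mask))

  # unknown column rejected
  df3 <- cbind(df, junk = 1)
  expect_error(read_prop_table(write_endpoint_csv(df3), sch), "unknown column")
  # missing required column
  expect_error(read_prop_table(write_endpoint_csv(df[, -6]), sch),
               "missing required")
  # duplicate row ids
  df4 <- df2; df4$id <- c("a", "a", "c")
  expect_error(read_prop_table(write_endpoint_csv(df4), sch), "duplicate")
  # non-numeric token with location
  df5 <- df2; df5$fish_lc50 <- c("1", "oops", "3")
  expect_error(read_prop_table(write_endpoint_csv(df5), sch),
               "row 2, column 'fish_lc50'")
})

test_that("missing-cell tokens NA/NaN/empty are all accepted", {
  sch <- endpoint_schema()
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,oral_ld50,inhalation_lc50,fish_lc50,bod_half_life,log_bcf",
               "a,,100,1,4,0.1", "b,NA,200,2,5,0.2", "c,nan,300,3,6,0.3"), p)
  pt <- read_prop_table(p, sch)
  expect_equal(unname(colSums(!pt$mask)),
               c(3L, 0L, 0L, 0L, 0L))
})

test_that("apply_sentinels fills only flagged missing inhalation cells", {
  sch <- endpoint_schema()
  vals <- matrix(c(10, NA, 30,
                   NA, 9800, NA,
                   1, 2, 3,
                   4, 5, 6,
                   .1, .2, .3), 3, 5,
                 dimnames = list(NULL, sch$name))
  pt <- prop_table(vals, sch, space = "raw")
  out <- apply_sentinels(pt, nonvolatile = c(TRUE, TRUE, FALSE))
  # flagged + missing -> 5001, observed
  expect_equal(out$values[1, "inhalation_lc50"], 5001)
  expect_true(out$mask[1, "inhalation_lc50"])
  # flagged but already observed -> untouched
  expect_equal(out$values[2, "inhalation_lc50"], 9800)
  # unflagged missing cell stays missing
  expect_false(out$mask[3, "inhalation_lc50"])
  # other columns' missingness untouched
  expect_equal(colSums(!out$mask)[-2], colSums(!pt$mask)[-2])
  # input not mutated
  expect_false(pt$mask[1, "inhalation_lc50"])
  # all-false flags -> identity
  id <- apply_sentinels(pt, rep(FALSE, 3))
  expect_identical(id$values, pt$values)
  expect_error(apply_sentinels(pt, TRUE), "length")
})

test_that("log transform maps to model space and round-trips exactly", {
  sch <- endpoint_schema()
  vals <- matrix(c(1, 8.03e-6, 5001, 123, 0.5,
                   2, 3, 4, 5, 6, NA, 7, 8, 9, 10), 3, 5,
                 dimnames = list(NULL, sch$name))
  pt <- prop_table(vals, sch, space = "raw")
  ms <- to_model_space(pt)
  expect_equal(ms$space, "model")
  expect_equal(ms$values[1, "oral_ld50"], 0)              # ln(1)
  expect_equal(ms$values[2, "oral_ld50"], -11.732, tolerance = 1e-4)
  expect_equal(ms$values[3, "oral_ld50"], log(5001))
  # log_bcf is not re-transformed
  expect_equal(ms$values[, "log_bcf"], pt$values[, "log_bcf"])
  # mask unchanged
  expect_identical(ms$mask, pt$mask)
  # round trip
  back <- from_model_space(ms)
  expect_equal(back$values[back$mask], pt$values[pt$mask],
               tolerance = 1e-12)
  expect_error(from_model_space(back), "already in raw")
  expect_error(to_model_space(ms), "already in model")
  # non-positive observed value in a log column
  bad <- vals; bad[1, "fish_lc50"] <- 0
  expect_error(to_model_space(prop_table(bad, sch)),
               "fish_lc50")
})
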