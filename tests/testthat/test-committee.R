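rand_sm <- function(seed, nm = 6L, ng = 4L, nonneg = FALSE) {
  set.seed(seed)
  v <- matrix(rnorm(nm * ng), nm, ng,
              dimnames = list(sprintf("M%d", 1:nm), sprintf("G%d", 1:ng)))
  if (nonneg) v <- abs(v) * rbinom(nm * ng, 1, 0.6)
  score_matrix(v, sprintf("rand%d", seed))
}

test_that("z-scoring centers, scales, and ignores affine changes", {
  m <- rand_sm(1)
  z <- zscore_matrix(m, "global")
  expect_lt(abs(mean(z$values)), 1e-12)
  expect_lt(abs(sd(z$values) - 1), 1e-12)
  z2 <- zscore_matrix(score_matrix(2 * m$values + 3, m$method), "global")
  expect_equal(z2$values, z$values)
  zg <- zscore_matrix(m, "per_gene")
  expect_true(all(abs(colMeans(zg$values)) < 1e-12))
  expect_true(all(abs(apply(zg$values, 2, sd) - 1) < 1e-12))
  const <- score_matrix(matrix(5, 3, 3), "const")
  expect_warning(zc <- zscore_matrix(const), "centered")
  expect_true(all(zc$values == 0))
})

test_that("unfiltered committees average z-scores with sane degeneracies", {
  a <- rand_sm(2); b <- rand_sm(3)
  expect_equal(combine_unfiltered(list(a))$values,
               zscore_matrix(a)$values)
  expect_equal(combine_unfiltered(list(a, a))$values,
               zscore_matrix(a)$values)
  comm <- combine_unfiltered(list(a, b))
  expect_equal(comm$values,
               (zscore_matrix(a)$values + zscore_matrix(b)$values) / 2)
  expect_equal(comm$method, "rand2+rand3")
  # z-scored opposites cancel exactly
  za <- zscore_matrix(a)
  neg <- score_matrix(-za$values, "neg")
  expect_true(all(abs(combine_unfiltered(list(za, neg))$values) < 1e-12))
  # mismatched gene sets are reported by name
  bad <- b
  colnames(bad$values)[2] <- "GX"
  expect_error(combine_unfiltered(list(a, bad)), "GX")
})

test_that("committees are invariant to positive affine member rescaling", {
  for (seed in 4:8) {
    a <- rand_sm(seed); b <- rand_sm(seed + 100)
    base <- combine_unfiltered(list(a, b))$values
    resc <- combine_unfiltered(list(
      score_matrix(0.37 * a$values - 2.2, a$method), b))$values
    expect_equal(resc, base, tolerance = 1e-12)
  }
})

test_that("a single-member committee preserves the member's ranking", {
  a <- rand_sm(9)
  expect_identical(order(combine_unfiltered(list(a))$values),
                   order(a$values))
})

test_that("the filtered committee is the gated member average", {
  members <- list(rand_sm(10), rand_sm(11), rand_sm(12))
  lasso <- rand_sm(13, nonneg = TRUE)
  filt <- combine_filtered(members, lasso)
  unf <- combine_unfiltered(members)
  expected <- unf$values
  expected[lasso$values < 1e-10] <- 0
  expect_equal(filt$values, expected)
  expect_equal(filt$method, sprintf("{%s}|LASSO", unf$method))
  # all-nonzero gate changes nothing; all-zero gate kills everything
  open <- score_matrix(abs(rand_sm(14)$values) + 1, "LASSO")
  expect_equal(combine_filtered(members, open)$values, unf$values)
  closed <- score_matrix(0 * open$values, "LASSO")
  expect_true(all(combine_filtered(members, closed)$values == 0))
  expect_error(combine_filtered(members, score_matrix(-open$values, "LASSO")),
               "non-negative")
})

test_that("filtered support is always inside the LASSO support", {
  for (seed in 20:29) {
    members <- list(rand_sm(seed), rand_sm(seed + 50))
    lasso <- rand_sm(seed + 200, nonneg = TRUE)
    filt <- combine_filtered(members, lasso)
    expect_true(all(lasso$values[filt$values != 0] > 0))
    expect_lte(sum(filt$values != 0), sum(lasso$values != 0))
  }
})

test_that("committee specification strings parse per the shorthand", {
  cs <- parse_committee("{RF.sf+RF.pi+ElNet}|LASSO")
  expect_equal(cs$members, c("RF.sf", "RF.pi", "ElNet"))
  expect_true(cs$filter_by_lasso)
  cs2 <- parse_committee("RF.sf+LASSO")
  expect_equal(cs2$members, c("RF.sf", "LASSO"))
  expect_false(cs2$filter_by_lasso)
  expect_error(parse_committee("RF.sf+BOGUS"), "unknown method")
  expect_error(parse_committee(""), "empty")
})
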