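edges_df <- function(reg, tgt) {
  ranked_edges_df <- data.frame(rank = seq_along(reg), regulator = reg,
                                target = tgt, score = 0, is_padded = FALSE,
                                stringsAsFactors = FALSE)
  ranked_edges_df
}

test_that("predictions are labelled against the gold over the universe", {
  uni <- paste0("G", 1:4)
  gold <- gold_network(c("G1", "G2", "G3"), c("G2", "G3", "G4"))
  pred <- edges_df(c("G1", "G4", "G2", "G1", "G4"),
                   c("G2", "G1", "G3", "G3", "G2"))
  lab <- label_predictions(pred, gold, uni)
  expect_equal(lab$labels, c(1L, 0L, 1L, 0L, 0L))
  expect_equal(lab$P, 3)
  expect_equal(lab$N, 9)
  # exact-match predictions are all positive
  allpos <- label_predictions(edges_df(gold$regulator, gold$target), gold, uni)
  expect_true(all(allpos$labels == 1L))
  expect_error(label_predictions(pred, gold[0, ], uni), "empty gold")
  expect_error(label_predictions(edges_df("G9", "G1"), gold, uni), "universe")
})

test_that("AUROC matches hand-derived values and symmetry", {
  expect_equal(auroc(c(1, 1, 0, 0), P = 2, N = 2), 1)
  expect_equal(auroc(c(1, 0, 1, 0), P = 2, N = 2), 0.75)
  expect_equal(auroc(c(0, 1, 0, 1), P = 2, N = 2), 0.25)
  expect_equal(auroc(c(1, 0, 1, 0), 2, 2) + auroc(rev(c(1, 0, 1, 0)), 2, 2), 1)
  expect_error(auroc(c(1, 0), P = 1, N = 0), "no negatives")
})

test_that("AUPR is the average precision over retrieved positives", {
  expect_equal(aupr(c(1, 1, 0, 0), P = 2, N = 2), 1)
  expect_equal(aupr(c(1, 0, 1, 0), P = 2, N = 2), (1 + 2 / 3) / 2)
  k <- 7
  expect_equal(aupr(c(rep(0, k - 1), 1), P = 1, N = k - 1), 1 / k)
  expect_error(aupr(integer(0), P = 0, N = 3), "no positives")
})

test_that("curves reproduce the prefix confusion counts", {
  lab <- c(1, 1, 0)
  roc <- roc_curve(lab, P = 2, N = 1)
  expect_equal(roc$x, c(0, 0, 0, 1))
  expect_equal(roc$y, c(0, 0.5, 1, 1))
  pr <- pr_curve(lab, P = 2, N = 1)
  expect_true(any(pr$x == 0.5 & pr$y == 1))
  expect_true(any(pr$x == 1 & abs(pr$y - 2 / 3) < 1e-12))
  # trapezoid over a complete ROC curve equals the AUROC
  for (seed in 1:5) {
    set.seed(seed)
    l <- sample(c(rep(1, 4), rep(0, 6)))
    r <- roc_curve(l, 4, 6)
    trap <- sum(diff(r$x) * (head(r$y, -1) + tail(r$y, -1)) / 2)
    expect_equal(trap, auroc(l, 4, 6), tolerance = 1e-12)
  }
})

test_that("empty prediction lists degrade to zero with a warning", {
  expect_warning(a <- auroc(integer(0), 2, 3), "empty")
  expect_equal(a, 0)
  expect_warning(p <- aupr(integer(0), 2, 3), "empty")
  expect_equal(p, 0)
  expect_warning(rc <- roc_curve(integer(0), 2, 3), "origin")
  expect_equal(nrow(rc), 1)
})

test_that("metrics agree exactly with brute-force oracles", {
  set.seed(99)
  for (i in 1:60) {
    inst <- random_instance()
    if (length(inst$labels)) {
      expect_identical(auroc(inst$labels, inst$P, inst$N),
                       brute_auroc(inst$labels, inst$P, inst$N))
      expect_equal(aupr(inst$labels, inst$P, inst$N),
                   brute_ap(inst$labels, inst$P), tolerance = 1e-12)
    }
  }
})

test_that("tie-aware AUROC gives half credit inside tie groups", {
  # two predictions sharing one score: positive and negative tie
  expect_equal(auroc(c(1, 0), 1, 1, tie_groups = c(5, 5)), 0.5)
  expect_equal(auroc(c(1, 0), 1, 1, tie_groups = c(5, 4)), 1)
  # all tied: random-guess value
  expect_equal(auroc(c(1, 0, 1, 0), 2, 2, tie_groups = rep(1, 4)), 0.5)
})

test_that("metrics are invariant to gene relabeling", {
  uni <- paste0("G", 1:5)
  gold <- gold_network(c("G1", "G2"), c("G3", "G5"))
  pred <- edges_df(c("G1", "G2", "G4"), c("G3", "G1", "G5"))
  lab1 <- label_predictions(pred, gold, uni)
  relab <- setNames(paste0("X", c(3, 5, 2, 4, 1)), uni)
  gold2 <- gold_network(relab[gold$regulator], relab[gold$target])
  pred2 <- edges_df(relab[pred$regulator], relab[pred$target])
  lab2 <- label_predictions(pred2, gold2, unname(relab))
  expect_identical(lab1, lab2)
})

test_that("random complete rankings average to AUROC one half", {
  set.seed(7)
  vals <- replicate(200, {
    l <- sample(c(rep(1, 5), rep(0, 20)))
    auroc(l, 5, 20)
  })
  expect_lt(abs(mean(vals) - 0.5), 0.03)
})

test_that("evaluate_edges ties the pieces together", {
  uni <- paste0("G", 1:4)
  gold <- gold_network(c("G1", "G2"), c("G2", "G3"))
  pred <- edges_df(c("G1", "G3", "G2"), c("G2", "G4", "G3"))
  ev <- evaluate_edges(pred, gold, uni)
  expect_s3_class(ev, "eqtl_eval")
  lab <- label_predictions(pred, gold, uni)
  expect_equal(ev$auroc, auroc(lab$labels, lab$P, lab$N))
  expect_equal(ev$aupr, aupr(lab$labels, lab$P, lab$N))
})
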