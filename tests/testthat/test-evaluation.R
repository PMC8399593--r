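test_that("confusion tallies match brute-force enumeration", {
  truth <- matrix(c(1, 0, 1, 0, 0, 1), 3, 2)
  pred <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2)
  cc <- confusion(pred, truth)
  expect_equal(unlist(cc), c(tp = 2, tn = 2, fp = 1, fn = 1))
  expect_equal(unname(unlist(cc)), unname(naive_confusion(pred, truth)))

  same <- confusion(truth, truth)
  expect_equal(c(same$fp, same$fn), c(0, 0))
  comp <- confusion(1 - truth, truth)
  expect_equal(c(comp$tp, comp$tn), c(0, 0))
  expect_error(confusion(matrix(0, 2, 2), truth), "dimensions")
})

test_that("metrics honor the undefined-denominator conventions", {
  # all-negative image segmented perfectly: accuracy/specificity 1, rest undefined
  m <- compute_metrics(confusion_counts(tp = 0, tn = 100, fp = 0, fn = 0))
  expect_equal(m$accuracy, 1)
  expect_equal(m$specificity, 1)
  expect_true(all(is.na(c(m$sensitivity, m$precision, m$jaccard, m$dice))))

  # no true Neo but false alarms: sensitivity undefined, the overlap scores
  # are defined zeros
  m2 <- compute_metrics(confusion_counts(tp = 0, tn = 99, fp = 1, fn = 0))
  expect_true(is.na(m2$sensitivity))
  expect_equal(c(m2$precision, m2$jaccard, m2$dice), c(0, 0, 0))

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("metric identities hold on randomized confusion counts", {
  set.seed(31)
  for (i in 1:200) {
    cc <- confusion_counts(tp = rpois(1, 20) + 1, tn = rpois(1, 200),
                           fp = rpois(1, 10), fn = rpois(1, 10))
    m <- compute_metrics(cc)
    expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
    expect_equal(m$dice,
                 2 * m$precision * m$sensitivity / (m$precision + m$sensitivity),
                 tolerance = 1e-12)
    expect_lte(m$jaccard, m$dice)
    expect_lte(m$dice, 1)
  }
})

test_that("compute_metrics agrees with a per-pixel comparison oracle on random masks", {
  set.seed(17)
  agree <- logical(1000)
  for (i in 1:1000) {
    truth <- matrix(rbinom(256, 1, runif(1, 0, 0.4)), 16, 16)
    pred <- matrix(rbinom(256, 1, runif(1, 0, 0.4)), 16, 16)
    nc <- naive_confusion(pred, truth)
    m <- compute_metrics(confusion(pred, truth))
    sens <- if (nc["tp"] + nc["fn"] == 0) NA_real_ else nc["tp"] / (nc["tp"] + nc["fn"])
    jac <- if (sum(nc[c("tp", "fp", "fn")]) == 0) NA_real_ else
      nc["tp"] / sum(nc[c("tp", "fp", "fn")])
    same <- function(a, b) (is.na(a) && is.na(b)) || isTRUE(abs(a - b) < 1e-12)
    agree[i] <- sum(nc) == 256 &&
      same(m$accuracy, unname((nc["tp"] + nc["tn"]) / 256)) &&
      same(m$sensitivity, unname(sens)) &&
      same(m$jaccard, unname(jac)) &&
      same(m$dice, unname(2 * nc["tp"] / (2 * nc["tp"] + nc["fp"] + nc["fn"])))
  }
  expect_equal(sum(agree), 1000)
})

test_that("patch-level classification flags tiles containing any Neo pixel", {
  pred <- matrix(0L, 400, 1184)
  truth <- matrix(0L, 400, 1184)
  cc0 <- patch_classify(pred, truth)
  expect_equal(unlist(cc0), c(tp = 0, tn = 8, fp = 0, fn = 0))  # 2 x 4 tiling

  pred[10, 10] <- 1L; truth[150, 200] <- 1L   # same tile (rows 1-200, cols 1-296)
  cc1 <- patch_classify(pred, truth)
  expect_equal(unlist(cc1), c(tp = 1, tn = 7, fp = 0, fn = 0))

  truth2 <- matrix(0L, 400, 1184); truth2[300, 500] <- 1L
  cc2 <- patch_classify(pred, truth2)
  expect_equal(unlist(cc2), c(tp = 0, tn = 6, fp = 1, fn = 1))

  expect_error(patch_classify(matrix(0, 30, 30), matrix(0, 30, 30)), "divisible")
})

test_that("segmentation assigns ties to NotNeo and preserves dimensions", {
  spec <- build_reference_spec(16, 16)
  m0 <- init_network(spec, init = "zero")  # every pixel exactly (0.5, 0.5)
  x <- matrix(runif(256, 0, 255), 16, 16)
  seg <- segment(m0, x)
  expect_equal(dim(seg), c(16, 16))
  expect_true(all(seg == 0))               # tie -> NotNeo

  m <- init_network(spec, seed = 2)
  seg2 <- segment(m, x)
  p <- forward(m, x)
  expect_equal(seg2, matrix(as.integer(p[, , 2] > 0.5), 16, 16))
})

test_that("averages exclude undefined entries and keep defined zeros", {
  recs <- list(
    compute_metrics(confusion_counts(tp = 8, tn = 80, fp = 2, fn = 2)),
    compute_metrics(confusion_counts(tp = 0, tn = 92, fp = 0, fn = 0)),
    compute_metrics(confusion_counts(tp = 0, tn = 91, fp = 1, fn = 0))
  )
  avg <- aggregate_report(recs)
  expect_equal(avg$sensitivity, 0.8)              # only record 1 defines it
  expect_equal(avg$precision, (0.8 + 0) / 2)      # record 3 contributes a zero
  expect_equal(avg$dice, (8 / 10 + 0) / 2 * 2 / 2)
  # single record: averages equal the record
  expect_equal(aggregate_report(recs[1]), as.data.frame(recs[[1]]))
  # a metric undefined everywhere stays undefined
  only_neg <- aggregate_report(recs[2])
  expect_true(is.na(only_neg$jaccard))
})

test_that("the reference clinical table satisfies identities and averaging", {
  tab <- reference_segmentation_metrics()
  expect_equal(nrow(tab), 50)

  # identities at printed 4-decimal precision (all operands are rounded)
  ok <- !is.na(tab$dice)
  expect_equal(sum(ok), 26)
  d_from_j <- 2 * tab$jaccard[ok] / (1 + tab$jaccard[ok])
  expect_lt(max(abs(d_from_j - tab$dice[ok])), 1.01e-4)
  oks <- ok & !is.na(tab$sensitivity)
  d_from_ps <- 2 * tab$precision[oks] * tab$sensitivity[oks] /
    (tab$precision[oks] + tab$sensitivity[oks])
  expect_lt(max(abs(d_from_ps - tab$dice[oks])), 1.01e-4)
  expect_true(all(tab$jaccard[ok] <= tab$dice[ok]))

  # defined-only averaging reproduces the published average row
  avg <- round_half_up(aggregate_report(tab), 4)
  expect_equal(avg$accuracy, 0.9948)
  expect_equal(avg$sensitivity, 0.8772)
  expect_equal(avg$specificity, 0.9976)
  expect_equal(avg$precision, 0.8696)
  expect_equal(avg$jaccard, 0.7643)
  expect_equal(avg$dice, 0.8466)
  # the counts of defined entries behind those means
  expect_equal(sum(!is.na(tab$sensitivity)), 25)
  expect_equal(sum(!is.na(tab$precision)), 26)
})

test_that("evaluation regression fixtures give the expected confusion counts", {
  fx <- make_fixtures(n_images = 4L, seed = 99L)
  for (i in seq_along(fx$masks)) {
    expect_true(sum(fx$masks[[i]]) > 0)  # both classes present
    cc <- confusion(fx$predictions[[i]], fx$masks[[i]])
    expect_equal(unlist(cc), fx$expected[[i]], ignore_attr = TRUE)
  }
  expect_identical(make_fixtures(n_images = 2L, seed = 99L)$expected,
                   fx$expected[1:2])
})

test_that("evaluation reports round-trip through CSV with half-up rounding", {
  fx <- make_fixtures(n_images = 3L, seed = 7L)
  rep <- evaluate_masks(fx$predictions, fx$masks,
                        tile_height = 48L, tile_width = 48L)
  expect_equal(nrow(rep$per_image), 3)
  expect_equal(rep$patch_confusion$tp + rep$patch_confusion$tn +
                 rep$patch_confusion$fp + rep$patch_confusion$fn, 3 * 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), 5)
  expect_equal(got$accuracy[1],
               round_half_up(rep$per_image$accuracy[1], 4))
})

test_that("Dice is unforgiving of single-pixel boundary errors on thin strokes", {
  # neovascular tangles are 1-2 px strokes; a uniform one-pixel dilation of
  # the truth already costs a quarter of the Dice score, which bounds what
  # any segmenter with ~1 px boundary uncertainty can achieve
  ph <- render_phantom(tiny_phantom(seed = 13, n_lesions = 2L))
  m <- ph$mask
  dil <- m
  dil[-1, ] <- pmax(dil[-1, ], m[-nrow(m), ])
  dil[-nrow(m), ] <- pmax(dil[-nrow(m), ], m[-1, ])
  dil[, -1] <- pmax(dil[, -1], m[, -ncol(m)])
  dil[, -ncol(m)] <- pmax(dil[, -ncol(m)], m[, -1])
  d <- compute_metrics(confusion(dil, m))$dice
  expect_lt(d, 0.85)
  expect_gt(d, 0.5)
})
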