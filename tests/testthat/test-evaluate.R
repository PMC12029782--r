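# The five printed confusion matrices of the study this protocol mirrors
# (per class: tp, fp, fn, tn). The 50-epoch run printed no counts.
counts_10_AS <- c(9, 8, 7, 35)
counts_100_AS <- c(15, 3, 1, 31)
counts_100_BAC <- c(23, 3, 5, 19)
counts_200_AS <- c(15, 3, 1, 29)
counts_200_BAC <- c(25, 1, 3, 19)
counts_500_AS <- c(15, 2, 1, 28)
counts_500_BAC <- c(23, 0, 5, 18)

test_that("metrics truncate to two decimals and reproduce printed values", {
  # 10 epochs, AS: 9/17 = 0.529 -> 0.52; 9/16 = 0.5625 -> 0.56
  expect_equal(precision_metric(9, 8), 0.52)
  expect_equal(recall_metric(9, 7), 0.56)
  # 500 epochs, BAC: no false positives; 23/28 = 0.8214 -> 0.82
  expect_equal(precision_metric(23, 0), 1)
  expect_equal(recall_metric(23, 5), 0.82)
  # 200 epochs, AS precision: 15/18 = 0.833 -> 0.83; recall 0.9375 -> 0.93
  expect_equal(precision_metric(15, 3), 0.83)
  expect_equal(recall_metric(15, 1), 0.93)
  # accuracies: 46/50 -> 0.92, 42/50 -> 0.84, 44/48 -> 0.91, 43/46 -> 0.93
  expect_equal(accuracy_metric(15, 3, 1, 31), 0.92)
  expect_equal(accuracy_metric(23, 3, 5, 19), 0.84)
  expect_equal(accuracy_metric(15, 3, 1, 29), 0.91)
  expect_equal(accuracy_metric(15, 2, 1, 28), 0.93)
})

test_that("F1 uses the truncated precision and recall", {
  # AS at 100-500 epochs: 2(.83)(.93)/1.76 = 0.877 -> 0.87
  expect_equal(f1_metric(0.83, 0.93), 0.87)
  # BAC at 500 epochs: 1.64/1.82 = 0.901 -> 0.90 (raw-count F1 is 0.884)
  expect_equal(f1_metric(1, 0.82), 0.90)
  expect_equal(f1_metric(1, 1), 1)
})

test_that("undefined metrics warn / error instead of silently reporting", {
  expect_warning(p <- precision_metric(0, 0), "undefined")
  expect_true(is.na(p))
  expect_warning(r <- recall_metric(0, 0), "undefined")
  expect_true(is.na(r))
  expect_warning(f <- f1_metric(0, 0), "undefined")
  expect_true(is.na(f))
  expect_error(accuracy_metric(0, 0, 0, 0), "total")
})

test_that("raw metrics lie in [0,1] and truncation only shrinks by < 0.01", {
  set.seed(31)
  for (i in 1:50) {
    cc <- sample(0:30, 4, replace = TRUE)
    if (cc[1] + cc[2] == 0 || cc[1] + cc[3] == 0) next
    raw_p <- cc[1] / (cc[1] + cc[2])
    p <- precision_metric(cc[1], cc[2])
    expect_gte(p, raw_p - 0.01)
    expect_lte(p, raw_p)
    expect_true(p >= 0 && p <= 1)
    # precision = 1 iff fp = 0; recall = 1 iff fn = 0
    expect_equal(p == 1, cc[2] == 0L)
    expect_equal(recall_metric(cc[1], cc[3]) == 1, cc[3] == 0L)
  }
})

test_that("known print inconsistencies stay flagged, not corrected", {
  # the source table prints Precision AS = 0.83 at 500 epochs, but the
  # printed counts give 15/17 = 0.882 -> 0.88; the counts win here
  expect_equal(precision_metric(counts_500_AS[1], counts_500_AS[2]), 0.88)
  # the 10-epoch in-text "accuracy" 0.52 is tp/(tp+fp) on the printed
  # counts, i.e. a precision; the true accuracy of those counts differs
  expect_equal(accuracy_metric(9, 8, 7, 35), 0.74)
})

test_that("IoU matching equals the exhaustive assignment oracle", {
  shape <- c(120, 120)
  # deterministic scene: one clean match plus one spurious prediction
  truth <- disk_scene(list(c(30, 30)), list(10), shape)
  pred <- disk_scene(list(c(31, 30), c(90, 90)), list(10, 8), shape)
  cc <- match_and_count(list(BAC = pred, AS = list()),
                        list(BAC = truth, AS = list()),
                        iou_threshold = 0.5, negative_units = 3)
  bac <- cc[cc$class == "BAC", ]
  expect_equal(unlist(bac[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(1L, 1L, 0L, 2L))

  # prediction with no truth at all
  cc2 <- match_and_count(list(BAC = pred[2], AS = list()),
                         list(BAC = list(), AS = list()), 0.5, 0)
  expect_equal(cc2$fp[cc2$class == "BAC"], 1L)
  expect_equal(cc2$tp[cc2$class == "BAC"], 0L)

  # randomized small scenes vs brute force
  set.seed(41)
  grid <- expand.grid(r = c(25, 60, 95), c = c(25, 60, 95))
  for (rep in 1:8) {
    nt <- sample(0:4, 1); np <- sample(0:4, 1)
    pick_t <- grid[sample(nrow(grid), nt), ]
    pick_p <- grid[sample(nrow(grid), np), ]
    truths <- disk_scene(split(as.matrix(pick_t), seq_len(nt)),
                         as.list(runif(nt, 8, 13)), shape)
    preds <- disk_scene(split(as.matrix(pick_p) +
                                matrix(runif(np * 2, -4, 4), np), seq_len(np)),
                        as.list(runif(np, 8, 13)), shape)
    cc <- match_and_count(list(BAC = preds, AS = list()),
                          list(BAC = truths, AS = list()), 0.5, 5)
    bac <- cc[cc$class == "BAC", ]
    tp_oracle <- brute_force_tp(preds, truths, 0.5)
    expect_equal(bac$tp, tp_oracle)
    expect_equal(bac$fp, np - tp_oracle)
    expect_equal(bac$fn, nt - tp_oracle)
    expect_equal(bac$tn, max(0L, 5L - bac$fp))
  }

  expect_error(match_and_count(list(), list(), iou_threshold = 0), "> 0")
})

test_that("the metric report reproduces a printed epoch-comparison table", {
  counts <- dplyr::bind_rows(
    confusion_counts("AS", 15, 3, 1, 31) |> dplyr::mutate(run = "100"),
    confusion_counts("BAC", 23, 3, 5, 19) |> dplyr::mutate(run = "100"),
    confusion_counts("AS", 15, 3, 1, 29) |> dplyr::mutate(run = "200"),
    confusion_counts("BAC", 25, 1, 3, 19) |> dplyr::mutate(run = "200"),
    confusion_counts("AS", 15, 2, 1, 28) |> dplyr::mutate(run = "500"),
    confusion_counts("BAC", 23, 0, 5, 18) |> dplyr::mutate(run = "500"))
  rep <- metrics_report(counts)
  get <- function(run, cls, metric) rep[[metric]][rep$run == run &
                                                    rep$class == cls]
  # every cell of the published table consistent with its printed counts
  expect_equal(get("100", "AS", "precision"), 0.83)
  expect_equal(get("200", "AS", "precision"), 0.83)
  expect_equal(get("100", "AS", "recall"), 0.93)
  expect_equal(get("200", "AS", "recall"), 0.93)
  expect_equal(get("500", "AS", "recall"), 0.93)
  expect_equal(get("100", "AS", "f1"), 0.87)
  expect_equal(get("200", "AS", "f1"), 0.87)
  expect_equal(get("100", "AS", "accuracy"), 0.92)
  expect_equal(get("200", "AS", "accuracy"), 0.91)
  expect_equal(get("500", "AS", "accuracy"), 0.93)
  expect_equal(get("100", "BAC", "accuracy"), 0.84)
  expect_equal(get("200", "BAC", "precision"), 0.96) # 25/26 -> 0.96
  expect_equal(get("500", "BAC", "precision"), 1)
  expect_equal(get("500", "BAC", "f1"), 0.90)

  wide <- metrics_report(counts, wide = TRUE)
  expect_true(all(c("100", "200", "500") %in% names(wide)))
  expect_equal(nrow(wide), 8) # 4 metrics x 2 classes

  empty <- metrics_report(confusion_counts(character(), integer(),
                                           integer(), integer(), integer()))
  expect_equal(nrow(empty), 0)
})
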