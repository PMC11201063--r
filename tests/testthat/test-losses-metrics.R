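# BCE-Dice loss, confusion metrics, ROC/AUC.

test_that("BCE-Dice loss is zero for a perfect binary prediction", {
  P <- array(1, c(2, 2))
  G <- array(1, c(2, 2))
  expect_equal(bce_dice_loss(P, G, sigma = 1), 0, tolerance = 1e-6)
})

test_that("the two-pixel worked example gives about 0.9431", {
  G <- c(1, 1)
  P <- c(0.5, 0.5)
  loss <- bce_dice_loss(P, G, sigma = 1)
  # BCE = -ln 0.5 ; Dice term = 1 - (2*1 + 1)/(2 + 1 + 1)
  expect_equal(loss, -log(0.5) + 0.25, tolerance = 1e-6)
  expect_equal(round(loss, 4), 0.9431)
})

test_that("the loss decreases monotonically as P approaches G", {
  G <- 1
  ps <- seq(0.1, 0.9, by = 0.1)
  ls <- vapply(ps, function(p) bce_dice_loss(p, G), numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("the loss is invariant under joint spatial permutation", {
  set.seed(51)
  P <- runif(24)
  G <- rbinom(24, 1, 0.4)
  perm <- sample(24)
  expect_equal(bce_dice_loss(P, G), bce_dice_loss(P[perm], G[perm]),
               tolerance = 1e-12)
})

test_that("per-pixel BCE symmetry holds on a single pixel", {
  p <- 0.3
  bce <- function(p, g) -(g * log(p) + (1 - g) * log(1 - p))
  expect_equal(bce(p, 1), bce(1 - p, 0), tolerance = 1e-12)
})

test_that("sum reduction matches mean reduction times the pixel count", {
  set.seed(52)
  P <- runif(10)
  G <- rbinom(10, 1, 0.5)
  lm <- bce_dice_loss(P, G, bce_reduction = "mean")
  ls <- bce_dice_loss(P, G, bce_reduction = "sum")
  dice <- 1 - (2 * sum(G * P) + 1) / (sum(G) + sum(P) + 1)
  expect_equal(ls - dice, (lm - dice) * 10, tolerance = 1e-9)
})

test_that("loss input validation rejects shape mismatch and non-binary truth", {
  expect_error(bce_dice_loss(c(0.5, 0.5), 1), "mismatch")
  expect_error(bce_dice_loss(c(0.5, 0.5), c(0.2, 1)), "binary")
})

test_that("confusion metrics reproduce the worked example TP=3 FP=1 FN=1 TN=5", {
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  gt <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(pred, gt)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 5)
  expect_equal(m$iou, 60)
  expect_equal(m$dsc, 75)
  expect_equal(m$se, 75)
  expect_equal(m$sp, 83.3333, tolerance = 1e-4)
  expect_equal(m$acc, 80)
})

test_that("perfect and complementary predictions hit the metric extremes", {
  g <- matrix(c(1, 1, 0, 0), 2, 2)
  perfect <- confusion_metrics(g, g)
  for (k in c("iou", "dsc", "se", "sp", "acc"))
    expect_equal(perfect[[k]], 100)
  flipped <- confusion_metrics(1 - g, g)
  expect_equal(flipped$iou, 0)
  expect_equal(flipped$acc, 0)
})

test_that("empty ground truth and empty prediction count as perfect overlap", {
  z <- matrix(0, 3, 3)
  m <- confusion_metrics(z, z)
  expect_equal(m$iou, 100)
  expect_equal(m$dsc, 100)
})

test_that("DSC = 2 IoU / (1 + IoU) on random confusion tables", {
  set.seed(53)
  for (i in 1:25) {
    pred <- rbinom(40, 1, runif(1, 0.2, 0.8))
    gt <- rbinom(40, 1, runif(1, 0.2, 0.8))
    m <- confusion_metrics(pred, gt)
    iou <- m$iou / 100
    expect_equal(m$dsc / 100, 2 * iou / (1 + iou), tolerance = 1e-12)
    expect_gte(m$dsc, m$iou)
  }
})

test_that("AUC equals 1 for separated scores and 0.5 for constant scores", {
  g <- c(rep(1, 4), rep(0, 4))
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1), g), 1)
  expect_equal(roc_auc(rep(0.5, 8), g), 0.5)
  expect_error(roc_auc(runif(4), rep(1, 4)), "single class")
})

test_that("AUC equals the pairwise Mann-Whitney oracle, ties counted half", {
  s <- c(0.9, 0.5, 0.5, 0.3, 0.2, 0.1)
  g <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(s, g), oracle_auc(s, g), tolerance = 1e-12)
  set.seed(54)
  for (i in 1:20) {
    n <- 50
    s <- round(runif(n), 2)  # provoke ties
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) next
    expect_equal(roc_auc(s, g), oracle_auc(s, g), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC library", {
  set.seed(56)
  s <- runif(300)
  g <- rbinom(300, 1, 0.35)
  a <- roc_auc(s, g)
  b <- as.numeric(pROC::auc(pROC::roc(g, s, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("the exported ROC curve spans (0,0) to (1,1) and is monotone", {
  set.seed(55)
  s <- runif(200)
  g <- rbinom(200, 1, 0.4)
  r <- roc_auc(s, g, curve = TRUE)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("metrics reports aggregate per image and serialise to CSV/JSON", {
  per <- rbind(confusion_metrics(c(1, 0), c(1, 0)),
               confusion_metrics(c(1, 0), c(0, 1)))
  rep <- metrics_report(per, auc = 0.9)
  expect_equal(rep$iou, 50)
  expect_equal(rep$n_images, 2)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_metrics(rep, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 3)  # two images + aggregate
  jj <- jsonlite::read_json(js)
  expect_equal(jj$auc, 0.9)
  unlink(c(csv, js))
})
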