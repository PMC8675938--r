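toy_risks <- function(cad = c(0.9, 0.8), non = c(0.1, 0.2)) {
  n <- length(cad) + length(non)
  df <- data.frame(subject_id = sprintf("s%d", seq_len(n)),
                   label = rep(c("CAD", "nonCAD"), c(length(cad), length(non))),
                   stringsAsFactors = FALSE)
  for (m in scgrisk:::MODEL_NAMES) df[[m]] <- c(cad, non)
  class(df) <- c("subject_risks", class(df))
  df
}

test_that("subject aggregation is the arithmetic mean of cycle probabilities", {
  expect_equal(aggregate_subject(c(0.2, 0.4, 0.9)), 0.5)
  expect_equal(aggregate_subject(rep(0.7, 12)), 0.7)
  set.seed(1)
  p <- runif(17)
  expect_equal(aggregate_subject(p), aggregate_subject(sample(p)))
  expect_error(aggregate_subject(numeric(0)), "aggregate")
})

test_that("fusion averages the right channel subsets", {
  r <- c(scg_x = 0.9, scg_y = 0.9, scg_z = 0.9,
         gcg_x = 0.3, gcg_y = 0.3, gcg_z = 0.3)
  f <- fuse_risks(r)
  expect_equal(unname(f["scg_axes"]), 0.9)
  expect_equal(unname(f["gcg_axes"]), 0.3)
  expect_equal(unname(f["all_axes"]), 0.6)
  same <- fuse_risks(setNames(rep(0.42, 6), names(r)))
  expect_equal(unname(same), rep(0.42, 3))
  set.seed(2)
  rr <- setNames(runif(6), names(r))
  expect_equal(unname(fuse_risks(rr)["all_axes"]), mean(rr))
  expect_error(fuse_risks(rr[-2]), "scg_y")
})

test_that("metrics match hand arithmetic under perfect separation", {
  m <- compute_metrics(toy_risks(), threshold = 0.5)
  expect_equal(nrow(m), 9)
  row <- m[m$model == "all_axes", ]
  expect_equal(row$auc, 1)
  expect_equal(row$sensitivity, 1)
  expect_equal(row$specificity, 1)
  expect_equal(row$ppv, 1)
  expect_equal(row$npv, 1)
  expect_equal(row$f1, 1)
  expect_equal(row$discrimination_slope, 0.85 - 0.15)
})

test_that("confusion metrics at the threshold follow their definitions", {
  ## CAD risks 0.9, 0.4; nonCAD risks 0.6, 0.1 at threshold 0.5:
  ## TP=1 FN=1 FP=1 TN=1
  m <- compute_metrics(toy_risks(cad = c(0.9, 0.4), non = c(0.6, 0.1)))
  row <- m[m$model == "scg_x", ]
  expect_equal(row$sensitivity, 0.5)
  expect_equal(row$specificity, 0.5)
  expect_equal(row$ppv, 0.5)
  expect_equal(row$npv, 0.5)
  expect_equal(row$f1, 0.5)
  expect_equal(row$auc, 0.75)       # 3 of 4 pairs correctly ordered
  ## Wilson interval for 1/2 at 95%
  expect_equal(c(row$sens_lo, row$sens_hi),
               scgrisk:::wilson_ci(1, 2), tolerance = 1e-12)
  expect_error(compute_metrics(toy_risks(non = numeric(0))), "both classes")
})

test_that("tied risks give a chance-level AUC and zero slope", {
  m <- compute_metrics(toy_risks(cad = c(0.5, 0.5), non = c(0.5, 0.5)))
  expect_equal(m$auc, rep(0.5, 9))
  expect_equal(m$discrimination_slope, rep(0, 9))
})

test_that("AUC is invariant under strictly monotone risk transforms", {
  set.seed(3)
  r <- toy_risks(cad = runif(10, 0.3, 1), non = runif(10, 0, 0.7))
  a1 <- compute_metrics(r)$auc
  r2 <- r
  for (mn in scgrisk:::MODEL_NAMES) r2[[mn]] <- plogis(5 * qlogis(r2[[mn]]))
  expect_equal(compute_metrics(r2)$auc, a1, tolerance = 1e-12)
})

test_that("the Wilson interval matches known reference values", {
  ## canonical case 8/10: (0.49, 0.943) to 3 dp
  ci <- scgrisk:::wilson_ci(8, 10)
  expect_equal(ci, c(0.4901625, 0.9433178), tolerance = 1e-6)
  expect_true(all(ci >= 0 & ci <= 1))
})

test_that("null-label DeLong intervals cover 0.5 at their nominal rate", {
  set.seed(4)
  n <- 40
  risks <- runif(n)
  labels <- rep(c("CAD", "nonCAD"), each = n / 2)
  covered <- logical(200)
  for (i in seq_len(200)) {
    y <- sample(labels)
    roc <- scgrisk:::roc_of(y, risks)
    ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
    covered[i] <- ci[1] <= 0.5 && ci[3] >= 0.5
  }
  expect_gte(mean(covered), 0.9)
})

test_that("paired model comparison behaves at its boundaries", {
  set.seed(5)
  n <- 40
  base <- toy_risks(cad = runif(n / 2, 0.2, 1), non = runif(n / 2, 0, 0.8))
  expect_equal(compare_models(base, "scg_x", "scg_x"), 1.0)
  ## a perfectly separating model against noise on 40 subjects
  strong <- base
  strong$scg_y <- c(seq(0.6, 0.99, length.out = n / 2),
                    seq(0.01, 0.4, length.out = n / 2))
  strong$gcg_y <- runif(n)
  expect_lt(compare_models(strong, "scg_y", "gcg_y"), 0.05)
})

test_that("paired comparison p-values are roughly uniform under the null", {
  set.seed(6)
  n <- 60
  pv <- replicate(60, {
    df <- toy_risks(cad = runif(n / 2), non = runif(n / 2))
    df$scg_x <- runif(n); df$scg_y <- runif(n)
    compare_models(df, "scg_x", "scg_y")
  })
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("duplicate recordings in a cohort are rejected by checksum", {
  sp <- synth_spec(n_per_class = 2, duration = 15, seed = 31)
  cohort <- generate_cohort(sp)
  dup <- cohort[[1]]
  dup$subject_id <- "impostor"
  expect_error(loso_run(c(cohort, list(dup)), scg_config()),
               "duplicate recordings")
})

test_that("unlabeled or single-class cohorts cannot be evaluated", {
  sp <- synth_spec(n_per_class = 2, duration = 15, seed = 32)
  cohort <- generate_cohort(sp)
  cohort[[1]]$label <- "unknown"
  expect_error(loso_run(cohort, scg_config()), "labeled")
  just_cad <- generate_cohort(sp)[1:2]
  expect_error(loso_run(just_cad, scg_config()), "2 subjects per class")
})

test_that("feature fingerprints distinguish different vector sets", {
  set.seed(7)
  a <- matrix(runif(10 * 750), 10)
  b <- matrix(runif(10 * 750), 10)
  fa <- scgrisk:::vector_fingerprints(a)
  expect_length(intersect(fa, scgrisk:::vector_fingerprints(b)), 0)
  expect_identical(fa, scgrisk:::vector_fingerprints(a))
  ## a shared row is detected
  b[4, ] <- a[2, ]
  expect_length(intersect(fa, scgrisk:::vector_fingerprints(b)), 1)
})
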