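MOTION_CHANNELS <- c("scg_x", "scg_y", "scg_z", "gcg_x", "gcg_y", "gcg_z")
MODEL_NAMES <- c(MOTION_CHANNELS, "all_axes", "scg_axes", "gcg_axes")

#' Aggregate per-cycle probabilities to one subject-level risk
#'
#' @param cycle_probs Non-empty numeric vector of per-cycle CAD
#'   probabilities.
#' @return Their arithmetic mean.
#' @export
aggregate_subject <- function(cycle_probs) {
  if (length(cycle_probs) == 0) stop("no cycle probabilities to aggregate")
  mean(cycle_probs)
}

#' Fuse per-channel risks into ensemble risks
#'
#' `all_axes` is the mean of all six channel risks, `scg_axes` the mean of
#' the three SCG risks, `gcg_axes` the mean of the three GCG risks.
#'
#' @param channel_risks Named numeric vector containing all six of
#'   `scg_x, scg_y, scg_z, gcg_x, gcg_y, gcg_z`.
#' @return Named numeric vector `c(all_axes, scg_axes, gcg_axes)`.
#' @export
fuse_risks <- function(channel_risks) {
  missing <- setdiff(MOTION_CHANNELS, names(channel_risks))
  if (length(missing))
    stop("missing channel risk(s): ", paste(missing, collapse = ", "))
  scg <- channel_risks[c("scg_x", "scg_y", "scg_z")]
  gcg <- channel_risks[c("gcg_x", "gcg_y", "gcg_z")]
  c(all_axes = mean(c(scg, gcg)), scg_axes = mean(scg), gcg_axes = mean(gcg))
}

rec_checksum <- function(rec) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(rec$channels, tf)
  unname(tools::md5sum(tf))
}

vector_fingerprints <- function(m) {
  w <- seq_len(ncol(m))
  paste(format(rowSums(m), digits = 15), format(m %*% w, digits = 15),
        sep = "|")
}

#' Leave-one-subject-out evaluation of a cohort
#'
#' For each of the N subjects, the pipeline trains six channel classifiers
#' on the feature vectors of the other N-1 subjects (with a subject-level
#' 80/20 train/validation split, stratified by class), predicts the
#' held-out subject's per-cycle CAD probabilities, averages them to one
#' risk per channel, and fuses the channel risks into the three ensemble
#' risks. Two hygiene guards run on every fold: recordings with identical
#' channel data are rejected up front (md5 checksum), and the held-out
#' subject's feature-vector fingerprints are asserted disjoint from its
#' fold's training and validation data.
#'
#' Folds whose training split would lose a class are skipped with a
#' warning.
#'
#' @param cohort List of [scg_recording()] objects with known labels.
#' @param cfg An [scg_config()]; `cfg$cnn`, `cfg$epochs`, `cfg$val_frac`
#'   and `cfg$seed` control training.
#' @param balance_train Balance each fold's training pool to equal subjects
#'   per class (random subjects of the larger class dropped). Holding one
#'   subject out necessarily leaves the other class over-represented; with
#'   few subjects that prior shift systematically depresses the held-out
#'   subject's risk, so balancing is on by default.
#' @param verbose Print per-fold progress.
#' @return A `data.frame` of class `subject_risks`: one row per subject
#'   with `subject_id`, `label`, the six channel risks and the three fused
#'   risks.
#' @export
loso_run <- function(cohort, cfg = scg_config(), balance_train = TRUE,
                     verbose = FALSE) {
  labels <- vapply(cohort, function(r) r$label, "")
  if (any(labels == "unknown"))
    stop("all cohort recordings must be labeled for training")
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    stop("need at least 2 subjects per class")
  checks <- vapply(cohort, rec_checksum, "")
  if (anyDuplicated(checks))
    stop("duplicate recordings detected (identical channel data); ",
         "leave-one-subject-out evaluation would leak the test subject")

  if (verbose) message("extracting features for ", length(cohort), " subjects")
  feats <- lapply(cohort, function(rec) {
    clean <- if (inherits(rec, "scg_clean")) rec else preprocess_recording(rec, cfg)
    extract_features(clean, cfg)
  })
  ids <- vapply(feats, `[[`, "", "subject_id")
  n <- length(cohort)
  set.seed(cfg$seed)
  fold_seeds <- sample.int(2^30, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    set.seed(fold_seeds[i])
    ## balance training subjects across classes: after holding one subject
    ## out, the remaining cohort over-represents the other class by one;
    ## at desk-scale cohort sizes that prior shift alone anti-ranks every
    ## held-out subject, so random subjects of the larger class are dropped
    ## until the fold's training pool is class-balanced (label-agnostic with
    ## respect to the held-out subject)
    if (balance_train) {
      tab <- table(labels[tr_idx])
      if (length(tab) == 2 && tab[1] != tab[2]) {
        big <- names(tab)[which.max(tab)]
        extra <- abs(tab[1] - tab[2])
        drop <- sample(tr_idx[labels[tr_idx] == big], extra)
        tr_idx <- setdiff(tr_idx, drop)
      }
    }
    ## stratified subject-level 80/20 inner split
    val_idx <- integer(0)
    for (cl in unique(labels[tr_idx])) {
      cl_idx <- tr_idx[labels[tr_idx] == cl]
      n_val <- max(1L, round(cfg$val_frac * length(cl_idx)))
      if (n_val >= length(cl_idx)) n_val <- length(cl_idx) - 1L
      if (n_val < 1L) {
        val_idx <- NULL
        break
      }
      val_idx <- c(val_idx, sample(cl_idx, n_val))
    }
    if (is.null(val_idx) ||
        length(unique(labels[setdiff(tr_idx, val_idx)])) < 2 ||
        length(unique(labels[val_idx])) < 2) {
      warning("fold ", i, " skipped: a class is missing from its training ",
              "or validation split")
      next
    }
    act_idx <- setdiff(tr_idx, val_idx)

    ch_risks <- stats::setNames(numeric(length(MOTION_CHANNELS)),
                                MOTION_CHANNELS)
    for (ch in MOTION_CHANNELS) {
      xs <- lapply(feats[act_idx], function(f) f$channels[[ch]])
      train_x <- do.call(rbind, xs)
      train_y <- rep(labels[act_idx], vapply(xs, nrow, 0L))
      vs <- lapply(feats[val_idx], function(f) f$channels[[ch]])
      val_x <- do.call(rbind, vs)
      val_y <- rep(labels[val_idx], vapply(vs, nrow, 0L))
      test_x <- feats[[i]]$channels[[ch]]

      ## leakage assertion: held-out vectors never in train/val
      test_fp <- vector_fingerprints(test_x)
      if (any(test_fp %in% c(vector_fingerprints(train_x),
                             vector_fingerprints(val_x))))
        stop("leakage detected: test-subject feature vectors present in ",
             "fold ", i, " training/validation data")

      model <- train_channel(train_x, train_y, val_x, val_y,
                             spec = cfg$cnn, epochs = cfg$epochs,
                             seed = fold_seeds[i] + match(ch, MOTION_CHANNELS),
                             channel = ch)
      ch_risks[ch] <- aggregate_subject(predict_cycles(model, test_x))
    }
    fused <- fuse_risks(ch_risks)
    rows[[i]] <- data.frame(subject_id = ids[i], label = labels[i],
                            t(ch_risks), t(fused),
                            stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fold %d/%d (%s, %s): fused risk %.3f", i, n, ids[i],
                      labels[i], fused["all_axes"]))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("subject_risks", class(out))
  out
}

#' @export
print.subject_risks <- function(x, ...) {
  cat(sprintf("subject_risks: %d subjects (%d CAD / %d nonCAD)\n",
              nrow(x), sum(x$label == "CAD"), sum(x$label == "nonCAD")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(center - half, center + half)
}

roc_of <- function(labels, risks) {
  pROC::roc(response = labels, predictor = risks,
            levels = c("nonCAD", "CAD"), direction = "<", quiet = TRUE)
}

#' Cohort-level performance metrics
#'
#' For each of the nine models (six single-channel, three fused) computes:
#' AUC with DeLong 95% CI; sensitivity, specificity, PPV and NPV at the
#' decision threshold, each with a Wilson 95% CI; the F1 score; and the
#' discrimination slope (mean predicted risk of the CAD group minus mean
#' predicted risk of the non-CAD group).
#'
#' @param risks A `subject_risks` data frame from [loso_run()].
#' @param threshold Decision threshold on predicted risk.
#' @return A `data.frame` of class `scg_metrics`, one row per model.
#' @export
compute_metrics <- function(risks, threshold = 0.5) {
  if (length(unique(risks$label)) < 2)
    stop("both classes must be present to compute metrics")
  y <- risks$label
  res <- lapply(MODEL_NAMES, function(m) {
    r <- risks[[m]]
    roc <- roc_of(y, r)
    auc <- as.numeric(pROC::auc(roc))
    ci <- tryCatch(
      suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong"))[c(1, 3)]),
      error = function(e) c(NA_real_, NA_real_))
    pred <- r > threshold
    tp <- sum(pred & y == "CAD"); fn <- sum(!pred & y == "CAD")
    tn <- sum(!pred & y == "nonCAD"); fp <- sum(pred & y == "nonCAD")
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f1 <- if (!is.na(ppv) && (ppv + sens) > 0) 2 * ppv * sens / (ppv + sens)
          else NA_real_
    sens_ci <- wilson_ci(tp, tp + fn); spec_ci <- wilson_ci(tn, tn + fp)
    ppv_ci <- wilson_ci(tp, tp + fp); npv_ci <- wilson_ci(tn, tn + fn)
    slope <- mean(r[y == "CAD"]) - mean(r[y == "nonCAD"])
    data.frame(model = m, auc = auc, auc_lo = ci[1], auc_hi = ci[2],
               f1 = f1,
               sensitivity = sens, sens_lo = sens_ci[1], sens_hi = sens_ci[2],
               specificity = spec, spec_lo = spec_ci[1], spec_hi = spec_ci[2],
               ppv = ppv, ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2],
               npv = npv, npv_lo = npv_ci[1], npv_hi = npv_ci[2],
               discrimination_slope = slope, threshold = threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("scg_metrics", class(out))
  out
}

#' @export
`[.scg_metrics` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- setdiff(class(out), "scg_metrics")
  out
}

#' @export
`[.subject_risks` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- setdiff(class(out), "subject_risks")
  out
}

#' @export
print.scg_metrics <- function(x, ...) {
  cat("cohort performance (one row per model):\n")
  df <- data.frame(model = x$model,
                   AUC = sprintf("%.2f (%.2f-%.2f)", x$auc, x$auc_lo, x$auc_hi),
                   F1 = sprintf("%.2f", x$f1),
                   sens = sprintf("%.2f", x$sensitivity),
                   spec = sprintf("%.2f", x$specificity),
                   slope = sprintf("%.2f", x$discrimination_slope))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two models' AUCs
#'
#' DeLong's paired test on the two models' risk scores over the common
#' subject set. Comparing a model with itself (identical scores) returns
#' p = 1 by convention, since the paired difference is degenerate.
#'
#' @param risks A `subject_risks` data frame.
#' @param model_a,model_b Model names among
#'   `scg_x, scg_y, scg_z, gcg_x, gcg_y, gcg_z, all_axes, scg_axes,
#'   gcg_axes`.
#' @return The two-sided p-value.
#' @export
compare_models <- function(risks, model_a, model_b) {
  stopifnot(model_a %in% MODEL_NAMES, model_b %in% MODEL_NAMES)
  ra <- risks[[model_a]]; rb <- risks[[model_b]]
  if (length(ra) != length(rb) || any(is.na(ra)) || any(is.na(rb)))
    stop("models must be scored on the same subjects")
  if (isTRUE(all.equal(ra, rb))) return(1.0)
  ta <- roc_of(risks$label, ra)
  tb <- roc_of(risks$label, rb)
  out <- tryCatch(pROC::roc.test(ta, tb, method = "delong", paired = TRUE),
                  error = function(e) NULL)
  if (is.null(out) || is.na(out$p.value)) return(1.0)
  as.numeric(out$p.value)
}
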