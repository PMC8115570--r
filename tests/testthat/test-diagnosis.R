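test_that("similarity counts agreeing positions", {
  a <- matrix(1L, 200, 350)
  expect_identical(similarity(a, a), 70000L)
  expect_identical(similarity(a, 1L - a), 0L)
  expect_error(similarity(matrix(0, 2, 2), matrix(0, 3, 3)), "same shape")

  # random pairs match a double-loop oracle
  set.seed(3)
  for (rep in 1:5) {
    f <- matrix(rbinom(16, 1, 0.5), 4, 4)
    s <- matrix(rbinom(16, 1, 0.5), 4, 4)
    cnt <- 0L
    for (i in 1:4) for (j in 1:4) if (f[i, j] == s[i, j]) cnt <- cnt + 1L
    expect_identical(similarity(f, s), cnt)
  }
})

test_that("similarity complement identity holds for every pair", {
  set.seed(4)
  for (rep in 1:10) {
    f <- matrix(rbinom(200, 1, runif(1)), 10, 20)
    s <- matrix(rbinom(200, 1, runif(1)), 10, 20)
    expect_identical(similarity(f, s) + similarity(f, 1L - s), 200L)
  }
})

test_that("the sparse similarity shortcut agrees with the matrix count", {
  set.seed(5)
  for (rep in 1:10) {
    s <- matrix(rbinom(300, 1, 0.3), 15, 20)
    fix_idx <- sample(300, sample(0:20, 1))
    f <- matrix(0L, 15, 20); f[fix_idx] <- 1L
    expect_identical(
      gazevam:::similarity_sparse(s, sum(s), fix_idx),
      as.integer(similarity(f, s)))
  }
})

test_that("frame votes go to the more similar group, ties to control", {
  f <- matrix(0L, 4, 4); f[1, 1] <- 1L
  sa <- f                      # identical to the fixation map
  sb <- 1L - f                 # complementary
  expect_identical(frame_vote(f, sa, sb), "case")
  expect_identical(frame_vote(f, sb, sa), "control")
  expect_identical(frame_vote(f, sa, sa), "control")  # tie
})

test_that("subjects are classified by the vote threshold", {
  expect_identical(classify_subject(28, 28), "case")
  expect_identical(classify_subject(27, 28), "control")
  expect_identical(classify_subject(0, 1), "control")
  expect_identical(classify_subject(0, 0), "case")  # threshold 0: all case
  expect_error(classify_subject(5, -1), "non-negative")
})

test_that("vote-threshold ROC matches the Mann-Whitney oracle", {
  counts <- c(40, 35, 28, 20, 12, 30)
  labels <- c("case", "case", "case", "control", "control", "control")
  roc <- roc_votes(counts, labels, case = "case", n_frames = 50)
  # pairwise U-statistic oracle
  pos <- counts[labels == "case"]; neg <- counts[labels == "control"]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  expect_equal(attr(roc, "auc"), u / (length(pos) * length(neg)))

  # perfectly separated counts
  roc1 <- roc_votes(c(40, 45, 5, 2), c("case", "case", "control", "control"),
                    n_frames = 50)
  expect_equal(attr(roc1, "auc"), 1)

  # exchangeable counts give exactly chance
  roc5 <- roc_votes(c(1, 2, 3, 1, 2, 3),
                    rep(c("case", "control"), each = 3), n_frames = 3)
  expect_equal(attr(roc5, "auc"), 0.5)

  expect_error(roc_votes(1:3, rep("case", 3)), "both classes")
})

test_that("ROC sweeps are monotone and label-swap symmetric", {
  set.seed(6)
  counts <- rbinom(30, 50, runif(30, 0.2, 0.8))
  labels <- rep(c("case", "control"), 15)
  roc <- roc_votes(counts, labels, n_frames = 50)
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  expect_true(all(roc$sensitivity >= 0 & roc$sensitivity <= 1))

  swapped <- ifelse(labels == "case", "control", "case")
  expect_equal(attr(roc_votes(counts, swapped, n_frames = 50), "auc"),
               1 - attr(roc, "auc"))
})

test_that("the Youden threshold maximises J with smallest-threshold ties", {
  # perfect separation at the gap
  roc <- roc_votes(c(40, 45, 5, 2), c("case", "case", "control", "control"),
                   n_frames = 50)
  th <- youden_threshold(roc)
  expect_equal(roc$youden[roc$threshold == th], 1)
  expect_true(th > 5 && th <= 40)

  # exhaustive-scan oracle on a small fixture
  counts <- c(4, 3, 2, 2, 1)
  labels <- c("case", "case", "control", "case", "control")
  roc2 <- roc_votes(counts, labels, n_frames = 5)
  best <- Inf; bestJ <- -Inf
  for (t in 0:6) {
    sens <- mean(counts[labels == "case"] >= t)
    spec <- mean(counts[labels == "control"] < t)
    if (sens + spec - 1 > bestJ) { bestJ <- sens + spec - 1; best <- t }
  }
  expect_identical(youden_threshold(roc2), best)

  # flat J: smallest threshold wins
  flat <- data.frame(threshold = 0:3, youden = rep(0, 4))
  expect_identical(youden_threshold(flat), 0L)
  expect_error(youden_threshold(flat[1, , drop = FALSE]), "two thresholds")
})

test_that("cross-validation folds partition subjects with both classes in training", {
  m <- tiny_manifest()
  coh <- simulate_cohort(
    m, n_per_group = 5,
    params_case = phenotype_params(p_geometric = 0.8, center_bias_sigma = 18),
    params_control = phenotype_params(p_geometric = 0.2, center_bias_sigma = 18),
    sampling_rate = 120, seed = 13)
  stim <- prepare_stimulus(coh$prep, n_diag_frames = 6, seed = 13)
  cv <- vam_crossval(coh$mapped, coh$labels, stim, case = "case", k = 5,
                     n_pos = 150, n_neg = 150,
                     control = vam_control(max_epochs = 60), seed = 13)
  expect_s3_class(cv, "vam_cv")
  # each fold tests exactly 2 subjects (20% of 10), one per class
  expect_true(all(table(cv$votes$fold) == 2))
  expect_true(all(table(cv$votes$fold, cv$votes$label) == 1))
  # every subject appears in exactly one test fold
  expect_identical(sort(cv$votes$subject), sort(names(coh$mapped)))
  # rates and AUC are proper proportions
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  ok <- !is.na(cv$folds$sensitivity)
  expect_true(all(cv$folds$sensitivity[ok] >= 0 & cv$folds$sensitivity[ok] <= 1))
  expect_true(all(cv$votes$case_votes <= length(stim$diag_frames)))
  expect_output(print(cv), "cross-validation")

  # the pluggable selectors run end to end and restrict the models
  cv_rel <- vam_crossval(coh$mapped, coh$labels, stim, case = "case", k = 2,
                         n_pos = 150, n_neg = 150, selector = "relief",
                         n_top = 8, control = vam_control(max_epochs = 40),
                         seed = 13)
  expect_s3_class(cv_rel, "vam_cv")
  expect_identical(cv_rel$selector, "relief")

  cv_ga <- vam_crossval(
    coh$mapped, coh$labels, stim, case = "case", k = 2,
    n_pos = 100, n_neg = 100, selector = "ga",
    select_control = ga_control(population_size = 6, generations = 2,
                                subset_size_target = 8, fitness_epochs = 5),
    control = vam_control(max_epochs = 40), seed = 13)
  expect_s3_class(cv_ga, "vam_cv")

  # the learned group models recover the side preference: the case model
  # predicts fixation mostly on the geometric half, the control model on
  # the biological half
  m_case <- gazevam:::fit_group_vam(stim, coh$mapped[coh$labels == "case"],
                                    "case", 150, 150, "none", NULL, 15,
                                    vam_control(max_epochs = 200), 13)
  m_ctrl <- gazevam:::fit_group_vam(stim, coh$mapped[coh$labels == "control"],
                                    "control", 150, 150, "none", NULL, 15,
                                    vam_control(max_epochs = 200), 13)
  geo_fraction <- function(model) {
    fr <- vapply(seq_along(stim$diag_frames), function(j) {
      f <- stim$diag_frames[j]
      sal <- binary_saliency_map(model, stim$diag_stacks[[j]])
      geo_cols <- if (coh$prep$side[f] == "left") 176:350 else 1:175
      sum(sal[, geo_cols]) / max(sum(sal), 1)
    }, numeric(1))
    mean(fr)
  }
  expect_gt(geo_fraction(m_case), 0.8)
  expect_lt(geo_fraction(m_ctrl), 0.2)

  # pluggable learner slot: a logistic-regression wrapper stands in for
  # the network and runs through the same harness
  logit_learner <- function(x, y, subset = NULL, group = "g",
                            control = NULL, seed = 1) {
    keep <- if (is.null(subset)) colnames(x) else subset
    df <- as.data.frame(x[, keep, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                       family = stats::binomial()))
    structure(list(fit = fit, keep = keep, group = group),
              class = "logit_vam")
  }
  registerS3method("predict", "logit_vam", function(object, newdata, ...) {
    nd <- as.data.frame(newdata[, object$keep, drop = FALSE])
    suppressWarnings(as.numeric(stats::predict(object$fit, newdata = nd,
                                               type = "response")))
  }, envir = asNamespace("stats"))
  cv_glm <- vam_crossval(coh$mapped, coh$labels, stim, case = "case", k = 2,
                         n_pos = 100, n_neg = 100, learner = logit_learner,
                         seed = 13)
  expect_s3_class(cv_glm, "vam_cv")
  expect_true(all(cv_glm$folds$auc >= 0 & cv_glm$folds$auc <= 1))
})
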