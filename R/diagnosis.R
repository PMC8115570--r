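#' Similarity between an individual fixation map and a saliency map
#'
#' The number of positions where the two binary maps agree — i.e. where
#' the model correctly predicts whether the pixel was fixated.  Ranges
#' from 0 to the number of pixels (70000 on the 200 x 350 working grid).
#'
#' @param fix binary individual fixation map.
#' @param sal binary saliency map of the same shape.
#' @return Integer match count.
#' @export
similarity <- function(fix, sal) {
  if (!identical(dim(fix), dim(sal)))
    stop("fixation and saliency maps must have the same shape")
  sum(fix == sal)
}

# Same count without materialising the fixation matrix: `fix_idx` are the
# linear indices of fixated pixels, `sal_ones` = sum(sal).
similarity_sparse <- function(sal, sal_ones, fix_idx) {
  length(sal) - sal_ones - length(fix_idx) + 2L * sum(sal[fix_idx])
}

#' Per-frame group vote
#'
#' The group whose binary saliency map agrees more with the subject's
#' fixation map receives the frame's vote.  Equal similarity is resolved
#' conservatively to the control group.
#'
#' @param fix binary individual fixation map.
#' @param sal_case,sal_control binary saliency maps of the case and
#'   control groups.
#' @return `"case"` or `"control"`.
#' @export
frame_vote <- function(fix, sal_case, sal_control) {
  if (similarity(fix, sal_case) > similarity(fix, sal_control)) "case"
  else "control"
}

#' Classify a subject from their case-vote count
#'
#' @param case_votes number of diagnosis frames voting for the case group.
#' @param threshold vote threshold: the subject is labelled case iff
#'   `case_votes >= threshold`.
#' @param labels length-2 character vector `c(case, control)` naming the
#'   returned labels.
#' @return The assigned label.
#' @export
classify_subject <- function(case_votes, threshold,
                             labels = c("case", "control")) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (case_votes >= threshold) labels[1] else labels[2]
}

#' ROC over integer vote thresholds, with trapezoidal AUC
#'
#' Sweeps the rule "classify as case when the vote count is at least t"
#' over every integer threshold from 0 to `n_frames + 1` (the extra
#' endpoint closes the curve at sensitivity 0 / specificity 1) and
#' computes sensitivity and specificity against the true labels.  The AUC
#' is the trapezoidal integral of the curve, which for integer counts
#' equals the Mann-Whitney probability with ties counted one half.
#'
#' @param counts integer case-vote counts, one per subject.
#' @param labels true group label per subject.
#' @param case label value counted as positive.
#' @param n_frames number of diagnosis frames (maximum possible count);
#'   default `max(counts)`.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, `youden`, and attribute `auc`.
#' @export
roc_votes <- function(counts, labels, case = "case", n_frames = max(counts)) {
  pos <- labels == case
  if (all(pos) || !any(pos))
    stop("both classes must be present to build a ROC curve")
  th <- 0:(n_frames + 1L)
  sens <- vapply(th, function(t) mean(counts[pos] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(counts[!pos] < t), numeric(1))
  roc <- data.frame(threshold = th, sensitivity = sens, specificity = spec,
                    youden = sens + spec - 1)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  attr(roc, "auc") <- abs(auc)
  roc
}

#' Youden-index operating threshold
#'
#' The vote threshold maximising J = sensitivity + specificity - 1; ties
#' go to the smallest threshold.
#'
#' @param roc a [roc_votes()] data frame.
#' @return The selected integer threshold.
#' @export
youden_threshold <- function(roc) {
  if (nrow(roc) < 2) stop("need at least two thresholds")
  roc$threshold[which.max(roc$youden)]
}

#' Precompute the stimulus-side inputs of learning and diagnosis
#'
#' Splits the preprocessed frames into diagnosis frames (sampled uniformly
#' across segments, seed-controlled, emulating an independent diagnosis
#' video) and learning frames; aggregates the learning frames into
#' low-motion frame sets; and computes the 28-channel feature stacks —
#' per-frame for diagnosis frames, frame-set means (streamed, so only one
#' stack per set is retained) for learning.  Everything here depends only
#' on the stimulus, so it is shared by all cross-validation folds.
#'
#' @param prep a [preprocess_stimulus()] result.
#' @param n_diag_frames diagnosis frames held out from learning.
#' @param threshold frame-aggregation motion threshold.
#' @param estimator,max_displacement motion estimator settings.
#' @param detectors semantic detectors used when `prep` carries no oracle
#'   masks.
#' @param seed seed for the diagnosis-frame draw.
#' @return Object of class `vam_stimulus` with `framesets`,
#'   `frameset_stacks`, `diag_frames`, `diag_stacks`, `dim` and the
#'   settings used.
#' @export
prepare_stimulus <- function(prep, n_diag_frames = 50, threshold = 0.33,
                             estimator = c("difference", "flow"),
                             max_displacement = 10,
                             detectors = default_detectors(), seed = 1) {
  stopifnot(inherits(prep, "frame_sequence"))
  estimator <- match.arg(estimator)
  nf <- length(prep$frames)
  if (n_diag_frames >= nf)
    stop("n_diag_frames must leave at least one learning frame")

  # stratified draw of diagnosis frames across segments
  segs <- prep$manifest$segments
  quota <- (segs$end_frame - segs$start_frame + 1L) / nf * n_diag_frames
  n_i <- floor(quota)
  rem <- order(-(quota - n_i))
  n_i[rem[seq_len(n_diag_frames - sum(n_i))]] <-
    n_i[rem[seq_len(n_diag_frames - sum(n_i))]] + 1L
  diag_frames <- with_seed(seed, {
    sort(unlist(lapply(seq_len(nrow(segs)), function(i) {
      if (n_i[i] == 0) return(integer(0))
      sample(segs$start_frame[i]:segs$end_frame[i], n_i[i])
    })))
  })
  learn_frames <- setdiff(seq_len(nf), diag_frames)

  sets <- aggregate_frames(prep$frames[learn_frames], threshold,
                           estimator, max_displacement)
  for (i in seq_along(sets))
    sets[[i]]$members <- learn_frames[sets[[i]]$members]
  set_of_frame <- rep(NA_integer_, nf)
  for (i in seq_along(sets)) set_of_frame[sets[[i]]$members] <- i

  # one streamed pass over all frames, in display order
  sums <- vector("list", length(sets))
  diag_stacks <- vector("list", length(diag_frames))
  names(diag_stacks) <- as.character(diag_frames)
  prev <- NULL
  for (f in seq_len(nf)) {
    masks_f <- if (!is.null(prep$masks))
      list(face = prep$masks$face[[f]], person = prep$masks$person[[f]])
    else NULL
    stack <- extract_feature_stack(prep$frames[[f]], prep$side[f],
                                   prev_frame = prev, masks = masks_f,
                                   detectors = detectors,
                                   estimator = estimator,
                                   max_displacement = max_displacement)
    if (f %in% diag_frames) {
      diag_stacks[[as.character(f)]] <- stack
    } else {
      si <- set_of_frame[f]
      sums[[si]] <- if (is.null(sums[[si]])) unclass(stack)
                    else sums[[si]] + unclass(stack)
    }
    prev <- prep$frames[[f]]
  }
  frameset_stacks <- lapply(seq_along(sets), function(i) {
    s <- sums[[i]] / length(sets[[i]]$members)
    dimnames(s) <- list(NULL, NULL, vam_channels())
    class(s) <- c("feature_stack", class(s))
    s
  })

  structure(list(framesets = sets,
                 frameset_stacks = frameset_stacks,
                 diag_frames = diag_frames,
                 diag_stacks = diag_stacks,
                 dim = prep$dim,
                 threshold = threshold,
                 estimator = estimator,
                 seed = seed),
            class = "vam_stimulus")
}

#' @export
print.vam_stimulus <- function(x, ...) {
  cat(sprintf(
    "Prepared stimulus: %d frame sets over %d learning frames, %d diagnosis frames\n",
    length(x$framesets),
    sum(vapply(x$framesets, function(s) length(s$members), 1L)),
    length(x$diag_frames)))
  invisible(x)
}

# Fit one group's VAM from the training subjects' pooled gaze.
fit_group_vam <- function(stim, group_samples, group, n_pos, n_neg,
                          selector, select_control, n_top, control, seed,
                          learner = vam) {
  agg <- aggregate_gaze(group_samples, stim$framesets)
  xs <- list(); ys <- list()
  for (i in seq_along(stim$framesets)) {
    gmap <- group_fixation_map(agg[agg$set_id == i, , drop = FALSE],
                               dim = stim$dim)
    coords <- tryCatch(
      select_coordinates(gmap, n_pos, n_neg, seed = seed + i),
      error = function(e) {
        warning("frame set ", i, " skipped for group '", group, "': ",
                conditionMessage(e))
        NULL
      })
    if (is.null(coords)) next
    pv <- build_training_vectors(stim$frameset_stacks[[i]], coords)
    xs[[length(xs) + 1L]] <- pv$x
    ys[[length(ys) + 1L]] <- pv$y
  }
  if (length(xs) == 0)
    stop("no frame set provided enough fixation support for group '",
         group, "'")
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  subset <- switch(selector,
    none = NULL,
    ga = ga_select(x, y, control = select_control, seed = seed),
    relief = {
      # Relief is quadratic in instances; score on a stratified subsample
      idx <- if (nrow(x) > 600) {
        with_seed(seed, unlist(lapply(split(seq_along(y), y), function(i)
          sample(i, min(length(i), 300)))))
      } else seq_along(y)
      w <- relief_scores(x[idx, , drop = FALSE], y[idx])
      names(sort(w, decreasing = TRUE))[seq_len(n_top)]
    })
  learner(x, y, subset = subset, group = group, control = control,
          seed = seed)
}

# Vote counts of a set of subjects over the diagnosis frames.
vote_counts <- function(stim, mapped_list, sal_case, sal_control) {
  hw <- prod(stim$dim)
  ones_case <- lapply(sal_case, sum)
  ones_ctrl <- lapply(sal_control, sum)
  vapply(mapped_list, function(mp) {
    votes <- 0L
    for (j in seq_along(stim$diag_frames)) {
      f <- stim$diag_frames[j]
      sub <- mp[mp$valid & !is.na(mp$frame) & mp$frame == f, , drop = FALSE]
      fix_idx <- unique(sub$row + 1L + sub$col * stim$dim[1])
      sc <- similarity_sparse(sal_case[[j]], ones_case[[j]], fix_idx)
      st <- similarity_sparse(sal_control[[j]], ones_ctrl[[j]], fix_idx)
      if (sc > st) votes <- votes + 1L
    }
    votes
  }, integer(1))
}

#' Subject-wise cross-validated evaluation of the full pipeline
#'
#' Runs the complete two-phase method under k-fold cross-validation over
#' subjects: in each fold the two group VAMs are learned from the training
#' subjects' gaze on the learning frame sets, both VAMs are applied to
#' each held-out diagnosis frame to produce binary saliency maps, and each
#' test subject is classified by per-frame voting.  The vote threshold is
#' chosen per fold by the Youden index — by default on the fold's own test
#' ROC, mirroring the published evaluation (optimistic); set
#' `threshold_mode = "train"` for the honest nested variant that derives
#' the threshold from the training subjects.
#'
#' @param mapped named list of `mapped_gaze` data frames, one per subject
#'   (see [map_gaze()]).
#' @param labels group label per subject (same order/names as `mapped`);
#'   exactly two distinct values.
#' @param stim a [prepare_stimulus()] result.
#' @param case the label value treated as the case group.
#' @param k folds.
#' @param n_pos,n_neg training coordinates per fixation map.
#' @param selector `"none"` (all 28 features), `"ga"` or `"relief"`.
#' @param select_control [ga_control()] used when `selector = "ga"`.
#' @param n_top subset size for `selector = "relief"`.
#' @param control [vam_control()] for the final fits.
#' @param learner pixel-classifier slot: a function
#'   `(x, y, subset, group, control, seed)` returning a fitted model whose
#'   `predict(model, feature_matrix)` yields fixation probabilities.
#'   Defaults to [vam()]; supplying e.g. an SVM wrapper re-runs the
#'   classifier/selector comparison grid with another learner.
#' @param threshold_mode `"test"` (per-fold Youden on the test ROC, as
#'   published) or `"train"`.
#' @param seed integer seed (fold assignment, coordinate sampling, network
#'   initialisation).
#' @return Object of class `vam_cv`: per-fold metrics (`folds`), their
#'   means (`mean`), per-subject vote counts (`votes`), per-fold ROC
#'   curves (`roc`) and the settings.
#' @export
vam_crossval <- function(mapped, labels, stim, case = "case", k = 5,
                         n_pos = 350, n_neg = 350,
                         selector = c("none", "ga", "relief"),
                         select_control = ga_control(),
                         n_top = 15,
                         control = vam_control(),
                         learner = vam,
                         threshold_mode = c("test", "train"),
                         seed = 1) {
  selector <- match.arg(selector)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(stim, "vam_stimulus"))
  labels <- as.character(labels)
  if (length(labels) != length(mapped))
    stop("one label per subject required")
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required")
  if (!case %in% groups) stop("case label '", case, "' not found")
  ctrl_lab <- setdiff(groups, case)
  nd <- length(stim$diag_frames)

  fold <- stratified_folds(as.integer(labels == case), k, seed)
  folds_df <- data.frame(fold = seq_len(k), auc = NA_real_,
                         threshold = NA_real_, precision = NA_real_,
                         sensitivity = NA_real_, specificity = NA_real_)
  votes_df <- data.frame(subject = names(mapped), label = labels,
                         fold = fold, case_votes = NA_integer_,
                         predicted = NA_character_,
                         stringsAsFactors = FALSE)
  rocs <- vector("list", k)

  for (kf in seq_len(k)) {
    tr <- which(fold != kf)
    te <- which(fold == kf)
    if (length(unique(labels[tr])) < 2)
      stop("fold ", kf, ": a class is absent from the training subjects")
    m_case <- fit_group_vam(stim, mapped[tr][labels[tr] == case], case,
                            n_pos, n_neg, selector, select_control, n_top,
                            control, seed + kf, learner)
    m_ctrl <- fit_group_vam(stim, mapped[tr][labels[tr] == ctrl_lab],
                            ctrl_lab, n_pos, n_neg, selector,
                            select_control, n_top, control, seed + kf,
                            learner)
    sal_case <- lapply(stim$diag_stacks, function(s) binary_saliency_map(m_case, s))
    sal_ctrl <- lapply(stim$diag_stacks, function(s) binary_saliency_map(m_ctrl, s))

    counts_te <- vote_counts(stim, mapped[te], sal_case, sal_ctrl)
    roc_te <- roc_votes(counts_te, labels[te], case = case, n_frames = nd)
    th <- if (threshold_mode == "test") {
      youden_threshold(roc_te)
    } else {
      counts_tr <- vote_counts(stim, mapped[tr], sal_case, sal_ctrl)
      youden_threshold(roc_votes(counts_tr, labels[tr], case = case,
                                 n_frames = nd))
    }
    pred <- ifelse(counts_te >= th, case, ctrl_lab)
    tp <- sum(pred == case & labels[te] == case)
    fp <- sum(pred == case & labels[te] != case)
    fn <- sum(pred != case & labels[te] == case)
    tn <- sum(pred != case & labels[te] != case)
    folds_df$auc[kf] <- attr(roc_te, "auc")
    folds_df$threshold[kf] <- th
    folds_df$precision[kf] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    folds_df$sensitivity[kf] <- tp / (tp + fn)
    folds_df$specificity[kf] <- tn / (tn + fp)
    votes_df$case_votes[fold == kf] <- counts_te
    votes_df$predicted[fold == kf] <- pred
    rocs[[kf]] <- roc_te
  }

  means <- colMeans(folds_df[, -1], na.rm = TRUE)
  structure(list(folds = folds_df, mean = means, votes = votes_df,
                 roc = rocs, case = case, control_label = ctrl_lab,
                 k = k, n_diag_frames = nd, selector = selector,
                 threshold_mode = threshold_mode, seed = seed),
            class = "vam_cv")
}

#' @export
print.vam_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold subject-wise cross-validation (%d diagnosis frames, selector '%s')\n",
    x$k, x$n_diag_frames, x$selector))
  print(x$folds, row.names = FALSE, digits = 3)
  cat(sprintf(
    "mean: AUC %.3f | precision %.3f | sensitivity %.3f | specificity %.3f | threshold %.1f\n",
    x$mean["auc"], x$mean["precision"], x$mean["sensitivity"],
    x$mean["specificity"], x$mean["threshold"]))
  invisible(x)
}
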