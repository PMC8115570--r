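#' Training configuration for a visual attention model
#'
#' Defaults follow the published training regime: at most 1000 cycles of
#' per-sample stochastic gradient descent, stopping early when the mean
#' epoch binary cross-entropy falls below `1e-7`, learning rate 0.01, ten
#' sigmoid hidden units and a linear output unit.  A linear output paired
#' with binary cross-entropy is read as logits-with-BCE: the logistic link
#' is applied inside the loss and at prediction, the only numerically
#' coherent interpretation.
#'
#' @param hidden hidden-layer width.
#' @param max_epochs maximum training cycles over the data.
#' @param learning_rate SGD step size.
#' @param loss_tolerance stop when the mean epoch loss drops below this.
#' @return List of class `vam_control`.
#' @export
vam_control <- function(hidden = 10, max_epochs = 1000, learning_rate = 0.01,
                        loss_tolerance = 1e-7) {
  stopifnot(hidden >= 1, max_epochs >= 1, learning_rate > 0,
            loss_tolerance > 0)
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 loss_tolerance = loss_tolerance),
            class = "vam_control")
}

#' Fit a visual attention model for one group
#'
#' A visual attention model (VAM) is a per-pixel binary classifier: given
#' the feature vector of a pixel, it predicts whether a viewer from the
#' model's group will fixate that pixel.  The classifier is a
#' single-hidden-layer neural network trained by per-sample stochastic
#' gradient descent on binary cross-entropy (see [vam_control()]).
#' Features are min-max normalised on the training data; the fitted
#' normalisation is stored and reapplied at prediction.
#'
#' @param x numeric matrix of pixel feature vectors (rows = pixels,
#'   named columns), or a `pixel_vectors` object (then `y` is taken from
#'   it).
#' @param y 0/1 labels (1 = fixated); both classes must be present.
#' @param subset optional feature subset: a `feature_subset` from
#'   [ga_select()], a logical mask over columns, or a character vector of
#'   feature names.  Default uses all columns.
#' @param group label stored with the model (e.g. `"case"`).
#' @param control a [vam_control()].
#' @param seed integer seed for weight initialisation and shuffling; the
#'   fit is deterministic given `(x, y, subset, control, seed)`.
#' @return Object of class `vam` with weights, the feature subset, the
#'   normalisation state, the loss history and training metadata.
#'   Supports `print`, `summary`, `coef`, `predict`, `plot` and
#'   `residuals`.
#' @examples
#' set.seed(1)
#' x <- cbind(a = runif(200), b = runif(200))
#' y <- as.integer(x[, 1] + x[, 2] > 1)
#' m <- vam(x, y, group = "demo", seed = 1,
#'          control = vam_control(max_epochs = 200))
#' mean((predict(m, x) >= 0.5) == y)
#' @export
vam <- function(x, y = NULL, subset = NULL, group = "group",
                control = vam_control(), seed = 1) {
  if (inherits(x, "pixel_vectors")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("x and y lengths differ")
  if (length(unique(y)) < 2)
    stop("both classes must be present to fit a VAM")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")

  keep <- resolve_subset(subset, colnames(x), ncol(x))
  xs <- x[, keep, drop = FALSE]

  mins <- apply(xs, 2, min)
  rngs <- apply(xs, 2, max) - mins
  rngs[rngs <= 0] <- 1
  xn <- sweep(sweep(xs, 2, mins), 2, rngs, "/")

  fit <- mlp_train_cpp(xn, y, control$hidden, control$max_epochs,
                       control$learning_rate, control$loss_tolerance,
                       as.integer(seed))
  prob <- mlp_forward(fit, xn)
  obj <- structure(list(
    group = group,
    features = colnames(xs),
    subset = keep,
    w1 = fit$w1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
    norm = list(min = mins, range = rngs),
    loss = fit$loss,
    final_loss = fit$loss[length(fit$loss)],
    epochs = fit$epochs,
    fitted = prob,
    y = y,
    control = control,
    seed = as.integer(seed)
  ), class = "vam")
  obj
}

resolve_subset <- function(subset, nms, p) {
  if (is.null(subset)) return(seq_len(p))
  if (inherits(subset, "feature_subset")) subset <- subset$names
  if (is.logical(subset)) {
    if (length(subset) != p) stop("logical subset length must match columns")
    return(which(subset))
  }
  if (is.character(subset)) {
    idx <- match(subset, nms)
    if (anyNA(idx)) stop("unknown feature names in subset: ",
                         paste(subset[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(subset)
}

# forward pass (vectorised): rows of xn are samples
mlp_forward <- function(fit, xn) {
  z1 <- tcrossprod(xn, fit$w1)
  z1 <- sweep(z1, 2, fit$b1, "+")
  a1 <- stats::plogis(z1)
  as.vector(stats::plogis(a1 %*% fit$w2 + fit$b2))
}

#' Predict fixation probability for pixel feature vectors
#'
#' @param object a fitted [vam()].
#' @param newdata matrix of feature vectors with the model's feature
#'   columns (extra columns are selected by name), or a `feature_stack`
#'   array (then a probability matrix over the frame grid is returned).
#' @param type `"response"` for probabilities in `[0, 1]`, `"class"` for
#'   the 0/1 decision at the 0.5 threshold (ties, p = 0.5, go to 1).
#' @param ... unused.
#' @return Numeric vector (or matrix for stacks) of predictions.
#' @export
predict.vam <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  as_map <- FALSE
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    d <- dim(newdata)
    as_map <- TRUE
    idx <- match(object$features, dimnames(newdata)[[3]])
    if (anyNA(idx)) stop("feature stack lacks channels: ",
                         paste(object$features[is.na(idx)], collapse = ", "))
    newdata <- matrix(newdata[, , idx], d[1] * d[2], length(idx))
    colnames(newdata) <- object$features
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata))) {
      missing <- setdiff(object$features, colnames(newdata))
      if (length(missing) > 0)
        stop("newdata lacks model feature columns: ",
             paste(missing, collapse = ", "))
      newdata <- newdata[, object$features, drop = FALSE]
    } else if (ncol(newdata) != length(object$features)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           length(object$features))
    }
  }
  xn <- sweep(sweep(newdata, 2, object$norm$min), 2, object$norm$range, "/")
  prob <- mlp_forward(object, xn)
  res <- if (type == "class") as.integer(prob >= 0.5) else prob
  if (as_map) matrix(res, d[1], d[2]) else res
}

#' Binary saliency map of a frame under a group's attention model
#'
#' Applies a fitted pixel classifier to every pixel of a feature stack and
#' thresholds the fixation probability at 0.5 (`>= 0.5` maps to 1).  Works
#' with any model whose `predict(model, feature_matrix)` returns fixation
#' probabilities (the pluggable-learner contract used by
#' [vam_crossval()]); rows of the matrix are pixels, columns the named
#' channels.
#'
#' @param model a fitted [vam()] or any conforming pixel classifier.
#' @param stack H x W x 28 `feature_stack` (per-frame or frame-set mean).
#' @return Binary integer matrix of class `saliency_map`, attribute
#'   `group`.
#' @export
binary_saliency_map <- function(model, stack) {
  d <- dim(stack)
  m <- matrix(stack, d[1] * d[2], d[3])
  colnames(m) <- dimnames(stack)[[3]]
  prob <- as.numeric(stats::predict(model, m))
  bits <- matrix(as.integer(prob >= 0.5), d[1], d[2])
  attr(bits, "group") <- model$group
  class(bits) <- c("saliency_map", class(bits))
  bits
}

#' @export
print.vam <- function(x, ...) {
  cat(sprintf("Visual attention model for group '%s'\n", x$group))
  cat(sprintf("  features: %d (%s%s)\n", length(x$features),
              paste(utils::head(x$features, 4), collapse = ", "),
              if (length(x$features) > 4) ", ..." else ""))
  cat(sprintf("  hidden units: %d | epochs run: %d | final BCE: %.5g\n",
              x$control$hidden, x$epochs, x$final_loss))
  invisible(x)
}

#' @export
summary.vam <- function(object, ...) {
  acc <- mean((object$fitted >= 0.5) == object$y)
  structure(list(group = object$group, n = length(object$y),
                 features = object$features, epochs = object$epochs,
                 final_loss = object$final_loss, train_accuracy = acc),
            class = "summary.vam")
}

#' @export
print.summary.vam <- function(x, ...) {
  cat(sprintf("VAM summary (group '%s')\n", x$group))
  cat(sprintf("  %d training pixels, %d features, %d epochs\n",
              x$n, length(x$features), x$epochs))
  cat(sprintf("  final mean BCE: %.5g | training accuracy: %.3f\n",
              x$final_loss, x$train_accuracy))
  invisible(x)
}

#' @export
coef.vam <- function(object, ...) {
  w1 <- object$w1
  dimnames(w1) <- list(paste0("h", seq_len(nrow(w1))), object$features)
  list(hidden = w1, hidden_bias = object$b1,
       output = object$w2, output_bias = object$b2)
}

#' @export
plot.vam <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "mean binary cross-entropy",
                 main = sprintf("VAM training loss (group '%s')", x$group), ...)
  invisible(x)
}

#' @export
residuals.vam <- function(object, ...) {
  object$y - object$fitted
}
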