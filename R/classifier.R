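#' Feed-forward classifier configuration
#'
#' Two ReLU hidden layers of 50 and 10 units feeding a softmax output, fit
#' by minibatch stochastic gradient descent on the categorical
#' cross-entropy, with early stopping on a held-out validation slice of
#' the training vectors.
#'
#' @param hidden_sizes integer vector of hidden-layer widths
#'   (default `c(50, 10)`).
#' @param learning_rate SGD step size (default 0.01).
#' @param max_epochs epoch cap (default 500).
#' @param patience epochs without validation improvement before stopping
#'   (default 20, must be >= 1).
#' @param validation_fraction fraction of training vectors held out,
#'   stratified, for early stopping (default 0.1).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed for init, shuffling and the validation split.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(50L, 10L), learning_rate = 0.01,
                       max_epochs = 500L, patience = 20L,
                       validation_fraction = 0.1, batch_size = 32L,
                       seed = 1L) {
  stopifnot(all(hidden_sizes >= 1L), patience >= 1L, learning_rate > 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

# row-wise softmax with the usual max-shift for numerical stability
softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mean categorical cross-entropy
#'
#' `-(1/N) * sum_i log p_i[y_i]`, the loss minimised by [train_mlp()].
#'
#' @param probs N x T matrix of class probabilities.
#' @param y integer class indices (1-based) of length N.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

mlp_forward <- function(w, x) {
  a <- list(x)
  n_layers <- length(w$W)
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% w$W[[l]] + matrix(w$b[[l]], nrow(a[[l]]),
                                      length(w$b[[l]]), byrow = TRUE)
    a[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else softmax(z)
  }
  a
}

#' Train the feed-forward subtype classifier
#'
#' Minimises the categorical cross-entropy by minibatch SGD. He-scaled
#' Gaussian initialisation; training stops when the validation loss has
#' not improved for `patience` epochs (the best-validation weights are
#' kept) or at `max_epochs`. Deterministic given `cfg$seed`.
#'
#' @param x numeric feature matrix (rows = training vectors).
#' @param labels character/factor class labels, length `nrow(x)`.
#' @param cfg an [mlp_config()].
#' @return object of class `coexsub_mlp` with weights, `classes`,
#'   `feature_names` and the training `history`.
#' @export
train_mlp <- function(x, labels, cfg = mlp_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  y <- match(as.character(labels), classes)
  n <- nrow(x); d <- ncol(x); t_out <- length(classes)
  dims <- c(d, cfg$hidden_sizes, t_out)

  with_seed(cfg$seed, {
    w <- list(W = list(), b = list())
    for (l in seq_len(length(dims) - 1L)) {
      w$W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                      sd = sqrt(2 / dims[l])),
                         dims[l], dims[l + 1L])
      w$b[[l]] <- numeric(dims[l + 1L])
    }

    # stratified validation slice for early stopping
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0) {
      for (c in seq_len(t_out)) {
        idx <- which(y == c)
        n_val <- max(1L, round(cfg$validation_fraction * length(idx)))
        if (n_val < length(idx))
          val_idx <- c(val_idx, sample(idx, n_val))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    best <- w; best_loss <- Inf; wait <- 0L; history <- numeric(0)
    n_layers <- length(w$W)
    onehot <- matrix(0, n, t_out); onehot[cbind(seq_len(n), y)] <- 1

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample(tr_idx)
      starts <- seq(1L, length(perm), by = cfg$batch_size)
      for (s0 in starts) {
        bi <- perm[s0:min(s0 + cfg$batch_size - 1L, length(perm))]
        a <- mlp_forward(w, x[bi, , drop = FALSE])
        m <- length(bi)
        delta <- (a[[n_layers + 1L]] - onehot[bi, , drop = FALSE]) / m
        for (l in n_layers:1) {
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(w$W[[l]])) * (a[[l]] > 0)
          w$W[[l]] <- w$W[[l]] - cfg$learning_rate * gW
          w$b[[l]] <- w$b[[l]] - cfg$learning_rate * gb
        }
      }
      mon_idx <- if (length(val_idx)) val_idx else tr_idx
      mon <- mlp_forward(w, x[mon_idx, , drop = FALSE])[[n_layers + 1L]]
      loss <- cross_entropy(mon, y[mon_idx])
      history <- c(history, loss)
      if (loss < best_loss - 1e-8) {
        best <- w; best_loss <- loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    structure(list(W = best$W, b = best$b, classes = classes,
                   feature_names = colnames(x), config = cfg,
                   history = history, val_loss = best_loss),
              class = "coexsub_mlp")
  })
}

#' Class probabilities or labels from a trained classifier
#'
#' @param object a `coexsub_mlp` from [train_mlp()].
#' @param x feature matrix with the training feature dimension.
#' @param type `"prob"` for the softmax matrix, `"class"` for argmax
#'   labels.
#' @param ... unused.
#' @return probability matrix (columns = classes) or character vector.
#' @export
predict.coexsub_mlp <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x), ncol(x) == nrow(object$W[[1L]]))
  probs <- mlp_forward(object, x)[[length(object$W) + 1L]]
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.coexsub_mlp <- function(x, ...) {
  dims <- c(nrow(x$W[[1L]]), vapply(x$W, ncol, integer(1L)))
  cat("feed-forward classifier", paste(dims, collapse = "-"),
      "| classes:", paste(x$classes, collapse = ", "), "\n")
  cat("epochs run:", length(x$history), "| best monitored loss:",
      format(x$val_loss, digits = 4L), "\n")
  invisible(x)
}

#' Predict sample labels by majority vote over reference sets
#'
#' Each sample's feature vectors (one per reference set) are classified
#' individually; the sample's label is the modal predicted class. Ties are
#' broken by the class with the highest mean softmax probability over the
#' sample's vectors, then by class order.
#'
#' @param model a `coexsub_mlp`.
#' @param feats list from [featurize_samples()] (`x`, `sample_id`,
#'   `set_id`).
#' @return `data.frame` with `sample_id`, `predicted`,
#'   `n_votes_for_winner`.
#' @export
predict_vote <- function(model, feats) {
  probs <- predict(model, feats$x, type = "prob")
  votes <- model$classes[max.col(probs, ties.method = "first")]
  ids <- unique(feats$sample_id)
  out <- lapply(ids, function(sid) {
    rows <- feats$sample_id == sid
    tab <- table(factor(votes[rows], levels = model$classes))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      mean_p <- colMeans(probs[rows, , drop = FALSE])
      top <- top[order(-mean_p[top], match(top, model$classes))][1L]
    }
    data.frame(sample_id = sid, predicted = top,
               n_votes_for_winner = as.integer(max(tab)))
  })
  do.call(rbind, out)
}

#' Multi-class evaluation report
#'
#' Accuracy is total true positives over the evaluated count. Macro
#' precision and recall are unweighted means of the per-class values (a
#' class never predicted gets precision 0, with a message). Macro-F1 is
#' the harmonic mean of macro-precision and macro-recall - not the mean of
#' per-class F1 scores.
#'
#' @param truth true labels.
#' @param predicted predicted labels (same length).
#' @param classes class order for the confusion matrix; defaults to the
#'   sorted union.
#' @return object of class `evaluation_report`: `confusion`, `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `per_class_recall`.
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes))
    classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  conf <- table(factor(truth, levels = classes),
                factor(predicted, levels = classes))
  conf <- unclass(conf)
  tp <- diag(conf)
  pred_pos <- colSums(conf)
  actual <- rowSums(conf)
  if (any(pred_pos == 0))
    coexsub_log("class(es) never predicted, precision set to 0: ",
                paste(classes[pred_pos == 0], collapse = ", "))
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(actual > 0, tp / actual, 0)
  macro_p <- mean(precision)
  macro_r <- mean(recall)
  macro_f1 <- if (macro_p + macro_r > 0) 2 * macro_p * macro_r / (macro_p + macro_r) else 0
  structure(list(confusion = conf, accuracy = sum(tp) / sum(conf),
                 macro_precision = macro_p, macro_recall = macro_r,
                 macro_f1 = macro_f1,
                 per_class_recall = stats::setNames(recall, classes)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | macro-P %.3f | macro-R %.3f | macro-F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  cat("per-class recall:",
      paste(sprintf("%s %.3f", names(x$per_class_recall), x$per_class_recall),
            collapse = ", "), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the classification stage
#'
#' Splits samples into stratified folds; for each fold, reference network
#' sets and the classifier are rebuilt from that fold's training portion
#' only, the held-out samples are featurized against every set and
#' predicted by vote, and an [evaluate_predictions()] report is produced.
#' The specific modules and edges in `spec` are treated as fixed inputs.
#'
#' @param ds an [expression_dataset()].
#' @param spec result of [specificity_stage()].
#' @param k number of folds (>= 2; every subtype must have >= k samples).
#' @param n_ref reference size `P` (see [build_reference_sets()]).
#' @param n_sets reference sets per fold.
#' @param cfg an [mlp_config()].
#' @param seed integer seed.
#' @return list with `folds` (one `evaluation_report` per fold) and `mean`
#'   (named vector of mean accuracy/macro metrics).
#' @export
cross_validate <- function(ds, spec, k = 10L, n_ref = NULL, n_sets = 10L,
                           cfg = mlp_config(), seed = 1L) {
  stopifnot(k >= 2L)
  sizes <- table(ds$labels)
  if (any(sizes < k))
    stop("subtype(s) smaller than k: ",
         paste(names(sizes)[sizes < k], collapse = ", "))
  fold_of <- stats::setNames(integer(length(ds$labels)), names(ds$labels))
  with_seed(derive_seed(seed, "cv_folds"), {
    for (s in subtypes(ds)) {
      ids <- sample(subtype_samples(ds, s))
      fold_of[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  classes <- sort(subtypes(ds))
  reports <- lapply(seq_len(k), function(f) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- names(fold_of)[fold_of != f]
    refs <- build_reference_sets(ds, train_ids, spec, n_ref = n_ref,
                                 n_sets = n_sets,
                                 seed = derive_seed(seed, paste0("refs", f)))
    tr <- featurize_training(ds, train_ids, refs,
                             seed = derive_seed(seed, paste0("feat", f)))
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(seed, paste0("mlp", f))
    model <- train_mlp(tr$x, tr$labels, cfg_f)
    te <- featurize_samples(ds, test_ids, refs)
    pred <- predict_vote(model, te)
    truth <- unname(ds$labels[pred$sample_id])
    evaluate_predictions(truth, pred$predicted, classes = classes)
  })
  metrics <- sapply(reports, function(r)
    c(accuracy = r$accuracy, macro_precision = r$macro_precision,
      macro_recall = r$macro_recall, macro_f1 = r$macro_f1))
  list(folds = reports, mean = rowMeans(metrics))
}
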