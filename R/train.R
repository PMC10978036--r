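#' Training configuration for the good/bad classifier
#'
#' Training minimizes binary cross-entropy with the Adam optimizer
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) on mini-batches, holding
#' out the final `val_split` fraction of a seeded shuffle for validation.
#'
#' @param epochs Maximum number of passes over the training split.
#' @param val_split Validation fraction in (0, 1).
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param stop_val_acc Optional early-stopping level: training ends after the
#'   first epoch whose validation accuracy reaches this value (default
#'   `NULL`, run all epochs).
#' @param restarts Number of additional seeded re-initializations to attempt
#'   if an attempt ends with validation accuracy below 0.9 (the fit is
#'   nonconvex and occasionally an initialization stalls with all scores on
#'   one side of zero; a fresh start escapes it).  The attempt with the best
#'   final validation accuracy is kept.  Default 0: single attempt.
#' @param seed Seed controlling the shuffle, the split, batch order and any
#'   restart re-initializations; training is reproducible given the seed
#'   (single-threaded).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, val_split = 0.10,
                         learning_rate = 1e-3, batch_size = 32L,
                         stop_val_acc = NULL, restarts = 0L, seed = 1L) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  restarts <- as.integer(restarts)
  stopifnot(epochs >= 1L, val_split > 0, val_split < 1,
            learning_rate > 0, batch_size >= 1L, length(seed) == 1L,
            restarts >= 0L,
            is.null(stop_val_acc) ||
              (stop_val_acc > 0 && stop_val_acc <= 1))
  structure(
    list(epochs = epochs, val_split = as.numeric(val_split),
         learning_rate = as.numeric(learning_rate), batch_size = batch_size,
         optimizer = "adam", loss = "binary-crossentropy",
         stop_val_acc = if (is.null(stop_val_acc)) NULL else as.numeric(stop_val_acc),
         restarts = restarts, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Numerically stable binary cross-entropy from the logit, and its derivative.
.bce_from_logit <- function(s, t) max(s, 0) - s * t + log1p(exp(-abs(s)))
.bce_grad_logit <- function(s, t) .sigmoid(s) - t

#' Train the good/bad reconstruction classifier
#'
#' Fits the network on a labelled corpus (label 1 = few-view "bad"
#' reconstruction, label 0 = full-view "good" one).  Images are rescaled by a
#' corpus-level constant (the maximum absolute intensity of the training
#' split), which is stored in the model and applied to every later input so
#' the score remains a fixed function of the image during reconstruction.
#'
#' @param model A [build_cnn()] model (untrained or to be fine-tuned).
#' @param corpus A [build_corpus()] corpus containing both labels.
#' @param tc A [train_config()].
#' @return A list of class `cnn_training` with elements `model` (the trained
#'   `cnn_prior`) and `report` (data frame with one row per epoch: epoch,
#'   train_loss, val_loss, val_acc).
#' @export
train_classifier <- function(model, corpus, tc = train_config()) {
  stopifnot(inherits(model, "cnn_prior"), inherits(corpus, "tomo_corpus"),
            inherits(tc, "train_config"))
  labels <- corpus$labels
  if (length(unique(labels)) < 2L) {
    stop("corpus must contain both labels (0 and 1)")
  }
  n <- length(labels)
  .with_seed(tc$seed, {
    perm <- sample.int(n)
    n_val <- max(1L, floor(tc$val_split * n))
    val_idx <- perm[(n - n_val + 1L):n]
    tr_idx <- perm[seq_len(n - n_val)]

    model$input_scale <- 1 / max(abs(corpus$images[tr_idx, , , drop = FALSE]), 1e-12)
    val_t <- labels[val_idx]

    run_attempt <- function(w) {
      mom <- lapply(w, function(p) p * 0)
      vel <- lapply(w, function(p) p * 0)
      lr <- tc$learning_rate
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      step <- 0L
      grad_names <- c(W1 = "dW1", W2 = "dW2", wd = "dwd",
                      b1 = "db1", b2 = "db2", bd = "dbd")
      report <- data.frame(epoch = seq_len(tc$epochs), train_loss = NA_real_,
                           val_loss = NA_real_, val_acc = NA_real_)
      for (ep in seq_len(tc$epochs)) {
        order_ep <- tr_idx[sample.int(length(tr_idx))]
        batch_losses <- numeric(0)
        for (b0 in seq(1L, length(order_ep), by = tc$batch_size)) {
          batch <- order_ep[b0:min(b0 + tc$batch_size - 1L, length(order_ep))]
          acc <- NULL
          loss_sum <- 0
          for (i in batch) {
            fw <- .cnn_forward(model, corpus$images[i, , ], keep = TRUE)
            t_i <- labels[i]
            loss_sum <- loss_sum + .bce_from_logit(fw$score, t_i)
            up <- .bce_grad_logit(fw$score, t_i)
            g <- .cnn_backward(model, fw, with_weights = TRUE,
                               with_input = FALSE)
            if (is.null(acc)) {
              acc <- lapply(names(w), function(nm) g[[grad_names[[nm]]]] * up)
              names(acc) <- names(w)
            } else {
              for (nm in names(w)) {
                acc[[nm]] <- acc[[nm]] + g[[grad_names[[nm]]]] * up
              }
            }
          }
          nb <- length(batch)
          step <- step + 1L
          for (nm in names(w)) {
            gb <- acc[[nm]] / nb
            mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gb
            vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gb^2
            mhat <- mom[[nm]] / (1 - b1^step)
            vhat <- vel[[nm]] / (1 - b2^step)
            w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
          }
          model$weights <- w
          batch_losses <- c(batch_losses, loss_sum / nb)
        }
        # validation with end-of-epoch weights
        val_s <- vapply(val_idx,
                        function(i) .cnn_forward(model, corpus$images[i, , ]),
                        numeric(1))
        report$train_loss[ep] <- mean(batch_losses)
        report$val_loss[ep] <- mean(mapply(.bce_from_logit, val_s, val_t))
        report$val_acc[ep] <- mean((val_s > 0) == (val_t == 1L))
        if (!is.null(tc$stop_val_acc) && report$val_acc[ep] >= tc$stop_val_acc) {
          report <- report[seq_len(ep), , drop = FALSE]
          break
        }
      }
      list(weights = w, report = report)
    }

    best <- NULL
    for (attempt in 0:tc$restarts) {
      w0 <- if (attempt == 0L) model$weights else {
        set.seed((tc$seed + 90001L * attempt) %% 2147483629L)
        .init_weights(model$config)
      }
      res <- run_attempt(w0)
      final_acc <- res$report$val_acc[nrow(res$report)]
      if (is.null(best) || final_acc > best$final_acc) {
        best <- res
        best$final_acc <- final_acc
      }
      if (best$final_acc >= 0.9) break
    }
    model$weights <- best$weights
    model$trained <- TRUE
    structure(list(model = model, report = best$report),
              class = "cnn_training")
  })
}

#' @export
#' @method print cnn_training
print.cnn_training <- function(x, ...) {
  last <- x$report[nrow(x$report), ]
  cat(sprintf(
    "Trained classifier: %d epochs, final train loss %.4f, val loss %.4f, val acc %.3f\n",
    nrow(x$report), last$train_loss, last$val_loss, last$val_acc))
  invisible(x)
}

#' Classification accuracy on a labelled corpus
#'
#' @param model A trained `cnn_prior`.
#' @param corpus A `tomo_corpus`.
#' @return Fraction of images whose thresholded score (logit > 0) matches the
#'   label.
#' @export
classifier_accuracy <- function(model, corpus) {
  stopifnot(inherits(model, "cnn_prior"), inherits(corpus, "tomo_corpus"))
  s <- vapply(seq_along(corpus$labels),
              function(i) cnn_score(model, corpus$images[i, , ]), numeric(1))
  mean((s > 0) == (corpus$labels == 1L))
}
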