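#' Training configuration
#'
#' Defaults follow the training regime the network was designed with:
#' mini-batch size 7, 10 epochs, momentum 0.9, initial learning rate 5e-4
#' (held constant; no schedule), validation patience 4. Class weights default
#' to uniform; a weighted mode is available for heavily imbalanced phantom
#' experiments (Neo pixels are typically ~1-3% of a patch).
#'
#' @param mini_batch_size patches per SGDM iteration.
#' @param max_epochs maximum passes over the training set.
#' @param momentum SGDM momentum in \[0, 1).
#' @param initial_learning_rate learning rate (> 0), constant throughout.
#' @param validation_patience number of validation evaluations allowed at or
#'   above the running minimum loss before training stops; `Inf` disables
#'   early stopping.
#' @param seed integer seed controlling shuffling (and any other training
#'   randomness).
#' @param class_weights length-2 numeric `(NotNeo, Neo)` cross-entropy
#'   weights.
#' @param validation_frequency evaluate the validation loss every this many
#'   iterations (default 1: after every mini-batch).
#' @param target_train_dice optional early exit: when set, training-set Dice
#'   is measured at every validation evaluation and training stops once it
#'   exceeds this value.
#' @return An object of class `training_config`.
#' @export
training_config <- function(mini_batch_size = 7L, max_epochs = 10L,
                            momentum = 0.9, initial_learning_rate = 5e-4,
                            validation_patience = 4L, seed = 1L,
                            class_weights = c(1, 1), validation_frequency = 1L,
                            target_train_dice = NULL) {
  assert_that(mini_batch_size >= 1 && max_epochs >= 1, "counts must be positive")
  assert_that(initial_learning_rate > 0, "learning rate must be > 0")
  assert_that(momentum >= 0 && momentum < 1, "momentum must be in [0, 1)")
  assert_that(is.infinite(validation_patience) || validation_patience >= 1,
              "validation_patience must be >= 1")
  assert_that(length(class_weights) == 2 && all(class_weights > 0),
              "class_weights must be two positive numbers")
  structure(list(mini_batch_size = as.integer(mini_batch_size),
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 initial_learning_rate = initial_learning_rate,
                 validation_patience = validation_patience,
                 seed = as.integer(seed), class_weights = as.numeric(class_weights),
                 validation_frequency = as.integer(validation_frequency),
                 target_train_dice = target_train_dice),
            class = "training_config")
}

#' Weighted per-pixel cross-entropy
#'
#' Mean over pixels of `-w_c * log p(true class)`, with probabilities clamped
#' below at 1e-12. With uniform probabilities 0.5 and unit weights the loss is
#' `log(2)`.
#'
#' @param probabilities H x W x 2 (or H x W x 2 x N) per-pixel class
#'   probabilities; channel 1 = NotNeo, channel 2 = Neo.
#' @param truth H x W (or H x W x N) 0/1 mask, 1 = Neo.
#' @param class_weights length-2 `(NotNeo, Neo)` weights.
#' @return Scalar loss.
#' @export
pixel_cross_entropy <- function(probabilities, truth, class_weights = c(1, 1)) {
  if (length(dim(probabilities)) == 3L) {
    probabilities <- array(probabilities, c(dim(probabilities), 1L))
  }
  d <- dim(probabilities)
  tv <- as.vector(truth)
  assert_that(length(tv) == d[1] * d[2] * d[4],
              "probabilities and truth shapes are not aligned")
  assert_that(all(tv %in% c(0, 1)), "truth must be binary 0/1")
  p_not <- as.vector(probabilities[, , 1, ])
  p_neo <- as.vector(probabilities[, , 2, ])
  p_true <- ifelse(tv == 1, p_neo, p_not)
  w <- class_weights[tv + 1]
  mean(-w * log(pmax(p_true, 1e-12)))
}

# Fused softmax + weighted cross-entropy: returns loss and d(loss)/d(logits).
softmax_ce <- function(logits, truth, class_weights = c(1, 1)) {
  probs <- softmax2(logits)
  d <- dim(probs)
  npix <- d[1] * d[2] * d[4]
  tv <- as.vector(truth)
  w <- class_weights[tv + 1]
  p1 <- as.vector(probs[, , 1, ]); p2 <- as.vector(probs[, , 2, ])
  p_true <- ifelse(tv == 1, p2, p1)
  loss <- mean(-w * log(pmax(p_true, 1e-12)))
  dl <- array(0, d)
  dl[, , 1, ] <- (p1 - (tv == 0)) * w / npix
  dl[, , 2, ] <- (p2 - (tv == 1)) * w / npix
  list(loss = loss, dlogits = dl, probs = probs)
}

#' One stochastic-gradient-descent-with-momentum update
#'
#' Applies `velocity <- momentum * velocity - learning_rate * gradient;
#' parameters <- parameters + velocity`, recursively over arbitrarily nested
#' parameter lists (only entries present in `gradients` are updated, so
#' batch-norm running statistics pass through untouched). With momentum 0
#' this is plain gradient descent.
#'
#' @param parameters numeric array or nested list of arrays.
#' @param gradients matching structure of gradients.
#' @param velocity matching structure (use [zero_velocity()] to create it).
#' @param learning_rate positive step size.
#' @param momentum momentum coefficient in \[0, 1).
#' @return list with updated `parameters` and `velocity`.
#' @export
sgdm_step <- function(parameters, gradients, velocity, learning_rate, momentum) {
  if (is.list(gradients)) {
    for (nm in names(gradients)) {
      r <- sgdm_step(parameters[[nm]], gradients[[nm]], velocity[[nm]],
                     learning_rate, momentum)
      parameters[[nm]] <- r$parameters
      velocity[[nm]] <- r$velocity
    }
    return(list(parameters = parameters, velocity = velocity))
  }
  assert_that(length(parameters) == length(gradients),
              "parameter/gradient shapes are not aligned")
  if (is.null(velocity)) velocity <- parameters * 0
  velocity <- momentum * velocity - learning_rate * gradients
  list(parameters = parameters + velocity, velocity = velocity)
}

#' @rdname sgdm_step
#' @export
zero_velocity <- function(parameters) {
  if (is.list(parameters)) return(lapply(parameters, zero_velocity))
  parameters * 0
}

#' Trace validation-patience early stopping over a loss sequence
#'
#' The patience counter counts validation evaluations whose loss is greater
#' than or equal to the running minimum; it resets only when a new strict
#' minimum is reached. Training stops when the counter reaches `patience`.
#' This pure function makes the stopping rule testable in isolation.
#'
#' @param val_losses numeric sequence of validation losses, in evaluation
#'   order.
#' @param patience allowed number of at-or-above-minimum evaluations.
#' @return list with `stop_iteration` (index of the evaluation that exhausted
#'   patience, or `NA` if never), `best_iteration` (index of the minimum) and
#'   `stopped` (logical).
#' @export
early_stopping_trace <- function(val_losses, patience) {
  best <- Inf; best_it <- NA_integer_; counter <- 0L
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best) {
      best <- val_losses[i]; best_it <- i; counter <- 0L
    } else {
      counter <- counter + 1L
      if (counter >= patience) {
        return(list(stop_iteration = i, best_iteration = best_it, stopped = TRUE))
      }
    }
  }
  list(stop_iteration = NA_integer_, best_iteration = best_it, stopped = FALSE)
}

# Stack a list of H x W patches into an (H, W, 1, N) batch.
stack_patches <- function(patches) {
  d <- dim(patches[[1]])
  array(unlist(patches, use.names = FALSE), c(d[1], d[2], 1L, length(patches)))
}

# Stack masks into (H, W, N).
stack_masks <- function(masks) {
  d <- dim(masks[[1]])
  array(unlist(masks, use.names = FALSE), c(d[1], d[2], length(masks)))
}

# Mean validation loss over the full set, evaluated in inference mode.
validation_loss <- function(model, val_x, val_y, class_weights, chunk = 8L) {
  n <- length(val_x)
  total <- 0
  for (s in seq(1, n, by = chunk)) {
    i <- s:min(s + chunk - 1, n)
    fwd <- net_forward(model, stack_patches(val_x[i]), training = FALSE)
    total <- total + length(i) *
      pixel_cross_entropy(fwd$probs, stack_masks(val_y[i]), class_weights)
  }
  total / n
}

# Training-set Dice in inference mode (micro-averaged over all pixels).
train_dice <- function(model, xs, ys, chunk = 8L) {
  tp <- fp <- fn <- 0
  for (s in seq(1, length(xs), by = chunk)) {
    i <- s:min(s + chunk - 1, length(xs))
    fwd <- net_forward(model, stack_patches(xs[i]), training = FALSE)
    pred <- as.vector(fwd$probs[, , 2, ]) > 0.5
    tru <- as.vector(stack_masks(ys[i])) == 1
    tp <- tp + sum(pred & tru); fp <- fp + sum(pred & !tru); fn <- fn + sum(!pred & tru)
  }
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the segmentation network
#'
#' SGDM training with per-pixel (optionally class-weighted) cross-entropy.
#' Patches are shuffled once per epoch under the run seed and consumed in
#' mini-batches of `mini_batch_size` (a final short batch is allowed). The
#' validation loss over the full validation set is evaluated every
#' `validation_frequency` iterations; the patience counter increments
#' whenever that loss is at or above the running minimum and training stops
#' when it reaches `validation_patience` or when `max_epochs` completes.
#' The returned model carries the parameters from the best (minimum
#' validation loss) iteration.
#'
#' @param model an initialized [init_network()] model.
#' @param data list with `train_x`, `train_y`, `val_x`, `val_y`: aligned lists
#'   of single-channel patches (8-bit intensities) and 0/1 masks, all of the
#'   model's input size.
#' @param config a [training_config()].
#' @param verbose print one structured log line per validation evaluation.
#' @return list with `model` (best parameters) and `history`, an object of
#'   class `training_history`: data.frame of per-evaluation `iteration`,
#'   `train_loss`, `val_loss`, `patience_counter`, plus attributes
#'   `stop_reason` (`"patience_exhausted"`, `"max_epochs"` or
#'   `"target_reached"`) and `best_iteration`.
#' @export
train_network <- function(model, data, config = training_config(), verbose = FALSE) {
  assert_that(length(data$train_x) > 0 && length(data$val_x) > 0,
              "training and validation sets must be non-empty")
  assert_that(length(data$train_x) == length(data$train_y) &&
                length(data$val_x) == length(data$val_y),
              "patch and mask lists must be aligned")
  n <- length(data$train_x)
  velocity <- zero_velocity(model$params)
  best_loss <- Inf; best_params <- model$params; best_iter <- 0L
  counter <- 0L; iter <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    order <- with_seed(config$seed + epoch, sample.int(n))
    stopping <- FALSE
    for (s in seq(1, n, by = config$mini_batch_size)) {
      idx <- order[s:min(s + config$mini_batch_size - 1, n)]
      iter <- iter + 1L
      x <- stack_patches(data$train_x[idx])
      y <- stack_masks(data$train_y[idx])
      fwd <- net_forward(model, x, training = TRUE, keep_cache = TRUE)
      model <- fwd$model  # batch-norm running statistics
      ce <- softmax_ce(fwd$logits, y, config$class_weights)
      grads <- net_backward(model, fwd, ce$dlogits)
      upd <- sgdm_step(model$params, grads, velocity,
                       config$initial_learning_rate, config$momentum)
      model$params <- upd$parameters
      velocity <- upd$velocity

      if (iter %% config$validation_frequency == 0L) {
        vl <- validation_loss(model, data$val_x, data$val_y, config$class_weights)
        if (vl < best_loss) {
          best_loss <- vl; best_params <- model$params; best_iter <- iter
          counter <- 0L
        } else {
          counter <- counter + 1L
        }
        hist[[length(hist) + 1L]] <- data.frame(iteration = iter,
                                                train_loss = ce$loss,
                                                val_loss = vl,
                                                patience_counter = counter)
        if (verbose) {
          message(sprintf("iteration=%d train_loss=%.6f val_loss=%.6f patience=%d",
                          iter, ce$loss, vl, counter))
        }
        if (!is.null(config$target_train_dice)) {
          dc <- train_dice(model, data$train_x, data$train_y)
          if (!is.na(dc) && dc > config$target_train_dice) {
            stop_reason <- "target_reached"
            best_params <- model$params; best_iter <- iter
            stopping <- TRUE
          }
        }
        if (!stopping && counter >= config$validation_patience) {
          stop_reason <- "patience_exhausted"
          stopping <- TRUE
        }
      }
      if (stopping) break
    }
    if (stopping) break
  }
  model$params <- best_params
  history <- if (length(hist) == 0) {
    data.frame(iteration = integer(0), train_loss = numeric(0),
               val_loss = numeric(0), patience_counter = integer(0))
  } else do.call(rbind, hist)
  attr(history, "stop_reason") <- stop_reason
  attr(history, "best_iteration") <- best_iter
  class(history) <- c("training_history", class(history))
  list(model = model, history = history)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("training history: %d evaluations, stop: %s, best iteration %d\n",
              nrow(x), attr(x, "stop_reason"), attr(x, "best_iteration")))
  invisible(x)
}

#' Write a training history as comma-separated text
#'
#' @param history a `training_history`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
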