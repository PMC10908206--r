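# Classifiers: the 3D CNN used for binary mutation-status prediction (three
# conv blocks with 32/16/8 channels + max-pooling, a 128-unit hidden layer
# with dropout 0.5, sigmoid output) and its 5-class subtype variant (sigmoid
# removed, raw class scores), plus the L1-regularized logistic multi-omic
# baseline.

#' Per-task training epoch presets
#'
#' Reference budgets: CNNs trained on generated volumes use 1300 (CDH1),
#' 1500 (PIK3CA) and 2000 (TP53) epochs; the subtype CNN uses 2500; CNNs on
#' real volumes use 300 for all three genes.
#'
#' @export
cnn_epoch_presets <- c(CDH1 = 1300L, PIK3CA = 1500L, TP53 = 2000L,
                       subtype = 2500L, real = 300L)

#' CNN classifier configuration
#'
#' Defaults follow the reference classifier: conv channels (32, 16, 8),
#' 128-unit hidden layer, dropout 0.5, batch size 1, Adam with
#' reduce-on-plateau learning-rate schedule, binary cross-entropy (binary) /
#' categorical cross-entropy (multiclass).
#'
#' @param volume_shape (depth, height, width); each >= 8 (three pool stages).
#' @param task `"TP53"`, `"PIK3CA"`, `"CDH1"` or `"subtype"` — selects the
#'   label column and, when `epochs = NULL`, the epoch preset.
#' @param conv_channels conv output channels (default `c(32, 16, 8)`).
#' @param fc_hidden hidden layer width (default 128).
#' @param dropout_p dropout probability in \[0, 1) (default 0.5).
#' @param n_outputs 1 (binary, sigmoid) or 5 (multiclass, raw scores);
#'   inferred from `task` when `NULL`.
#' @param batch_size minibatch size (default 1).
#' @param optimizer `"Adam"` (default) or `"SGD"`.
#' @param learning_rate initial learning rate.
#' @param lr_factor,lr_patience,min_lr reduce-on-plateau schedule: multiply
#'   the rate by `lr_factor` after `lr_patience` epochs without improvement,
#'   never below `min_lr`.
#' @param epochs training epochs; `NULL` = task preset.
#' @param seed integer seed.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(volume_shape,
                       task = "TP53",
                       conv_channels = c(32L, 16L, 8L),
                       fc_hidden = 128L,
                       dropout_p = 0.5,
                       n_outputs = NULL,
                       batch_size = 1L,
                       optimizer = c("Adam", "SGD"),
                       learning_rate = 1e-3,
                       lr_factor = 0.5,
                       lr_patience = 10L,
                       min_lr = 1e-6,
                       epochs = NULL,
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (length(conv_channels) < 1L) stop("cnn_config: `conv_channels` must be nonempty")
  if (dropout_p < 0 || dropout_p >= 1) stop("cnn_config: `dropout_p` must be in [0, 1)")
  n_pool <- length(conv_channels)
  if (any(volume_shape < 2L^n_pool)) {
    stop("cnn_config: volume_shape too small for ", n_pool,
         " pooling stages; minimum shape is ",
         paste(rep(2L^n_pool, 3), collapse = "x"))
  }
  if (is.null(n_outputs)) n_outputs <- if (identical(task, "subtype")) 5L else 1L
  if (!n_outputs %in% c(1L, 5L)) stop("cnn_config: `n_outputs` must be 1 or 5")
  if (is.null(epochs)) {
    epochs <- if (task %in% names(cnn_epoch_presets)) cnn_epoch_presets[[task]] else 300L
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 task = task,
                 conv_channels = as.integer(conv_channels),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_p = dropout_p,
                 n_outputs = as.integer(n_outputs),
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer,
                 learning_rate = learning_rate,
                 lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 min_lr = min_lr,
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

build_cnn_trunk <- function(config) {
  sp <- config$volume_shape
  ch <- config$conv_channels
  layers <- list()
  c_in <- 1L
  for (c_out in ch) {
    layers <- c(layers, list(nn_conv3(c_in, c_out, k = 3L, stride = 1L, pad = 1L),
                             nn_relu(), nn_pool(2L)))
    sp <- sp %/% 2L
    c_in <- c_out
  }
  flat <- prod(sp) * c_in
  layers <- c(layers, list(nn_flatten(),
                           nn_dense(flat, config$fc_hidden),
                           nn_relu(),
                           nn_dropout(config$dropout_p),
                           nn_dense(config$fc_hidden, config$n_outputs,
                                    init_sd = 0.01)))
  structure(list(layers = layers), class = "cgan_net")
}

#' Build the binary mutation-status CNN
#'
#' Three 3D conv (kernel 3) + max-pool blocks with 32 -> 16 -> 8 output
#' channels, flatten, a 128-unit fully-connected layer with ReLU and dropout
#' 0.5, and a single sigmoid output unit. [predict_proba()] returns the
#' sigmoid probability; training uses binary cross-entropy on the logit for
#' numerical stability (mathematically the same objective).
#'
#' @param config a [cnn_config()] with `n_outputs = 1`. Parameter init
#'   consumes the current RNG stream.
#' @return A `cnn_model` with `$head = "sigmoid"`.
#' @export
build_mutation_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  if (config$n_outputs != 1L) stop("build_mutation_cnn: needs n_outputs = 1")
  structure(list(net = build_cnn_trunk(config), head = "sigmoid",
                 config = config), class = "cnn_model")
}

#' Build the 5-class subtype CNN
#'
#' Same trunk as the mutation CNN with the sigmoid removed: five raw class
#' scores; the predicted class is the argmax, on the coding Normal=0,
#' Basal=1, LumA=2, LumB=3, HER2=4.
#'
#' @param config a [cnn_config()] with `n_outputs = 5`.
#' @return A `cnn_model` with `$head = "linear"`.
#' @export
build_subtype_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  if (config$n_outputs != 5L) stop("build_subtype_cnn: needs n_outputs = 5")
  structure(list(net = build_cnn_trunk(config), head = "linear",
                 config = config), class = "cnn_model")
}

# Stack a list of volume3d into a (D,H,W,1,N) tensor rescaled to [-1, 1].
stack_volumes <- function(volumes, sp) {
  n <- length(volumes)
  x <- array(0, c(sp, 1L, n))
  for (i in seq_len(n)) {
    if (!all(dim(volumes[[i]]$data) == sp)) {
      stop("volume shape ", paste(dim(volumes[[i]]$data), collapse = "x"),
           " does not match expected ", paste(sp, collapse = "x"))
    }
    x[, , , 1L, i] <- volume_rescale(volumes[[i]])
  }
  x
}

softmax_cols <- function(l) {
  l <- sweep(l, 2L, apply(l, 2L, max))
  e <- exp(l)
  sweep(e, 2L, colSums(e), `/`)
}

#' Train a CNN classifier
#'
#' Mini-batch training with the configured optimizer and loss (binary or
#' categorical cross-entropy), plateau-based learning-rate reduction, loss
#' history recorded per epoch, fully seeded.
#'
#' @param model a `cnn_model` from [build_mutation_cnn()] /
#'   [build_subtype_cnn()] (its parameters are re-initialized from
#'   `config$seed` for reproducibility).
#' @param train_records list of patient records carrying the task's label.
#' @param config optional [cnn_config()] override (defaults to the model's).
#' @param verbose print loss every `verbose` epochs (0 = silent).
#' @return The fitted `cnn_model` with `$loss_history` and `$lr_history`.
#' @export
train_classifier <- function(model, train_records, config = NULL, verbose = 0L) {
  stopifnot(inherits(model, "cnn_model"))
  config <- config %||% model$config
  cases <- expand_cases(train_records)
  if (length(cases) == 0L) stop("train_classifier: empty training set")
  labels <- vapply(cases, record_label, numeric(1), key = config$task)
  if (length(unique(labels)) < 2L) {
    stop("train_classifier: training set contains a single class")
  }
  binary <- config$n_outputs == 1L
  if (binary && !all(labels %in% c(0, 1))) {
    stop("train_classifier: binary labels must be 0/1")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  net <- build_cnn_trunk(config)   # re-init under the seed
  opt <- adam_init(net)
  n <- length(cases)
  x <- stack_volumes(lapply(cases, function(r) r$volumes[[1]]), config$volume_shape)
  bs <- min(config$batch_size, n)
  lr <- config$learning_rate
  best <- Inf; stall <- 0L
  hist <- numeric(config$epochs)
  lrh <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    acc <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      m <- length(idx)
      xb <- x[, , , , idx, drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      logits <- fw$y
      if (binary) {
        yb <- labels[idx]
        p <- stats::plogis(drop(logits))
        loss <- -mean(yb * log(pmax(p, 1e-12)) + (1 - yb) * log(pmax(1 - p, 1e-12)))
        grad <- matrix((p - yb) / m, nrow = 1L)
      } else {
        yb <- as.integer(labels[idx])
        p <- softmax_cols(logits)
        loss <- -mean(log(pmax(p[cbind(yb + 1L, seq_len(m))], 1e-12)))
        grad <- p
        grad[cbind(yb + 1L, seq_len(m))] <- grad[cbind(yb + 1L, seq_len(m))] - 1
        grad <- grad / m
      }
      if (!is.finite(loss)) stop("train_classifier: non-finite loss at epoch ", ep)
      bw <- nn_backward(net, fw$caches, grad, skip_input_grad = TRUE)
      if (config$optimizer == "Adam") {
        st <- adam_step(net, bw$grads, opt, lr)
        net <- st$net; opt <- st$state
      } else {
        for (i in seq_along(net$layers)) {
          g <- bw$grads[[i]]
          if (is.null(g)) next
          for (nm in names(g)) {
            net$layers[[i]]$par[[nm]] <- net$layers[[i]]$par[[nm]] - lr * g[[nm]]
          }
        }
      }
      acc <- acc + loss * m; nb <- nb + m
    }
    hist[ep] <- acc / nb
    lrh[ep] <- lr
    # reduce-on-plateau on the epoch training loss
    if (!is.finite(best) || hist[ep] < best - 1e-4 * abs(best)) {
      best <- hist[ep]; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$lr_patience && lr > config$min_lr) {
        lr <- max(config$min_lr, lr * config$lr_factor)
        stall <- 0L
      }
    }
    if (verbose > 0 && ep %% verbose == 0L) {
      message(sprintf("epoch %d/%d  loss %.5f  lr %.2e", ep, config$epochs,
                      hist[ep], lr))
    }
  }
  model$net <- net
  model$config <- config
  model$loss_history <- data.frame(epoch = seq_len(config$epochs), loss = hist)
  model$lr_history <- lrh
  model
}

#' Predict probabilities / class scores for volumes
#'
#' Deterministic (dropout disabled in evaluation). Binary models return a
#' probability in (0, 1) per volume; multiclass models return an n x 5
#' matrix of raw class scores (argmax = predicted subtype code).
#'
#' @param model a fitted `cnn_model`.
#' @param volumes list of [volume3d()].
#' @param batch forward batch size.
#' @return Numeric vector (binary) or n x 5 matrix (multiclass).
#' @export
predict_proba <- function(model, volumes, batch = 32L) {
  stopifnot(inherits(model, "cnn_model"))
  sp <- model$config$volume_shape
  n <- length(volumes)
  if (n == 0L) return(if (model$head == "sigmoid") numeric(0) else matrix(0, 0, 5))
  out <- matrix(0, model$config$n_outputs, n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    xb <- stack_volumes(volumes[idx], sp)
    out[, idx] <- nn_forward(model$net, xb, training = FALSE)$y
  }
  if (model$head == "sigmoid") stats::plogis(drop(out)) else t(out)
}

#' L1-regularized logistic baseline on multi-omic latents
#'
#' The pure-genomics comparison arm: an L1-penalized logistic regression fit
#' on the latent feature matrix, penalty strength chosen by internal
#' cross-validation (deterministic fold assignment from the seed).
#'
#' @param latents n x d latent matrix.
#' @param labels 0/1 vector of length n.
#' @param test_split held-out fraction (default 0.2, stratified).
#' @param seed integer seed.
#' @param nfolds internal CV folds for the penalty path (default 5).
#' @return `list(coefficients = named vector (incl. intercept), lambda =,
#'   test = data.frame(truth, prob))`.
#' @export
logistic_l1_baseline <- function(latents, labels, test_split = 0.2, seed = 1L,
                                 nfolds = 5L) {
  latents <- as.matrix(latents)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("logistic_l1_baseline: labels contain a single class")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(latents)
  idx_pos <- which(labels == 1); idx_neg <- which(labels == 0)
  n_test <- round(n * test_split)
  t_pos <- round(length(idx_pos) * test_split)
  t_neg <- min(length(idx_neg), n_test - t_pos)
  test_idx <- sort(c(sample(idx_pos, t_pos), sample(idx_neg, t_neg)))
  tr <- setdiff(seq_len(n), test_idx)
  foldid <- sample(rep_len(seq_len(nfolds), length(tr)))
  fit <- glmnet::cv.glmnet(latents[tr, , drop = FALSE], labels[tr],
                           family = "binomial", alpha = 1, foldid = foldid,
                           standardize = TRUE)
  prob <- as.numeric(stats::predict(fit, latents[test_idx, , drop = FALSE],
                                    s = "lambda.min", type = "response"))
  co <- as.numeric(stats::coef(fit, s = "lambda.min"))
  names(co) <- rownames(stats::coef(fit, s = "lambda.min"))
  list(coefficients = co, lambda = fit$lambda.min,
       test = data.frame(truth = labels[test_idx], prob = prob))
}
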