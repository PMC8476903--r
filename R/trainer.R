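# Training: Adam with weight decay, per-epoch target augmentation, MSE
# tracking, and patient-wise K-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the published run: adaptive-moment estimation with
#' learning rate 0.001, weight decay 0.0002, beta1 0.9, beta2 0.999,
#' smooth-L1 loss with beta 0.5, 5000 epochs, single-sample batches, and
#' the reference scores translated by a random -2..2 degree circular shift
#' every epoch.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param weight_decay L2 weight decay added to the gradient
#'   (default 0.0002).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param epochs training epochs (default 5000; reduce for desk-scale
#'   runs).
#' @param loss `"smooth_l1"` (default), `"l1"` or `"l2"`.
#' @param loss_beta smooth-L1 threshold (default 0.5).
#' @param seed RNG seed fixing the whole training trajectory.
#' @param batch_size samples per gradient step (default 1; the only
#'   supported value).
#' @param folds K for cross-validation (default 5).
#' @param augment apply the per-epoch circular-shift augmentation to the
#'   reference scores (default TRUE).
#' @param paired_shift also roll the feature tensor's angle blocks by the
#'   same shift (default FALSE: the stated augmentation translates the
#'   target only). Requires the shift in degrees to be a multiple of the
#'   tensor's angle step.
#' @return object of class `baods_control`.
#' @export
baods_train_control <- function(learning_rate = 0.001, weight_decay = 2e-4,
                                beta1 = 0.9, beta2 = 0.999, epochs = 5000,
                                loss = c("smooth_l1", "l1", "l2"),
                                loss_beta = 0.5, seed = 1, batch_size = 1,
                                folds = 5, augment = TRUE,
                                paired_shift = FALSE) {
  loss <- match.arg(loss)
  if (epochs < 1) stop("epochs must be >= 1")
  if (folds < 2) stop("folds must be >= 2")
  if (learning_rate <= 0 || beta1 <= 0 || beta2 <= 0)
    stop("rates must be > 0")
  if (batch_size != 1) stop("only batch_size = 1 is supported")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
                 loss = loss, loss_beta = loss_beta, seed = as.integer(seed),
                 batch_size = 1L, folds = as.integer(folds),
                 augment = isTRUE(augment),
                 paired_shift = isTRUE(paired_shift)),
            class = "baods_control")
}

# circularly roll the angle-block axis of a (1, n_angles*225, bins) tensor
# by `shift_deg` degrees; the shift must land on whole angle blocks
roll_angle_blocks <- function(x, shift_deg) {
  n_blocks <- dim(x)[2] / 225L
  step <- 360 / n_blocks
  if (shift_deg %% step != 0)
    stop("paired shift of ", shift_deg, " deg is not a multiple of the ",
         "tensor's ", step, " deg angle step")
  k <- shift_deg / step
  if (k == 0) return(x)
  blk <- rep(((seq_len(n_blocks) - 1L - k) %% n_blocks), each = 225L)
  x[, blk * 225L + rep(seq_len(225L), n_blocks), , drop = FALSE]
}

# zero-filled copies of all parameter arrays (Adam moment buffers)
zero_like_params <- function(params) {
  lapply(params, function(p)
    if (is.null(p)) NULL else lapply(p, function(a) a * 0))
}

#' Train a network on (feature tensor, ranking score) pairs
#'
#' Single-sample Adam steps over the dataset in fixed order, one pass per
#' epoch. When augmentation is on, each sample's reference score is
#' circularly shifted by a fresh uniform draw from -2..2 degrees every
#' epoch; the tracked MSE is always computed against the unaugmented
#' reference. Identical (seed, config, data) give identical traces and
#' parameters.
#'
#' @param net a `baods_net` from [build_net()].
#' @param data list of samples, each `list(x = <feature matrix or
#'   baods_features>, y = <length-360 reference score>)`, optionally with
#'   `case_id`.
#' @param control a [baods_train_control()].
#' @return the trained `baods_net`, with `$trace` (data.frame epoch, loss,
#'   mse), `$fitted` (final-epoch predictions, one column per sample) and
#'   `$refs` (reference scores).
#' @export
train <- function(net, data, control = baods_train_control()) {
  stopifnot(inherits(net, "baods_net"), length(data) >= 1)
  xs <- lapply(data, function(s) {
    x <- if (inherits(s$x, "baods_features")) s$x$values else s$x
    if (is.matrix(x)) dim(x) <- c(1L, nrow(x), ncol(x))
    x
  })
  ys <- lapply(data, function(s) as.numeric(s$y))
  set.seed(control$seed)
  m <- zero_like_params(net$params)
  v <- zero_like_params(net$params)
  tstep <- 0L
  b1 <- control$beta1; b2 <- control$beta2
  lr <- control$learning_rate; wd <- control$weight_decay
  n <- length(data)
  trace <- matrix(0, control$epochs, 3)
  fitted <- NULL
  for (e in seq_len(control$epochs)) {
    loss_acc <- 0; mse_acc <- 0
    preds <- matrix(0, length(ys[[1]]), n)
    for (si in seq_len(n)) {
      yref <- ys[[si]]
      xcur <- xs[[si]]
      if (control$augment) {
        ytgt <- augment_sbeam(yref)
        if (control$paired_shift)
          xcur <- roll_angle_blocks(xcur, attr(ytgt, "shift"))
      } else ytgt <- yref
      fw <- net_forward(net, xcur, training = TRUE)
      net <- fw$net
      l <- baods_loss(ytgt, fw$y, type = control$loss,
                      beta = control$loss_beta)
      if (!is.finite(l))
        stop("non-finite loss at epoch ", e, ", sample ", si)
      loss_acc <- loss_acc + l
      mse_acc <- mse_acc + mean((fw$y - yref)^2)
      preds[, si] <- fw$y
      dy <- baods_loss_grad(ytgt, fw$y, type = control$loss,
                            beta = control$loss_beta)
      grads <- net_backward(net, fw$caches, dy)
      tstep <- tstep + 1L
      corr1 <- 1 - b1^tstep
      corr2 <- 1 - b2^tstep
      for (li in seq_along(net$params)) {
        if (is.null(grads[[li]])) next
        for (f in names(grads[[li]])) {
          g <- grads[[li]][[f]] + wd * net$params[[li]][[f]]
          m[[li]][[f]] <- b1 * m[[li]][[f]] + (1 - b1) * g
          v[[li]][[f]] <- b2 * v[[li]][[f]] + (1 - b2) * g^2
          net$params[[li]][[f]] <- net$params[[li]][[f]] -
            lr * (m[[li]][[f]] / corr1) /
            (sqrt(v[[li]][[f]] / corr2) + 1e-8)
        }
      }
    }
    trace[e, ] <- c(e, loss_acc / n, mse_acc / n)
    fitted <- preds
  }
  net$trace <- data.frame(epoch = trace[, 1], loss = trace[, 2],
                          mse = trace[, 3])
  net$fitted <- fitted
  net$refs <- do.call(cbind, ys)
  net$control <- control
  net
}

#' Patient-wise K-fold assignment
#'
#' Case ids are sorted, shuffled with the seed, and dealt round-robin into
#' `K` folds, so folds are disjoint, cover all cases, differ in size by at
#' most one, and do not depend on the input order.
#'
#' @param case_ids character or numeric case identifiers (unique).
#' @param K number of folds (>= 2, <= number of cases).
#' @param seed RNG seed.
#' @return named integer vector mapping case id to fold index in 0..K-1.
#' @export
kfold_split <- function(case_ids, K = 5, seed = 1) {
  ids <- sort(as.character(case_ids))
  if (anyDuplicated(ids)) stop("case ids must be unique")
  if (length(ids) < K)
    stop("fewer cases (", length(ids), ") than folds (", K, ")")
  set.seed(seed)
  perm <- ids[sample.int(length(ids))]
  fold <- rep_len(seq_len(K) - 1L, length(ids))
  names(fold) <- perm
  fold[ids]
}

#' K-fold cross-validation of the ranking network
#'
#' Trains one fresh network per fold on the out-of-fold samples and
#' evaluates the mean squared error of the (clamped) predictions on the
#' held-out fold.
#'
#' @param data list of samples as in [train()], each with a `case_id`.
#' @param spec a [baods_netspec()] matching the feature tensors.
#' @param control a [baods_train_control()]; `control$folds` is K.
#' @return list with `per_fold` (data.frame fold, n_test, mse), `mean`,
#'   `sd`, and the fold `assignment`.
#' @export
crossvalidate <- function(data, spec, control = baods_train_control()) {
  ids <- vapply(data, function(s) as.character(s$case_id), character(1))
  assign <- kfold_split(ids, K = control$folds, seed = control$seed)
  res <- data.frame(fold = seq_len(control$folds) - 1L, n_test = 0L,
                    mse = NA_real_)
  for (k in seq_len(control$folds) - 1L) {
    test_ids <- names(assign)[assign == k]
    tr <- data[!(ids %in% test_ids)]
    te <- data[ids %in% test_ids]
    net <- build_net(spec, seed = control$seed + k)
    net <- train(net, tr, control)
    mse <- mean(vapply(te, function(s) {
      p <- predict_sbeam(net, s$x)
      mean((p - as.numeric(s$y))^2)
    }, numeric(1)))
    res$n_test[res$fold == k] <- length(te)
    res$mse[res$fold == k] <- mse
  }
  list(per_fold = res, mean = mean(res$mse), sd = stats::sd(res$mse),
       assignment = assign)
}
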