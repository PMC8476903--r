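#' Fit the beam-angle ranking network
#'
#' The package's central modelling function: builds a network from `spec`,
#' trains it on the supplied cases' feature tensors and reference ranking
#' scores, and returns the fitted model as a classed object with the usual
#' accessor methods (`print`, `summary`, `coef`, `predict`, `plot`,
#' `residuals`).
#'
#' @param x list of feature tensors ([build_feature_tensor()] outputs or
#'   plain matrices), one per case.
#' @param targets list of length-360 reference ranking scores
#'   ([make_sbeam()] outputs), parallel to `x`.
#' @param spec a [baods_netspec()]; must match the feature tensor
#'   dimensions.
#' @param control a [baods_train_control()].
#' @param case_ids optional case identifiers (defaults to the feature
#'   tensors' own ids, or seq_along).
#' @return fitted object of class `baods_net`.
#' @examples
#' cfg <- phantom_config(shape = c(24, 24, 12), spacing = c(12, 12, 12),
#'                       noise_sd = 0)
#' case <- generate_case(cfg)
#' ft <- build_feature_tensor(case, angle_step = 45, n_bins = 40)
#' sb <- make_sbeam(case$clinical_angles)
#' spec <- baods_netspec(n_angles = 8, n_bins = 40,
#'                       conv_channels = c(3, 1),
#'                       pool_after = c(FALSE, FALSE), hidden = 32)
#' fit <- baods_fit(list(ft), list(sb), spec,
#'                  baods_train_control(epochs = 3, seed = 1))
#' print(fit)
#' @export
baods_fit <- function(x, targets, spec = baods_netspec(),
                      control = baods_train_control(), case_ids = NULL) {
  stopifnot(length(x) == length(targets), length(x) >= 1)
  if (is.null(case_ids))
    case_ids <- vapply(seq_along(x), function(i) {
      if (inherits(x[[i]], "baods_features")) x[[i]]$case_id
      else as.character(i)
    }, character(1))
  data <- lapply(seq_along(x), function(i)
    list(x = x[[i]], y = targets[[i]], case_id = case_ids[i]))
  net <- build_net(spec, seed = control$seed)
  net <- train(net, data, control)
  net$call <- match.call()
  net
}

#' @export
print.baods_net <- function(x, ...) {
  nl <- length(x$spec$layers)
  nconv <- sum(vapply(x$spec$layers, function(l) l$type == "conv", logical(1)))
  nlin <- sum(vapply(x$spec$layers, function(l) l$type == "linear",
                     logical(1)))
  cat(sprintf(
    "<baods_net> %d layers (%d conv, %d linear), %d parameters\n",
    nl, nconv, nlin, n_params(x)))
  cat(sprintf("  input (C,H,W) = (%s), output length %d\n",
              paste(x$spec$input_shape, collapse = ", "), x$spec$n_out))
  if (!is.null(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  trained %d epochs (%s loss): final loss %.5f, MSE %.5f\n",
                nrow(x$trace), x$control$loss, last$loss, last$mse))
  } else {
    cat("  untrained (random initialization)\n")
  }
  invisible(x)
}

#' @export
summary.baods_net <- function(object, ...) {
  out <- list(shapes = shape_inference(object$spec),
              n_params = n_params(object),
              trace = object$trace,
              control = object$control)
  class(out) <- "summary.baods_net"
  out
}

#' @export
print.summary.baods_net <- function(x, ...) {
  cat("Layer shapes:\n")
  for (i in seq_along(x$shapes))
    cat(sprintf("  %2d %-8s (%s)\n", i, x$shapes[[i]]$type,
                paste(x$shapes[[i]]$shape, collapse = ", ")))
  cat(sprintf("Parameters: %d\n", x$n_params))
  if (!is.null(x$trace)) {
    cat(sprintf("Training: %d epochs, final loss %.5f, final MSE %.5f\n",
                nrow(x$trace), x$trace$loss[nrow(x$trace)],
                x$trace$mse[nrow(x$trace)]))
  }
  invisible(x)
}

#' @export
coef.baods_net <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$params)) {
    p <- object$params[[i]]
    if (is.null(p)) next
    for (f in names(p))
      out[[sprintf("L%02d.%s.%s", i, object$spec$layers[[i]]$type, f)]] <-
        p[[f]]
  }
  out
}

#' @export
predict.baods_net <- function(object, newdata, ...) {
  if (inherits(newdata, "baods_features") || is.matrix(newdata) ||
      is.array(newdata))
    return(predict_sbeam(object, newdata))
  if (is.list(newdata))
    return(lapply(newdata, function(x) predict_sbeam(object, x)))
  stop("newdata must be a feature tensor or a list of them")
}

#' @export
plot.baods_net <- function(x, which = c("trace", "mse"), ...) {
  which <- match.arg(which)
  if (is.null(x$trace)) stop("network has not been trained")
  if (which == "trace") {
    graphics::plot(x$trace$epoch, x$trace$loss, type = "l",
                   xlab = "epoch", ylab = paste(x$control$loss, "loss"),
                   main = "training loss", ...)
  } else {
    graphics::plot(x$trace$epoch, x$trace$mse, type = "l",
                   xlab = "epoch", ylab = "MSE vs reference",
                   main = "training MSE", ...)
  }
  invisible(x)
}

#' @export
residuals.baods_net <- function(object, ...) {
  if (is.null(object$fitted))
    stop("network has not been trained")
  object$fitted - object$refs
}
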