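#' Fit the universal multiple linear regression transformation
#'
#' Least-squares fit of the 12 reference leads on the three standardized
#' chest leads plus a constant bias term, pooled over all training samples
#' (the "universal" coefficient: one matrix for every subject).
#'
#' @param cl_train 3 x T matrix of standardized chest leads.
#' @param leads_train 12 x T matrix of reference leads (microvolts).
#' @return Object of class `mlr_model` with `b`, the 12 x 4 coefficient
#'   matrix (columns: bias, CL1..CL3).
#' @export
fit_mlr <- function(cl_train, leads_train) {
  stopifnot(is.matrix(cl_train), nrow(cl_train) == 3L,
            is.matrix(leads_train), nrow(leads_train) == 12L,
            ncol(cl_train) == ncol(leads_train))
  if (ncol(cl_train) <= 4L)
    stop("need more than 4 samples to fit the regression", call. = FALSE)
  X <- cbind(1, t(cl_train))                       # T x 4
  qx <- qr(X)
  if (qx$rank < 4L)
    stop("chest-lead matrix is rank deficient; cannot fit MLR",
         call. = FALSE)
  coef <- qr.coef(qx, t(leads_train))              # 4 x 12
  b <- t(coef)
  dimnames(b) <- list(rownames(leads_train),
                      c("bias", "CL1", "CL2", "CL3"))
  structure(list(b = b), class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, cl_test, ...) {
  stopifnot(is.matrix(cl_test), nrow(cl_test) == 3L)
  out <- object$b %*% rbind(1, cl_test)
  rownames(out) <- rownames(object$b)
  out
}

#' ANN training hyperparameters
#'
#' Full-batch gradient descent with an adaptive ("bold driver") step size:
#' the step grows by 10% after each accepted update and halves when an update
#' would increase the loss, which makes the recorded training loss
#' non-increasing by construction.  Training stops at `max_epochs`, when the
#' relative loss improvement stays below `tol` for `patience` accepted steps,
#' or when the step size underflows.
#'
#' @param hidden Hidden-layer width (the study design fixes 6).
#' @param max_epochs Maximum number of epochs.
#' @param lr_init Initial step size.
#' @param tol Relative-improvement threshold for the plateau stop.
#' @param patience Consecutive below-threshold steps before stopping.
#' @param output Output activation: `"linear"` (default; signed voltages) or
#'   `"softmax"`.
#' @return List of hyperparameters.
#' @export
ann_hyperparams <- function(hidden = 6L, max_epochs = 2000L, lr_init = 0.1,
                            tol = 1e-8, patience = 10L,
                            output = c("linear", "softmax")) {
  output <- match.arg(output)
  stopifnot(hidden >= 1, max_epochs >= 1, lr_init > 0, tol >= 0,
            patience >= 1)
  list(hidden = as.integer(hidden), max_epochs = as.integer(max_epochs),
       lr_init = lr_init, tol = tol, patience = as.integer(patience),
       output = output)
}

ann_pack <- function(W1, b1, W2, b2) c(W1, b1, W2, b2)

ann_unpack <- function(theta, n_in, n_hid, n_out) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(n_hid * n_in)], n_hid, n_in)
  i <- i + n_hid * n_in
  b1 <- theta[i + seq_len(n_hid)]; i <- i + n_hid
  W2 <- matrix(theta[i + seq_len(n_out * n_hid)], n_out, n_hid)
  i <- i + n_out * n_hid
  b2 <- theta[i + seq_len(n_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

logistic <- function(a) 1 / (1 + exp(-a))

ann_forward <- function(w, X, output = "linear") {
  H <- logistic(w$W1 %*% X + w$b1)
  A2 <- w$W2 %*% H + w$b2
  Y <- if (output == "softmax") {
    E <- exp(A2 - rep(apply(A2, 2L, max), each = nrow(A2)))
    E / rep(colSums(E), each = nrow(A2))
  } else A2
  list(H = H, Y = Y)
}

ann_loss_grad <- function(theta, X, Tm, n_hid, output) {
  n_out <- nrow(Tm)
  w <- ann_unpack(theta, nrow(X), n_hid, n_out)
  fw <- ann_forward(w, X, output)
  R <- fw$Y - Tm
  loss <- mean(R^2)
  dY <- 2 * R / length(R)
  dA2 <- if (output == "softmax") {
    s <- colSums(dY * fw$Y)
    fw$Y * (dY - rep(s, each = n_out))
  } else dY
  gW2 <- tcrossprod(dA2, fw$H)
  gb2 <- rowSums(dA2)
  dH <- crossprod(w$W2, dA2)
  dA1 <- dH * fw$H * (1 - fw$H)
  gW1 <- tcrossprod(dA1, X)
  gb1 <- rowSums(dA1)
  list(loss = loss, grad = ann_pack(gW1, gb1, gW2, gb2))
}

ann_loss <- function(theta, X, Tm, n_hid, output) {
  w <- ann_unpack(theta, nrow(X), n_hid, nrow(Tm))
  mean((ann_forward(w, X, output)$Y - Tm)^2)
}

#' Fit one feedforward neural network (3-6-12)
#'
#' Single-hidden-layer feedforward network mapping the three standardized
#' chest leads to the twelve (standardized) target leads: logistic-sigmoid
#' hidden units, linear output by default (a softmax output mode is provided
#' for completeness, but a softmax constrains outputs to a positive simplex
#' and cannot represent signed voltages — see the package vignette).  Weights
#' are initialized uniformly in +/- 1/sqrt(fan-in) from `seed` and trained by
#' full-batch backpropagation ([ann_hyperparams()]).  Identical seed and data
#' give an identical model.
#'
#' @param cl_train 3 x T standardized chest leads.
#' @param leads_train_std 12 x T standardized target leads.
#' @param seed Integer seed for the weight initialization.
#' @param hyperparams See [ann_hyperparams()].
#' @return Object of class `ann_model`: weights `W1`, `b1`, `W2`, `b2`,
#'   the `seed`, `output` mode, and the recorded `loss_trace` (one value per
#'   accepted epoch, non-increasing).
#' @export
fit_ann <- function(cl_train, leads_train_std, seed,
                    hyperparams = ann_hyperparams()) {
  stopifnot(is.matrix(cl_train), is.matrix(leads_train_std),
            ncol(cl_train) == ncol(leads_train_std))
  hp <- hyperparams
  n_in <- nrow(cl_train); n_out <- nrow(leads_train_std); n_hid <- hp$hidden
  w0 <- with_seed(seed, {
    r1 <- 1 / sqrt(n_in); r2 <- 1 / sqrt(n_hid)
    list(W1 = matrix(stats::runif(n_hid * n_in, -r1, r1), n_hid, n_in),
         b1 = stats::runif(n_hid, -r1, r1),
         W2 = matrix(stats::runif(n_out * n_hid, -r2, r2), n_out, n_hid),
         b2 = stats::runif(n_out, -r2, r2))
  })
  if (hp$output == "linear") {
    # warm-start the linear readout: least squares on the (random) initial
    # hidden activations, so backpropagation starts from the best linear
    # combination of those features rather than from noise
    H0 <- logistic(w0$W1 %*% cl_train + w0$b1)
    co <- tryCatch(qr.coef(qr(cbind(1, t(H0))), t(leads_train_std)),
                   error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) {
      w0$b2 <- co[1L, ]
      w0$W2 <- t(co[-1L, , drop = FALSE])
    }
  }
  theta <- ann_pack(w0$W1, w0$b1, w0$W2, w0$b2)
  lr <- hp$lr_init
  lg <- ann_loss_grad(theta, cl_train, leads_train_std, n_hid, hp$output)
  if (!is.finite(lg$loss))
    stop("ANN training diverged: non-finite loss", call. = FALSE)
  trace <- lg$loss
  flat <- 0L
  for (epoch in seq_len(hp$max_epochs)) {
    cand <- theta - lr * lg$grad
    lgc <- ann_loss_grad(cand, cl_train, leads_train_std, n_hid, hp$output)
    if (!is.finite(lgc$loss))
      stop("ANN training diverged: non-finite loss", call. = FALSE)
    if (lgc$loss <= lg$loss) {      # accept: candidate gradient is reused
      rel <- (lg$loss - lgc$loss) / max(lg$loss, 1e-300)
      theta <- cand
      lg <- lgc
      trace <- c(trace, lgc$loss)
      lr <- lr * 1.1
      flat <- if (rel < hp$tol) flat + 1L else 0L
      if (flat >= hp$patience) break
    } else {
      lr <- lr / 2
      if (lr < 1e-14) break
    }
  }
  w <- ann_unpack(theta, n_in, n_hid, n_out)
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 output = hp$output, seed = seed, loss_trace = trace),
            class = "ann_model")
}

#' @export
predict.ann_model <- function(object, cl_test, ...) {
  stopifnot(is.matrix(cl_test), nrow(cl_test) == ncol(object$W1))
  ann_forward(object, cl_test, object$output)$Y
}

#' Fit the five-seed ANN ensemble
#'
#' Trains the network five times from different random initializations (the
#' backpropagation reaches different local minima) and averages the member
#' outputs pointwise.  Targets are standardized internally with the training
#' statistics; predictions are inverted back to microvolts.
#'
#' @param cl_train 3 x T standardized chest leads.
#' @param leads_train 12 x T reference leads (microvolts).
#' @param seeds Five distinct integer seeds.
#' @param hyperparams See [ann_hyperparams()].
#' @return Object of class `ensemble_model`: `members` (list of
#'   `ann_model`), `target_stats` (center/scale used for inversion), `seeds`.
#' @export
fit_ensemble <- function(cl_train, leads_train, seeds = 1:5,
                         hyperparams = ann_hyperparams()) {
  if (anyDuplicated(seeds))
    stop("ensemble seeds must be distinct", call. = FALSE)
  std <- standardize(leads_train)
  members <- lapply(seeds, function(s)
    fit_ann(cl_train, std$x, seed = s, hyperparams = hyperparams))
  structure(list(members = members,
                 target_stats = list(center = std$center, scale = std$scale),
                 seeds = seeds),
            class = "ensemble_model")
}

#' @export
predict.ensemble_model <- function(object, cl_test, ...) {
  preds <- lapply(object$members, predict, cl_test = cl_test)
  avg <- Reduce(`+`, preds) / length(preds)
  out <- unstandardize(avg, object$target_stats)
  rownames(out) <- lead_names_12()[seq_len(nrow(out))]
  out
}

#' Serialize a fitted model to / from JSON
#'
#' @param model A `mlr_model`, `ann_model` or `ensemble_model`.
#' @param path File path.
#' @return `model_from_json()` returns the model object.
#' @export
model_to_json <- function(model, path) {
  cls <- class(model)[1L]
  payload <- switch(cls,
    mlr_model = list(type = "mlr", b = model$b),
    ann_model = list(type = "ann", W1 = model$W1, b1 = model$b1,
                     W2 = model$W2, b2 = model$b2, output = model$output,
                     seed = model$seed),
    ensemble_model = list(
      type = "ensemble", seeds = model$seeds,
      target_center = model$target_stats$center,
      target_scale = model$target_stats$scale,
      members = lapply(model$members, function(m)
        list(W1 = m$W1, b1 = m$b1, W2 = m$W2, b2 = m$b2,
             output = m$output, seed = m$seed))),
    stop("unknown model class: ", cls, call. = FALSE))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(m) do.call(rbind, lapply(m, unlist))
  mk_ann <- function(m) structure(
    list(W1 = as_mat(m$W1), b1 = unlist(m$b1),
         W2 = as_mat(m$W2), b2 = unlist(m$b2),
         output = m$output, seed = m$seed, loss_trace = NULL),
    class = "ann_model")
  switch(p$type,
    mlr = {
      b <- as_mat(p$b)
      dimnames(b) <- list(lead_names_12(), c("bias", "CL1", "CL2", "CL3"))
      structure(list(b = b), class = "mlr_model")
    },
    ann = mk_ann(p),
    ensemble = structure(
      list(members = lapply(p$members, mk_ann),
           target_stats = list(center = unlist(p$target_center),
                               scale = unlist(p$target_scale)),
           seeds = unlist(p$seeds)),
      class = "ensemble_model"),
    stop("unknown model type in ", path, call. = FALSE))
}
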