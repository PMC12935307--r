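#' Mean binary cross-entropy loss
#'
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))` over residues. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` for numerical safety before taking
#' logs.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @return Non-negative scalar.
#' @examples
#' bce_loss(c(0.5, 0.5), c(1, 0)) # log(2)
#' @export
bce_loss <- function(p, y) {
  if (length(p) != length(y)) stop("probabilities and labels differ in length")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  y <- as.numeric(y)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Random input masking
#'
#' Zeroes an independent Bernoulli(`rate`) subset of input coordinates
#' (independently per residue), the input-corruption regularizer applied
#' during training steps. Inference never masks.
#'
#' @param x Feature matrix.
#' @param rate Masking rate in `[0, 1)`.
#' @return Matrix of the same shape with a random subset of entries zeroed.
#' @export
mask_inputs <- function(x, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(x)
  x * (matrix(stats::runif(length(x)), nrow(x), ncol(x)) >= rate)
}

#' Trainable parameter count of the residue classifier
#'
#' Closed-form count for a fully connected network
#' `input -> hidden[1] -> ... -> hidden[k] -> 1`, counting weights and
#' biases.
#'
#' @param input_dim Input dimension.
#' @param hidden Hidden-layer widths.
#' @return Integer parameter count.
#' @examples
#' mlp_parameter_count(24) # (24+1)*2000 + 2001*1000 + 1001*500 + 501
#' @export
mlp_parameter_count <- function(input_dim, hidden = c(2000, 1000, 500)) {
  dims <- c(input_dim, hidden, 1)
  sum((dims[-length(dims)] + 1) * dims[-1])
}

.sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# He-initialised weights for ReLU hidden layers; logistic output layer
.init_weights <- function(input_dim, hidden) {
  dims <- c(input_dim, hidden, 1)
  lapply(seq_len(length(dims) - 1), function(l) {
    list(W = matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                 sqrt(2 / dims[l])), dims[l], dims[l + 1]),
         b = numeric(dims[l + 1]))
  })
}

# forward pass; returns activations for backprop when training = TRUE
.forward <- function(weights, x, dropout = 0, training = FALSE) {
  L <- length(weights)
  acts <- vector("list", L)
  a <- x
  for (l in seq_len(L - 1)) {
    z <- sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    h <- pmax(z, 0)
    if (training && dropout > 0) {
      keep <- matrix(stats::runif(length(h)), nrow(h), ncol(h)) >= dropout
      h <- h * keep / (1 - dropout)  # inverted dropout
      acts[[l]] <- list(input = a, h = h, relu_mask = z > 0, drop = keep)
    } else {
      acts[[l]] <- list(input = a, h = h, relu_mask = z > 0, drop = NULL)
    }
    a <- h
  }
  z <- drop(a %*% weights[[L]]$W) + weights[[L]]$b
  p <- .sigmoid(z)
  list(p = p, acts = acts, last_input = a)
}

# gradient of mean BCE wrt all parameters
.backward <- function(weights, fw, y, dropout) {
  L <- length(weights)
  n <- length(y)
  grads <- vector("list", L)
  delta <- matrix((fw$p - y) / n, ncol = 1)          # dL/dz at the output
  grads[[L]] <- list(W = crossprod(fw$last_input, delta),
                     b = colSums(delta))
  back <- delta %*% t(weights[[L]]$W)
  for (l in rev(seq_len(L - 1))) {
    a <- fw$acts[[l]]
    d <- back * a$relu_mask
    if (!is.null(a$drop)) d <- d * a$drop / (1 - dropout)
    # note: dropout applied after ReLU, so the chain passes through both
    grads[[l]] <- list(W = crossprod(a$input, d), b = colSums(d))
    if (l > 1) back <- d %*% t(weights[[l]]$W)
  }
  grads
}

.default_selection_metric <- function(probs, labels, groups) {
  vals <- vapply(split(seq_along(labels), groups), function(idx) {
    y <- labels[idx]
    if (length(unique(y)) < 2L) return(NA_real_)
    pr_auc(y, probs[idx])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Fit the multilayer-perceptron paratope classifier
#'
#' Trains a fully connected network (default hidden widths 2000, 1000, 500
#' with ReLU activations and a logistic output) mapping per-residue feature
#' vectors to paratope probabilities, by minimising mean binary
#' cross-entropy with the Adam optimizer. The training protocol applies
#' dropout to all hidden layers, random masking of a fraction of the input
#' coordinates (training steps only), L2 weight decay on weights (biases
#' excluded), sequence-level batches with the loss averaged over all
#' residues in a batch, and early stopping: after every epoch the selection
#' metric (per-protein-averaged validation PR AUC by default) is evaluated
#' and the parameters of the best epoch are retained; training halts when
#' the metric has not improved for `patience` epochs or at `max_epochs`.
#'
#' @param x Numeric feature matrix, one row per residue.
#' @param y Binary labels aligned with the rows of `x`.
#' @param groups Sequence (protein) identifier per row; batching and
#'   per-protein metric averaging operate at this level. Defaults to one
#'   group.
#' @param validation List with elements `x`, `y` and optionally `groups`:
#'   the validation set driving checkpoint selection. Must contain at least
#'   one positive label (otherwise the selection metric is undefined).
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout rate for hidden layers.
#' @param mask_rate Input masking rate.
#' @param learning_rate Adam learning rate.
#' @param batch_size Number of sequences per batch.
#' @param weight_decay L2 regularization weight (applied to weights only).
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Maximum number of epochs.
#' @param seed Integer seed controlling initialization, shuffling, masking
#'   and dropout; identical inputs and seed reproduce the fit exactly.
#' @param selection_metric Optional replacement for the validation metric:
#'   a `function(probs, labels, groups)` returning a scalar to maximise.
#' @param verbose Print one line per epoch.
#' @return Object of class `paratope_mlp` with components `weights` (best
#'   checkpoint), `config`, `history` (per-epoch training loss and
#'   validation metric), `best_epoch`, `n_parameters`, `fitted`
#'   (training-set probabilities under the returned weights), `y`, `groups`.
#' @seealso [predict.paratope_mlp()], [mlp_parameter_count()], [bce_loss()]
#' @export
paratope_mlp <- function(x, y, groups = NULL, validation,
                         hidden = c(2000, 1000, 500),
                         dropout = 0.4, mask_rate = 0.4,
                         learning_rate = 1e-5, batch_size = 16,
                         weight_decay = 1e-5, patience = 10,
                         max_epochs = 300, seed = 1L,
                         selection_metric = NULL, verbose = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)),
            all(hidden > 0), dropout >= 0, dropout < 1,
            mask_rate >= 0, mask_rate < 1,
            learning_rate > 0, batch_size >= 1, weight_decay >= 0,
            patience >= 1, max_epochs >= 1)
  if (nrow(x) == 0L) stop("empty training set")
  if (is.null(groups)) groups <- rep(1L, nrow(x))
  groups <- as.integer(factor(groups, levels = unique(groups)))
  if (missing(validation) || is.null(validation)) {
    stop("a validation set is required for checkpoint selection")
  }
  vx <- as.matrix(validation$x)
  vy <- as.numeric(validation$y)
  vg <- validation$groups
  if (is.null(vg)) vg <- rep(1L, nrow(vx))
  vg <- as.integer(factor(vg, levels = unique(vg)))
  if (sum(vy == 1) == 0L) {
    stop("validation set has no positive labels; the selection metric is undefined")
  }
  if (ncol(vx) != ncol(x)) stop("validation feature dimension differs from training")
  metric_fn <- if (is.null(selection_metric)) .default_selection_metric else selection_metric

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  weights <- .init_weights(ncol(x), hidden)
  L <- length(weights)
  # Adam state
  mW <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
  vW <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  seq_rows <- split(seq_len(nrow(x)), groups)
  n_seq <- length(seq_rows)
  best_metric <- -Inf
  best_epoch <- 0L
  best_weights <- weights
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_metric = numeric())

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n_seq)
    batch_of <- ceiling(seq_along(ord) / batch_size)
    losses <- numeric(0)
    for (bi in unique(batch_of)) {
      rows <- unlist(seq_rows[ord[batch_of == bi]], use.names = FALSE)
      xb <- x[rows, , drop = FALSE]
      yb <- y[rows]
      if (mask_rate > 0) xb <- mask_inputs(xb, mask_rate)
      fw <- .forward(weights, xb, dropout, training = TRUE)
      losses <- c(losses, bce_loss(fw$p, yb))
      gr <- .backward(weights, fw, yb, dropout)
      step <- step + 1L
      for (l in seq_len(L)) {
        gW <- gr[[l]]$W + weight_decay * weights[[l]]$W  # L2 on weights only
        gb <- gr[[l]]$b
        mW[[l]]$W <- beta1 * mW[[l]]$W + (1 - beta1) * gW
        mW[[l]]$b <- beta1 * mW[[l]]$b + (1 - beta1) * gb
        vW[[l]]$W <- beta2 * vW[[l]]$W + (1 - beta2) * gW^2
        vW[[l]]$b <- beta2 * vW[[l]]$b + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step
        corr2 <- 1 - beta2^step
        weights[[l]]$W <- weights[[l]]$W -
          learning_rate * (mW[[l]]$W / corr1) / (sqrt(vW[[l]]$W / corr2) + eps)
        weights[[l]]$b <- weights[[l]]$b -
          learning_rate * (mW[[l]]$b / corr1) / (sqrt(vW[[l]]$b / corr2) + eps)
      }
    }
    val_probs <- .forward(weights, vx)$p
    metric <- metric_fn(val_probs, vy, vg)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_metric = metric))
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  val metric %.4f\n",
                  epoch, mean(losses), metric))
    }
    if (is.finite(metric) && metric > best_metric) {
      best_metric <- metric
      best_epoch <- epoch
      best_weights <- weights
    }
    if (epoch - best_epoch >= patience) break
  }

  fitted <- .forward(best_weights, x)$p
  out <- list(weights = best_weights,
              config = list(input_dim = ncol(x), hidden = hidden,
                            dropout = dropout, mask_rate = mask_rate,
                            learning_rate = learning_rate,
                            batch_size = batch_size,
                            weight_decay = weight_decay,
                            patience = patience, max_epochs = max_epochs,
                            seed = seed),
              history = history, best_epoch = best_epoch,
              best_metric = best_metric,
              n_parameters = mlp_parameter_count(ncol(x), hidden),
              fitted = fitted, y = y, groups = groups)
  class(out) <- "paratope_mlp"
  out
}

#' Predict paratope probabilities
#'
#' Deterministic forward pass of a fitted classifier: no dropout and no
#' input masking are applied at inference.
#'
#' @param object A fitted `paratope_mlp`.
#' @param newdata Feature matrix with `object$config$input_dim` columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict.paratope_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$config$input_dim) {
    stop("feature dimension ", ncol(newdata), " does not match model input ",
         object$config$input_dim)
  }
  .forward(object$weights, newdata)$p
}

#' @export
print.paratope_mlp <- function(x, ...) {
  cat("paratope_mlp:", x$config$input_dim, "->",
      paste(x$config$hidden, collapse = " -> "), "-> 1\n")
  cat(sprintf("  %s trainable parameters; trained %d epoch(s), best epoch %d (val metric %.4f)\n",
              format(x$n_parameters, big.mark = ","), nrow(x$history),
              x$best_epoch, x$best_metric))
  invisible(x)
}

#' @export
summary.paratope_mlp <- function(object, ...) {
  cat("Multilayer-perceptron paratope classifier\n\n")
  print(object)
  cfg <- object$config
  cat(sprintf("\n  dropout %.2f | input mask %.2f | lr %g | batch %d sequences | L2 %g\n",
              cfg$dropout, cfg$mask_rate, cfg$learning_rate, cfg$batch_size,
              cfg$weight_decay))
  cat(sprintf("  early stopping: patience %d, max %d epochs, seed %d\n",
              cfg$patience, cfg$max_epochs, cfg$seed))
  cat(sprintf("\n  final train loss %.4f | training prevalence %.3f\n",
              utils::tail(object$history$train_loss, 1), mean(object$y)))
  invisible(object)
}

#' @export
coef.paratope_mlp <- function(object, ...) {
  object$weights
}

#' @export
residuals.paratope_mlp <- function(object, ...) {
  object$y - object$fitted
}

#' Plot training history
#'
#' Training loss and validation metric per epoch, with the selected
#' checkpoint marked.
#'
#' @param x A fitted `paratope_mlp`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.paratope_mlp <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training BCE", ...)
  graphics::plot(h$epoch, h$val_metric, type = "l", xlab = "epoch",
                 ylab = "validation metric", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
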