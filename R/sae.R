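## Stacked autoencoder: greedy layer-wise pretraining + supervised
## fine-tuning through a softmax head. All gradients are derived and
## implemented here; sae_gradient_check() validates them against central
## finite differences.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)  # shift for overflow safety
  e <- exp(z)
  e / rowSums(e)
}

#' Training control parameters for the stacked autoencoder
#'
#' @param lr_pretrain Learning rate of the layer-wise reconstruction phase.
#' @param lr_finetune Learning rate of the supervised fine-tuning phase.
#' @param momentum Momentum coefficient in [0, 1) for both phases.
#' @param batch_size Mini-batch size.
#' @param pretrain_epochs Epochs per layer of unsupervised pretraining.
#' @param finetune_epochs Epochs of supervised fine-tuning.
#' @return A list of class `sae_control`.
#' @export
sae_control <- function(lr_pretrain = 0.5, lr_finetune = 0.1,
                        momentum = 0.5, batch_size = 100L,
                        pretrain_epochs = 20L, finetune_epochs = 50L) {
  stopifnot(lr_pretrain >= 0, lr_finetune >= 0,
            momentum >= 0, momentum < 1,
            batch_size >= 1, pretrain_epochs >= 1, finetune_epochs >= 1)
  out <- list(lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
              momentum = momentum, batch_size = as.integer(batch_size),
              pretrain_epochs = as.integer(pretrain_epochs),
              finetune_epochs = as.integer(finetune_epochs))
  class(out) <- "sae_control"
  out
}

#' Initialize an untrained stacked autoencoder
#'
#' Encoder weights are drawn uniformly on +/- 4*sqrt(6 / (fan_in + fan_out))
#' (the classical scale for sigmoid units); all biases and the softmax head
#' start at zero. Decoder weights (used only during pretraining) are drawn
#' the same way. The same seed always yields bitwise-identical parameters.
#'
#' @param layer_sizes Integer vector: input size, hidden sizes..., and a
#'   final output size of 2 (interaction vs non-interaction).
#' @param activation Hidden-layer nonlinearity; only `"sigmoid"` is built in.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `sae` (untrained).
#' @export
#' @examples
#' m <- sae_init(c(420, 400, 2), seed = 1)
sae_init <- function(layer_sizes, activation = "sigmoid", seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) {
    stop("need at least an input and an output size")
  }
  if (any(layer_sizes <= 0L)) stop("layer sizes must be positive")
  if (layer_sizes[length(layer_sizes)] != 2L) {
    stop("output layer must have size 2 (two classes)")
  }
  if (!identical(activation, "sigmoid")) {
    stop("unsupported activation: ", activation)
  }
  hidden <- layer_sizes[-c(1L, length(layer_sizes))]
  dims <- c(layer_sizes[1L], hidden)  # encoder stack dims
  layers <- with_seed(seed, {
    lapply(seq_along(hidden), function(l) {
      fan_in <- dims[l]; fan_out <- dims[l + 1L]
      r <- 4 * sqrt(6 / (fan_in + fan_out))
      list(
        W_enc = matrix(stats::runif(fan_out * fan_in, -r, r), fan_out, fan_in),
        b_enc = numeric(fan_out),
        W_dec = matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out),
        b_dec = numeric(fan_in)
      )
    })
  })
  model <- list(
    layer_sizes = layer_sizes,
    activation = activation,
    layers = layers,
    head = list(W = matrix(0, 2L, dims[length(dims)]), b = numeric(2L)),
    seed = as.integer(seed),
    pretrain_trace = vector("list", length(layers)),
    finetune_trace = NULL
  )
  class(model) <- "sae"
  model
}

# Encoder forward pass: returns list of activations a^(0)=X, a^(1), ..., a^(L)
sae_activations <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1L]) {
    stop("input has ", ncol(X), " columns; model expects ",
         model$layer_sizes[1L])
  }
  acts <- vector("list", length(model$layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    acts[[l + 1L]] <- sigmoid(acts[[l]] %*% t(lay$W_enc) +
                              rep(lay$b_enc, each = nrow(X)))
  }
  acts
}

#' Forward pass through a stacked autoencoder
#'
#' @param model An `sae` object.
#' @param X Numeric matrix of inputs (rows = samples).
#' @return List with `activations` (per-layer activations, first element the
#'   input) and `prob` (n x 2 softmax class probabilities; column 1 = class 0,
#'   column 2 = class 1 "interaction").
#' @export
sae_forward <- function(model, X) {
  acts <- sae_activations(model, X)
  top <- acts[[length(acts)]]
  logits <- top %*% t(model$head$W) + rep(model$head$b, each = nrow(top))
  prob <- softmax_rows(logits)
  colnames(prob) <- c("p0", "p1")
  list(activations = acts, prob = prob)
}

# --- pretraining -----------------------------------------------------------

# Loss and gradients of the single-layer reconstruction objective
# L = 1/(2m) sum (xhat - x)^2, xhat = f(W_dec f(W_enc x + b_enc) + b_dec).
ae_loss_grad <- function(layer, X, want_grad = TRUE) {
  m <- nrow(X)
  H <- sigmoid(X %*% t(layer$W_enc) + rep(layer$b_enc, each = m))
  Xhat <- sigmoid(H %*% t(layer$W_dec) + rep(layer$b_dec, each = m))
  R <- Xhat - X
  loss <- sum(R * R) / (2 * m)
  if (!want_grad) return(list(loss = loss))
  d2 <- R * Xhat * (1 - Xhat) / m
  d1 <- (d2 %*% layer$W_dec) * H * (1 - H)
  list(loss = loss,
       grad = list(W_enc = t(d1) %*% X, b_enc = colSums(d1),
                   W_dec = t(d2) %*% H, b_dec = colSums(d2)))
}

#' Unsupervised pretraining of one autoencoder layer
#'
#' Trains the encoder/decoder pair of the given layer to reconstruct its
#' input (the activation of the previous layer) under mean squared error,
#' by mini-batch gradient descent with momentum. Decoder parameters are kept
#' on the layer for inspection but take no part in later computation.
#'
#' @param model An `sae` object.
#' @param layer_index Which layer to pretrain (1-based).
#' @param X Input activation matrix for that layer (the raw input for layer
#'   1; use [sae_activations()] outputs for deeper layers).
#' @param control An [sae_control()] list.
#' @param seed Seed governing mini-batch shuffling.
#' @return The model with updated layer parameters and the per-epoch
#'   reconstruction loss appended to `pretrain_trace[[layer_index]]`.
#' @export
sae_pretrain_layer <- function(model, layer_index, X,
                               control = sae_control(), seed = model$seed) {
  stopifnot(inherits(model, "sae"),
            layer_index >= 1, layer_index <= length(model$layers))
  X <- as.matrix(X)
  layer <- model$layers[[layer_index]]
  if (ncol(X) != ncol(layer$W_enc)) {
    stop("layer ", layer_index, " expects input width ", ncol(layer$W_enc),
         ", got ", ncol(X))
  }
  m <- nrow(X)
  vel <- lapply(layer[c("W_enc", "b_enc", "W_dec", "b_dec")],
                function(p) p * 0)
  trace <- numeric(control$pretrain_epochs)
  with_seed(derive_seed(seed, 100L + layer_index), {
    for (epoch in seq_len(control$pretrain_epochs)) {
      ord <- sample.int(m)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        lg <- ae_loss_grad(layer, X[idx, , drop = FALSE])
        epoch_loss <- epoch_loss + lg$loss * length(idx)
        for (p in names(vel)) {
          vel[[p]] <- control$momentum * vel[[p]] -
            control$lr_pretrain * lg$grad[[p]]
          layer[[p]] <- layer[[p]] + vel[[p]]
        }
      }
      trace[epoch] <- epoch_loss / m
      if (!is.finite(trace[epoch])) {
        stop("non-finite reconstruction loss at epoch ", epoch)
      }
    }
  })
  model$layers[[layer_index]] <- layer
  model$pretrain_trace[[layer_index]] <-
    c(model$pretrain_trace[[layer_index]], trace)
  model
}

# --- fine-tuning -----------------------------------------------------------

# Cross-entropy loss and gradients wrt all encoder weights + softmax head.
ft_loss_grad <- function(model, X, y, want_grad = TRUE) {
  m <- nrow(X)
  acts <- sae_activations(model, X)
  top <- acts[[length(acts)]]
  logits <- top %*% t(model$head$W) + rep(model$head$b, each = m)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(m), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  if (!want_grad) return(list(loss = loss))
  Y <- matrix(0, m, 2L)
  Y[cbind(seq_len(m), y + 1L)] <- 1
  dlog <- (P - Y) / m
  grad <- list(head = list(W = t(dlog) %*% top, b = colSums(dlog)),
               layers = vector("list", length(model$layers)))
  delta <- (dlog %*% model$head$W) * top * (1 - top)
  for (l in rev(seq_along(model$layers))) {
    a_prev <- acts[[l]]
    grad$layers[[l]] <- list(W_enc = t(delta) %*% a_prev,
                             b_enc = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% model$layers[[l]]$W_enc) * a_prev * (1 - a_prev)
    }
  }
  list(loss = loss, grad = grad)
}

#' Supervised fine-tuning of the whole stack
#'
#' Back-propagates softmax cross-entropy through the encoder stack, updating
#' every encoder weight and the head by mini-batch gradient descent with
#' momentum. Mini-batch order is reshuffled each epoch under the seed.
#'
#' @param model An `sae` object (typically pretrained).
#' @param X Input matrix.
#' @param y Integer labels in {0, 1} (1 = interaction).
#' @param control An [sae_control()] list.
#' @param seed Seed for batch shuffling.
#' @return The model with updated parameters and `finetune_trace` (per-epoch
#'   mean cross-entropy).
#' @export
sae_finetune <- function(model, X, y, control = sae_control(),
                         seed = model$seed) {
  stopifnot(inherits(model, "sae"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (any(!y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  m <- nrow(X)
  vel <- list(head = lapply(model$head, function(p) p * 0),
              layers = lapply(model$layers, function(l)
                list(W_enc = l$W_enc * 0, b_enc = l$b_enc * 0)))
  trace <- numeric(control$finetune_epochs)
  with_seed(derive_seed(seed, 200L), {
    for (epoch in seq_len(control$finetune_epochs)) {
      ord <- sample.int(m)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        lg <- ft_loss_grad(model, X[idx, , drop = FALSE], y[idx])
        epoch_loss <- epoch_loss + lg$loss * length(idx)
        for (p in c("W", "b")) {
          vel$head[[p]] <- control$momentum * vel$head[[p]] -
            control$lr_finetune * lg$grad$head[[p]]
          model$head[[p]] <- model$head[[p]] + vel$head[[p]]
        }
        for (l in seq_along(model$layers)) {
          for (p in c("W_enc", "b_enc")) {
            vel$layers[[l]][[p]] <- control$momentum * vel$layers[[l]][[p]] -
              control$lr_finetune * lg$grad$layers[[l]][[p]]
            model$layers[[l]][[p]] <- model$layers[[l]][[p]] +
              vel$layers[[l]][[p]]
          }
        }
      }
      trace[epoch] <- epoch_loss / m
      if (!is.finite(trace[epoch])) {
        stop("non-finite fine-tuning loss at epoch ", epoch)
      }
    }
  })
  model$finetune_trace <- c(model$finetune_trace, trace)
  model
}

# --- gradient checking -----------------------------------------------------

# Flatten/unflatten helpers over a named list of numeric arrays.
flatten_params <- function(lst) unlist(lst, use.names = FALSE)

#' Finite-difference validation of the analytic gradients
#'
#' Perturbs every parameter of the relevant objective by +/- epsilon,
#' recomputes the loss, and compares the central difference with the
#' analytic gradient. Intended for small toy models.
#'
#' @param model An `sae` object (keep it to a few hundred parameters).
#' @param X Input matrix.
#' @param y Labels in {0, 1}; required for `objective = "finetune"`.
#' @param objective `"finetune"` (cross-entropy through the whole stack) or
#'   `"pretrain"` (reconstruction loss of `layer_index`).
#' @param layer_index Layer checked under the pretraining objective.
#' @param epsilon Perturbation size (default 1e-5).
#' @return Maximum relative discrepancy
#'   `max |g_analytic - g_numeric| / max(1, |g_a| + |g_n|)` over parameters.
#' @export
sae_gradient_check <- function(model, X, y = NULL,
                               objective = c("finetune", "pretrain"),
                               layer_index = 1L, epsilon = 1e-5) {
  objective <- match.arg(objective)
  X <- as.matrix(X)
  if (objective == "finetune") {
    if (is.null(y)) stop("labels required for the fine-tuning objective")
    y <- as.integer(y)
    ana <- ft_loss_grad(model, X, y)$grad
    ga <- c(flatten_params(ana$head),
            flatten_params(lapply(ana$layers, function(l) l[c("W_enc", "b_enc")])))
    get_par <- function(m) c(flatten_params(m$head),
                             flatten_params(lapply(m$layers, function(l)
                               l[c("W_enc", "b_enc")])))
    set_par <- function(m, v) {
      i <- 0L
      take <- function(p) {
        out <- array(v[(i + 1L):(i + length(p))], dim = dim(p) %||% length(p))
        i <<- i + length(p)
        out
      }
      m$head$W <- take(m$head$W); m$head$b <- as.numeric(take(m$head$b))
      for (l in seq_along(m$layers)) {
        m$layers[[l]]$W_enc <- take(m$layers[[l]]$W_enc)
        m$layers[[l]]$b_enc <- as.numeric(take(m$layers[[l]]$b_enc))
      }
      m
    }
    loss_at <- function(v) ft_loss_grad(set_par(model, v), X, y,
                                        want_grad = FALSE)$loss
    theta <- get_par(model)
  } else {
    layer <- model$layers[[layer_index]]
    ana <- ae_loss_grad(layer, X)$grad
    ga <- flatten_params(ana)
    theta <- flatten_params(layer[c("W_enc", "b_enc", "W_dec", "b_dec")])
    set_par <- function(v) {
      i <- 0L
      out <- layer
      for (p in c("W_enc", "b_enc", "W_dec", "b_dec")) {
        n <- length(layer[[p]])
        val <- v[(i + 1L):(i + n)]
        out[[p]] <- if (is.matrix(layer[[p]])) {
          array(val, dim = dim(layer[[p]]))
        } else {
          val
        }
        i <- i + n
      }
      out
    }
    loss_at <- function(v) ae_loss_grad(set_par(v), X, want_grad = FALSE)$loss
  }
  gn <- vapply(seq_along(theta), function(k) {
    up <- theta; up[k] <- up[k] + epsilon
    dn <- theta; dn[k] <- dn[k] - epsilon
    (loss_at(up) - loss_at(dn)) / (2 * epsilon)
  }, numeric(1))
  max(abs(ga - gn) / pmax(1, abs(ga) + abs(gn)))
}

# --- the user-facing fitting function --------------------------------------

#' Fit a stacked-autoencoder interaction classifier
#'
#' The standard workflow: initialize the encoder stack, greedily pretrain
#' each layer to reconstruct its input, then fine-tune the whole stack plus
#' a 2-class softmax head with back-propagated classification error.
#'
#' @param x Numeric matrix of pair feature vectors (rows = samples), values
#'   ideally in [0, 1] (see [encode_pair_matrix()]).
#' @param y Labels in {0, 1}; 1 = interaction.
#' @param hidden Integer vector of hidden-layer sizes (default 400, the
#'   one-hidden-layer architecture that performs best for AC input).
#' @param control Training hyperparameters, see [sae_control()].
#' @param pretrain Run the unsupervised pretraining phase (default TRUE).
#' @param seed Integer seed; fixes initialization and batch order, making
#'   the whole fit reproducible.
#' @return A fitted object of class `sae` with components `layers`, `head`,
#'   `pretrain_trace`, `finetune_trace`, `fitted.values` (training
#'   probability of interaction), `y`, `control` and `call`. Methods:
#'   [predict.sae()], `print`, `summary`, `coef`, `plot`, `simulate`,
#'   `residuals`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), 50, 4)
#' y <- as.integer(x[, 1] + x[, 2] > 1)
#' fit <- sae(x, y, hidden = 6, seed = 1,
#'            control = sae_control(batch_size = 10, pretrain_epochs = 5,
#'                                  finetune_epochs = 30))
#' mean(predict(fit, x) == y)
sae <- function(x, y, hidden = 400L, control = sae_control(),
                pretrain = TRUE, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  model <- sae_init(c(ncol(x), hidden, 2L), seed = seed)
  if (pretrain) {
    inp <- x
    for (l in seq_along(model$layers)) {
      model <- sae_pretrain_layer(model, l, inp, control, seed = seed)
      if (l < length(model$layers)) {
        inp <- sae_activations(model, x)[[l + 1L]]
      }
    }
  }
  model <- sae_finetune(model, x, y, control, seed = seed)
  p1 <- sae_forward(model, x)$prob[, 2L]
  model$fitted.values <- p1
  model$y <- y
  model$control <- control
  model$call <- match.call()
  model
}

#' Predict interaction labels or probabilities
#'
#' Class labels are the argmax of the softmax output; a probability of
#' exactly 0.5 is resolved to the negative (non-interaction) class.
#'
#' @param object A fitted `sae`.
#' @param newdata Numeric matrix of pair feature vectors.
#' @param type `"class"` for 0/1 labels (default) or `"prob"` for the n x 2
#'   probability matrix.
#' @param ... Unused.
#' @return Integer labels or a probability matrix.
#' @export
predict.sae <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  prob <- sae_forward(object, as.matrix(newdata))$prob
  if (type == "prob") return(prob)
  as.integer(prob[, 2L] > 0.5)
}

#' @export
print.sae <- function(x, ...) {
  cat("Stacked autoencoder classifier\n")
  cat("  architecture: [", paste(x$layer_sizes, collapse = ", "), "]\n",
      sep = "")
  cat("  activation:  ", x$activation, "\n")
  trained <- !is.null(x$finetune_trace)
  cat("  status:      ", if (trained) "fine-tuned" else "initialized", "\n")
  if (trained) {
    cat("  final cross-entropy:",
        format(utils::tail(x$finetune_trace, 1), digits = 4), "\n")
  }
  if (!is.null(x$fitted.values)) {
    acc <- mean(as.integer(x$fitted.values > 0.5) == x$y)
    cat("  training accuracy:  ", format(acc, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
summary.sae <- function(object, ...) {
  n_enc <- sum(vapply(object$layers, function(l)
    length(l$W_enc) + length(l$b_enc), numeric(1)))
  n_head <- length(object$head$W) + length(object$head$b)
  out <- list(
    layer_sizes = object$layer_sizes,
    n_parameters = n_enc + n_head,
    pretrain_final_loss = vapply(object$pretrain_trace, function(tr)
      if (length(tr)) utils::tail(tr, 1) else NA_real_, numeric(1)),
    finetune_final_loss = if (length(object$finetune_trace))
      utils::tail(object$finetune_trace, 1) else NA_real_,
    training_accuracy = if (!is.null(object$fitted.values))
      mean(as.integer(object$fitted.values > 0.5) == object$y) else NA_real_
  )
  class(out) <- "summary.sae"
  out
}

#' @export
print.summary.sae <- function(x, ...) {
  cat("Stacked autoencoder classifier [",
      paste(x$layer_sizes, collapse = ", "), "], ",
      x$n_parameters, " trainable parameters\n", sep = "")
  cat("  pretraining final reconstruction loss per layer:",
      paste(format(x$pretrain_final_loss, digits = 4), collapse = ", "), "\n")
  cat("  fine-tuning final cross-entropy:",
      format(x$finetune_final_loss, digits = 4), "\n")
  cat("  training accuracy:", format(x$training_accuracy, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.sae <- function(object, ...) {
  c(lapply(object$layers, function(l) list(W = l$W_enc, b = l$b_enc)),
    list(head = object$head))
}

#' @export
residuals.sae <- function(object, ...) {
  if (is.null(object$fitted.values)) stop("model has no stored fit")
  object$y - object$fitted.values
}

#' @export
plot.sae <- function(x, ...) {
  pre <- unlist(x$pretrain_trace)
  ft <- x$finetune_trace
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (length(pre)) {
    graphics::plot(pre, type = "l", xlab = "epoch (all layers)",
                   ylab = "reconstruction MSE", main = "Pretraining", ...)
  }
  if (length(ft)) {
    graphics::plot(ft, type = "l", xlab = "epoch",
                   ylab = "cross-entropy", main = "Fine-tuning", ...)
  }
  invisible(x)
}

#' @export
simulate.sae <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  p1 <- if (is.null(newdata)) {
    object$fitted.values %||% stop("model has no stored fit; give newdata")
  } else {
    sae_forward(object, as.matrix(newdata))$prob[, 2L]
  }
  run <- function() stats::rbinom(length(p1), 1L, p1)
  sims <- if (is.null(seed)) {
    replicate(nsim, run())
  } else {
    with_seed(seed, replicate(nsim, run()))
  }
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

# --- serialization ---------------------------------------------------------

#' Save or load a fitted model as self-describing JSON
#'
#' All weights are written at full precision so a load/save round trip
#' reproduces predictions bitwise. The file also carries the encoding scheme
#' and the fitted feature scaler when supplied, so a saved model is a
#' complete predictor for raw sequences.
#'
#' @param model A fitted `sae`.
#' @param path Output path.
#' @param scaler Optional `feature_scaler` to embed.
#' @param scheme Optional encoding scheme label ("AC" or "CT").
#' @param lag_max Optional AC lag recorded for provenance.
#' @return `path` invisibly (`save_sae`); the restored `sae` (`load_sae`)
#'   with `scaler`/`scheme` attached if they were saved.
#' @export
save_sae <- function(model, path, scaler = NULL, scheme = NULL,
                     lag_max = NULL) {
  obj <- list(
    format = "ppisae-model",
    version = 1L,
    layer_sizes = model$layer_sizes,
    activation = model$activation,
    seed = model$seed,
    layers = lapply(model$layers, function(l)
      list(W_enc = l$W_enc, b_enc = l$b_enc,
           W_dec = l$W_dec, b_dec = l$b_dec)),
    head = model$head,
    scheme = scheme,
    lag_max = lag_max,
    scaler = if (!is.null(scaler)) {
      list(min = as.numeric(scaler$min), range = as.numeric(scaler$range))
    }
  )
  # 17 significant digits: lossless round trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_sae
#' @export
load_sae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "ppisae-model")) {
    stop("not a ppisae model file: ", path)
  }
  relist_layer <- function(l) list(
    W_enc = as.matrix(l$W_enc), b_enc = as.numeric(l$b_enc),
    W_dec = as.matrix(l$W_dec), b_dec = as.numeric(l$b_dec))
  layers <- lapply(obj$layers, relist_layer)
  model <- list(
    layer_sizes = as.integer(obj$layer_sizes),
    activation = obj$activation,
    layers = layers,
    head = list(W = as.matrix(obj$head$W), b = as.numeric(obj$head$b)),
    seed = as.integer(obj$seed),
    pretrain_trace = vector("list", length(layers)),
    finetune_trace = NULL
  )
  class(model) <- "sae"
  if (!is.null(obj$scaler)) {
    sc <- list(min = as.numeric(obj$scaler$min),
               range = as.numeric(obj$scaler$range))
    class(sc) <- "feature_scaler"
    model$scaler <- sc
  }
  model$scheme <- obj$scheme
  model$lag_max <- obj$lag_max
  model
}
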