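# Shared neural-network primitives: activation registry, Glorot
# initialisation, softmax, and an Adam optimiser over named parameter lists.

.activations <- list(
  ReLU = list(f = function(x) pmax(x, 0),
              df = function(x, y) (x > 0) * 1),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 df = function(x, y) y * (1 - y)),
  tanh = list(f = tanh,
              df = function(x, y) 1 - y^2),
  identity = list(f = identity,
                  df = function(x, y) 1)
)

activation <- function(name) {
  a <- .activations[[name]]
  if (is.null(a)) stop("unknown activation: ", name, " (registry: ",
                       paste(names(.activations), collapse = ", "), ")")
  a
}

# Glorot/Xavier uniform init: limit sqrt(6 / (fan_in + fan_out))
glorot <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam over a flat named list of numeric arrays.
adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(state = state, params = params)
}

#' Training configuration
#'
#' Hyperparameters for the gradient-based trainers. Full-scale defaults
#' mirror the published protocol (Adam, MSE, learning rate 0.00095, 400
#' epochs, batch 64 for the auto-encoder; categorical cross-entropy,
#' learning rate 1e-5, 300 epochs, batch 8 for the delineator); desk-scale
#' runs pass smaller `epochs` and a learning rate suited to short schedules.
#'
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Mini-batch size (>= 1); the final partial batch is used.
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Optimiser name; only `"adam"` is implemented.
#' @param loss Loss name, `"mse"` or `"categorical_crossentropy"`.
#' @param lr_schedule `"constant"`, or `"cosine"` (cosine annealing of the
#'   learning rate to 0 over the epochs — recommended for short schedules,
#'   where a fixed step size leaves the optimiser hovering at its
#'   gradient-noise floor).
#' @param seed Integer seed fixing initialisation and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 400, batch_size = 64,
                         learning_rate = 0.00095, optimizer = "adam",
                         loss = "mse", lr_schedule = c("constant", "cosine"),
                         seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  if (optimizer != "adam") stop("train_config: only 'adam' is implemented")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = loss, lr_schedule = lr_schedule,
                 seed = as.integer(seed)),
            class = "train_config")
}

# learning rate for epoch ep under the config's schedule
epoch_lr <- function(cfg, ep) {
  if (identical(cfg$lr_schedule, "cosine"))
    cfg$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
  else cfg$learning_rate
}
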