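# The five first-order optimizers of the tuning grid. "decay" is the
# classic per-update inverse-time learning-rate decay:
#   lr_t = lr / (1 + decay * (t - 1)),  t = 1, 2, ... update count.

OPTIMIZERS <- c("adagrad", "adam", "nag", "rmsprop", "sgd")
OPT_EPS <- 1e-8
NAG_MOMENTUM <- 0.9
RMSPROP_RHO <- 0.9
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999

make_optimizer <- function(name, learning_rate, decay) {
  name <- match.arg(name, OPTIMIZERS)
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stopf("learning_rate must be > 0")
  }
  list(name = name, lr = learning_rate, decay = decay, t = 0L)
}

# One parameter-array update. st is this parameter's state list (possibly
# empty); returns list(p = updated values, st = updated state).
optim_update_param <- function(opt, lr_t, p, g, st) {
  switch(opt$name,
    sgd = list(p = p - lr_t * g, st = st),
    nag = {
      v <- st$v %||% (g * 0)
      v <- NAG_MOMENTUM * v - lr_t * g
      list(p = p + NAG_MOMENTUM * v - lr_t * g, st = list(v = v))
    },
    adagrad = {
      acc <- (st$acc %||% (g * 0)) + g * g
      list(p = p - lr_t * g / (sqrt(acc) + OPT_EPS), st = list(acc = acc))
    },
    rmsprop = {
      acc <- RMSPROP_RHO * (st$acc %||% (g * 0)) + (1 - RMSPROP_RHO) * g * g
      list(p = p - lr_t * g / (sqrt(acc) + OPT_EPS), st = list(acc = acc))
    },
    adam = {
      m <- ADAM_BETA1 * (st$m %||% (g * 0)) + (1 - ADAM_BETA1) * g
      v <- ADAM_BETA2 * (st$v %||% (g * 0)) + (1 - ADAM_BETA2) * g * g
      mh <- m / (1 - ADAM_BETA1^opt$t)
      vh <- v / (1 - ADAM_BETA2^opt$t)
      list(p = p - lr_t * mh / (sqrt(vh) + OPT_EPS), st = list(m = m, v = v))
    }
  )
}

# Apply one optimizer step across every parameter of the predictor.
# state is a nested list mirroring (path, layer, param); returns both the
# updated predictor and state, with the step counter advanced.
optim_step <- function(opt, pred, grads, state) {
  opt$t <- opt$t + 1L
  lr_t <- opt$lr / (1 + opt$decay * (opt$t - 1L))
  for (path in c("image", "sex", "head")) {
    g_path <- grads[[path]]
    if (is.null(g_path)) next
    layers_field <- paste0(path, "_layers")
    layers <- pred[[layers_field]]
    for (i in seq_along(g_path)) {
      gl <- g_path[[i]]
      if (is.null(gl)) next
      for (pn in names(gl)) {
        key <- paste(path, i, pn, sep = ".")
        upd <- optim_update_param(opt, lr_t, layers[[i]][[pn]], gl[[pn]],
                                  state[[key]] %||% list())
        layers[[i]][[pn]] <- upd$p
        state[[key]] <- upd$st
      }
    }
    pred[[layers_field]] <- layers
  }
  list(opt = opt, pred = pred, state = state)
}
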