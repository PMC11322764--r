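# Internal numeric helpers shared by the learning modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

# derivative of LeakyReLU wrt its pre-activation (1 on x>0, slope otherwise;
# the measure-zero kink at 0 takes the negative branch)
leaky_relu_grad <- function(x, slope) {
  slope + (1 - slope) * (x > 0)
}

# Glorot/Xavier uniform initialization for a fan_in x fan_out weight matrix.
xavier_matrix <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Minimal Adam optimizer over a named list of numeric arrays. Moment
# estimates are kept as flat vectors; parameters keep their original shape.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) numeric(length(p))),
    v = lapply(params, function(p) numeric(length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    upd <- .adam_fused(params[[nm]], grads[[nm]], state$m[[nm]],
                       state$v[[nm]], lr, beta1, beta2, eps, bc1, bc2)
    params[[nm]][] <- upd$p
    state$m[[nm]] <- upd$m
    state$v[[nm]] <- upd$v
  }
  list(params = params, state = state)
}

# Shape-checked stop() with a consistent prefix so callers can grep stages.
stop_mdlink <- function(...) stop(..., call. = FALSE)

is_binary_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))
}
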