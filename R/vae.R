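# Variational autoencoder, implemented directly on matrices.
#
# Architecture (for input width D):
#   encoder:  D -> hidden1 (affine, batch-norm, ReLU) -> (mu, logvar) of
#             width latent_dim
#   sampling: z = mu + epsilon_std * exp(logvar/2) * eps,  eps ~ N(0,1)
#   decoder:  latent_dim -> hidden3 (affine, ReLU) -> D (affine, sigmoid)
# Loss: binary cross-entropy summed over features + Gaussian KL to N(0,I),
# averaged over the batch. Optimised with Adam.
#
# No deep-learning backend is assumed: forward and backward passes (including
# batch normalisation) are written out explicitly, which keeps training fully
# reproducible from a single integer seed via R's own RNG.

.BN_EPS <- 1e-3     # batch-norm variance floor (Keras default)
.BN_MOMENTUM <- 0.99  # running-statistics momentum (Keras default)
.CLAMP <- 1e-7      # sigmoid output clamp away from {0,1}

#' VAE hyperparameter configuration
#'
#' Defaults are the published training recipe for the 878-dimensional spliced
#' matrices: 300-100-300 bottleneck, batch size 20, learning rate 0.001,
#' sampling standard deviation 1, 50 epochs, 9/1 train/validation split.
#'
#' @param input_dim width of the training rows (spliced matrix columns).
#' @param hidden1,latent_dim,hidden3 layer widths.
#' @param batch_size minibatch rows; reduced to the data size if larger.
#' @param learning_rate Adam step size.
#' @param epsilon_std standard deviation multiplier of the latent sampling
#'   noise.
#' @param epochs training epochs (no early stopping).
#' @param validation_fraction fraction of rows held out and monitored (never
#'   trained on); in `[0, 1)`.
#' @param seed integer seed controlling initialisation, the data split,
#'   shuffling and sampling noise.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(input_dim, hidden1 = 300, latent_dim = 100,
                       hidden3 = 300, batch_size = 20, learning_rate = 0.001,
                       epsilon_std = 1, epochs = 50,
                       validation_fraction = 0.1, seed = 1L) {
  stopifnot(input_dim >= 1, hidden1 >= 1, latent_dim >= 1, hidden3 >= 1,
            batch_size >= 1, learning_rate > 0, epsilon_std >= 0, epochs >= 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden1 = as.integer(hidden1),
                 latent_dim = as.integer(latent_dim),
                 hidden3 = as.integer(hidden3),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epsilon_std = epsilon_std,
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "vae_config")
}

# Glorot-uniform weight matrix
.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialise an untrained VAE
#'
#' Glorot-uniform weights, zero biases, identity batch-norm. Consumes the
#' config seed so two initialisations with one seed are identical.
#'
#' @param config a [vae_config()].
#' @return object of class `trained_vae` with empty training history.
#' @export
init_vae <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  set.seed(config$seed)
  D <- config$input_dim; h1 <- config$hidden1
  L <- config$latent_dim; h3 <- config$hidden3
  par <- list(
    W1 = .glorot(D, h1),  b1 = numeric(h1),
    bn_gamma = rep(1, h1), bn_beta = numeric(h1),
    Wmu = .glorot(h1, L), bmu = numeric(L),
    Wlv = .glorot(h1, L), blv = numeric(L),
    W3 = .glorot(L, h3),  b3 = numeric(h3),
    W4 = .glorot(h3, D),  b4 = numeric(D))
  structure(list(par = par,
                 running_mean = numeric(h1),
                 running_var = rep(1, h1),
                 config = config,
                 history = data.frame(epoch = integer(),
                                      train_loss = numeric(),
                                      val_loss = numeric())),
            class = "trained_vae")
}

#' @export
print.trained_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("trained_vae: %d-%d-%d-%d-%d, %d epoch(s) trained\n",
              cfg$input_dim, cfg$hidden1, cfg$latent_dim, cfg$hidden3,
              cfg$input_dim, nrow(x$history)))
  invisible(x)
}

.as_row_matrix <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != width)
    stop(sprintf("%s: input width %d does not match expected %d",
                 what, ncol(x), width))
  if (any(!is.finite(x))) stop(what, ": non-finite input")
  x
}

#' Encode inputs to latent mean and log-variance
#'
#' Deterministic inference-mode pass: batch normalisation uses the running
#' statistics accumulated during training, so encoding a batch equals
#' encoding its rows one at a time.
#'
#' @param model a `trained_vae`.
#' @param x row vector or matrix of rows, entries in `[0,1]`.
#' @return list with matrices `mu` and `logvar` (one row per input row).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "trained_vae"))
  x <- .as_row_matrix(x, model$config$input_dim, "encode")
  p <- model$par
  z1 <- sweep(x %*% p$W1, 2, p$b1, "+")
  xhat <- sweep(sweep(z1, 2, model$running_mean, "-"), 2,
                sqrt(model$running_var + .BN_EPS), "/")
  h1 <- pmax(sweep(sweep(xhat, 2, p$bn_gamma, "*"), 2, p$bn_beta, "+"), 0)
  list(mu = sweep(h1 %*% p$Wmu, 2, p$bmu, "+"),
       logvar = sweep(h1 %*% p$Wlv, 2, p$blv, "+"))
}

#' Reparameterised latent sample
#'
#' `z = mu + epsilon_std * exp(logvar / 2) * eps` with `eps` standard normal
#' draws from R's RNG stream (seed it with `set.seed()` for reproducibility).
#'
#' @param mu,logvar latent mean and log-variance (vectors or matrices of the
#'   same shape).
#' @param epsilon_std noise scale; 0 gives `z = mu`.
#' @return sample of the same shape as `mu`.
#' @export
reparameterize <- function(mu, logvar, epsilon_std = 1) {
  stopifnot(identical(dim(mu), dim(logvar)), length(mu) == length(logvar))
  if (epsilon_std == 0) return(mu)
  eps <- stats::rnorm(length(mu))
  if (!is.null(dim(mu))) eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + epsilon_std * exp(logvar / 2) * eps
}

#' Decode latent vectors to reconstructions
#'
#' Deterministic decoder pass; outputs are sigmoid activations clamped to the
#' open interval `(0,1)`.
#'
#' @param model a `trained_vae`.
#' @param z latent row vector or matrix of rows.
#' @return reconstruction matrix, one row per latent row.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "trained_vae"))
  z <- .as_row_matrix(z, model$config$latent_dim, "decode")
  p <- model$par
  h3 <- pmax(sweep(z %*% p$W3, 2, p$b3, "+"), 0)
  out <- stats::plogis(sweep(h3 %*% p$W4, 2, p$b4, "+"))
  pmin(pmax(out, .CLAMP), 1 - .CLAMP)
}

#' VAE loss: reconstruction + KL divergence
#'
#' Reconstruction is binary cross-entropy summed over features; the KL term
#' is the closed-form divergence of the diagonal Gaussian `N(mu, exp(logvar))`
#' from the standard normal prior,
#' `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)`. Both are averaged over rows
#' when matrices are passed. Reconstructions are clamped away from {0,1}
#' before the logarithm.
#'
#' @param x inputs in `[0,1]`; vector or matrix.
#' @param x_hat reconstructions of the same shape.
#' @param mu,logvar latent statistics of the rows.
#' @return list with `reconstruction`, `kl` and `total` (their sum).
#' @export
vae_loss <- function(x, x_hat, mu, logvar) {
  x <- rbind(x); x_hat <- rbind(x_hat); mu <- rbind(mu); logvar <- rbind(logvar)
  stopifnot(identical(dim(x), dim(x_hat)), identical(dim(mu), dim(logvar)),
            nrow(x) == nrow(mu))
  x_hat <- pmin(pmax(x_hat, .CLAMP), 1 - .CLAMP)
  rec <- -rowSums(x * log(x_hat) + (1 - x) * log(1 - x_hat))
  kl <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  out <- list(reconstruction = mean(rec), kl = mean(kl))
  out$total <- out$reconstruction + out$kl
  stopifnot(all(is.finite(unlist(out))))
  out
}

# one training forward/backward pass on batch X (n x D); returns gradients,
# batch statistics and the loss terms
.vae_batch_grad <- function(par, X, epsilon_std) {
  n <- nrow(X)
  z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  mb <- colMeans(z1)
  zc <- sweep(z1, 2, mb, "-")
  vb <- colMeans(zc^2)
  inv_sd <- 1 / sqrt(vb + .BN_EPS)
  xn <- sweep(zc, 2, inv_sd, "*")
  a1 <- sweep(sweep(xn, 2, par$bn_gamma, "*"), 2, par$bn_beta, "+")
  h1 <- pmax(a1, 0)
  mu <- sweep(h1 %*% par$Wmu, 2, par$bmu, "+")
  lv <- sweep(h1 %*% par$Wlv, 2, par$blv, "+")
  sdz <- epsilon_std * exp(lv / 2)
  eps <- matrix(stats::rnorm(length(mu)), n)
  z <- mu + sdz * eps
  a3 <- sweep(z %*% par$W3, 2, par$b3, "+")
  h3 <- pmax(a3, 0)
  logits <- sweep(h3 %*% par$W4, 2, par$b4, "+")
  xh <- stats::plogis(logits)
  xh_c <- pmin(pmax(xh, .CLAMP), 1 - .CLAMP)

  rec <- mean(-rowSums(X * log(xh_c) + (1 - X) * log(1 - xh_c)))
  kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))

  # backward
  dlogits <- (xh - X) / n
  gW4 <- crossprod(h3, dlogits); gb4 <- colSums(dlogits)
  dh3 <- tcrossprod(dlogits, par$W4) * (a3 > 0)
  gW3 <- crossprod(z, dh3); gb3 <- colSums(dh3)
  dz <- tcrossprod(dh3, par$W3)
  dmu <- dz + mu / n
  dlv <- dz * (sdz * eps / 2) + (exp(lv) - 1) / (2 * n)
  gWmu <- crossprod(h1, dmu); gbmu <- colSums(dmu)
  gWlv <- crossprod(h1, dlv); gblv <- colSums(dlv)
  dh1 <- (tcrossprod(dmu, par$Wmu) + tcrossprod(dlv, par$Wlv)) * (a1 > 0)
  g_gamma <- colSums(dh1 * xn); g_beta <- colSums(dh1)
  dxn <- sweep(dh1, 2, par$bn_gamma, "*")
  # batch-norm backward (biased batch variance)
  dz1 <- sweep(dxn, 2, colMeans(dxn), "-") -
    xn * rep(colMeans(dxn * xn), each = n)
  dz1 <- sweep(dz1, 2, inv_sd, "*")
  gW1 <- crossprod(X, dz1); gb1 <- colSums(dz1)

  list(grads = list(W1 = gW1, b1 = gb1, bn_gamma = g_gamma, bn_beta = g_beta,
                    Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
                    W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4),
       batch_mean = mb, batch_var = vb,
       reconstruction = rec, kl = kl, total = rec + kl)
}

# inference-mode loss of a row block (mean latent, no sampling noise)
.vae_eval_loss <- function(model, X) {
  enc <- encode(model, X)
  xh <- decode(model, enc$mu)
  vae_loss(X, xh, enc$mu, enc$logvar)$total
}

#' Train a VAE on a spliced feature matrix
#'
#' Runs Adam for exactly `config$epochs` epochs (no early stopping) on a
#' seeded train/validation row split with per-epoch shuffling. The validation
#' loss is monitored and recorded only; final-epoch parameters are returned.
#' Two calls with the same data and seed produce identical histories and
#' parameters.
#'
#' @param data a [spliced_matrix()] or plain numeric matrix in `[0,1]`.
#' @param config a [vae_config()]; its `input_dim` must match the data width.
#' @return a `trained_vae` with per-epoch `history`
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_vae <- function(data, config) {
  X <- if (inherits(data, "spliced_matrix")) data$values else as.matrix(data)
  stopifnot(inherits(config, "vae_config"))
  if (ncol(X) != config$input_dim)
    stop("train_vae: data width ", ncol(X), " does not match config input_dim ",
         config$input_dim)
  model <- init_vae(config)   # also seeds the RNG stream used below
  n <- nrow(X)
  batch_size <- min(config$batch_size, n)
  n_val <- floor(config$validation_fraction * n)
  perm <- sample.int(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
  train_idx <- setdiff(perm, val_idx)
  if (length(train_idx) == 0) stop("train_vae: no training rows left after split")
  Xtr <- X[train_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]

  adam_m <- lapply(model$par, function(p) p * 0)
  adam_v <- lapply(model$par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; step <- 0L
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1, nrow(Xtr), by = batch_size)
    epoch_loss <- 0; epoch_rows <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, nrow(Xtr))]
      res <- .vae_batch_grad(model$par, Xtr[idx, , drop = FALSE],
                             config$epsilon_std)
      if (!is.finite(res$total))
        stop(sprintf("train_vae: non-finite loss at epoch %d, batch %d",
                     epoch, 1L + (s - 1L) %/% batch_size))
      model$running_mean <- .BN_MOMENTUM * model$running_mean +
        (1 - .BN_MOMENTUM) * res$batch_mean
      model$running_var <- .BN_MOMENTUM * model$running_var +
        (1 - .BN_MOMENTUM) * res$batch_var
      step <- step + 1L
      for (nm in names(model$par)) {
        g <- res$grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        model$par[[nm]] <- model$par[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
      epoch_loss <- epoch_loss + res$total * length(idx)
      epoch_rows <- epoch_rows + length(idx)
    }
    history[[epoch]] <- data.frame(
      epoch = epoch,
      train_loss = epoch_loss / epoch_rows,
      val_loss = if (n_val > 0) .vae_eval_loss(model, Xval) else NA_real_)
  }
  if (config$epochs > 0) {
    # finalise inference-mode batch-norm statistics as the exact first and
    # second moments of the pre-activation over the training rows: the
    # momentum-averaged running statistics are still biased toward their
    # initialisation when the step count is small
    z1 <- sweep(Xtr %*% model$par$W1, 2, model$par$b1, "+")
    model$running_mean <- colMeans(z1)
    model$running_var <- colMeans(sweep(z1, 2, colMeans(z1), "-")^2)
    model$history <- do.call(rbind, history)
  }
  model
}

# ---- checkpoint serialisation ----------------------------------------------

#' Save / load a trained VAE checkpoint
#'
#' Portable versioned JSON holding the config, parameters and running
#' batch-norm statistics at full double precision.
#'
#' @param model a `trained_vae`.
#' @param path checkpoint file path.
#' @return `save_vae` returns `path`; `load_vae` the restored `trained_vae`.
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "trained_vae"))
  obj <- list(format = "mdvae-vae-checkpoint", version = 1L,
              config = unclass(model$config),
              par = model$par,
              running_mean = model$running_mean,
              running_var = model$running_var,
              history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mdvae-vae-checkpoint"))
    stop("load_vae: not a VAE checkpoint: ", path)
  cfg <- do.call(vae_config, obj$config)
  par <- obj$par
  for (nm in c("W1", "Wmu", "Wlv", "W3", "W4"))
    par[[nm]] <- as.matrix(par[[nm]])
  hist <- as.data.frame(obj$history)
  if (nrow(hist) == 0)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
  structure(list(par = par,
                 running_mean = as.numeric(obj$running_mean),
                 running_var = as.numeric(obj$running_var),
                 config = cfg, history = hist),
            class = "trained_vae")
}
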