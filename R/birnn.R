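# Bidirectional GRU classifier with attention, implemented with plain
# matrix algebra (forward pass and exact backpropagation), since the
# sequence model is the package's own contribution. Gate columns are laid
# out [reset | update | candidate], each hidden_size wide.

#' Embedding dimension rule
#'
#' The embedding width is the floor of the fourth root of the vocabulary
#' size `D` (at least 1).
#'
#' @param D vocabulary size.
#' @return integer embedding dimension.
#' @export
embeddingDim <- function(D) {
  max(1L, as.integer(floor(D^0.25 + 1e-9)))
}

#' Architecture configuration for the BIRNN
#'
#' @param L maximal sequence length.
#' @param D vocabulary size (ignored for dense input).
#' @param hidden_size GRU hidden width per direction (default 64).
#' @param extra_dims width of the optional per-sample side vector
#'   concatenated before the final affine layer.
#' @param input_dim when non-`NULL`, the per-timestep input is a dense
#'   vector of this width (the interpolated multivariate layout) and the
#'   embedding lookup is bypassed.
#' @return list of architecture sizes.
#' @export
birnnConfig <- function(L, D, hidden_size = 64L, extra_dims = 0L,
                        input_dim = NULL) {
  list(L = as.integer(L), D = as.integer(D),
       embedding_dim = embeddingDim(D),
       hidden_size = as.integer(hidden_size),
       extra_dims = as.integer(extra_dims),
       input_dim = if (is.null(input_dim)) NULL else as.integer(input_dim))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.initMat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

#' Initialize a BIRNN model
#'
#' @param config from [birnnConfig()].
#' @param seed integer seed for the parameter draw.
#' @return a [BirnnModel-class].
#' @export
birnnInit <- function(config, seed = 1L) {
  set.seed(seed)
  h <- config$hidden_size
  e <- if (is.null(config$input_dim)) config$embedding_dim else
    config$input_dim
  params <- list()
  if (is.null(config$input_dim))
    params$E <- .initMat(config$D, config$embedding_dim, 0.1)
  for (d in c("f", "b")) {
    params[[paste0("Wx_", d)]] <- .initMat(e, 3L * h)
    params[[paste0("Wh_", d)]] <- .initMat(h, 3L * h)
    params[[paste0("bx_", d)]] <- matrix(0, 1, 3L * h)
    params[[paste0("bh_", d)]] <- matrix(0, 1, 3L * h)
  }
  params$wa <- .initMat(2L * h, 1L)
  params$ba <- matrix(0, 1, 1)
  params$wo <- .initMat(2L * h + config$extra_dims, 1L)
  params$bo <- matrix(0, 1, 1)
  new("BirnnModel", config = config, params = params)
}

# One GRU pass over a list of per-timestep inputs. xs: list over time of
# B x in matrices; msk: B x L validity (hidden state is carried through
# masked positions). Returns per-timestep hidden states and caches.
.gruForward <- function(xs, msk, Wx, Wh, bx, bh, h_size) {
  L <- length(xs); B <- nrow(xs[[1]])
  h <- matrix(0, B, h_size)
  H <- vector("list", L); cache <- vector("list", L)
  ih <- seq_len(h_size)
  for (t in seq_len(L)) {
    x <- xs[[t]]
    A <- x %*% Wx + matrix(bx, B, 3L * h_size, byrow = TRUE)
    Bh <- h %*% Wh + matrix(bh, B, 3L * h_size, byrow = TRUE)
    r <- .sigmoid(A[, ih, drop = FALSE] + Bh[, ih, drop = FALSE])
    z <- .sigmoid(A[, ih + h_size, drop = FALSE] +
                    Bh[, ih + h_size, drop = FALSE])
    Bh3 <- Bh[, ih + 2L * h_size, drop = FALSE]
    nn <- tanh(A[, ih + 2L * h_size, drop = FALSE] + r * Bh3)
    hnew <- (1 - z) * nn + z * h
    m <- msk[, t]
    h_t <- m * hnew + (1 - m) * h
    cache[[t]] <- list(x = x, h_prev = h, r = r, z = z, nn = nn,
                       Bh3 = Bh3, m = m)
    h <- h_t
    H[[t]] <- h_t
  }
  list(H = H, cache = cache)
}

# Backpropagation through .gruForward. dH: list over time of gradients
# w.r.t. the emitted hidden states. Returns parameter gradients and the
# per-timestep input gradients.
.gruBackward <- function(dH, cache, Wx, Wh, h_size) {
  L <- length(cache); B <- nrow(cache[[1]]$x)
  ih <- seq_len(h_size)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, h_size, 3L * h_size)
  dbx <- matrix(0, 1, 3L * h_size); dbh <- matrix(0, 1, 3L * h_size)
  dxs <- vector("list", L)
  dh_carry <- matrix(0, B, h_size)
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    dh <- dh_carry + if (is.null(dH[[t]])) 0 else dH[[t]]
    dhnew <- cc$m * dh
    dh_prev <- (1 - cc$m) * dh
    dz <- dhnew * (cc$h_prev - cc$nn)
    dnn <- dhnew * (1 - cc$z)
    dh_prev <- dh_prev + dhnew * cc$z
    da_n <- dnn * (1 - cc$nn^2)
    dBh3 <- da_n * cc$r
    dr <- da_n * cc$Bh3
    da_r <- dr * cc$r * (1 - cc$r)
    da_z <- dz * cc$z * (1 - cc$z)
    dA <- cbind(da_r, da_z, da_n)
    dBh <- cbind(da_r, da_z, dBh3)
    dWx <- dWx + crossprod(cc$x, dA)
    dWh <- dWh + crossprod(cc$h_prev, dBh)
    dbx <- dbx + colSums(dA)
    dbh <- dbh + colSums(dBh)
    dxs[[t]] <- dA %*% t(Wx)
    dh_carry <- dh_prev + dBh %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, dbx = dbx, dbh = dbh, dxs = dxs)
}

# Per-timestep input matrices for a batch: embedding lookup for token
# input, slices of the dense array otherwise.
.inputSlices <- function(params, config, batch) {
  L <- config$L
  if (is.null(config$input_dim)) {
    lapply(seq_len(L), function(t)
      params$E[batch$indices[, t], , drop = FALSE])
  } else {
    B <- dim(batch$dense)[1]
    lapply(seq_len(L), function(t)
      matrix(batch$dense[, t, ], nrow = B))
  }
}

# Forward pass up to the attention-pooled feature vector (the
# pre-classifier representation used both by the standalone model and by
# multimodal fusion).
.birnnFeatures <- function(params, config, batch) {
  h <- config$hidden_size; L <- config$L
  B <- nrow(batch$mask)
  xs <- .inputSlices(params, config, batch)
  fwd <- .gruForward(xs, batch$mask, params$Wx_f, params$Wh_f,
                     params$bx_f, params$bh_f, h)
  msk_rev <- batch$mask[, rev(seq_len(L)), drop = FALSE]
  bwd <- .gruForward(xs[rev(seq_len(L))], msk_rev, params$Wx_b,
                     params$Wh_b, params$bx_b, params$bh_b, h)
  Hb <- bwd$H[rev(seq_len(L))]  # re-align backward outputs with time
  Hcat <- lapply(seq_len(L), function(t) cbind(fwd$H[[t]], Hb[[t]]))

  U <- vapply(Hcat, function(a)
    as.numeric(a %*% params$wa) + params$ba[1, 1], numeric(B))
  if (B == 1L) U <- matrix(U, 1L)
  U[batch$mask == 0] <- -Inf
  mx <- apply(U, 1, max)
  dead <- !is.finite(mx)  # all-pad samples: uniform attention fallback
  if (any(dead)) U[dead, ] <- 0
  mx[dead] <- 0
  EU <- exp(U - mx)
  alpha <- EU / rowSums(EU)
  ctx <- matrix(0, B, 2L * h)
  for (t in seq_len(L)) ctx <- ctx + alpha[, t] * Hcat[[t]]
  list(feat = ctx,
       cache = list(xs = xs, fwd = fwd, bwd = bwd, Hcat = Hcat,
                    alpha = alpha, dead = dead, batch = batch))
}

# Backward from a gradient on the pooled feature vector down to all
# parameters (and, for token input, the embedding rows).
.birnnFeaturesBackward <- function(params, config, cache, dctx) {
  h <- config$hidden_size; L <- config$L
  batch <- cache$batch
  B <- nrow(batch$mask)
  alpha <- cache$alpha
  Hcat <- cache$Hcat

  dalpha <- vapply(seq_len(L), function(t)
    rowSums(dctx * Hcat[[t]]), numeric(B))
  if (B == 1L) dalpha <- matrix(dalpha, 1L)
  inner <- rowSums(alpha * dalpha)
  dU <- alpha * (dalpha - inner)
  dU[batch$mask == 0] <- 0
  dU[cache$dead, ] <- 0

  dwa <- matrix(0, 2L * h, 1)
  dba <- 0
  dHcat <- vector("list", L)
  for (t in seq_len(L)) {
    dHt <- alpha[, t] * dctx
    dHt <- dHt + dU[, t] %*% t(params$wa)
    dwa <- dwa + crossprod(Hcat[[t]], dU[, t, drop = FALSE])
    dba <- dba + sum(dU[, t])
    dHcat[[t]] <- dHt
  }

  ihf <- seq_len(h)
  dHf <- lapply(dHcat, function(m) m[, ihf, drop = FALSE])
  dHb <- lapply(dHcat, function(m) m[, ihf + h, drop = FALSE])
  gf <- .gruBackward(dHf, cache$fwd$cache, params$Wx_f, params$Wh_f, h)
  gb <- .gruBackward(dHb[rev(seq_len(L))], cache$bwd$cache,
                     params$Wx_b, params$Wh_b, h)
  dxs_b <- gb$dxs[rev(seq_len(L))]

  grads <- list(
    Wx_f = gf$dWx, Wh_f = gf$dWh, bx_f = gf$dbx, bh_f = gf$dbh,
    Wx_b = gb$dWx, Wh_b = gb$dWh, bx_b = gb$dbx, bh_b = gb$dbh,
    wa = dwa, ba = matrix(dba, 1, 1))
  if (is.null(config$input_dim)) {
    dE <- matrix(0, config$D, config$embedding_dim)
    for (t in seq_len(L)) {
      dx <- gf$dxs[[t]] + dxs_b[[t]]
      agg <- rowsum(dx, group = batch$indices[, t])
      rows <- as.integer(rownames(agg))
      dE[rows, ] <- dE[rows, , drop = FALSE] + agg
    }
    grads$E <- dE
  }
  grads
}

#' Forward pass of the BIRNN
#'
#' Embedding lookup (or dense per-timestep input), a forward-time GRU
#' and a reversed-time GRU, per-timestep concatenation of both outputs,
#' attention pooling over valid positions (an all-pad sample falls back
#' to uniform weights), concatenation with the optional extra modality
#' vector, and an affine map to one score per sample.
#'
#' @param model a [BirnnModel-class].
#' @param batch list with `indices` (B x L integer matrix) and `mask`
#'   (B x L), or `dense` (B x L x input_dim array) and `mask`; plus
#'   `extra` (B x extra_dims) when configured.
#' @param params optionally, parameters overriding `model@params`.
#' @return list with `score` (raw), `prob` (sigmoid), `feat` (the
#'   pooled pre-classifier vector) and `attention` (the weight matrix).
#' @export
birnnForward <- function(model, batch, params = NULL) {
  if (is.null(params)) params <- model@params
  config <- model@config
  ff <- .birnnFeatures(params, config, batch)
  feat <- ff$feat
  if (config$extra_dims > 0L) {
    if (is.null(batch$extra) || ncol(batch$extra) != config$extra_dims)
      stop("batch extra vector width must equal extra_dims")
    feat_full <- cbind(feat, batch$extra)
  } else feat_full <- feat
  score <- as.numeric(feat_full %*% params$wo) + params$bo[1, 1]
  list(score = score, prob = .sigmoid(score), feat = ff$feat,
       attention = ff$cache$alpha, cache = ff$cache,
       feat_full = feat_full)
}

# Mean binary cross-entropy loss and exact parameter gradients for one
# batch (batch$labels in {0,1}).
.birnnLossGrads <- function(model, batch, params = NULL,
                            pos_weight = 1) {
  if (is.null(params)) params <- model@params
  config <- model@config
  out <- birnnForward(model, batch, params)
  y <- batch$labels
  p <- out$prob
  eps <- 1e-12
  w <- ifelse(y == 1, pos_weight, 1)
  loss <- -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  B <- length(y)
  dscore <- w * (p - y) / B
  dfeat_full <- dscore %*% t(params$wo)
  grads <- list(
    wo = crossprod(out$feat_full, matrix(dscore, ncol = 1)),
    bo = matrix(sum(dscore), 1, 1))
  h2 <- 2L * config$hidden_size
  dctx <- dfeat_full[, seq_len(h2), drop = FALSE]
  grads <- c(grads,
             .birnnFeaturesBackward(params, config, out$cache, dctx))
  list(loss = loss, grads = grads, prob = p)
}
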