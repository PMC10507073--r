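# Common model interface used by the training engine: predicted
# probabilities, loss + gradients for a batch, and parameter get/set.

#' Predicted probabilities for a batch
#' @param model a trainable model object.
#' @param batch a batch in the model's input format.
#' @export
setGeneric("modelPredict", function(model, batch)
  standardGeneric("modelPredict"))

#' Loss and parameter gradients for a batch
#' @param model a trainable model object.
#' @param batch a batch with `labels`.
#' @param pos_weight optional positive-class loss weight.
#' @export
setGeneric("modelLossGrads", function(model, batch, pos_weight = 1)
  standardGeneric("modelLossGrads"))

#' Get model parameters
#' @param model a trainable model object.
#' @export
setGeneric("modelParams", function(model) standardGeneric("modelParams"))

#' Replace model parameters
#' @param model a trainable model object.
#' @param params a parameter list of the model's own structure.
#' @export
setGeneric("modelSetParams", function(model, params)
  standardGeneric("modelSetParams"))

setMethod("modelPredict", "BirnnModel", function(model, batch)
  birnnForward(model, batch)$prob)
setMethod("modelLossGrads", "BirnnModel",
          function(model, batch, pos_weight = 1)
            .birnnLossGrads(model, batch, pos_weight = pos_weight))
setMethod("modelParams", "BirnnModel", function(model) model@params)
setMethod("modelSetParams", "BirnnModel", function(model, params) {
  model@params <- params
  model
})

#' Slice a batch out of an EncodedSampleSet
#' @param samples an [EncodedSampleSet-class].
#' @param rows row indices.
#' @return a batch list (`indices`, `mask`, `extra`, `labels`).
#' @export
batchFromSamples <- function(samples, rows = seq_len(length(samples))) {
  list(indices = samples@indices[rows, , drop = FALSE],
       mask = samples@mask[rows, , drop = FALSE],
       extra = samples@extra[rows, , drop = FALSE],
       labels = samples@labels[rows])
}

# ---------------------------------------------------------------------
# Text scorer: contract + a small trainable reference implementation.

#' Trainable chunk scorer (neural bag of words)
#'
#' Reference implementation of the text-scorer contract: maps each note
#' chunk to a readmission probability via a mean-pooled token embedding
#' and a logistic head, and is fine-tunable on labeled chunks. Any
#' scorer honouring [scoreChunks()] — e.g. a pretrained clinical
#' language model — can be dropped in its place.
#'
#' @slot params list with `E` (vocab x dim), `w` (dim x 1), `b`.
#' @slot vocab_size,dim sizes.
#' @export
setClass("BagTextScorer", representation(
  params = "list", vocab_size = "integer", dim = "integer"))

#' Create a BagTextScorer
#' @param vocab_size tokenizer vocabulary size.
#' @param dim embedding width.
#' @param seed integer seed.
#' @return a [BagTextScorer-class].
#' @export
bagTextScorer <- function(vocab_size, dim = 16L, seed = 1L) {
  set.seed(seed)
  new("BagTextScorer",
      params = list(E = .initMat(vocab_size, dim, 0.1),
                    w = .initMat(dim, 1L), b = matrix(0, 1, 1)),
      vocab_size = as.integer(vocab_size), dim = as.integer(dim))
}

#' Score note chunks
#'
#' @param scorer a text scorer.
#' @param chunks list of integer token-id vectors (one per chunk).
#' @return numeric vector of per-chunk probabilities in `[0, 1]`.
#' @export
setGeneric("scoreChunks", function(scorer, chunks)
  standardGeneric("scoreChunks"))

.bagPool <- function(params, ids) {
  if (!length(ids)) return(rep(0, nrow(params$w)))
  colMeans(params$E[ids, , drop = FALSE])
}

setMethod("scoreChunks", "BagTextScorer", function(scorer, chunks) {
  vapply(chunks, function(ids) {
    pooled <- .bagPool(scorer@params, ids)
    .sigmoid(sum(pooled * scorer@params$w) + scorer@params$b[1, 1])
  }, numeric(1))
})

#' Aggregated note score
#'
#' Scores every chunk of a note and combines them with
#' [aggregateChunkScores()].
#'
#' @param scorer a text scorer.
#' @param chunks list of integer token-id vectors.
#' @return a single probability.
#' @export
scoreNote <- function(scorer, chunks) {
  aggregateChunkScores(scoreChunks(scorer, chunks))
}

#' Fine-tune a text scorer on labeled chunks
#'
#' Each chunk inherits its note's label; the scorer is fitted by
#' full-batch gradient descent on binary cross-entropy.
#'
#' @param scorer a [BagTextScorer-class].
#' @param chunks list of integer token-id vectors.
#' @param labels 0/1 label per chunk.
#' @param lr learning rate.
#' @param epochs gradient steps.
#' @return the fine-tuned scorer.
#' @export
fitTextScorer <- function(scorer, chunks, labels, lr = 0.5, epochs = 60L) {
  p <- scorer@params
  n <- length(chunks)
  for (ep in seq_len(epochs)) {
    dE <- matrix(0, nrow(p$E), ncol(p$E))
    dw <- matrix(0, nrow(p$w), 1); db <- 0
    for (i in seq_len(n)) {
      ids <- chunks[[i]]
      pooled <- .bagPool(p, ids)
      prob <- .sigmoid(sum(pooled * p$w) + p$b[1, 1])
      dlogit <- (prob - labels[i]) / n
      dw <- dw + dlogit * matrix(pooled, ncol = 1)
      db <- db + dlogit
      if (length(ids)) {
        dpool <- dlogit * as.numeric(p$w)
        contrib <- matrix(dpool, length(ids), length(dpool),
                          byrow = TRUE) / length(ids)
        agg <- rowsum(contrib, group = ids)
        rows <- as.integer(rownames(agg))
        dE[rows, ] <- dE[rows, , drop = FALSE] + agg
      }
    }
    p$E <- p$E - lr * dE
    p$w <- p$w - lr * dw
    p$b <- p$b - lr * db
  }
  scorer@params <- p
  scorer
}

# ---------------------------------------------------------------------
# Multimodal fusion.

#' Multimodal fusion model
#'
#' Concatenates the pre-classifier vector of each component — a BIRNN's
#' post-attention vector, a text scorer's aggregated probability as a
#' one-element vector, a passthrough modality's raw feature block (e.g.
#' the demographics one-hot) — and applies a single affine map to a
#' score. All trainable components are trained jointly.
#'
#' @slot components named list; each element has `kind`
#'   (`"birnn"`, `"text"`, `"passthrough"`), `width`, and for trainable
#'   kinds the component model.
#' @slot params list: per-component parameter lists plus the fusion
#'   weights `wo`, `bo`.
#' @export
setClass("FusedModel", representation(
  components = "list", params = "list"))

#' Combine component models into a fused multimodal model
#'
#' @param components named list; each element one of a
#'   [BirnnModel-class], a [BagTextScorer-class], or
#'   `list(kind = "passthrough", width = w)` for a raw feature block.
#' @param seed seed for the fusion-layer initialization.
#' @return a [FusedModel-class]. Its batches are named lists holding one
#'   sub-batch per component (a BIRNN batch, a `chunks` list, or a
#'   feature matrix) plus `labels`.
#' @export
combineMultimodal <- function(components, seed = 1L) {
  if (length(components) < 1L) stop("need at least one component")
  comp <- list(); par <- list(components = list())
  for (nm in names(components)) {
    x <- components[[nm]]
    if (is(x, "BirnnModel")) {
      comp[[nm]] <- list(kind = "birnn", width = 2L * x@config$hidden_size,
                         model = x)
      par$components[[nm]] <- x@params
    } else if (is(x, "BagTextScorer")) {
      comp[[nm]] <- list(kind = "text", width = 1L, model = x)
      par$components[[nm]] <- x@params
    } else if (is.list(x) && identical(x$kind, "passthrough")) {
      comp[[nm]] <- list(kind = "passthrough", width = as.integer(x$width))
      par$components[[nm]] <- list()
    } else stop("unsupported component: ", nm)
  }
  set.seed(seed)
  total <- sum(vapply(comp, function(c) c$width, 1L))
  par$wo <- .initMat(total, 1L)
  par$bo <- matrix(0, 1, 1)
  new("FusedModel", components = comp, params = par)
}

#' Total pre-classifier width of a fused model
#' @param model a [FusedModel-class].
#' @export
fusionWidth <- function(model) {
  sum(vapply(model@components, function(c) c$width, 1L))
}

.fusedFeatures <- function(model, batch, params) {
  feats <- list(); caches <- list()
  for (nm in names(model@components)) {
    cmp <- model@components[[nm]]
    sub <- batch[[nm]]
    if (cmp$kind == "birnn") {
      ff <- .birnnFeatures(params$components[[nm]], cmp$model@config, sub)
      feats[[nm]] <- ff$feat
      caches[[nm]] <- ff$cache
    } else if (cmp$kind == "text") {
      sc <- cmp$model
      sc@params <- params$components[[nm]]
      probs <- lapply(sub, function(ch) scoreChunks(sc, ch))
      feats[[nm]] <- matrix(vapply(probs, aggregateChunkScores, numeric(1)),
                            ncol = 1)
      caches[[nm]] <- list(chunk_probs = probs, chunks = sub)
    } else {
      feats[[nm]] <- sub
      caches[[nm]] <- NULL
    }
  }
  list(feat = do.call(cbind, feats), caches = caches,
       widths = vapply(model@components, function(c) c$width, 1L))
}

setMethod("modelPredict", "FusedModel", function(model, batch) {
  ff <- .fusedFeatures(model, batch, model@params)
  .sigmoid(as.numeric(ff$feat %*% model@params$wo) + model@params$bo[1, 1])
})

setMethod("modelLossGrads", "FusedModel",
          function(model, batch, pos_weight = 1) {
  params <- model@params
  ff <- .fusedFeatures(model, batch, params)
  score <- as.numeric(ff$feat %*% params$wo) + params$bo[1, 1]
  p <- .sigmoid(score)
  y <- batch$labels
  eps <- 1e-12
  w <- ifelse(y == 1, pos_weight, 1)
  loss <- -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  B <- length(y)
  dscore <- w * (p - y) / B
  grads <- list(components = list(),
                wo = crossprod(ff$feat, matrix(dscore, ncol = 1)),
                bo = matrix(sum(dscore), 1, 1))
  dfeat <- dscore %*% t(params$wo)
  off <- 0L
  for (nm in names(model@components)) {
    cmp <- model@components[[nm]]
    cols <- off + seq_len(cmp$width)
    dsub <- dfeat[, cols, drop = FALSE]
    if (cmp$kind == "birnn") {
      grads$components[[nm]] <- .birnnFeaturesBackward(
        params$components[[nm]], cmp$model@config, ff$caches[[nm]], dsub)
    } else if (cmp$kind == "text") {
      pc <- params$components[[nm]]
      dE <- matrix(0, nrow(pc$E), ncol(pc$E))
      dw <- matrix(0, nrow(pc$w), 1); db <- 0
      cache <- ff$caches[[nm]]
      for (i in seq_along(cache$chunks)) {
        probs <- cache$chunk_probs[[i]]
        n <- length(probs)
        # d(aggregate)/d(chunk prob): mean share + max share to argmax
        dp <- rep((1 / n) * (n / 2) / (1 + n / 2), n)
        dp[which.max(probs)] <- dp[which.max(probs)] + 1 / (1 + n / 2)
        dp <- dp * dsub[i, 1]
        for (j in seq_len(n)) {
          ids <- cache$chunks[[i]][[j]]
          dlogit <- dp[j] * probs[j] * (1 - probs[j])
          pooled <- .bagPool(pc, ids)
          dw <- dw + dlogit * matrix(pooled, ncol = 1)
          db <- db + dlogit
          if (length(ids)) {
            dpool <- dlogit * as.numeric(pc$w)
            contrib <- matrix(dpool, length(ids), length(dpool),
                              byrow = TRUE) / length(ids)
            agg <- rowsum(contrib, group = ids)
            rows <- as.integer(rownames(agg))
            dE[rows, ] <- dE[rows, , drop = FALSE] + agg
          }
        }
      }
      grads$components[[nm]] <- list(E = dE, w = dw, b = matrix(db, 1, 1))
    } else {
      grads$components[[nm]] <- list()
    }
    off <- off + cmp$width
  }
  list(loss = loss, grads = grads, prob = p)
})

setMethod("modelParams", "FusedModel", function(model) model@params)
setMethod("modelSetParams", "FusedModel", function(model, params) {
  model@params <- params
  model
})

# ---------------------------------------------------------------------
# Tabular baseline.

#' Random-forest baseline on tabular features
#'
#' Ensemble-of-trees probability scorer for the flattened ICD-9 one-hot
#' + demographics one-hot representation.
#'
#' @param features numeric feature matrix.
#' @param labels 0/1 labels (both classes required).
#' @param seed integer seed.
#' @param ntree number of trees.
#' @return list with `model` and `predictProb(newdata)`.
#' @export
fitTabularBaseline <- function(features, labels, seed = 1L, ntree = 300L) {
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(features), y = factor(labels, levels = c(0, 1)),
    ntree = ntree)
  list(model = fit,
       predictProb = function(newdata)
         unname(predict(fit, as.data.frame(newdata), type = "prob")[, "1"]))
}
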