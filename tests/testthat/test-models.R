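makeBatch <- function(B, L, D, seed = 1, extra_dims = 0) {
  set.seed(seed)
  list(indices = matrix(sample.int(D, B * L, replace = TRUE), B, L),
       mask = matrix(1, B, L),
       extra = matrix(rnorm(B * extra_dims), B, extra_dims),
       labels = rep(c(0, 1), length.out = B))
}

test_that("embedding width is the floor of the fourth root of D", {
  expect_equal(embeddingDim(16), 2L)
  expect_equal(embeddingDim(81), 3L)
  expect_equal(embeddingDim(80), 2L)
  expect_equal(embeddingDim(1), 1L)
  cfg <- birnnConfig(10, 81)
  expect_equal(cfg$embedding_dim, 3L)
})

test_that("attention weights are a distribution over valid positions", {
  model <- birnnInit(birnnConfig(L = 6, D = 15, hidden_size = 4), seed = 2)
  batch <- makeBatch(5, 6, 15, seed = 3)
  batch$mask[2, 4:6] <- 0
  batch$indices[2, 4:6] <- 1L
  out <- birnnForward(model, batch)
  expect_equal(rowSums(out$attention), rep(1, 5))
  expect_equal(sum(out$attention[2, 4:6]), 0)
  expect_true(all(is.finite(out$score)))
})

test_that("masked positions cannot influence the score", {
  model <- birnnInit(birnnConfig(L = 8, D = 12, hidden_size = 3), seed = 4)
  batch <- makeBatch(3, 8, 12, seed = 5)
  batch$mask[1, 6:8] <- 0
  batch$indices[1, 6:8] <- 1L
  s0 <- birnnForward(model, batch)$score
  tampered <- batch
  tampered$indices[1, 6:8] <- c(5L, 9L, 2L)  # junk under the mask
  s1 <- birnnForward(model, tampered)$score
  expect_equal(s0, s1, tolerance = 1e-12)
})

test_that("an all-pad sample still yields a finite defined score", {
  model <- birnnInit(birnnConfig(L = 4, D = 8, hidden_size = 2,
                                 extra_dims = 2), seed = 1)
  batch <- list(indices = matrix(1L, 1, 4), mask = matrix(0, 1, 4),
                extra = matrix(c(0.3, -0.2), 1, 2), labels = 1)
  out <- birnnForward(model, batch)
  expect_true(is.finite(out$score))
  expect_equal(rowSums(out$attention), 1)
})

test_that("the forward pass matches a step-by-step manual computation", {
  # L = 2, hidden = 1, embedding = 1: small enough to compute by hand.
  cfg <- birnnConfig(L = 2, D = 3, hidden_size = 1)
  model <- birnnInit(cfg, seed = 1)
  p <- model@params
  p$E <- matrix(c(0, 0.5, -1), 3, 1)
  p$Wx_f <- matrix(c(0.1, 0.2, 0.3), 1, 3)   # [r z n]
  p$Wh_f <- matrix(c(0.4, -0.1, 0.2), 1, 3)
  p$bx_f <- matrix(c(0.05, 0, -0.05), 1, 3)
  p$bh_f <- matrix(0, 1, 3)
  p$Wx_b <- p$Wx_f; p$Wh_b <- p$Wh_f; p$bx_b <- p$bx_f; p$bh_b <- p$bh_f
  p$wa <- matrix(c(1, -1), 2, 1); p$ba <- matrix(0.2, 1, 1)
  p$wo <- matrix(c(0.7, 0.3), 2, 1); p$bo <- matrix(-0.1, 1, 1)

  sig <- function(x) 1 / (1 + exp(-x))
  gru_cell <- function(x, h, Wx, Wh, bx, bh) {
    r <- sig(x * Wx[1] + bx[1] + h * Wh[1] + bh[1])
    z <- sig(x * Wx[2] + bx[2] + h * Wh[2] + bh[2])
    nn <- tanh(x * Wx[3] + bx[3] + r * (h * Wh[3] + bh[3]))
    (1 - z) * nn + z * h
  }
  x1 <- 0.5; x2 <- -1  # tokens 2 and 3
  hf1 <- gru_cell(x1, 0, p$Wx_f, p$Wh_f, p$bx_f, p$bh_f)
  hf2 <- gru_cell(x2, hf1, p$Wx_f, p$Wh_f, p$bx_f, p$bh_f)
  hb2 <- gru_cell(x2, 0, p$Wx_b, p$Wh_b, p$bx_b, p$bh_b)
  hb1 <- gru_cell(x1, hb2, p$Wx_b, p$Wh_b, p$bx_b, p$bh_b)
  a1 <- c(hf1, hb1); a2 <- c(hf2, hb2)
  u1 <- sum(a1 * c(1, -1)) + 0.2
  u2 <- sum(a2 * c(1, -1)) + 0.2
  al <- exp(c(u1, u2)) / sum(exp(c(u1, u2)))
  ctx <- al[1] * a1 + al[2] * a2
  manual_score <- sum(ctx * c(0.7, 0.3)) - 0.1

  batch <- list(indices = matrix(c(2L, 3L), 1, 2), mask = matrix(1, 1, 2))
  out <- birnnForward(model, batch, params = p)
  expect_equal(out$score, manual_score, tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- birnnConfig(L = 5, D = 11, hidden_size = 3, extra_dims = 2)
  model <- birnnInit(cfg, seed = 7)
  batch <- makeBatch(4, 5, 11, seed = 8, extra_dims = 2)
  batch$mask[1, 4:5] <- 0; batch$indices[1, 4:5] <- 1L
  lg <- modelLossGrads(model, batch)
  p <- model@params
  eps <- 1e-6
  set.seed(9)
  for (nm in names(p)) {
    k <- sample.int(length(p[[nm]]), 1)
    idx <- arrayInd(k, dim(p[[nm]]))
    pp <- p
    pp[[nm]][idx[1], idx[2]] <- pp[[nm]][idx[1], idx[2]] + eps
    l1 <- modelLossGrads(modelSetParams(model, pp), batch)$loss
    pp[[nm]][idx[1], idx[2]] <- pp[[nm]][idx[1], idx[2]] - 2 * eps
    l2 <- modelLossGrads(modelSetParams(model, pp), batch)$loss
    g_num <- (l1 - l2) / (2 * eps)
    g_an <- lg$grads[[nm]][idx[1], idx[2]]
    expect_equal(g_an, g_num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("reversing input and swapping GRUs mirrors the representation", {
  cfg <- birnnConfig(L = 6, D = 9, hidden_size = 3)
  model <- birnnInit(cfg, seed = 11)
  batch <- makeBatch(2, 6, 9, seed = 12)
  ff <- ReadmitTA:::.birnnFeatures(model@params, cfg, batch)
  H1 <- lapply(ff$cache$Hcat, identity)

  swapped <- model@params
  for (f in c("Wx", "Wh", "bx", "bh")) {
    tmp <- swapped[[paste0(f, "_f")]]
    swapped[[paste0(f, "_f")]] <- swapped[[paste0(f, "_b")]]
    swapped[[paste0(f, "_b")]] <- tmp
  }
  rev_batch <- batch
  rev_batch$indices <- batch$indices[, 6:1, drop = FALSE]
  rev_batch$mask <- batch$mask[, 6:1, drop = FALSE]
  ff2 <- ReadmitTA:::.birnnFeatures(swapped, cfg, rev_batch)
  H2 <- ff2$cache$Hcat
  h <- cfg$hidden_size
  for (t in 1:6) {
    mirrored <- cbind(H2[[7 - t]][, (h + 1):(2 * h), drop = FALSE],
                      H2[[7 - t]][, 1:h, drop = FALSE])
    expect_equal(H1[[t]], mirrored, tolerance = 1e-12)
  }
})

test_that("inference is deterministic given fixed parameters", {
  model <- birnnInit(birnnConfig(L = 5, D = 10, hidden_size = 3), seed = 1)
  batch <- makeBatch(4, 5, 10, seed = 2)
  expect_identical(modelPredict(model, batch), modelPredict(model, batch))
})

test_that("fusion width adds component widths and demographics", {
  chart <- birnnInit(birnnConfig(L = 5, D = 10, hidden_size = 7), seed = 1)
  icd <- birnnInit(birnnConfig(L = 4, D = 20, hidden_size = 5), seed = 2)
  fused <- combineMultimodal(list(
    charts = chart, icd9 = icd,
    demo = list(kind = "passthrough", width = 14)), seed = 3)
  expect_equal(fusionWidth(fused), 2 * 7 + 2 * 5 + 14)
  expect_equal(nrow(fused@params$wo), 2 * 7 + 2 * 5 + 14)
})

test_that("a single-component fusion reduces to that model's features", {
  chart <- birnnInit(birnnConfig(L = 5, D = 10, hidden_size = 4), seed = 4)
  fused <- combineMultimodal(list(charts = chart), seed = 5)
  batch <- makeBatch(3, 5, 10, seed = 6)
  fbatch <- list(charts = batch, labels = batch$labels)
  probs <- modelPredict(fused, fbatch)
  feat <- birnnForward(chart, batch)$feat
  manual <- 1 / (1 + exp(-(as.numeric(feat %*% fused@params$wo) +
                             fused@params$bo[1, 1])))
  expect_equal(probs, manual, tolerance = 1e-12)
})

test_that("zeroing a component changes the score only via its weights", {
  chart <- birnnInit(birnnConfig(L = 4, D = 8, hidden_size = 3), seed = 7)
  fused <- combineMultimodal(list(
    charts = chart, demo = list(kind = "passthrough", width = 3)), seed = 8)
  batch <- makeBatch(2, 4, 8, seed = 9)
  demo <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  fb <- list(charts = batch, demo = demo, labels = batch$labels)
  fb0 <- list(charts = batch, demo = demo * 0, labels = batch$labels)
  logit <- function(p) log(p / (1 - p))
  delta <- logit(modelPredict(fused, fb)) - logit(modelPredict(fused, fb0))
  w_demo <- fused@params$wo[(2 * 3 + 1):(2 * 3 + 3), 1]
  expect_equal(delta, as.numeric(demo %*% w_demo), tolerance = 1e-9)
})

test_that("the chunk scorer stays in [0,1] and improves with fine-tuning", {
  sc <- bagTextScorer(vocab_size = 30, dim = 4, seed = 1)
  set.seed(2)
  pos_chunks <- lapply(1:25, function(i) sample(1:10, 8, replace = TRUE))
  neg_chunks <- lapply(1:25, function(i) sample(21:30, 8, replace = TRUE))
  chunks <- c(pos_chunks, neg_chunks)
  labels <- c(rep(1, 25), rep(0, 25))
  p0 <- scoreChunks(sc, chunks)
  expect_true(all(p0 >= 0 & p0 <= 1))
  fitted <- fitTextScorer(sc, chunks, labels)
  p1 <- scoreChunks(fitted, chunks)
  auc0 <- computeMetrics(p0, labels, 0.5)$auroc
  auc1 <- computeMetrics(p1, labels, 0.5)$auroc
  expect_gt(auc1, max(auc0, 0.95))
  expect_equal(scoreNote(fitted, chunks[1:3]),
               aggregateChunkScores(scoreChunks(fitted, chunks[1:3])))
})

test_that("the random-forest baseline behaves as a seeded prob scorer", {
  set.seed(5)
  x <- rbind(matrix(rnorm(80, 2), 40), matrix(rnorm(80, -2), 40))
  y <- c(rep(1, 40), rep(0, 40))
  fit <- fitTabularBaseline(x, y, seed = 1)
  expect_equal(computeMetrics(fit$predictProb(x), y, 0.5)$auroc, 1)

  y_shuf <- sample(y)
  idx <- 1:60
  fit2 <- fitTabularBaseline(x[idx, ], y_shuf[idx], seed = 2)
  auc <- computeMetrics(fit2$predictProb(x[-idx, ]), y_shuf[-idx],
                        0.5)$auroc
  expect_gt(auc, 0.2); expect_lt(auc, 0.8)

  fit3 <- fitTabularBaseline(x, y, seed = 1)
  expect_identical(fit$predictProb(x), fit3$predictProb(x))
  expect_error(fitTabularBaseline(x, rep(1, 80)), "both classes")
})
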