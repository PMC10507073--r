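#' Training-protocol configuration
#'
#' Defaults follow the study protocol: batches of 64, a validation
#' evaluation every 200 optimizer steps, a stop loss of 7 (training
#' halts once the count of consecutive non-improving evaluations
#' exceeds 7), and per-model-family learning rates — `2e-5` with decay
#' 0.9 for text models, `1e-3` with decay 0.97 for everything else. The
#' learning rate is multiplied by `lr_decay` at every non-improving
#' evaluation and never reset; the non-improvement counter resets on
#' improvement. `max_steps` is a safety cap (default
#' `20 * ceil(n_train / batch_size)`, set when training starts).
#'
#' @param batch_size minibatch size.
#' @param eval_every_steps steps between validation evaluations.
#' @param stop_loss early-stopping patience.
#' @param lr_initial initial learning rate.
#' @param lr_decay multiplicative decay per non-improving evaluation.
#' @param max_steps optional hard cap on optimizer steps.
#' @param pos_weight positive-class loss weight (1 = unweighted).
#' @param seed integer seed for batch shuffling.
#' @param text use the text-model learning-rate preset.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(batch_size = 64L, eval_every_steps = 200L,
                        stop_loss = 7L, lr_initial = NULL, lr_decay = NULL,
                        max_steps = NULL, pos_weight = 1, seed = 1L,
                        text = FALSE) {
  if (is.null(lr_initial)) lr_initial <- if (text) 2e-5 else 1e-3
  if (is.null(lr_decay)) lr_decay <- if (text) 0.9 else 0.97
  stopifnot(batch_size > 0, eval_every_steps > 0, stop_loss > 0,
            lr_initial > 0, lr_decay > 0, lr_decay < 1)
  structure(list(batch_size = as.integer(batch_size),
                 eval_every_steps = as.integer(eval_every_steps),
                 stop_loss = as.integer(stop_loss),
                 lr_initial = lr_initial, lr_decay = lr_decay,
                 max_steps = max_steps, pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# Adam optimizer over (possibly nested) lists of parameter matrices.
.adamInit <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else p * 0
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        res <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- upd(params, grads, state$m, state$v)
  state$m <- res$m; state$v <- res$v
  list(params = res$p, state = state)
}

#' Core training loop: checkpointing, decay, stop loss
#'
#' Protocol driver shared by all models. Every `eval_every_steps` steps
#' the validation AUPRC is computed; if it exceeds the best seen so far
#' the current parameters are checkpointed and the non-improvement
#' counter resets, otherwise the learning rate is multiplied by
#' `lr_decay` and the counter increments. Training stops once the
#' counter exceeds `stop_loss` (or `max_steps` is reached) and the last
#' saved checkpoint is returned. After `m` consecutive non-improving
#' evaluations the learning rate equals `lr_initial * lr_decay^m`; it is
#' never reset.
#'
#' Exposed separately from [trainModel()] so the protocol can be driven
#' with scripted evaluation sequences.
#'
#' @param stepFun `function(lr)` performing one optimizer step.
#' @param evalFun `function()` returning the validation AUPRC.
#' @param snapshotFun `function()` returning the current parameters.
#' @param config a [trainConfig()].
#' @return list with `best` (last checkpointed snapshot, `NULL` if no
#'   evaluation ever ran), `best_auprc`, `history` (one row per
#'   evaluation: `step`, `val_auprc`, `learning_rate`, `improved`,
#'   `checkpoint_saved`) and `steps_run`.
#' @export
trainLoop <- function(stepFun, evalFun, snapshotFun, config) {
  lr <- config$lr_initial
  best <- NULL; best_auprc <- -Inf
  counter <- 0L; step <- 0L
  hist <- list()
  max_steps <- if (is.null(config$max_steps)) Inf else config$max_steps
  while (step < max_steps) {
    stepFun(lr)
    step <- step + 1L
    if (step %% config$eval_every_steps == 0L) {
      auprc <- evalFun()
      improved <- is.finite(auprc) && auprc > best_auprc
      if (improved) {
        best_auprc <- auprc
        best <- snapshotFun()
        counter <- 0L
      } else {
        lr <- lr * config$lr_decay
        counter <- counter + 1L
      }
      hist[[length(hist) + 1L]] <- data.table::data.table(
        step = step, val_auprc = auprc, learning_rate = lr,
        improved = improved, checkpoint_saved = improved)
      if (counter > config$stop_loss) break
    }
  }
  list(best = best, best_auprc = best_auprc,
       history = if (length(hist)) data.table::rbindlist(hist) else
         data.table::data.table(step = integer(), val_auprc = numeric(),
                                learning_rate = numeric(),
                                improved = logical(),
                                checkpoint_saved = logical()),
       steps_run = step)
}

#' Dataset wrapper around an EncodedSampleSet
#' @param samples an [EncodedSampleSet-class].
#' @return list with `n`, `labels`, `batch(rows)`.
#' @export
sampleDataset <- function(samples) {
  list(n = length(samples), labels = samples@labels,
       batch = function(rows) batchFromSamples(samples, rows))
}

#' Dataset wrapper for a fused multimodal model
#'
#' @param parts named list matching the fused model's components: an
#'   [EncodedSampleSet-class] for a BIRNN component, a numeric matrix
#'   for a passthrough component, or a list of per-sample chunk lists
#'   for a text component. All parts must be row-aligned.
#' @param labels 0/1 labels.
#' @return list with `n`, `labels`, `batch(rows)`.
#' @export
fusedDataset <- function(parts, labels) {
  n <- length(labels)
  list(n = n, labels = labels, batch = function(rows) {
    out <- lapply(parts, function(p) {
      if (is(p, "EncodedSampleSet")) batchFromSamples(p, rows)
      else if (is.matrix(p)) p[rows, , drop = FALSE]
      else p[rows]
    })
    out$labels <- labels[rows]
    out
  })
}

.predictDataset <- function(model, dataset, chunk = 256L) {
  rows <- seq_len(dataset$n)
  parts <- split(rows, ceiling(rows / chunk))
  unlist(lapply(parts, function(rr) modelPredict(model, dataset$batch(rr))))
}

#' Train a model with the study protocol
#'
#' Minimizes binary cross-entropy with Adam over shuffled minibatches,
#' evaluating validation AUPRC on the protocol schedule (see
#' [trainLoop()]), and returns the last checkpointed model. If no
#' evaluation ever ran (e.g. `max_steps` below the evaluation period),
#' the initial model is returned with a warning.
#'
#' @param model a model implementing the [modelLossGrads()] interface.
#' @param train,val datasets from [sampleDataset()] / [fusedDataset()];
#'   the validation labels must contain both classes.
#' @param config a [trainConfig()].
#' @return list with `model` (best checkpoint), `history`,
#'   `best_auprc`, `steps_run`.
#' @export
trainModel <- function(model, train, val, config = trainConfig()) {
  force(model)  # evaluate before seeding so inline model construction
                # (which may seed the RNG itself) cannot perturb shuffling
  if (train$n == 0L) stop("empty training data")
  if (length(unique(val$labels)) < 2L)
    stop("validation data must contain both classes")
  if (is.null(config$max_steps))
    config$max_steps <- 20L * ceiling(train$n / config$batch_size)
  set.seed(config$seed)
  params <- modelParams(model)
  opt <- .adamInit(params)
  order_pool <- integer(0)

  nextRows <- function() {
    if (length(order_pool) < config$batch_size)
      order_pool <<- c(order_pool, sample.int(train$n))
    rows <- order_pool[seq_len(config$batch_size)]
    order_pool <<- order_pool[-seq_len(config$batch_size)]
    rows
  }
  stepFun <- function(lr) {
    batch <- train$batch(nextRows())
    lg <- modelLossGrads(modelSetParams(model, params), batch,
                         pos_weight = config$pos_weight)
    if (!is.finite(lg$loss))
      stop("non-finite training loss (lr=", format(lr),
           "); aborting with diagnostics: mean prob=",
           format(mean(lg$prob)))
    res <- .adamStep(params, lg$grads, opt, lr)
    params <<- res$params
    opt <<- res$state
  }
  evalFun <- function() {
    probs <- .predictDataset(modelSetParams(model, params), val)
    computeMetrics(probs, val$labels, threshold = 0.5)$auprc
  }
  snapshotFun <- function() params

  res <- trainLoop(stepFun, evalFun, snapshotFun, config)
  if (is.null(res$best)) {
    warning("no evaluation ever ran; returning the initial model")
    best_model <- model
  } else {
    best_model <- modelSetParams(model, res$best)
  }
  list(model = best_model, history = res$history,
       best_auprc = res$best_auprc, steps_run = res$steps_run)
}

.parseModality <- function(modality) {
  toks <- strsplit(modality, "+", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  bad <- setdiff(toks, c("A", "B1", "D"))
  if (length(bad))
    stop("unsupported modality token(s): ", paste(bad, collapse = ", "),
         " (supported here: A = abstracted charts, B1 = ICD-9 one-hot, ",
         "D = demographics; the text pathways run through the text-scorer ",
         "functions)")
  toks
}

#' Run a per-fold experiment for one modality combination
#'
#' For each requested fold: encodings are built using that fold's
#' training data only (the charts vocabulary comes from the knowledge
#' base and is fold-independent; the ICD-9 vocabulary is built from
#' training admissions), the model is trained with the study protocol,
#' the decision threshold is selected on the validation predictions,
#' and the five metrics are computed on the fold's test stays.
#'
#' @param tables an [EHRTables-class].
#' @param cohort cohort table from [buildCohort()].
#' @param folds a [FoldSplit-class].
#' @param modality combination string over tokens `A` (abstracted
#'   charts), `B1` (ICD-9 one-hot) and `D` (demographics), e.g.
#'   `"A+D"`, `"A+B1+D"`.
#' @param kb a [KnowledgeBase-class].
#' @param config a [trainConfig()].
#' @param gradients gradient abstraction for the charts pathway
#'   (`"none"`, `"simple"`, `"thresholded"`).
#' @param L charts sequence length.
#' @param hidden_size GRU width.
#' @param which_folds fold indices to run (default: all).
#' @param seed base seed for model initialization.
#' @return list with `reports` (per-fold metric table), `summary`
#'   (when >1 fold), `predictions` (per fold: `icustay_id`, `label`,
#'   `score`), `histories`.
#' @export
runExperiment <- function(tables, cohort, folds, modality = "A+D",
                          kb = loadKnowledgeBase(), config = trainConfig(),
                          gradients = "simple", L = 128L, hidden_size = 16L,
                          which_folds = NULL, seed = 1L) {
  toks <- .parseModality(modality)
  if (is.null(which_folds)) which_folds <- seq_len(folds@k)
  cohort <- data.table::as.data.table(cohort)
  reports <- list(); preds <- list(); hists <- list()

  for (f in which_folds) {
    fold <- folds@folds[[f]]
    rows <- list(train = which(cohort$subject_id %in% fold$train),
                 val = which(cohort$subject_id %in% fold$val),
                 test = which(cohort$subject_id %in% fold$test))
    demo <- if ("D" %in% toks) demographicsMatrix(cohort) else NULL

    build <- function(rr) {
      parts <- list()
      if ("A" %in% toks)
        parts$charts <- encodeChartsSamples(
          tables, cohort[rr, ], kb, L = L, gradients = gradients)
      if ("B1" %in% toks) {
        train_codes <- tables@diagnoses_icd$icd9_code[
          tables@diagnoses_icd$hadm_id %in% cohort$hadm_id[rows$train]]
        vocab <- buildIcd9Vocab(train_codes)
        parts$icd9 <- encodeIcd9Samples(tables, cohort[rr, ], vocab,
                                        L_codes = 30L)
      }
      if ("D" %in% toks) parts$demo <- demo[rr, , drop = FALSE]
      parts
    }

    seq_toks <- intersect(toks, c("A", "B1"))
    makeModelData <- function(parts, labels) {
      if (length(seq_toks) == 1L && length(toks) <= 2L) {
        # single sequence model, demographics as the extra vector
        smp <- parts[[if (seq_toks == "A") "charts" else "icd9"]]
        extra_w <- if ("D" %in% toks) ncol(parts$demo) else 0L
        if ("D" %in% toks) smp@extra <- parts$demo
        cfg <- birnnConfig(smp@L, length(smp@vocab),
                           hidden_size = hidden_size,
                           extra_dims = extra_w)
        list(model = birnnInit(cfg, seed = seed + f),
             data = sampleDataset(smp))
      } else {
        comps <- list()
        fparts <- list()
        if ("A" %in% toks) {
          cfgA <- birnnConfig(parts$charts@L, length(parts$charts@vocab),
                              hidden_size = hidden_size)
          comps$charts <- birnnInit(cfgA, seed = seed + f)
          fparts$charts <- parts$charts
        }
        if ("B1" %in% toks) {
          cfgB <- birnnConfig(parts$icd9@L, length(parts$icd9@vocab),
                              hidden_size = hidden_size)
          comps$icd9 <- birnnInit(cfgB, seed = seed + f + 100L)
          fparts$icd9 <- parts$icd9
        }
        if ("D" %in% toks) {
          comps$demo <- list(kind = "passthrough", width = ncol(parts$demo))
          fparts$demo <- parts$demo
        }
        list(model = combineMultimodal(comps, seed = seed + f),
             data = fusedDataset(fparts, labels))
      }
    }

    parts_train <- build(rows$train)
    parts_val <- build(rows$val)
    parts_test <- build(rows$test)
    md_train <- makeModelData(parts_train, cohort$label[rows$train])
    md_val <- makeModelData(parts_val, cohort$label[rows$val])
    md_test <- makeModelData(parts_test, cohort$label[rows$test])

    fit <- trainModel(md_train$model, md_train$data, md_val$data, config)
    val_probs <- .predictDataset(fit$model, md_val$data)
    th <- findOptimalThreshold(val_probs, cohort$label[rows$val])
    test_probs <- .predictDataset(fit$model, md_test$data)
    reports[[length(reports) + 1L]] <-
      computeMetrics(test_probs, cohort$label[rows$test],
                     threshold = th, fold = f)
    preds[[as.character(f)]] <- data.table::data.table(
      icustay_id = cohort$icustay_id[rows$test],
      label = cohort$label[rows$test], score = test_probs)
    hists[[as.character(f)]] <- fit$history
  }
  reports <- data.table::rbindlist(reports)
  list(reports = reports,
       summary = if (nrow(reports) > 1L) aggregateFolds(reports) else NULL,
       predictions = preds, histories = hists)
}
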