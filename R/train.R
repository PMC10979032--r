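# Training (Adam on the autodiff engine), prediction, and evaluation.

#' Precompute featurization caches for a dataset
#'
#' Parses and featurizes every drug and protein once; training and
#' evaluation reuse the caches (featurization is deterministic and
#' seed-independent).
#'
#' @param ds A `dta_dataset`.
#' @param config A [dta_config()].
#' @param provider Embedding provider.
#' @return List with `drugs` and `proteins` cache lists.
#' @export
dta_precompute <- function(ds, config = dta_config(),
                           provider = synthetic_embedding_provider()) {
  drugs <- lapply(names(ds$drugs), function(id)
    dta_drug_cache(ds$drugs[[id]], id, config))
  names(drugs) <- names(ds$drugs)
  prots <- lapply(ds$proteins, dta_protein_cache, provider = provider,
                  config = config)
  list(drugs = drugs, proteins = prots, provider_width = provider$width)
}

# Adam optimizer state over a named parameter list
.dta_adam_new <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.dta_adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# forward + squared-error loss for a batch of pair indices; returns grads
# and the batch sum of squared errors
.dta_batch_grads <- function(params, caches, pairs, idx, config,
                             training = TRUE) {
  tp <- ad_tape()
  P <- .dta_pnodes(tp, params)
  loss <- NULL
  for (k in idx) {
    dc <- caches$drugs[[pairs$drug_id[k]]]
    pc <- caches$proteins[[pairs$protein_id[k]]]
    pred <- .fwd_pair(tp, P, dc, pc, config, training = training)
    term <- ad_sqerr(tp, pred, pairs$affinity[k])
    loss <- if (is.null(loss)) term else ad_add(tp, loss, term)
  }
  sse <- as.numeric(ad_value(loss))
  scaled <- ad_scale(tp, loss, 1 / length(idx))
  ad_backward(tp, scaled)
  list(grads = lapply(P, function(nd) nd$g), sse = sse)
}

#' Train the affinity model
#'
#' Minimizes mean squared error between predicted and observed affinity
#' with Adam.  Fully seeded: initialization, batch order, and dropout draw
#' from one RNG stream, so identical inputs and seed reproduce the loss
#' sequence exactly.  When a split plan is given, training uses the
#' non-test, non-validation parts of the chosen fold and the
#' best-validation-MSE parameters are kept; without a plan the model trains
#' (and is returned) on all pairs — the overfit-capacity setting.
#'
#' @param ds A `dta_dataset`.
#' @param plan Optional [make_splits()] plan.
#' @param hp A [dta_config()].
#' @param seed Training seed.
#' @param fold Cross-validation fold (1..5) selecting the validation part.
#' @param caches Optional precomputed [dta_precompute()] caches.
#' @param provider Embedding provider (used if `caches` is missing).
#' @param val_every Validate every this many epochs.
#' @param verbose Print per-epoch progress.
#' @return Object of class `dta_trained`: list with `model`, `log` (data
#'   frame `epoch`, `train_mse`, `val_mse`), `seed`, `caches`.
#' @export
train_model <- function(ds, plan = NULL, hp = dta_config(), seed = 1L,
                        fold = 1L, caches = NULL,
                        provider = synthetic_embedding_provider(),
                        val_every = 5L, verbose = FALSE) {
  if (is.null(caches)) caches <- dta_precompute(ds, hp, provider)
  pairs <- ds$pairs
  if (is.null(plan)) {
    train_idx <- seq_len(nrow(pairs))
    val_idx <- integer(0)
  } else {
    val_idx <- plan$cv_folds[[fold]]
    train_idx <- setdiff(which(plan$part != plan$test_part), val_idx)
  }
  model <- dta_init_model(hp, embed_width = caches$provider_width,
                          seed = seed)
  model$params$head_fc2_b[] <- mean(pairs$affinity[train_idx])
  state <- .dta_adam_new(model$params)
  log <- data.frame(epoch = integer(0), train_mse = numeric(0),
                    val_mse = numeric(0))
  best_val <- Inf
  best_params <- model$params
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / hp$train_batch))
    sse <- 0
    for (b in batches) {
      res <- .dta_batch_grads(model$params, caches, pairs, b, hp)
      if (!is.finite(res$sse))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      sse <- sse + res$sse
      upd <- .dta_adam_step(model$params, res$grads, state, hp$lr)
      model$params <- upd$params
      state <- upd$state
    }
    train_mse <- sse / length(train_idx)
    val_mse <- NA_real_
    if (length(val_idx) && (epoch %% val_every == 0L ||
                            epoch == hp$epochs)) {
      vp <- dta_predict(model, ds, val_idx, caches)
      val_mse <- mean((pairs$affinity[val_idx] - vp)^2)
      if (val_mse < best_val) {
        best_val <- val_mse
        best_params <- model$params
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse))
    if (verbose)
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %s", epoch,
                      train_mse,
                      if (is.na(val_mse)) "-" else sprintf("%.4f", val_mse)))
  }
  if (length(val_idx)) model$params <- best_params
  structure(list(model = model, log = log, seed = as.integer(seed),
                 caches = caches, plan = plan, fold = fold),
            class = "dta_trained")
}

#' Predict affinities for dataset pairs
#'
#' @param model A `dta_model` (or `dta_trained`).
#' @param ds The `dta_dataset` the pairs refer to.
#' @param idx Pair row indices (default: all).
#' @param caches Precomputed caches (required if `model` is a bare
#'   `dta_model` without them).
#' @return Numeric vector of predictions (dropout disabled; deterministic).
#' @export
dta_predict <- function(model, ds, idx = seq_len(nrow(ds$pairs)),
                        caches = NULL) {
  if (inherits(model, "dta_trained")) {
    if (is.null(caches)) caches <- model$caches
    model <- model$model
  }
  if (is.null(caches)) stop("featurization caches required")
  vapply(idx, function(k) {
    tp <- ad_tape()
    P <- .dta_cnodes(tp, model$params)
    dc <- caches$drugs[[ds$pairs$drug_id[k]]]
    pc <- caches$proteins[[ds$pairs$protein_id[k]]]
    as.numeric(ad_value(.fwd_pair(tp, P, dc, pc, model$config)))
  }, numeric(1))
}

#' Evaluate a trained model on the held-out test part
#'
#' Emits predictions for the test part (or explicit indices), computes the
#' six-metric report, and optionally writes a predictions TSV whose
#' recomputed metrics reproduce the report.
#'
#' @param trained A `dta_trained` (or a `dta_model` plus `caches`).
#' @param ds The dataset.
#' @param plan The split plan (defaults to the one stored at training).
#' @param idx Optional explicit pair indices overriding the test part.
#' @param pred_tsv Optional path for the predictions TSV (columns
#'   `drug_id`, `protein_id`, `y_true`, `y_pred`).
#' @param caches Caches when `trained` is a bare model.
#' @return List with `metrics` (a `dta_metric_report`) and `predictions`
#'   (data frame).
#' @export
evaluate_model <- function(trained, ds, plan = NULL, idx = NULL,
                           pred_tsv = NULL, caches = NULL) {
  if (inherits(trained, "dta_trained")) {
    if (is.null(plan)) plan <- trained$plan
    if (is.null(caches)) caches <- trained$caches
  }
  if (is.null(idx)) {
    if (is.null(plan)) stop("either a split plan or explicit indices needed")
    idx <- which(plan$part == plan$test_part)
  }
  yhat <- dta_predict(trained, ds, idx, caches)
  y <- ds$pairs$affinity[idx]
  preds <- data.frame(drug_id = ds$pairs$drug_id[idx],
                      protein_id = ds$pairs$protein_id[idx],
                      y_true = y, y_pred = yhat)
  if (!is.null(pred_tsv)) {
    out <- preds
    # full precision so recomputed metrics reproduce the report exactly
    out$y_true <- sprintf("%.17g", out$y_true)
    out$y_pred <- sprintf("%.17g", out$y_pred)
    utils::write.table(out, pred_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  list(metrics = regression_metrics(y, yhat), predictions = preds)
}

#' Save / load model checkpoints
#'
#' @param model A `dta_model` or `dta_trained`.
#' @param path Checkpoint file path.
#' @return `dta_save_model` returns `path` invisibly; `dta_load_model`
#'   returns the model.
#' @export
dta_save_model <- function(model, path) {
  if (inherits(model, "dta_trained")) model <- model$model
  saveRDS(model, path)
  invisible(path)
}

#' @rdname dta_save_model
#' @export
dta_load_model <- function(path) readRDS(path)
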