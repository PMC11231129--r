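#' Training configuration
#'
#' Defaults follow the reference protocol for this task: mean absolute
#' error loss, Adadelta, batch size 128, at most 400 epochs with early
#' stopping after 50 epochs without improvement of the validation mean
#' squared error, and run-time augmentation of the training pairs.
#'
#' @param max_epochs maximum number of epochs.
#' @param batch_size patches per parameter update.
#' @param patience epochs without validation-MSE improvement before
#'   stopping (must be < `max_epochs`).
#' @param optimizer_name `"adadelta"` (default), `"adam"`, `"sgd"`, or
#'   `"frozen"` (no updates; useful for exercising the stopping logic).
#'   Adadelta is the reference protocol; Adam converges much faster on
#'   small patch budgets and is the practical choice for short runs.
#' @param rho,epsilon Adadelta decay and conditioning constants.
#' @param lr learning rate for `"sgd"` and `"adam"`.
#' @param lr_decay_epoch epoch after which `lr` is multiplied by
#'   `lr_decay_factor` (`NULL` = constant rate); a standard step
#'   schedule that lets Adam settle into the minimum late in training.
#' @param lr_decay_factor multiplier applied from `lr_decay_epoch + 1` on.
#' @param augment apply run-time flips + gamma to training pairs.
#' @param seed integer seed controlling shuffling and augmentation.
#' @param verbose print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 400L, batch_size = 128L, patience = 50L,
                         optimizer_name = c("adadelta", "adam", "sgd", "frozen"),
                         rho = 0.95, epsilon = 1e-6, lr = 1e-3,
                         lr_decay_epoch = NULL, lr_decay_factor = 0.3,
                         augment = TRUE, seed = 1L, verbose = FALSE) {
  optimizer_name <- match.arg(optimizer_name)
  stopifnot(max_epochs >= 1L, batch_size >= 1L, patience >= 1L,
            patience < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 optimizer_name = optimizer_name, rho = rho,
                 epsilon = epsilon, lr = lr,
                 lr_decay_epoch = lr_decay_epoch,
                 lr_decay_factor = lr_decay_factor,
                 augment = isTRUE(augment),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Patient-level k-fold split
#'
#' Patients are shuffled (deterministically given `seed`) and partitioned
#' into `k` near-equal folds. For fold `f`, the test set is fold `f`
#' (`1/k` of patients); the validation set takes a fraction
#' `(1 - 1/k)/k` of all patients from the folds following `f` in rotation
#' order (so with `k = 5`: 20% test, 16% validation, 64% training);
#' everything else trains. Every patient appears in the test set of
#' exactly one fold, and all volumes of a patient stay on the patient's
#' side of every partition, so no patient's gates leak between training
#' and evaluation.
#'
#' @param patient_ids character or integer vector of unique patient ids.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return An object of class `fold_assignment`: list of `k` elements,
#'   each with `train`, `validation`, `test` id vectors.
#' @export
split_patients <- function(patient_ids, k = 5L, seed = 1L) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (n < k) stop("need at least k = ", k, " patients", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  shuffled <- sample(patient_ids)
  # near-equal fold sizes: first (n mod k) folds get the extra patient
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold_ids <- split(shuffled, rep(seq_len(k), times = sizes))
  n_val <- max(1L, as.integer(round(n * (1 - 1 / k) / k)))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    rest <- unlist(fold_ids[c(seq_len(k)[-seq_len(f)], seq_len(f - 1L))],
                   use.names = FALSE)  # folds after f in rotation order
    folds[[f]] <- list(test = fold_ids[[f]],
                       validation = rest[seq_len(n_val)],
                       train = rest[-seq_len(n_val)])
  }
  structure(folds, class = "fold_assignment")
}

mae_loss <- function(out, target) mean(abs(out - target))
mse_loss <- function(out, target) mean((out - target)^2)

adadelta_init <- function(params)
  lapply(params, function(p) list(
    Eg2_W = matrix(0, nrow(p$W), ncol(p$W)), Edx2_W = matrix(0, nrow(p$W), ncol(p$W)),
    Eg2_b = numeric(length(p$b)), Edx2_b = numeric(length(p$b))))

adadelta_step <- function(params, grads, state, rho, eps) {
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$Eg2_W <- rho * s$Eg2_W + (1 - rho) * g$W^2
    dW <- -sqrt(s$Edx2_W + eps) / sqrt(s$Eg2_W + eps) * g$W
    s$Edx2_W <- rho * s$Edx2_W + (1 - rho) * dW^2
    params[[nm]]$W <- params[[nm]]$W + dW
    s$Eg2_b <- rho * s$Eg2_b + (1 - rho) * g$b^2
    db <- -sqrt(s$Edx2_b + eps) / sqrt(s$Eg2_b + eps) * g$b
    s$Edx2_b <- rho * s$Edx2_b + (1 - rho) * db^2
    params[[nm]]$b <- params[[nm]]$b + db
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

adam_init <- function(params)
  lapply(params, function(p) list(
    m_W = matrix(0, nrow(p$W), ncol(p$W)), v_W = matrix(0, nrow(p$W), ncol(p$W)),
    m_b = numeric(length(p$b)), v_b = numeric(length(p$b))))

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$m_W <- beta1 * s$m_W + (1 - beta1) * g$W
    s$v_W <- beta2 * s$v_W + (1 - beta2) * g$W^2
    params[[nm]]$W <- params[[nm]]$W - lr * corr * s$m_W / (sqrt(s$v_W) + eps)
    s$m_b <- beta1 * s$m_b + (1 - beta1) * g$b
    s$v_b <- beta2 * s$v_b + (1 - beta2) * g$b^2
    params[[nm]]$b <- params[[nm]]$b - lr * corr * s$m_b / (sqrt(s$v_b) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

eval_dataset_mse <- function(model, pairs) {
  tot <- 0
  for (p in pairs) {
    out <- unet_forward(model, p$input)$out
    tot <- tot + mse_loss(out, p$target)
  }
  tot / length(pairs)
}

#' Train a residual U-Net on patch pairs
#'
#' Minimises the mean absolute error between network output and target
#' patches, tracking the mean squared error on the validation pairs after
#' every epoch. The first epoch establishes the running best; training
#' stops at `max_epochs` or when the validation MSE has not strictly
#' improved for `patience` consecutive epochs. The returned model carries
#' the parameters from the best-validation epoch, not the last one. Augmentation (flips + shared gamma) is applied to training pairs
#' only and is redrawn per sample per epoch.
#'
#' @param model a [build_model()] result.
#' @param train_pairs,val_pairs lists of `patch_pair` objects.
#' @param config a [train_config()].
#' @return List: `model` (best-epoch parameters), `history` (data frame of
#'   per-epoch training loss and validation MSE), `best_epoch`,
#'   `best_val_mse`, `epochs_run`.
#' @export
train_unet <- function(model, train_pairs, val_pairs, config = train_config()) {
  stopifnot(inherits(model, "unet_model"), length(train_pairs) >= 1L,
            length(val_pairs) >= 1L, inherits(config, "train_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  state <- switch(config$optimizer_name,
                  adadelta = adadelta_init(model$params),
                  adam = adam_init(model$params),
                  NULL)
  step_count <- 0L
  best_params <- model$params
  init_val <- eval_dataset_mse(model, val_pairs)   # untrained baseline
  best_val <- Inf                                  # epoch 1 establishes best
  best_epoch <- 0L
  bad_epochs <- 0L
  hist <- list()
  n <- length(train_pairs)
  for (epoch in seq_len(config$max_epochs)) {
    lr_now <- config$lr
    if (!is.null(config$lr_decay_epoch) && epoch > config$lr_decay_epoch)
      lr_now <- config$lr * config$lr_decay_factor
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      acc <- NULL
      bl <- 0
      for (j in idx) {
        pr <- train_pairs[[j]]
        if (config$augment)
          pr <- augment_pair(pr, seed = config$seed + 1000L * epoch + j)
        fw <- unet_forward(model, pr$input, keep_cache = TRUE)
        resid <- fw$out - pr$target
        bl <- bl + mean(abs(resid))
        dout <- sign(resid) / length(resid)
        g <- unet_backward(model, fw$cache, dout)
        if (is.null(acc)) acc <- g
        else for (nm in names(g)) {
          acc[[nm]]$W <- acc[[nm]]$W + g[[nm]]$W
          acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
        }
      }
      for (nm in names(acc)) {
        acc[[nm]]$W <- acc[[nm]]$W / length(idx)
        acc[[nm]]$b <- acc[[nm]]$b / length(idx)
      }
      if (any(!vapply(acc, function(a) all(is.finite(a$W)) && all(is.finite(a$b)), TRUE)))
        stop("training diverged (non-finite gradient) at epoch ", epoch,
             call. = FALSE)
      step_count <- step_count + 1L
      if (config$optimizer_name == "adadelta") {
        st <- adadelta_step(model$params, acc, state, config$rho, config$epsilon)
        model$params <- st$params; state <- st$state
      } else if (config$optimizer_name == "adam") {
        st <- adam_step(model$params, acc, state, lr_now, step_count)
        model$params <- st$params; state <- st$state
      } else if (config$optimizer_name == "sgd") {
        for (nm in names(acc)) {
          model$params[[nm]]$W <- model$params[[nm]]$W - lr_now * acc[[nm]]$W
          model$params[[nm]]$b <- model$params[[nm]]$b - lr_now * acc[[nm]]$b
        }
      } # "frozen": no update
      ep_loss <- ep_loss + bl / length(idx); nb <- nb + 1L
    }
    val_mse <- eval_dataset_mse(model, val_pairs)
    if (!is.finite(val_mse))
      stop("training diverged (non-finite validation MSE) at epoch ", epoch,
           call. = FALSE)
    hist[[epoch]] <- data.frame(epoch = epoch, train_mae = ep_loss / nb,
                                val_mse = val_mse)
    if (config$verbose)
      message(sprintf("epoch %3d: train MAE %.6f, val MSE %.6f",
                      epoch, ep_loss / nb, val_mse))
    if (val_mse < best_val) {
      best_val <- val_mse; best_params <- model$params
      best_epoch <- epoch; bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best_epoch, best_val_mse = best_val,
       init_val_mse = init_val, epochs_run = length(hist))
}

#' Save / load a trained model
#'
#' Checkpoints carry the network spec and parameters plus free-form
#' provenance (e.g. training history and normalization policy).
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`).
#' @param provenance optional list stored alongside.
#' @return `path` (save) or the `unet_model` (load).
#' @export
save_model <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(spec = unclass(model$spec), params = model$params,
               provenance = provenance), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(spec = structure(obj$spec, class = "unet_spec"),
                 params = obj$params),
            class = "unet_model")
}
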