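#' Configuration of the semi-supervised latent classifier
#'
#' The annotation model is a variational autoencoder with a
#' negative-binomial observation model and a linear-softmax classifier head
#' on the latent space. Training follows a two-phase schedule: an
#' unsupervised warm-up maximizing the evidence lower bound (ELBO) for a
#' fixed number of epochs, then semi-supervised fine-tuning minimizing
#' `-ELBO + class_weight * cross-entropy` on labeled cells, with labeled
#' cells split 5:1 into train and validation (stratified), early stopping
#' on validation classification accuracy (patience 5, improvement threshold
#' 0.001, best state restored) and learning-rate reduction on training-loss
#' plateau (patience 8, factor 0.1).
#'
#' @param latent_dim latent dimensionality D (default 50).
#' @param n_layers hidden layers in encoder and decoder (default 2).
#' @param hidden_dim units per hidden layer.
#' @param class_weight weight of the classification loss.
#' @param learning_rate Adam learning rate.
#' @param unsup_epochs unsupervised warm-up epochs (default 5).
#' @param max_epochs cap on semi-supervised epochs.
#' @param early_stop_patience,early_stop_threshold early-stopping patience
#'   (epochs) and minimum accuracy improvement.
#' @param plateau_patience,plateau_factor learning-rate plateau schedule.
#' @param batch_size minibatch size.
#' @param kl_weight weight on the KL term (1 = proper ELBO).
#' @param split_ratio train:validation split of labeled cells.
#' @param use_batch_covariate append a one-hot sample (batch) covariate to
#'   encoder/decoder inputs, keyed on `sample_ID`; `NULL` = automatic
#'   (on when more than one sample).
#' @param seed integer seed driving initialization, split and minibatches.
#' @return a `LatentModelConfig` list.
#' @export
latent_model_config <- function(latent_dim = 50, n_layers = 2,
                                hidden_dim = 128, class_weight = 50,
                                learning_rate = 1e-3, unsup_epochs = 5,
                                max_epochs = 60, early_stop_patience = 5,
                                early_stop_threshold = 0.001,
                                plateau_patience = 8, plateau_factor = 0.1,
                                batch_size = 128, kl_weight = 1,
                                split_ratio = c(5, 1),
                                use_batch_covariate = NULL, seed = 0) {
  stopifnot(latent_dim >= 1, n_layers >= 1, hidden_dim >= 1,
            early_stop_patience >= 1, plateau_patience >= 1,
            plateau_factor > 0, plateau_factor < 1, length(split_ratio) == 2)
  cfg <- as.list(environment())
  class(cfg) <- "LatentModelConfig"
  cfg
}

## dense encoder-input construction shared by fit/encode
.lm_inputs <- function(ds, panel_genes, batch_levels = NULL) {
  missing <- setdiff(panel_genes, colnames(ds$counts))
  if (length(missing))
    warning(sprintf("%d panel gene(s) absent from dataset; zero-filled",
                    length(missing)))
  X <- matrix(0, nrow(ds$counts), length(panel_genes),
              dimnames = list(rownames(ds$counts), panel_genes))
  present <- intersect(panel_genes, colnames(ds$counts))
  X[, present] <- as.matrix(ds$counts[, present, drop = FALSE])
  lib <- pmax(rowSums(X), 1)
  xin <- log1p(X / lib * 1e4)
  B <- NULL
  if (!is.null(batch_levels)) {
    s <- as.character(ds$metadata$sample_ID)
    B <- matrix(0, nrow(X), length(batch_levels))
    hit <- match(s, batch_levels)
    ok <- !is.na(hit)
    B[cbind(which(ok), hit[ok])] <- 1
  }
  list(X = X, xin = xin, lib = lib, B = B)
}

.lm_init_params <- function(p, nb, cfg) {
  enc_layers <- .nn_mlp_init(p + nb, cfg$hidden_dim, cfg$n_layers)
  dec_layers <- .nn_mlp_init(cfg$latent_dim + nb, cfg$hidden_dim, cfg$n_layers)
  lv_head <- .nn_linear_init(cfg$hidden_dim, cfg$latent_dim, scale = 0.01)
  lv_head$b <- rep(-1, cfg$latent_dim)  # start with modest posterior noise
  list(
    enc = list(layers = enc_layers,
               mu = .nn_linear_init(cfg$hidden_dim, cfg$latent_dim),
               lv = lv_head),
    dec = list(layers = dec_layers,
               out = .nn_linear_init(cfg$hidden_dim, p)),
    log_theta = rep(0, p),
    clf = list(W = matrix(0, cfg$latent_dim, 0), b = numeric(0))
  )
}

## deterministic forward to posterior mean (and optional class logits)
.lm_encode_mu <- function(params, xin, B) {
  enc_in <- if (is.null(B)) xin else cbind(xin, B)
  h <- .nn_mlp_forward(params$enc$layers, enc_in)$out
  sweep(h %*% params$enc$mu$W, 2, params$enc$mu$b, "+")
}

## loss + gradients on one minibatch; yb integer class index (NA = unlabeled)
.lm_batch_grad <- function(params, xb, xinb, Bb, lb, yb, cfg, eps) {
  n <- nrow(xb); D <- cfg$latent_dim
  enc_in <- if (is.null(Bb)) xinb else cbind(xinb, Bb)
  encf <- .nn_mlp_forward(params$enc$layers, enc_in)
  h <- encf$out
  mu_e <- sweep(h %*% params$enc$mu$W, 2, params$enc$mu$b, "+")
  lv_raw <- sweep(h %*% params$enc$lv$W, 2, params$enc$lv$b, "+")
  lv <- pmin(pmax(lv_raw, -10), 10)
  lv_ok <- lv_raw > -10 & lv_raw < 10
  sd_z <- exp(0.5 * lv)
  z <- mu_e + sd_z * eps

  dec_in <- if (is.null(Bb)) z else cbind(z, Bb)
  decf <- .nn_mlp_forward(params$dec$layers, dec_in)
  logits <- sweep(decf$out %*% params$dec$out$W, 2, params$dec$out$b, "+")
  p <- .softmax_rows(logits)
  mu <- pmax(lb * p, 1e-10)
  theta <- exp(pmin(pmax(params$log_theta, -8), 12))
  Th <- matrix(theta, n, length(theta), byrow = TRUE)

  nbll <- nb_loglik(xb, mu, Th)
  kl <- 0.5 * (exp(lv) + mu_e^2 - 1 - lv)
  loss <- (-sum(nbll) + cfg$kl_weight * sum(kl)) / n

  ## decoder gradients
  dmu <- -(xb / mu - (xb + Th) / (Th + mu)) / n
  s <- dmu * lb
  rs <- rowSums(p * s)
  dlogits <- p * (s - rs)
  g_out <- list(W = crossprod(decf$out, dlogits), b = colSums(dlogits))
  decb <- .nn_mlp_backward(params$dec$layers, decf$caches,
                           tcrossprod(dlogits, params$dec$out$W))
  dz <- decb$d_input[, seq_len(D), drop = FALSE]
  dterm <- digamma(xb + Th) - digamma(Th) + log(Th) + 1 -
    log(Th + mu) - (xb + Th) / (Th + mu)
  g_log_theta <- -colSums(dterm) * theta / n

  ## classifier gradients on labeled cells
  labeled <- which(!is.na(yb))
  ce <- 0
  g_clf <- list(W = params$clf$W * 0, b = params$clf$b * 0)
  if (length(labeled) && ncol(params$clf$W) > 0 && cfg$class_weight > 0) {
    clog <- sweep(z %*% params$clf$W, 2, params$clf$b, "+")
    q <- .softmax_rows(clog)
    pick <- cbind(labeled, yb[labeled])
    ce <- -sum(log(pmax(q[pick], 1e-12)))
    dclog <- matrix(0, n, ncol(q))
    dclog[labeled, ] <- q[labeled, , drop = FALSE]
    dclog[pick] <- dclog[pick] - 1
    dclog <- dclog * (cfg$class_weight / n)
    g_clf <- list(W = crossprod(z, dclog), b = colSums(dclog))
    dz <- dz + tcrossprod(dclog, params$clf$W)
    loss <- loss + cfg$class_weight * ce / n
  }

  ## through the reparameterization into the encoder
  dmu_e <- dz + cfg$kl_weight * mu_e / n
  dlv <- (dz * eps * 0.5 * sd_z +
            cfg$kl_weight * 0.5 * (exp(lv) - 1) / n) * lv_ok
  g_mu <- list(W = crossprod(h, dmu_e), b = colSums(dmu_e))
  g_lv <- list(W = crossprod(h, dlv), b = colSums(dlv))
  d_h <- tcrossprod(dmu_e, params$enc$mu$W) + tcrossprod(dlv, params$enc$lv$W)
  encb <- .nn_mlp_backward(params$enc$layers, encf$caches, d_h)

  list(loss = loss,
       grads = list(enc = list(layers = encb$grads, mu = g_mu, lv = g_lv),
                    dec = list(layers = decb$grads, out = g_out),
                    log_theta = g_log_theta, clf = g_clf))
}

## deterministic full-data ELBO (posterior mean as latent point)
.lm_elbo <- function(params, xb, xinb, Bb, lb, cfg) {
  mu_e <- .lm_encode_mu(params, xinb, Bb)
  enc_in <- if (is.null(Bb)) xinb else cbind(xinb, Bb)
  h <- .nn_mlp_forward(params$enc$layers, enc_in)$out
  lv <- pmin(pmax(sweep(h %*% params$enc$lv$W, 2, params$enc$lv$b, "+"),
                  -10), 10)
  dec_in <- if (is.null(Bb)) mu_e else cbind(mu_e, Bb)
  g <- .nn_mlp_forward(params$dec$layers, dec_in)$out
  logits <- sweep(g %*% params$dec$out$W, 2, params$dec$out$b, "+")
  p <- .softmax_rows(logits)
  mu <- pmax(lb * p, 1e-10)
  theta <- exp(pmin(pmax(params$log_theta, -8), 12))
  Th <- matrix(theta, nrow(xb), length(theta), byrow = TRUE)
  (sum(nb_loglik(xb, mu, Th)) -
      cfg$kl_weight * 0.5 * sum(exp(lv) + mu_e^2 - 1 - lv)) / nrow(xb)
}

#' Fit the semi-supervised negative-binomial latent classifier
#'
#' Phase 1 trains the autoencoder unsupervised for `unsup_epochs` epochs,
#' maximizing the ELBO (NB reconstruction of raw panel counts with the
#' observed panel library size as mean offset, encoder fed log1p
#' 10,000-scaled counts, Gaussian prior on the latent). Phase 2 adds the
#' linear-softmax classifier head and minimizes `-ELBO + class_weight *
#' cross-entropy` on labeled training cells, early-stopping on validation
#' accuracy and restoring the best state. Fully deterministic given
#' `cfg$seed`.
#'
#' @param ref `AnnotatedDataset` with raw counts.
#' @param labels per-cell labels (NA = unlabeled); at least two classes.
#' @param panel `FeaturePanel` or character vector of panel genes; must be
#'   a subset of the dataset's genes.
#' @param cfg a [latent_model_config()].
#' @return a `TrainedLatentModel`: parameters, panel, label vocabulary,
#'   training history (`elbo`, `train_loss`, `val_accuracy`), the
#'   train/validation cell ids and the best validation accuracy.
#' @export
fit_latent_model <- function(ref, labels, panel,
                             cfg = latent_model_config()) {
  stopifnot(inherits(ref, "AnnotatedDataset"))
  genes <- if (inherits(panel, "FeaturePanel")) panel$genes else
    as.character(panel)
  if (!length(genes)) stop("empty feature panel")
  if (length(setdiff(genes, colnames(ref$counts))))
    stop("panel contains genes absent from the reference")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(ref$counts))
  classes <- sort(unique(labels[!is.na(labels)]))
  if (length(classes) < 2)
    stop("need at least 2 label classes to train a classifier")

  batch_levels <- NULL
  use_b <- cfg$use_batch_covariate
  if ("sample_ID" %in% names(ref$metadata)) {
    lv <- sort(unique(as.character(ref$metadata$sample_ID)))
    if (isTRUE(use_b) || (is.null(use_b) && length(lv) > 1))
      batch_levels <- lv
  }
  inp <- .lm_inputs(ref, genes, batch_levels)
  n <- nrow(inp$X)
  y <- match(labels, classes)

  set.seed(cfg$seed)
  ## stratified train:validation split of labeled cells
  val_frac <- cfg$split_ratio[2] / sum(cfg$split_ratio)
  val_idx <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(y == k)
    idx <- idx[sample.int(length(idx))]
    nv <- max(1L, floor(length(idx) * val_frac))
    if (nv >= length(idx)) nv <- length(idx) - 1L
    if (nv > 0) val_idx <- c(val_idx, idx[seq_len(nv)])
  }
  train_cells <- setdiff(seq_len(n), val_idx)

  params <- .lm_init_params(length(genes), length(batch_levels), cfg)
  params$clf <- list(
    W = matrix(stats::rnorm(cfg$latent_dim * length(classes), 0, 0.01),
               cfg$latent_dim, length(classes)),
    b = rep(0, length(classes)))
  opt <- .adam_init(params)
  lr <- cfg$learning_rate

  run_epoch <- function(cells, supervised) {
    ord <- cells[sample.int(length(cells))]
    total <- 0
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      i <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      if (length(i) < 2L) next
      eps <- matrix(stats::rnorm(length(i) * cfg$latent_dim),
                    length(i), cfg$latent_dim)
      cfg_b <- cfg
      if (!supervised) cfg_b$class_weight <- 0
      r <- .lm_batch_grad(params, inp$X[i, , drop = FALSE],
                          inp$xin[i, , drop = FALSE],
                          if (is.null(inp$B)) NULL else
                            inp$B[i, , drop = FALSE],
                          inp$lib[i], y[i], cfg_b, eps)
      st <- .adam_step(params, r$grads, opt, lr)
      params <<- st$params; opt <<- st$state
      total <- total + r$loss * length(i)
    }
    total / length(ord)
  }
  val_accuracy <- function() {
    if (!length(val_idx)) return(NA_real_)
    mu <- .lm_encode_mu(params, inp$xin[val_idx, , drop = FALSE],
                        if (is.null(inp$B)) NULL else
                          inp$B[val_idx, , drop = FALSE])
    pred <- max.col(sweep(mu %*% params$clf$W, 2, params$clf$b, "+"),
                    ties.method = "first")
    mean(pred == y[val_idx])
  }

  ## phase 1: unsupervised warm-up on training (+ unlabeled) cells
  history <- list(elbo = numeric(0), train_loss = numeric(0),
                  val_accuracy = numeric(0))
  for (e in seq_len(cfg$unsup_epochs)) {
    run_epoch(train_cells, supervised = FALSE)
    history$elbo <- c(history$elbo,
                      .lm_elbo(params, inp$X[train_cells, , drop = FALSE],
                               inp$xin[train_cells, , drop = FALSE],
                               if (is.null(inp$B)) NULL else
                                 inp$B[train_cells, , drop = FALSE],
                               inp$lib[train_cells], cfg))
  }

  ## phase 2: semi-supervised fine-tuning with early stopping
  best_acc <- -Inf; best_params <- params
  wait <- 0L; plateau_wait <- 0L; best_loss <- Inf
  for (e in seq_len(cfg$max_epochs)) {
    tl <- run_epoch(train_cells, supervised = TRUE)
    acc <- val_accuracy()
    history$train_loss <- c(history$train_loss, tl)
    history$val_accuracy <- c(history$val_accuracy, acc)
    if (tl < best_loss - 1e-10) { best_loss <- tl; plateau_wait <- 0L }
    else {
      plateau_wait <- plateau_wait + 1L
      if (plateau_wait >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        plateau_wait <- 0L
      }
    }
    improved <- acc > best_acc + cfg$early_stop_threshold
    if (acc > best_acc) { best_acc <- acc; best_params <- params }
    if (improved) wait <- 0L else wait <- wait + 1L
    if (wait >= cfg$early_stop_patience) break
  }
  params <- best_params

  structure(list(
    params = params, panel = genes, classes = classes,
    batch_levels = batch_levels, cfg = cfg, history = history,
    train_cells = rownames(ref$counts)[train_cells],
    val_cells = rownames(ref$counts)[val_idx],
    best_val_accuracy = best_acc
  ), class = "TrainedLatentModel")
}

#' @export
print.TrainedLatentModel <- function(x, ...) {
  cat(sprintf(paste0("TrainedLatentModel: %d panel genes, %d classes, ",
                     "D = %d; best val accuracy %.3f\n"),
              length(x$panel), length(x$classes), x$cfg$latent_dim,
              x$best_val_accuracy))
  invisible(x)
}

#' Encode cells into the latent space
#'
#' Deterministic posterior mean of the encoder for each cell. Panel genes
#' absent from the dataset are zero-filled with a warning; unseen samples
#' get a zero batch covariate.
#'
#' @param model a `TrainedLatentModel`.
#' @param ds `AnnotatedDataset`.
#' @return cells x D numeric matrix.
#' @export
encode <- function(model, ds) {
  stopifnot(inherits(model, "TrainedLatentModel"),
            inherits(ds, "AnnotatedDataset"))
  inp <- .lm_inputs(ds, model$panel, model$batch_levels)
  mu <- .lm_encode_mu(model$params, inp$xin, inp$B)
  rownames(mu) <- rownames(ds$counts)
  mu
}

#' Classify cells with the latent classifier head
#'
#' @param model a `TrainedLatentModel`.
#' @param ds `AnnotatedDataset`.
#' @return list with `labels` (character) and `prob` (cells x classes
#'   matrix; rows sum to 1).
#' @export
classify <- function(model, ds) {
  z <- encode(model, ds)
  logits <- sweep(z %*% model$params$clf$W, 2, model$params$clf$b, "+")
  prob <- .softmax_rows(logits)
  colnames(prob) <- model$classes
  rownames(prob) <- rownames(z)
  labels <- model$classes[max.col(prob, ties.method = "first")]
  names(labels) <- rownames(z)
  list(labels = labels, prob = prob)
}

#' Hyperparameter grid for model selection
#'
#' Defaults span the search space used for atlas-scale annotation: latent
#' dimensions 10-100, 1-10 network layers and 10 initialization seeds.
#'
#' @param latent_dims,n_layers,seeds candidate values.
#' @return a `HyperparamGrid` list.
#' @export
hyperparam_grid <- function(latent_dims = seq(10, 100, by = 10),
                            n_layers = 1:10, seeds = 0:9) {
  stopifnot(length(latent_dims) > 0, length(n_layers) > 0, length(seeds) > 0)
  structure(list(latent_dims = latent_dims, n_layers = n_layers,
                 seeds = seeds), class = "HyperparamGrid")
}

#' Grid search over latent-model hyperparameters
#'
#' Trains one model per grid point and returns the one with the highest
#' validation accuracy; ties are broken toward the smaller latent
#' dimension, then fewer layers, then the smaller seed. Grid points whose
#' training fails are logged and skipped.
#'
#' @inheritParams fit_latent_model
#' @param grid a [hyperparam_grid()].
#' @return the best `TrainedLatentModel`, with the winning grid point in
#'   the `grid_point` field.
#' @export
hyperparameter_search <- function(ref, labels, panel,
                                  grid = hyperparam_grid(),
                                  cfg = latent_model_config()) {
  stopifnot(inherits(grid, "HyperparamGrid"))
  combos <- expand.grid(seed = sort(grid$seeds),
                        n_layers = sort(grid$n_layers),
                        latent_dim = sort(grid$latent_dims))
  combos <- combos[order(combos$latent_dim, combos$n_layers, combos$seed), ]
  best <- NULL; best_acc <- -Inf
  for (i in seq_len(nrow(combos))) {
    cfg_i <- cfg
    cfg_i$latent_dim <- combos$latent_dim[i]
    cfg_i$n_layers <- combos$n_layers[i]
    cfg_i$seed <- combos$seed[i]
    m <- tryCatch(fit_latent_model(ref, labels, panel, cfg_i),
                  error = function(e) {
                    message(sprintf("grid point (D=%d, L=%d, seed=%d) failed: %s",
                                    combos$latent_dim[i], combos$n_layers[i],
                                    combos$seed[i], conditionMessage(e)))
                    NULL
                  })
    if (is.null(m)) next
    if (m$best_val_accuracy > best_acc) {  # strict: earlier (smaller) wins ties
      best_acc <- m$best_val_accuracy
      best <- m
      best$grid_point <- as.list(combos[i, ])
    }
  }
  if (is.null(best)) stop("all grid points failed")
  best
}

#' Latent-space logistic label transfer
#'
#' Multinomial logistic (softmax-linear) model fit by penalized maximum
#' likelihood on reference embeddings and applied to query embeddings —
#' the label-transfer step used after cross-species integration.
#'
#' @param ref_latent reference cells x D embedding.
#' @param ref_labels reference labels (at least 2 classes).
#' @param query_latent query cells x D embedding (same D).
#' @param l2_strength L2 (weight-decay) penalty.
#' @return list with `labels` and `prob` for the query cells.
#' @export
logistic_transfer <- function(ref_latent, ref_labels, query_latent,
                              l2_strength = 1.0) {
  ref_latent <- as.matrix(ref_latent); query_latent <- as.matrix(query_latent)
  if (ncol(ref_latent) != ncol(query_latent))
    stop("reference and query embeddings have different dimensions")
  yl <- factor(ref_labels)
  if (nlevels(yl) < 2) stop("need at least 2 reference classes")
  dtrain <- data.frame(.y = yl, ref_latent)
  set.seed(0)  # multinom's nnet backend draws random starting weights
  fit <- nnet::multinom(.y ~ ., data = dtrain, decay = l2_strength,
                        trace = FALSE, maxit = 500, MaxNWts = 1e5)
  dq <- data.frame(query_latent)
  colnames(dq) <- colnames(dtrain)[-1]
  prob <- stats::predict(fit, newdata = dq, type = "probs")
  if (is.null(dim(prob))) {  # two-class case returns P(level 2)
    prob <- cbind(1 - prob, prob)
    colnames(prob) <- levels(yl)
  }
  rownames(prob) <- rownames(query_latent)
  labels <- levels(yl)[max.col(prob, ties.method = "first")]
  names(labels) <- rownames(query_latent)
  list(labels = labels, prob = prob)
}

#' Persist / restore a trained latent model
#'
#' The model is written as a directory: `config.json` (architecture,
#' vocabulary, batch levels, history), `panel.txt` (one gene per line) and
#' `params.rds` (parameter arrays).
#'
#' @param model a `TrainedLatentModel`.
#' @param dir target directory.
#' @return `load_latent_model` returns the restored model.
#' @export
save_latent_model <- function(model, dir) {
  stopifnot(inherits(model, "TrainedLatentModel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(classes = model$classes, batch_levels = model$batch_levels,
               cfg = unclass(model$cfg), history = model$history,
               train_cells = model$train_cells, val_cells = model$val_cells,
               best_val_accuracy = model$best_val_accuracy)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(model$panel, file.path(dir, "panel.txt"))
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_latent_model
#' @export
load_latent_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- meta$cfg
  class(cfg) <- "LatentModelConfig"
  structure(list(
    params = readRDS(file.path(dir, "params.rds")),
    panel = readLines(file.path(dir, "panel.txt")),
    classes = meta$classes,
    batch_levels = if (length(meta$batch_levels)) meta$batch_levels else NULL,
    cfg = cfg, history = meta$history,
    train_cells = meta$train_cells, val_cells = meta$val_cells,
    best_val_accuracy = meta$best_val_accuracy
  ), class = "TrainedLatentModel")
}
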