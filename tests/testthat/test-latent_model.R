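test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(99)
  n <- 5; p <- 6; D <- 2
  cfg <- latent_model_config(latent_dim = D, n_layers = 1, hidden_dim = 4,
                             class_weight = 3, seed = 0)
  params <- scAtlasKit:::.lm_init_params(p, 0, cfg)
  params$clf <- list(W = matrix(rnorm(D * 2, 0, 0.1), D, 2), b = c(0.1, -0.2))
  xb <- matrix(rpois(n * p, 4), n, p)
  lb <- rowSums(xb)
  xinb <- log1p(xb / lb * 1e4)
  yb <- c(1L, 2L, NA, 1L, 2L)
  eps_noise <- matrix(rnorm(n * D), n, D)

  loss_fn <- function(pp) scAtlasKit:::.lm_batch_grad(pp, xb, xinb, NULL, lb,
                                                      yb, cfg, eps_noise)$loss
  r <- scAtlasKit:::.lm_batch_grad(params, xb, xinb, NULL, lb, yb, cfg,
                                   eps_noise)
  h <- 1e-6
  check_leaf <- function(path) {
    g_ana <- r$grads
    p_cur <- params
    for (k in path) { g_ana <- g_ana[[k]]; p_cur <- p_cur[[k]] }
    idx <- seq_len(min(length(p_cur), 5))
    for (i in idx) {
      pp <- params
      ref <- pp
      # perturb element i of the leaf at `path`
      leaf <- p_cur; leaf[i] <- leaf[i] + h
      assign_leaf <- function(obj, path, value) {
        if (!length(path)) return(value)
        obj[[path[1]]] <- assign_leaf(obj[[path[1]]], path[-1], value)
        obj
      }
      pp <- assign_leaf(pp, path, leaf)
      g_num <- (loss_fn(pp) - r$loss) / h
      expect_equal(g_ana[i], g_num, tolerance = 1e-3)
    }
  }
  check_leaf(c("enc", "layers", 1, "W"))
  check_leaf(c("enc", "layers", 1, "b"))
  check_leaf(c("enc", "mu", "W"))
  check_leaf(c("enc", "lv", "W"))
  check_leaf(c("dec", "layers", 1, "W"))
  check_leaf(c("dec", "out", "W"))
  check_leaf(c("dec", "out", "b"))
  check_leaf("log_theta")
  check_leaf(c("clf", "W"))
  check_leaf(c("clf", "b"))
})

test_that("NB log-likelihood approaches Poisson as dispersion vanishes", {
  x <- 0:20
  mu <- 3.7
  expect_equal(nb_loglik(x, mu, theta = 1e8), dpois(x, mu, log = TRUE),
               tolerance = 1e-6)
})

test_that("the classifier separates a well-structured synthetic atlas", {
  sim <- small_atlas(classes = 4, subtypes = 1, cells = 200, genes = 400,
                     seed = 0, markers_per_type = 20, doublet_rate = 0)
  ds <- sim$dataset
  mt <- rank_markers_wilcoxon(ds, ds$labels1)
  panel <- select_feature_genes(mt, 50)
  m <- fit_latent_model(ds, ds$labels1, panel, quick_cfg())
  # held-out (validation split) accuracy on well-separated types
  expect_gte(m$best_val_accuracy, 0.95)
  # ELBO is non-decreasing over warm-up epochs within 1% tolerance
  e <- m$history$elbo
  expect_true(all(diff(e) >= -0.01 * abs(e[-length(e)])))
  # probabilities normalize; embedding has the configured dimension
  pr <- classify(m, ds)
  expect_equal(unname(rowSums(pr$prob)), rep(1, nrow(ds$counts)),
               tolerance = 1e-6)
  z <- encode(m, ds)
  expect_identical(ncol(z), 10L)
  # training cells of a pure type are recovered
  for (cl in unique(ds$labels1))
    expect_gte(mean(pr$labels[ds$labels1 == cl] == cl), 0.95)
})

test_that("degenerate label sets are rejected", {
  ds <- random_dataset(30, 20, seed = 1)
  expect_error(fit_latent_model(ds, rep("only", 30), colnames(ds$counts)[1:5],
                                quick_cfg()),
               "at least 2")
  expect_error(fit_latent_model(ds, rep(c("a", "b"), 15), character(0),
                                quick_cfg()),
               "empty")
  expect_error(fit_latent_model(ds, rep(c("a", "b"), 15), "NOT_THERE",
                                quick_cfg()),
               "absent")
})

test_that("encoding is deterministic and separates types in latent space", {
  sim <- small_atlas(classes = 2, subtypes = 1, cells = 250, genes = 200,
                     markers_per_type = 20, seed = 0, doublet_rate = 0)
  ds <- sim$dataset
  m <- fit_latent_model(ds, ds$labels1, colnames(ds$counts),
                        quick_cfg(batch_size = 64))
  z <- encode(m, ds)
  # identical cells embed identically
  dup_counts <- ds$counts[c(1, 1), ]
  rownames(dup_counts) <- c("a", "b")
  dup <- annotated_dataset(dup_counts,
                           data.frame(cell_ID = c("a", "b"),
                                      sample_ID = ds$metadata$sample_ID[c(1, 1)]))
  zd <- encode(m, dup)
  expect_equal(zd[1, ], zd[2, ])
  # centroid distance between types exceeds mean within-type distance
  c1 <- colMeans(z[ds$labels1 == "K01", ]); c2 <- colMeans(z[ds$labels1 == "K02", ])
  between <- sqrt(sum((c1 - c2)^2))
  within <- mean(sqrt(rowSums(sweep(z[ds$labels1 == "K01", ], 2, c1)^2)))
  expect_gt(between, within)
  # classification is invariant to cell order
  perm <- sample(nrow(ds$counts))
  pr_perm <- classify(m, subset_dataset(ds, cells = perm))
  pr <- classify(m, ds)
  expect_identical(unname(pr_perm$labels), unname(pr$labels[perm]))
})

test_that("training is bitwise reproducible and early stopping restores the best state", {
  sim <- small_atlas(classes = 3, subtypes = 1, cells = 80, genes = 150,
                     seed = 2, doublet_rate = 0)
  ds <- sim$dataset
  cfg <- quick_cfg(max_epochs = 15)
  m1 <- fit_latent_model(ds, ds$labels1, colnames(ds$counts), cfg)
  m2 <- fit_latent_model(ds, ds$labels1, colnames(ds$counts), cfg)
  expect_identical(classify(m1, ds)$labels, classify(m2, ds)$labels)
  expect_identical(m1$params, m2$params)
  # halted no later than patience epochs after the best epoch
  va <- m1$history$val_accuracy
  expect_lte(length(va) - which.max(va), cfg$early_stop_patience)
  # restored parameters reproduce the best recorded validation accuracy
  vi <- match(m1$val_cells, rownames(ds$counts))
  acc <- mean(classify(m1, subset_dataset(ds, cells = vi))$labels ==
                ds$labels1[vi])
  expect_equal(acc, m1$best_val_accuracy)
})

test_that("model persistence roundtrips through the on-disk layout", {
  sim <- small_atlas(classes = 2, subtypes = 1, cells = 60, genes = 120,
                     seed = 3, doublet_rate = 0)
  ds <- sim$dataset
  m <- fit_latent_model(ds, ds$labels1, colnames(ds$counts),
                        quick_cfg(max_epochs = 6))
  dir <- withr::local_tempdir()
  save_latent_model(m, dir)
  back <- load_latent_model(dir)
  expect_equal(encode(back, ds), encode(m, ds))
  expect_identical(back$classes, m$classes)
  expect_identical(classify(back, ds)$labels, classify(m, ds)$labels)
})

test_that("a singleton hyperparameter grid reproduces a direct fit", {
  sim <- small_atlas(classes = 2, subtypes = 1, cells = 60, genes = 120,
                     seed = 4, doublet_rate = 0)
  ds <- sim$dataset
  cfg <- quick_cfg(max_epochs = 6)
  grid <- hyperparam_grid(latent_dims = 10, n_layers = 2, seeds = 0)
  best <- hyperparameter_search(ds, ds$labels1, colnames(ds$counts),
                                grid, cfg)
  direct <- fit_latent_model(ds, ds$labels1, colnames(ds$counts), cfg)
  expect_equal(best$best_val_accuracy, direct$best_val_accuracy)
  expect_identical(classify(best, ds)$labels, classify(direct, ds)$labels)
  # two-point grid returns the better validation accuracy
  grid2 <- hyperparam_grid(latent_dims = c(2, 10), n_layers = 2, seeds = 0)
  best2 <- hyperparameter_search(ds, ds$labels1, colnames(ds$counts),
                                 grid2, cfg)
  expect_gte(best2$best_val_accuracy, best$best_val_accuracy - 1e-12)
})

test_that("logistic label transfer recovers separable classes", {
  set.seed(0)
  n <- 500
  ref <- rbind(matrix(rnorm(n * 2, -5), n, 2), matrix(rnorm(n * 2, 5), n, 2))
  lab <- rep(c("neg", "pos"), each = n)
  qry <- rbind(matrix(rnorm(n * 2, -5), n, 2), matrix(rnorm(n * 2, 5), n, 2))
  res <- logistic_transfer(ref, lab, qry)
  expect_gte(mean(res$labels == lab), 0.99)
  expect_equal(unname(rowSums(res$prob)), rep(1, 2 * n), tolerance = 1e-9)
  # memorization on separable data when query = reference
  res2 <- logistic_transfer(ref, lab, ref)
  expect_gte(mean(res2$labels == lab), 0.99)
  expect_error(logistic_transfer(ref, lab, qry[, 1, drop = FALSE]),
               "dimension")
  expect_error(logistic_transfer(ref, rep("one", 2 * n), qry), "2")
})
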