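#' Aggregate single-cell counts into pseudobulk samples
#'
#' Sums raw counts per (sample, gene) over the cells passing the
#' population filter, producing a samples x genes count matrix with
#' sample-level covariates carried from the cell metadata (which must be
#' constant within each sample). Samples aggregating fewer than
#' `min_cells` cells are dropped with a warning.
#'
#' @param ds `AnnotatedDataset` with raw counts.
#' @param sample_field metadata column defining samples.
#' @param group_field metadata column holding the biological group.
#' @param population_filter optional logical vector over cells, or a
#'   function `ds -> logical`, selecting the cell population.
#' @param min_cells minimum cells per retained sample (default 10).
#' @param covariates metadata columns carried to the sample level.
#' @return a `PseudobulkMatrix`: list with `counts` (samples x genes) and
#'   `samples` (data.frame with `sample_ID`, `group`, covariates,
#'   `n_cells`).
#' @export
aggregate_pseudobulk <- function(ds, sample_field = "sample_ID",
                                 group_field = "group",
                                 population_filter = NULL, min_cells = 10,
                                 covariates = c("donor_ID", "donor_age",
                                                "donor_sex")) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  for (f in c(sample_field, group_field))
    if (!f %in% names(ds$metadata)) stop("metadata field missing: ", f)
  keep <- rep(TRUE, nrow(ds$counts))
  if (!is.null(population_filter)) {
    keep <- if (is.function(population_filter)) population_filter(ds)
    else as.logical(population_filter)
    stopifnot(length(keep) == nrow(ds$counts))
  }
  md <- ds$metadata[keep, , drop = FALSE]
  cnt <- ds$counts[keep, , drop = FALSE]
  samp <- as.character(md[[sample_field]])
  slev <- sort(unique(samp))
  ind <- Matrix::sparseMatrix(i = match(samp, slev), j = seq_along(samp),
                              x = 1, dims = c(length(slev), length(samp)))
  agg <- as.matrix(ind %*% cnt)
  rownames(agg) <- slev
  n_cells <- as.vector(ind %*% rep(1, length(samp)))

  covariates <- intersect(covariates, names(md))
  sdf <- data.frame(sample_ID = slev, stringsAsFactors = FALSE)
  for (f in c(group_field, covariates)) {
    vals <- tapply(as.character(md[[f]]), samp, function(v) {
      u <- unique(v)
      if (length(u) > 1)
        stop(sprintf("covariate '%s' varies within a sample", f))
      u
    })
    sdf[[if (f == group_field) "group" else f]] <- unname(vals[slev])
  }
  sdf$n_cells <- n_cells
  ok <- n_cells >= min_cells
  if (!all(ok))
    warning(sprintf("dropping %d sample(s) with fewer than %d cells",
                    sum(!ok), min_cells))
  if (!any(ok)) stop("no samples survive the min_cells filter")
  structure(list(counts = agg[ok, , drop = FALSE],
                 samples = sdf[ok, , drop = FALSE]),
            class = "PseudobulkMatrix")
}

#' @export
print.PseudobulkMatrix <- function(x, ...) {
  cat(sprintf("PseudobulkMatrix: %d samples x %d genes (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Choose the differential-expression design
#'
#' Builds the full/reduced model for the likelihood-ratio test. Donor
#' identity is the preferred batch covariate (`~ donor_ID + group`); when
#' donor is confounded (collinear) with the biological group — every donor
#' contributing to exactly one group level, as in cross-region comparisons
#' — donor demographics are used instead (`~ donor_age + donor_sex +
#' group`). `mode = "auto"` applies that rule automatically.
#'
#' @param pb a `PseudobulkMatrix`.
#' @param mode `"auto"`, `"donor_covariate"` or `"demographic_covariate"`.
#' @return a `DEDesign`: list with `full_terms`, `reduced_terms`,
#'   `confounded`, `mode_used`.
#' @export
build_design <- function(pb, mode = c("auto", "donor_covariate",
                                      "demographic_covariate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pb, "PseudobulkMatrix"))
  if (length(unique(pb$samples$group)) < 2)
    stop("group must have at least 2 levels")
  confounded <- FALSE
  if ("donor_ID" %in% names(pb$samples)) {
    per_donor <- tapply(pb$samples$group, pb$samples$donor_ID,
                        function(g) length(unique(g)))
    confounded <- all(per_donor == 1)
  } else confounded <- TRUE
  use_demo <- switch(mode,
                     auto = confounded,
                     donor_covariate = FALSE,
                     demographic_covariate = TRUE)
  reduced <- if (use_demo) c("donor_age", "donor_sex") else "donor_ID"
  reduced <- intersect(reduced, names(pb$samples))
  structure(list(full_terms = c(reduced, "group"), reduced_terms = reduced,
                 confounded = confounded,
                 mode_used = if (use_demo) "demographic_covariate"
                 else "donor_covariate"),
            class = "DEDesign")
}

## covariate table with sensible types (numeric when fully parseable)
.de_model_frame <- function(samples, terms) {
  df <- data.frame(row.names = seq_len(nrow(samples)))
  for (f in terms) {
    v <- samples[[f]]
    num <- suppressWarnings(as.numeric(v))
    df[[f]] <- if (!anyNA(num)) num else factor(v)
  }
  df
}

## prune aliased columns, keeping track of which belong to the group term
.de_design_matrix <- function(df, terms) {
  if (!length(terms)) {
    X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, group_cols = integer(0)))
  }
  ff <- stats::reformulate(terms)
  X <- stats::model.matrix(ff, df)
  asn <- attr(X, "assign")
  gidx <- which(attr(stats::terms(ff), "term.labels") == "group")
  q <- qr(X)
  keep <- sort(q$pivot[seq_len(q$rank)])
  list(X = X[, keep, drop = FALSE],
       group_cols = which(asn[keep] == if (length(gidx)) gidx else -1))
}

## one NB GLM fit at fixed dispersion phi; returns loglik and CR adjustment
.nb_fit <- function(y, X, off, phi) {
  theta <- 1 / max(phi, 1e-10)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = MASS::negative.binomial(theta = theta, link = "log"),
    offset = off, control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- pmax(fit$fitted.values, 1e-10)
  ll <- sum(nb_loglik(y, mu, theta))
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(w))
  cr <- -0.5 * as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  list(coef = fit$coefficients, ll = ll, cr = cr,
       converged = fit$converged)
}

#' Negative-binomial GLM differential expression with likelihood-ratio test
#'
#' Per gene, fits `log mu_s = x_s' beta + log N_s` (N_s = sample library
#' size) under full and reduced designs and tests the group effect with
#' `LR = 2 (l_full - l_reduced)` against a chi-squared null with degrees
#' of freedom equal to the design rank difference. Gene-wise dispersions
#' are estimated by maximizing the Cox-Reid adjusted profile likelihood
#' and shrunk toward the common (all-gene) dispersion on the log scale
#' with weight `shrink_weight` on the gene-specific estimate. BH-adjusted
#' q-values are computed across tested genes. Non-converged fits are
#' flagged, not dropped.
#'
#' @param pb a `PseudobulkMatrix`.
#' @param design a [build_design()] result.
#' @param min_total genes with fewer total pseudobulk counts are not
#'   tested (reported with NA statistics).
#' @param shrink_weight weight of the gene-specific dispersion in the
#'   log-scale shrinkage average (default 0.25).
#' @param dispersion optional fixed dispersion overriding estimation
#'   (e.g. a value near 0 reproduces the Poisson GLM LRT).
#' @return `DEResult` data.frame: `gene`, `log2FC` (group effect),
#'   `LR`, `p_value`, `q_value`, `dispersion`, `converged`, `tested`.
#' @export
fit_nb_glm_lrt <- function(pb, design, min_total = 10, shrink_weight = 0.25,
                           dispersion = NULL) {
  stopifnot(inherits(pb, "PseudobulkMatrix"), inherits(design, "DEDesign"))
  Y <- pb$counts
  off <- log(pmax(rowSums(Y), 1))
  df_cov <- .de_model_frame(pb$samples, design$full_terms)
  full <- .de_design_matrix(df_cov, design$full_terms)
  red <- .de_design_matrix(df_cov, design$reduced_terms)
  df_test <- ncol(full$X) - ncol(red$X)
  if (df_test <= 0 || !length(full$group_cols))
    stop("singular design: group effect is not estimable")
  if (nrow(Y) < ncol(full$X) + 1)
    stop("fewer samples than the full design can support")

  tested <- colSums(Y) >= min_total
  genes_t <- which(tested)
  log_interval <- c(log(1e-6), log(10))

  if (is.null(dispersion)) {
    apl_one <- function(y, lphi) {
      f <- .nb_fit(y, full$X, off, exp(lphi))
      f$ll + f$cr
    }
    tag <- vapply(genes_t, function(j)
      stats::optimize(function(l) apl_one(Y[, j], l),
                      interval = log_interval, maximum = TRUE)$maximum,
      numeric(1))
    common <- stats::optimize(function(l)
      sum(vapply(genes_t, function(j) apl_one(Y[, j], l), numeric(1))),
      interval = log_interval, maximum = TRUE)$maximum
    lphi <- shrink_weight * tag + (1 - shrink_weight) * common
    phi <- stats::setNames(exp(lphi), colnames(Y)[genes_t])
  } else {
    phi <- stats::setNames(rep(dispersion, length(genes_t)),
                           colnames(Y)[genes_t])
  }

  out <- data.frame(gene = colnames(Y), log2FC = NA_real_, LR = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    dispersion = NA_real_, converged = NA,
                    tested = tested, stringsAsFactors = FALSE)
  gc_last <- full$group_cols[length(full$group_cols)]
  for (k in seq_along(genes_t)) {
    j <- genes_t[k]
    ph <- phi[k]
    ffit <- .nb_fit(Y[, j], full$X, off, ph)
    rfit <- .nb_fit(Y[, j], red$X, off, ph)
    lr <- max(0, 2 * (ffit$ll - rfit$ll))
    out$log2FC[j] <- ffit$coef[gc_last] / log(2)
    out$LR[j] <- lr
    out$p_value[j] <- stats::pchisq(lr, df = df_test, lower.tail = FALSE)
    out$dispersion[j] <- ph
    out$converged[j] <- ffit$converged && rfit$converged
  }
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  attr(out, "df_test") <- df_test
  attr(out, "design") <- design
  class(out) <- c("DEResult", class(out))
  out
}

#' Select significant differentially expressed genes
#'
#' Strict cutoffs: BH-adjusted p-value below `q_max` AND absolute log2
#' fold change above `min_abs_lfc` (a gene at exactly the fold-change
#' cutoff is excluded).
#'
#' @param res a `DEResult`.
#' @param q_max adjusted p-value cutoff (default 0.05).
#' @param min_abs_lfc absolute log2FC cutoff (default 0.5).
#' @return character vector of significant gene ids.
#' @export
significant_degs <- function(res, q_max = 0.05, min_abs_lfc = 0.5) {
  keep <- !is.na(res$q_value) & res$q_value < q_max &
    abs(res$log2FC) > min_abs_lfc
  res$gene[keep]
}
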