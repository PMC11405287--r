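#' Quality-control thresholds
#'
#' Defaults follow the atlas filtering rules: cells with fewer than 200
#' total counts, doublet scores above 0.3 or mitochondrial fractions above
#' 10% are removed (all strict inequalities: a cell at exactly 200 counts,
#' score 0.30 or fraction 0.10 is retained).
#'
#' @param min_counts minimum total counts (cells with fewer are removed).
#' @param max_doublet_score maximum doublet score (strictly above removed).
#' @param max_mito_fraction maximum mitochondrial fraction (strictly above
#'   removed).
#' @return a `QCThresholds` list.
#' @export
qc_thresholds <- function(min_counts = 200, max_doublet_score = 0.3,
                          max_mito_fraction = 0.10) {
  stopifnot(min_counts >= 0,
            max_doublet_score >= 0, max_doublet_score <= 1,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_counts = min_counts,
                 max_doublet_score = max_doublet_score,
                 max_mito_fraction = max_mito_fraction),
            class = "QCThresholds")
}

#' Per-cell mitochondrial count fraction
#'
#' Fraction of each cell's counts falling on mitochondrial genes,
#' identified by default via the `MT-`/`mt-` gene-id prefix
#' (case-insensitive) or by an explicit gene list.
#'
#' @param ds `AnnotatedDataset`.
#' @param mito_genes optional explicit character vector of mitochondrial
#'   gene ids; default: ids with prefix `MT-` (any case).
#' @return numeric vector of fractions in `[0, 1]`; cells with zero total
#'   counts get 0 and are flagged in the `zero_total` attribute.
#' @export
mito_fraction <- function(ds, mito_genes = NULL) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  gid <- colnames(ds$counts)
  mito <- if (is.null(mito_genes)) gid[grepl("^mt-", gid, ignore.case = TRUE)]
  else intersect(mito_genes, gid)
  tot <- Matrix::rowSums(ds$counts)
  mt <- if (length(mito)) Matrix::rowSums(ds$counts[, mito, drop = FALSE])
  else rep(0, length(tot))
  frac <- ifelse(tot > 0, mt / pmax(tot, 1), 0)
  names(frac) <- rownames(ds$counts)
  attr(frac, "zero_total") <- tot == 0
  frac
}

#' Simulated-doublet kNN score
#'
#' A simplified doublet scorer in the style of simulation-based detectors:
#' synthetic doublets are created by summing the raw counts of uniformly
#' sampled observed cell pairs; observed and simulated profiles are jointly
#' library-normalized (to 10,000 counts), log1p-transformed and reduced by
#' PCA; for each cell the fraction `f` of its `k` nearest neighbours that
#' are simulated doublets is corrected for the simulation ratio
#' `r = n_sim / n_cells`, giving `score = f / (f + r * (1 - f))`.
#' Deterministic given the seed.
#'
#' @param ds `AnnotatedDataset`.
#' @param n_sim number of simulated doublets (default: one per cell).
#' @param n_pcs number of principal components.
#' @param k neighbourhood size (default `round(0.5 * sqrt(n_cells))`).
#' @param seed integer seed.
#' @param return_sim also return the scores of the simulated doublets.
#' @return numeric vector of per-cell scores in `[0, 1]`; when
#'   `return_sim = TRUE` a list with elements `observed` and `simulated`.
#' @export
doublet_score <- function(ds, n_sim = NULL, n_pcs = 30, k = NULL, seed = 0,
                          return_sim = FALSE) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  n <- nrow(ds$counts)
  if (is.null(n_sim)) n_sim <- n
  if (is.null(k)) k <- max(1L, round(0.5 * sqrt(n)))
  if (n < 2L * k) stop("too few cells for the requested neighbourhood size")
  if (n_sim == 0) {
    out <- stats::setNames(rep(0, n), rownames(ds$counts))
    return(if (return_sim) list(observed = out, simulated = numeric(0)) else out)
  }
  set.seed(seed)
  i1 <- sample.int(n, n_sim, replace = TRUE)
  i2 <- sample.int(n, n_sim, replace = TRUE)
  bump <- i1 == i2
  i2[bump] <- (i2[bump] %% n) + 1L
  sim <- ds$counts[i1, , drop = FALSE] + ds$counts[i2, , drop = FALSE]
  joint <- rbind(ds$counts, sim)
  E <- normalize_counts(joint, log1p = TRUE)
  Ed <- as.matrix(E)
  n_pcs <- min(n_pcs, ncol(Ed) - 1L, nrow(Ed) - 1L)
  pcs <- stats::prcomp(Ed, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  is_sim <- c(rep(FALSE, n), rep(TRUE, n_sim))
  ## brute-force kNN over the joint embedding, blockwise
  nj <- nrow(pcs)
  sq <- rowSums(pcs^2)
  f <- numeric(nj)
  bs <- 1024L
  for (start in seq(1L, nj, by = bs)) {
    idx <- start:min(start + bs - 1L, nj)
    d2 <- outer(sq[idx], sq, "+") - 2 * pcs[idx, , drop = FALSE] %*% t(pcs)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    for (r in seq_along(idx)) {
      nb <- order(d2[r, ])[seq_len(k)]
      f[idx[r]] <- mean(is_sim[nb])
    }
  }
  r <- n_sim / n
  score <- f / (f + r * (1 - f))
  score[f == 0] <- 0
  obs <- stats::setNames(score[!is_sim], rownames(ds$counts))
  if (return_sim) list(observed = obs, simulated = score[is_sim]) else obs
}

#' Apply the atlas quality-control filter
#'
#' Cells carrying a published annotation (a value other than `"N/A"`/empty
#' in `published_label_field`) are retained unconditionally and skipped for
#' QC — except cells labeled `"doublet"`, which are removed. Unlabeled
#' cells are retained iff total counts >= `min_counts` AND doublet score
#' <= `max_doublet_score` AND mitochondrial fraction <=
#' `max_mito_fraction`.
#'
#' @param ds `AnnotatedDataset`.
#' @param thresholds a [qc_thresholds()].
#' @param published_label_field metadata column holding published labels
#'   (default `"original_name"`); set to `NULL` to treat all cells as
#'   unlabeled.
#' @param mito_genes optional explicit mitochondrial gene list.
#' @param seed seed for the doublet scorer when scores must be computed.
#' @param compute_doublet compute doublet scores when the dataset carries
#'   none; if `FALSE` and scores are missing, an error is raised.
#' @return list with `dataset` (the filtered `AnnotatedDataset`) and
#'   `report` (a `QCReport`: per-cell flags plus per-criterion counts;
#'   `removed + retained + skipped` equals the input cell count).
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds(),
                     published_label_field = "original_name",
                     mito_genes = NULL, seed = 0, compute_doublet = TRUE) {
  stopifnot(inherits(ds, "AnnotatedDataset"),
            inherits(thresholds, "QCThresholds"))
  n <- nrow(ds$counts)
  published <- rep(NA_character_, n)
  if (!is.null(published_label_field) &&
      published_label_field %in% names(ds$metadata)) {
    published <- as.character(ds$metadata[[published_label_field]])
    published[published %in% c("", "N/A")] <- NA_character_
  }
  has_label <- !is.na(published)
  is_doublet_label <- has_label & tolower(published) == "doublet"
  skipped <- has_label & !is_doublet_label

  total <- Matrix::rowSums(ds$counts)
  mito <- mito_fraction(ds, mito_genes)
  dscore <- ds$doublet_score
  needs_filter <- !has_label
  if (is.null(dscore)) {
    if (any(needs_filter)) {
      if (!compute_doublet)
        stop("doublet scores missing and compute_doublet = FALSE")
      dscore <- doublet_score(ds, seed = seed)
    } else dscore <- rep(0, n)
  }

  pass_counts <- total >= thresholds$min_counts
  pass_doublet <- dscore <= thresholds$max_doublet_score
  pass_mito <- mito <= thresholds$max_mito_fraction
  retained_unlabeled <- needs_filter & pass_counts & pass_doublet & pass_mito
  keep <- skipped | retained_unlabeled

  flags <- data.frame(
    cell_ID = rownames(ds$counts),
    published_label = published,
    skipped_qc = skipped,
    removed_doublet_label = is_doublet_label,
    pass_counts = pass_counts, pass_doublet = pass_doublet,
    pass_mito = pass_mito, retained = keep,
    stringsAsFactors = FALSE)
  report <- structure(list(
    flags = flags,
    n_input = n,
    n_skipped = sum(skipped),
    n_retained = sum(retained_unlabeled),
    n_removed = sum(!keep),
    n_removed_doublet_label = sum(is_doublet_label),
    n_removed_counts = sum(needs_filter & !pass_counts),
    n_removed_doublet_score = sum(needs_filter & !pass_doublet),
    n_removed_mito = sum(needs_filter & !pass_mito),
    thresholds = thresholds), class = "QCReport")
  list(dataset = subset_dataset(ds, cells = keep), report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0(
    "QCReport: %d cells in; %d skipped (published label), %d passed filters,",
    " %d removed\n  removed: %d doublet-labeled, %d low counts,",
    " %d doublet score, %d mito fraction\n"),
    x$n_input, x$n_skipped, x$n_retained, x$n_removed,
    x$n_removed_doublet_label, x$n_removed_counts,
    x$n_removed_doublet_score, x$n_removed_mito))
  invisible(x)
}
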