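#' Library-size normalization
#'
#' Scales each cell to a fixed total (default 10,000 counts) and optionally
#' applies `log1p` — the ecosystem-standard normalization used for marker
#' testing, variable-gene selection and encoder inputs throughout the
#' toolkit.
#'
#' @param counts cells x genes (sparse) count matrix.
#' @param scale_to per-cell target total.
#' @param log1p apply `log(1 + x)` after scaling.
#' @return sparse matrix of normalized values.
#' @export
normalize_counts <- function(counts, scale_to = 1e4, log1p = TRUE) {
  tot <- Matrix::rowSums(counts)
  fac <- ifelse(tot > 0, scale_to / tot, 0)
  out <- Matrix::Diagonal(x = fac) %*% counts
  dimnames(out) <- dimnames(counts)
  if (log1p) out@x <- log1p(out@x)
  as(out, "CsparseMatrix")
}

## ranks + tie correction term sum(t^3 - t) per column of a dense matrix
.rank_with_ties <- function(X) {
  n <- nrow(X)
  R <- matrix(0, n, ncol(X))
  tiesum <- numeric(ncol(X))
  has_ties <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    R[, j] <- rank(x)
    t <- tabulate(match(x, unique(x)))
    t <- t[t > 1]
    if (length(t)) {
      tiesum[j] <- sum(t^3 - t)
      has_ties[j] <- TRUE
    }
  }
  list(rank = R, tiesum = tiesum, has_ties = has_ties)
}

## two-sided rank-sum p-values for one group vs rest, vectorized over genes;
## exact (no ties, n <= 50) matches stats::wilcox.test's exact path, else a
## tie-corrected normal approximation with continuity correction
.wilcox_p <- function(W, n1, n2, tiesum, has_ties) {
  N <- n1 + n2
  p <- numeric(length(W))
  exact <- !has_ties & N <= 50
  if (any(exact)) {
    w <- W[exact]
    up <- w > n1 * n2 / 2
    pe <- ifelse(up,
                 stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE),
                 stats::pwilcox(w, n1, n2))
    p[exact] <- pmin(2 * pe, 1)
  }
  if (any(!exact)) {
    w <- W[!exact]
    z <- w - n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tiesum[!exact] / (N * (N - 1)))
    sigma <- sqrt(pmax(sigma2, 0))
    zc <- z - sign(z) * 0.5
    pn <- ifelse(sigma > 0,
                 2 * stats::pnorm(-abs(zc) / sigma),
                 1)
    p[!exact] <- pmin(pn, 1)
  }
  p
}

#' One-vs-rest Wilcoxon marker statistics
#'
#' For every group, a two-sided Wilcoxon rank-sum test of each gene's
#' log1p library-normalized expression (cells scaled to 10,000 counts) in
#' the group against all other cells, with Benjamini-Hochberg adjustment
#' within each group across genes. Log fold changes are computed on the
#' normalized (non-log) scale: `log2FC = log2((mean_in + eps) /
#' (mean_out + eps))` with `eps = 1e-9`. Small tie-free comparisons use the
#' exact rank-sum distribution; larger or tied ones use the tie-corrected
#' normal approximation with continuity correction (matching
#' [stats::wilcox.test()]'s behavior).
#'
#' @param ds `AnnotatedDataset` with raw counts.
#' @param groups per-cell group labels, or the name of a metadata column.
#' @return `MarkerTable` data.frame with columns `group`, `gene`, `log2FC`,
#'   `p_value`, `q_value`, `frac_in`, `frac_out`.
#' @export
rank_markers_wilcoxon <- function(ds, groups) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  if (length(groups) == 1L && is.character(groups))
    groups <- ds$metadata[[groups]]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(ds$counts))
  keep <- !is.na(groups)
  cnt <- ds$counts[keep, , drop = FALSE]
  groups <- groups[keep]
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 cells")

  E <- normalize_counts(cnt, log1p = FALSE)  # ranks invariant to log1p
  Ed <- as.matrix(E)
  rk <- .rank_with_ties(Ed)
  N <- nrow(Ed)
  detected <- cnt > 0
  eps <- 1e-9
  res <- lapply(glev, function(g) {
    ing <- groups == g
    n1 <- sum(ing); n2 <- N - n1
    R1 <- colSums(rk$rank[ing, , drop = FALSE])
    W <- R1 - n1 * (n1 + 1) / 2
    p <- .wilcox_p(W, n1, n2, rk$tiesum, rk$has_ties)
    mi <- colMeans(Ed[ing, , drop = FALSE])
    mo <- colMeans(Ed[!ing, , drop = FALSE])
    data.frame(group = g, gene = colnames(cnt),
               log2FC = log2((mi + eps) / (mo + eps)),
               p_value = p,
               q_value = stats::p.adjust(p, method = "BH"),
               frac_in = Matrix::colSums(detected[ing, , drop = FALSE]) / n1,
               frac_out = Matrix::colSums(detected[!ing, , drop = FALSE]) / n2,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Build a feature panel from marker statistics
#'
#' For each group, the top `n_per_type` genes ranked by adjusted p-value
#' ascending, then |log2FC| descending, then gene id ascending; the panel
#' is the deduplicated union (first occurrence preserved, groups processed
#' in their order of appearance in the table). Groups with fewer genes than
#' requested contribute all of theirs with a warning.
#'
#' @param mt a `MarkerTable` from [rank_markers_wilcoxon()].
#' @param n_per_type feature genes selected per group (default 200, the
#'   atlas convention for per-type feature panels).
#' @return a `FeaturePanel`: list with `genes` (ordered unique gene ids)
#'   and `provenance` (named list gene -> contributing groups).
#' @export
select_feature_genes <- function(mt, n_per_type = 200) {
  stopifnot(is.data.frame(mt), nrow(mt) > 0)
  glev <- unique(mt$group)
  per_group <- lapply(glev, function(g) {
    sub <- mt[mt$group == g, , drop = FALSE]
    ord <- order(sub$q_value, -abs(sub$log2FC), sub$gene)
    if (nrow(sub) < n_per_type)
      warning(sprintf("group '%s' has only %d genes (< %d requested)",
                      g, nrow(sub), n_per_type))
    sub$gene[ord][seq_len(min(n_per_type, nrow(sub)))]
  })
  names(per_group) <- glev
  genes <- unique(unlist(per_group, use.names = FALSE))
  provenance <- lapply(stats::setNames(genes, genes), function(g)
    glev[vapply(per_group, function(x) g %in% x, logical(1))])
  structure(list(genes = genes, provenance = provenance),
            class = "FeaturePanel")
}

#' @export
print.FeaturePanel <- function(x, ...) {
  cat(sprintf("FeaturePanel: %d genes from %d group(s)\n", length(x$genes),
              length(unique(unlist(x$provenance)))))
  invisible(x)
}

#' Dispersion-based highly variable gene selection
#'
#' Ranks genes by normalized dispersion of log1p library-normalized
#' expression: per-gene dispersion `var/mean` is z-scored within 20
#' equal-frequency bins of the gene mean, and the top `n` genes are
#' returned (ties broken by gene id). Deterministic and invariant to cell
#' order.
#'
#' @param ds `AnnotatedDataset`.
#' @param n number of genes to select.
#' @param n_bins number of mean bins.
#' @return character vector of `n` gene ids.
#' @export
select_hvg <- function(ds, n = 2000, n_bins = 20) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  if (n > ncol(ds$counts)) stop("n exceeds the gene count")
  E <- normalize_counts(ds$counts, log1p = TRUE)
  m <- Matrix::colSums(E) / nrow(E)
  v <- Matrix::colSums(E^2) / nrow(E) - m^2
  v <- v * nrow(E) / max(1, (nrow(E) - 1))
  d <- ifelse(m > 0, v / m, 0)
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) cut(m, breaks = br, include.lowest = TRUE)
  else factor(rep(1, length(m)))
  mu_b <- tapply(d, bin, mean)[bin]
  sd_b <- tapply(d, bin, stats::sd)[bin]
  nd <- ifelse(!is.na(sd_b) & sd_b > 0, (d - mu_b) / sd_b, 0)
  ord <- order(-nd, colnames(ds$counts))
  colnames(ds$counts)[ord][seq_len(n)]
}
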