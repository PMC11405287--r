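#' The conserved cross-species proliferative (NPC) marker module
#'
#' Eight markers of proliferating neural progenitors conserved between
#' human and mouse: TOP2A, HMGB2, PBK, UBE2C, RRM2, CDCA3, CCNA2 and TPX.
#' The eighth symbol is kept verbatim; `alias_tpx2 = TRUE` maps it to the
#' standard symbol TPX2 for panels that use that name.
#'
#' @param alias_tpx2 replace `"TPX"` with `"TPX2"`.
#' @param name module name.
#' @return a `GeneModule`: list with `name` and `genes`.
#' @export
npc_gene_module <- function(alias_tpx2 = FALSE, name = "NPC") {
  genes <- c("TOP2A", "HMGB2", "PBK", "UBE2C", "RRM2", "CDCA3", "CCNA2",
             if (alias_tpx2) "TPX2" else "TPX")
  gene_module(name, genes)
}

#' Construct a gene module
#'
#' @param name module name.
#' @param genes non-empty character vector of unique gene ids.
#' @return a `GeneModule` list.
#' @export
gene_module <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene module must be non-empty")
  if (anyDuplicated(genes)) stop("duplicate genes in module")
  structure(list(name = name, genes = genes), class = "GeneModule")
}

#' Gene-module co-expression score
#'
#' Per-cell count of module genes detected with at least one UMI:
#' `score_c = sum_g 1[count_{c,g} >= 1]`. Module genes absent from the
#' matrix contribute 0 (with a warning).
#'
#' @param ds `AnnotatedDataset` with raw counts.
#' @param module a `GeneModule` (default: the NPC module).
#' @return integer vector of per-cell scores in `[0, length(module$genes)]`.
#' @export
npc_module_score <- function(ds, module = npc_gene_module()) {
  stopifnot(inherits(ds, "AnnotatedDataset"), inherits(module, "GeneModule"))
  present <- intersect(module$genes, colnames(ds$counts))
  if (length(present) < length(module$genes))
    warning(sprintf("%d module gene(s) absent from the matrix: %s",
                    length(module$genes) - length(present),
                    paste(setdiff(module$genes, present), collapse = ", ")))
  if (!length(present))
    return(stats::setNames(rep(0L, nrow(ds$counts)), rownames(ds$counts)))
  sub <- ds$counts[, present, drop = FALSE]
  score <- as.integer(Matrix::rowSums(sub >= 1))
  stats::setNames(score, rownames(ds$counts))
}

#' Call putative proliferative cells from module scores
#'
#' A cell is flagged putative when its module score reaches the cutoff
#' (default: at least 3 of the module markers detected).
#'
#' @param scores integer module scores.
#' @param threshold minimum score (inclusive).
#' @return logical vector aligned to `scores`.
#' @export
classify_putative_npc <- function(scores, threshold = 3) {
  stopifnot(is.numeric(scores), threshold >= 0)
  scores >= threshold
}

#' Fraction of cells expressing each module gene, per cell type
#'
#' @param ds `AnnotatedDataset` with raw counts.
#' @param labels per-cell type labels aligned to the dataset.
#' @param module a `GeneModule`.
#' @return data.frame with columns `cell_type`, `gene`, `fraction`
#'   (fraction of the type's cells with at least one UMI of the gene;
#'   genes absent from the matrix get 0).
#' @export
module_fraction_by_type <- function(ds, labels, module = npc_gene_module()) {
  stopifnot(inherits(ds, "AnnotatedDataset"),
            length(labels) == nrow(ds$counts))
  types <- sort(unique(as.character(labels)))
  out <- expand.grid(cell_type = types, gene = module$genes,
                     stringsAsFactors = FALSE)
  out$fraction <- 0
  present <- intersect(module$genes, colnames(ds$counts))
  for (ty in types) {
    i <- which(labels == ty)
    if (!length(i)) stop("empty cell type: ", ty)
    fr <- Matrix::colSums(ds$counts[i, present, drop = FALSE] >= 1) / length(i)
    out$fraction[out$cell_type == ty & out$gene %in% present] <-
      fr[match(out$gene[out$cell_type == ty & out$gene %in% present], present)]
  }
  out
}

#' Relative score distribution against a reference population
#'
#' For each observed score value, the number of cells with that score as a
#' percentage of a reference population (by default the putative cells,
#' score >= 3), mirroring how rare proliferative populations are profiled
#' against the putative-NPC denominator.
#'
#' @param scores integer module scores.
#' @param reference_subset logical/integer index defining the denominator
#'   population; default: cells with `scores >= threshold`.
#' @param threshold default-denominator cutoff.
#' @return data.frame with columns `score` and `percentage`.
#' @export
score_distribution <- function(scores, reference_subset = NULL, threshold = 3) {
  stopifnot(is.numeric(scores))
  if (is.null(reference_subset)) reference_subset <- scores >= threshold
  n_ref <- if (is.logical(reference_subset)) sum(reference_subset) else
    length(reference_subset)
  if (n_ref == 0) stop("empty reference population (zero denominator)")
  tab <- table(scores)
  data.frame(score = as.numeric(names(tab)),
             percentage = 100 * as.numeric(tab) / n_ref)
}

#' Silhouette score of a covariate grouping within each cell type
#'
#' Measures how strongly a covariate (e.g. sequencing method, donor sex)
#' separates cells inside each cell type in a latent embedding. For each
#' cell, `a` is the mean Euclidean distance to the other cells of its
#' covariate group (excluding itself) and `b` the smallest mean distance to
#' any other group; the silhouette coefficient is `(b - a) / max(a, b)`.
#' Cells in singleton groups get coefficient 0, and a cell type with fewer
#' than two covariate groups has no defined score (NA). Scores near 0 mean
#' the covariate does not structure the embedding (good mixing).
#'
#' @param latent cells x D numeric embedding.
#' @param cell_type_labels per-cell cell-type labels.
#' @param covariate_labels per-cell covariate labels.
#' @return data.frame with columns `cell_type`, `silhouette` (mean
#'   coefficient over the type's cells, NA when undefined), `n_cells`,
#'   `n_groups`.
#' @export
silhouette_covariate <- function(latent, cell_type_labels, covariate_labels) {
  latent <- as.matrix(latent)
  stopifnot(nrow(latent) == length(cell_type_labels),
            nrow(latent) == length(covariate_labels))
  types <- sort(unique(as.character(cell_type_labels)))
  res <- lapply(types, function(ty) {
    i <- which(cell_type_labels == ty)
    grp <- as.character(covariate_labels[i])
    ng <- length(unique(grp))
    if (ng < 2)
      return(data.frame(cell_type = ty, silhouette = NA_real_,
                        n_cells = length(i), n_groups = ng))
    d <- as.matrix(stats::dist(latent[i, , drop = FALSE]))
    s <- vapply(seq_along(i), function(j) {
      own <- which(grp == grp[j])
      if (length(own) == 1L) return(0)  # singleton group convention
      a <- sum(d[j, own]) / (length(own) - 1L)
      b <- min(vapply(setdiff(unique(grp), grp[j]), function(g)
        mean(d[j, grp == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    data.frame(cell_type = ty, silhouette = mean(s),
               n_cells = length(i), n_groups = ng)
  })
  do.call(rbind, res)
}
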