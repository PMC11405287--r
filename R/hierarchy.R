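#' Train a two-level hierarchical annotator
#'
#' Level 1 trains one latent classifier over the hierarchy's classes using
#' a feature panel of the top marker genes per class (Wilcoxon one-vs-rest,
#' `n_per_type` genes each). For every class with at least two subtypes
#' each holding `min_cells_per_subtype` cells, a level-2 model is trained
#' on the class's cells with a subtype-level panel; classes failing the
#' criterion get no level-2 model and pass their label through.
#'
#' @param ref `AnnotatedDataset` carrying `labels1`/`labels2` consistent
#'   with `tree` (NA-labeled cells participate unsupervised).
#' @param tree a [label_tree()].
#' @param cfg [latent_model_config()] used for all models.
#' @param n_per_type feature genes per type for panel construction.
#' @param min_cells_per_subtype minimum cells per subtype for level-2
#'   training (default 20).
#' @return a `HierarchicalAnnotator`: level-1 model, per-class level-2
#'   models, the tree and the panels used.
#' @export
train_hierarchy <- function(ref, tree, cfg = latent_model_config(),
                            n_per_type = 200, min_cells_per_subtype = 20) {
  stopifnot(inherits(ref, "AnnotatedDataset"), inherits(tree, "LabelTree"))
  if (is.null(ref$labels1) || is.null(ref$labels2))
    stop("reference must carry level-1 and level-2 labels")
  check_labels_against_tree(tree, ref$labels1, ref$labels2)

  labeled <- !is.na(ref$labels1)
  mt1 <- rank_markers_wilcoxon(ref, ref$labels1)
  panel1 <- select_feature_genes(mt1, n_per_type = n_per_type)
  level1 <- fit_latent_model(ref, ref$labels1, panel1, cfg)

  level2 <- list()
  for (cl in names(tree$classes)) {
    subs <- tree$classes[[cl]]
    if (length(subs) < 2) next
    in_class <- labeled & ref$labels1 == cl
    counts <- table(factor(ref$labels2[in_class], levels = subs))
    if (any(counts < min_cells_per_subtype)) {
      warning(sprintf(
        "class '%s': subtype(s) below %d cells; no level-2 model trained",
        cl, min_cells_per_subtype))
      next
    }
    sub_ds <- subset_dataset(ref, cells = which(in_class))
    mt2 <- rank_markers_wilcoxon(sub_ds, sub_ds$labels2)
    panel2 <- select_feature_genes(mt2, n_per_type = n_per_type)
    level2[[cl]] <- fit_latent_model(sub_ds, sub_ds$labels2, panel2, cfg)
  }
  structure(list(level1 = level1, level2 = level2, tree = tree,
                 min_cells_per_subtype = min_cells_per_subtype),
            class = "HierarchicalAnnotator")
}

#' @export
print.HierarchicalAnnotator <- function(x, ...) {
  cat(sprintf("HierarchicalAnnotator: %d classes, %d level-2 models\n",
              length(x$level1$classes), length(x$level2)))
  invisible(x)
}

#' Predict two-level labels for a dataset
#'
#' Cells are first classified at level 1, then each cell is routed to its
#' predicted class's level-2 model when one exists. Classes without a
#' level-2 model yield the class's single subtype when the tree defines
#' exactly one, and the class label itself otherwise. Every cell is scored
#' by exactly one level-2 model.
#'
#' @param annot a `HierarchicalAnnotator`.
#' @param ds `AnnotatedDataset`.
#' @return data.frame with columns `cell_ID`, `level1`, `level2`.
#' @export
predict_hierarchy <- function(annot, ds) {
  stopifnot(inherits(annot, "HierarchicalAnnotator"),
            inherits(ds, "AnnotatedDataset"))
  l1 <- classify(annot$level1, ds)$labels
  l2 <- l1
  for (cl in unique(l1)) {
    i <- which(l1 == cl)
    if (cl %in% names(annot$level2)) {
      sub <- subset_dataset(ds, cells = i)
      l2[i] <- classify(annot$level2[[cl]], sub)$labels
    } else if (cl %in% names(annot$tree$classes) &&
               length(annot$tree$classes[[cl]]) == 1L) {
      l2[i] <- annot$tree$classes[[cl]]
    }
  }
  data.frame(cell_ID = rownames(ds$counts), level1 = unname(l1),
             level2 = unname(l2), stringsAsFactors = FALSE)
}

#' Validation metrics of a trained hierarchy
#'
#' Recomputes, on the stratified validation split held out inside each
#' model, the level-1 per-type recall (row-normalized confusion diagonal),
#' its macro average and minimum, and the overall level-2 validation
#' accuracy pooled over all class models.
#'
#' @param annot a `HierarchicalAnnotator`.
#' @param ref the reference `AnnotatedDataset` the hierarchy was trained on.
#' @return list with `level1_per_type` (named recall vector),
#'   `level1_macro`, `level1_min`, `level2_accuracy`, `n_val_level1`,
#'   `n_val_level2`.
#' @export
evaluate_hierarchy_validation <- function(annot, ref) {
  stopifnot(inherits(annot, "HierarchicalAnnotator"))
  m1 <- annot$level1
  vi <- match(m1$val_cells, rownames(ref$counts))
  vds <- subset_dataset(ref, cells = vi)
  pred1 <- classify(m1, vds)$labels
  conf <- evaluate_confusion(ref$labels1[vi], pred1)
  n2 <- 0L; correct2 <- 0L
  for (cl in names(annot$level2)) {
    m2 <- annot$level2[[cl]]
    vi2 <- match(m2$val_cells, rownames(ref$counts))
    p2 <- classify(m2, subset_dataset(ref, cells = vi2))$labels
    correct2 <- correct2 + sum(p2 == ref$labels2[vi2])
    n2 <- n2 + length(vi2)
  }
  list(level1_per_type = conf$per_type_accuracy,
       level1_macro = conf$mean_accuracy,
       level1_min = min(conf$per_type_accuracy),
       level2_accuracy = if (n2 > 0) correct2 / n2 else NA_real_,
       n_val_level1 = length(vi), n_val_level2 = n2)
}

#' Consensus label from votes of multiple annotation methods
#'
#' Per cell, the label predicted by more than half of the voting methods;
#' if no label reaches a strict majority the cell is labeled
#' `"unannotated"`. Missing votes (NA) are treated as abstentions: the
#' majority is taken over the methods that did vote for that cell, and a
#' cell with no votes at all is `"unannotated"`.
#'
#' @param vt cells x methods matrix or data.frame of label strings
#'   (a `cell_ID` column, if present, is used for names).
#' @return named character vector of consensus labels.
#' @export
consensus_vote <- function(vt) {
  ids <- NULL
  if (is.data.frame(vt) && "cell_ID" %in% names(vt)) {
    ids <- vt$cell_ID
    vt <- vt[, setdiff(names(vt), "cell_ID"), drop = FALSE]
  }
  vt <- as.matrix(vt)
  if (ncol(vt) < 1) stop("need at least one voting method")
  if (anyDuplicated(colnames(vt))) stop("method names must be unique")
  out <- apply(vt, 1, function(v) {
    v <- v[!is.na(v) & v != ""]
    if (!length(v)) return("unannotated")
    tab <- table(v)
    top <- which.max(tab)
    if (tab[top] > length(v) / 2) names(tab)[top] else "unannotated"
  })
  names(out) <- if (!is.null(ids)) ids else rownames(vt)
  out
}

#' Confusion matrix and per-type accuracy
#'
#' Rows are reported (true) labels, columns predicted labels; rows are
#' normalized to proportions so the diagonal holds per-type accuracy
#' (recall). Mean accuracy is the unweighted (macro) average over types.
#'
#' @param true_labels,pred_labels aligned label vectors.
#' @return list with `matrix` (row-normalized), `counts` (raw
#'   cross-tabulation), `per_type_accuracy` and `mean_accuracy`.
#' @export
evaluate_confusion <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  tl <- as.character(true_labels); pl <- as.character(pred_labels)
  rows <- sort(unique(tl))
  cols <- sort(unique(c(tl, pl)))
  counts <- table(factor(tl, levels = rows), factor(pl, levels = cols))
  counts <- matrix(counts, nrow = length(rows),
                   dimnames = list(reported = rows, predicted = cols))
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs > 0, rs, 1)
  per_type <- vapply(rows, function(r) norm[r, r], numeric(1))
  list(matrix = norm, counts = counts, per_type_accuracy = per_type,
       mean_accuracy = mean(per_type))
}

#' Persist / restore a hierarchical annotator
#'
#' Directory layout: `tree.json`, `level1/` and `level2/<class>/` model
#' directories (see [save_latent_model()]).
#'
#' @param annot a `HierarchicalAnnotator`.
#' @param dir target directory.
#' @return `load_hierarchy` returns the restored annotator.
#' @export
save_hierarchy <- function(annot, dir) {
  stopifnot(inherits(annot, "HierarchicalAnnotator"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_tree(annot$tree, file.path(dir, "tree.json"))
  jsonlite::write_json(list(min_cells_per_subtype =
                              annot$min_cells_per_subtype),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  save_latent_model(annot$level1, file.path(dir, "level1"))
  for (cl in names(annot$level2))
    save_latent_model(annot$level2[[cl]], file.path(dir, "level2", cl))
  invisible(dir)
}

#' @rdname save_hierarchy
#' @export
load_hierarchy <- function(dir) {
  tree <- read_label_tree(file.path(dir, "tree.json"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  l2dir <- file.path(dir, "level2")
  level2 <- list()
  if (dir.exists(l2dir))
    for (cl in list.dirs(l2dir, recursive = FALSE, full.names = FALSE))
      level2[[cl]] <- load_latent_model(file.path(l2dir, cl))
  structure(list(level1 = load_latent_model(file.path(dir, "level1")),
                 level2 = level2, tree = tree,
                 min_cells_per_subtype = meta$min_cells_per_subtype),
            class = "HierarchicalAnnotator")
}
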