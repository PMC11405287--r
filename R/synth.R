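#' Configuration for the synthetic atlas generator
#'
#' Defines the statistical structure the annotation and DE machinery assume:
#' a two-level hierarchy of cell types with class- and subtype-specific
#' marker genes elevated by a multiplicative fold change, negative-binomial
#' counts with log-normal library sizes and per-sample (batch) gene factors,
#' doublets formed by summing random cell pairs, a mitochondrial gene block
#' with controlled per-cell fractions, and an optional rare proliferative
#' (NPC-like) population co-expressing a marker module.
#'
#' Defaults describe a well-separated desk-scale atlas: 10 classes x 3
#' subtypes, 200 cells per subtype, 3,000 genes with 20 class markers and 20
#' subtype markers per type at 8-fold elevation, NB dispersion 0.1, 6
#' samples with log-normal batch factors (sd 0.1), 5% doublets, 13
#' mitochondrial genes at 1-8% per-cell fractions, and library sizes
#' log-normal around 2,500 counts.
#'
#' @param tree `LabelTree` (default: 10 classes `T01..T10`, subtypes
#'   `T01a/T01b/T01c`, ...).
#' @param n_cells_per_subtype singlet cells simulated per subtype.
#' @param n_genes total gene count, including marker/mito/module blocks.
#' @param markers_per_type marker genes per class and per subtype.
#' @param marker_fold_change multiplicative elevation of a type's markers.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param n_samples number of samples (batches); cells assigned uniformly.
#' @param batch_effect_sd sd of log-normal gene x sample batch factors.
#' @param doublet_rate fraction of extra cells simulated as pair-sums.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library size parameters.
#' @param mito_gene_count,mito_fraction_range mitochondrial gene block size
#'   and per-cell fraction range (uniform).
#' @param npc_module_genes gene names of the proliferative marker module.
#' @param npc_fraction if > 0, a rare extra subtype `"NPC"` (own class) of
#'   this relative size co-expresses the module genes.
#' @param group_effect optional list(`n_genes`, `log2fc`) of group-affected
#'   genes used by [simulate_de_cohort()].
#' @param seed integer seed; all randomness derives from it.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(tree = NULL,
                         n_cells_per_subtype = 200,
                         n_genes = 3000,
                         markers_per_type = 20,
                         marker_fold_change = 8,
                         nb_dispersion = 0.1,
                         n_samples = 6,
                         batch_effect_sd = 0.1,
                         doublet_rate = 0.05,
                         lib_size_meanlog = log(2500),
                         lib_size_sdlog = 0.35,
                         mito_gene_count = 13,
                         mito_fraction_range = c(0.01, 0.08),
                         npc_module_genes = npc_gene_module()$genes,
                         npc_fraction = 0,
                         group_effect = NULL,
                         seed = 0) {
  if (is.null(tree)) {
    cls <- sprintf("T%02d", 1:10)
    tree <- label_tree(stats::setNames(
      lapply(cls, function(k) paste0(k, c("a", "b", "c"))), cls))
  }
  stopifnot(inherits(tree, "LabelTree"),
            n_cells_per_subtype >= 1, n_genes >= 1,
            marker_fold_change > 0, nb_dispersion > 0,
            doublet_rate >= 0, doublet_rate <= 1,
            npc_fraction >= 0, npc_fraction <= 1,
            all(mito_fraction_range >= 0), all(mito_fraction_range <= 1))
  cfg <- list(tree = tree, n_cells_per_subtype = n_cells_per_subtype,
              n_genes = n_genes, markers_per_type = markers_per_type,
              marker_fold_change = marker_fold_change,
              nb_dispersion = nb_dispersion, n_samples = n_samples,
              batch_effect_sd = batch_effect_sd, doublet_rate = doublet_rate,
              lib_size_meanlog = lib_size_meanlog,
              lib_size_sdlog = lib_size_sdlog,
              mito_gene_count = mito_gene_count,
              mito_fraction_range = mito_fraction_range,
              npc_module_genes = npc_module_genes,
              npc_fraction = npc_fraction,
              group_effect = group_effect, seed = seed)
  class(cfg) <- "SynthConfig"
  cfg
}

## NB draws row-block-wise: mean matrix rows = cells.
.rnbinom_matrix <- function(mu, size) {
  n <- length(mu)
  matrix(stats::rnbinom(n, mu = as.vector(mu), size = size),
         nrow = nrow(mu), ncol = ncol(mu))
}

#' Simulate a hierarchically structured synthetic atlas
#'
#' Generates counts `x_{cg} ~ NB(mean = l_c * p_{g,t(c)} * b_{g,s(c)},
#' dispersion)`: `p` are type-specific gene proportions in which the type's
#' class and subtype markers are elevated by the configured fold change,
#' `b` are log-normal gene x sample batch factors and `l_c` log-normal
#' library sizes. Mitochondrial genes receive a per-cell share drawn from
#' the configured fraction range; doublets are raw count sums of two random
#' singlets and are labeled `"doublet"` in the published-annotation column;
#' an optional rare NPC-like population expresses the module genes at high
#' level. Fully reproducible given the config seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `dataset` (an `AnnotatedDataset` whose metadata carries
#'   curated fields and whose `original_name`/`original_name2` columns hold
#'   the published labels, `"doublet"` for doublets) and `truth` (marker
#'   assignments, per-cell type labels, doublet flags, generative
#'   parameters).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  classes <- names(tree$classes)
  subtypes <- unlist(tree$classes, use.names = FALSE)
  sub2class <- rep(classes, vapply(tree$classes, length, integer(1)))
  names(sub2class) <- subtypes

  n_mito <- cfg$mito_gene_count
  module <- if (cfg$npc_fraction > 0) cfg$npc_module_genes else character(0)
  n_marker_slots <- cfg$markers_per_type * (length(classes) + length(subtypes))
  n_bg <- cfg$n_genes - n_mito - length(module) - n_marker_slots
  if (n_bg < 0) stop("n_genes too small for the marker/mito/module blocks")

  gene_ids <- c(
    if (n_mito > 0) sprintf("MT-%d", seq_len(n_mito)),
    module,
    sprintf("MK%04d", seq_len(n_marker_slots)),
    sprintf("G%05d", seq_len(n_bg))
  )
  stopifnot(!anyDuplicated(gene_ids), length(gene_ids) == cfg$n_genes)
  is_mito <- grepl("^MT-", gene_ids)

  ## baseline gene weights; marker slots pinned to weight 1 so the in/out
  ## mean ratio of a marker equals the fold change in expectation
  w <- stats::rlnorm(cfg$n_genes, 0, 1)
  marker_idx <- which(startsWith(gene_ids, "MK"))
  w[marker_idx] <- 1
  w[gene_ids %in% module] <- 1

  ## assign marker blocks: classes first, then subtypes
  blocks <- split(marker_idx,
                  rep(seq_len(length(classes) + length(subtypes)),
                      each = cfg$markers_per_type))
  class_markers <- stats::setNames(blocks[seq_along(classes)], classes)
  subtype_markers <- stats::setNames(
    blocks[length(classes) + seq_along(subtypes)], subtypes)

  all_subtypes <- subtypes
  n_per <- rep(cfg$n_cells_per_subtype, length(subtypes))
  if (cfg$npc_fraction > 0) {
    all_subtypes <- c(all_subtypes, "NPC")
    sub2class <- c(sub2class, NPC = "NPC")
    n_per <- c(n_per, max(2L, round(cfg$npc_fraction *
                                      sum(n_per) / (1 - cfg$npc_fraction))))
  }
  cell_sub <- rep(all_subtypes, n_per)
  n_cells <- length(cell_sub)
  cell_class <- unname(sub2class[cell_sub])

  sample_id <- sprintf("S%02d", sample.int(cfg$n_samples, n_cells, replace = TRUE))
  batch <- matrix(stats::rlnorm(cfg$n_genes * cfg$n_samples, 0,
                                cfg$batch_effect_sd),
                  nrow = cfg$n_samples)
  rownames(batch) <- sprintf("S%02d", seq_len(cfg$n_samples))
  libsize <- stats::rlnorm(n_cells, cfg$lib_size_meanlog, cfg$lib_size_sdlog)
  mito_frac <- stats::runif(n_cells, cfg$mito_fraction_range[1],
                            cfg$mito_fraction_range[2])

  ## per-type gene weights
  type_w <- sapply(all_subtypes, function(st) {
    wt <- w
    cl <- sub2class[[st]]
    if (st == "NPC") {
      wt[gene_ids %in% module] <- 40  # strong co-expression of the module
    } else {
      # module genes are silent outside the proliferative pool
      if (length(module)) wt[gene_ids %in% module] <- 0.005
      wt[class_markers[[cl]]] <- wt[class_markers[[cl]]] * cfg$marker_fold_change
      wt[subtype_markers[[st]]] <- wt[subtype_markers[[st]]] * cfg$marker_fold_change
    }
    wt
  })  # genes x types

  counts <- matrix(0L, n_cells, cfg$n_genes)
  for (s in rownames(batch)) {
    idx <- which(sample_id == s)
    if (!length(idx)) next
    for (st in unique(cell_sub[idx])) {
      i <- idx[cell_sub[idx] == st]
      v <- type_w[, st] * batch[s, ]
      v_non <- v; v_non[is_mito] <- 0
      p_non <- v_non / sum(v_non)
      ## mean matrix for these cells: non-mito scaled by (1 - f_c), mito
      ## block split uniformly to hit the per-cell target fraction
      P <- outer(1 - mito_frac[i], p_non)
      if (any(is_mito))
        P[, is_mito] <- mito_frac[i] / sum(is_mito)
      mu <- P * libsize[i]
      counts[i, ] <- .rnbinom_matrix(mu, size = 1 / cfg$nb_dispersion)
    }
  }

  ## doublets: raw count sums of two random distinct singlets
  n_dbl <- round(cfg$doublet_rate * n_cells)
  if (n_dbl > 0) {
    i1 <- sample.int(n_cells, n_dbl, replace = TRUE)
    i2 <- sample.int(n_cells, n_dbl, replace = TRUE)
    bump <- i1 == i2
    i2[bump] <- (i2[bump] %% n_cells) + 1L
    dbl <- counts[i1, , drop = FALSE] + counts[i2, , drop = FALSE]
    counts <- rbind(counts, dbl)
  }
  total <- n_cells + n_dbl
  cell_ids <- sprintf("cell%05d", seq_len(total))
  rownames(counts) <- cell_ids
  colnames(counts) <- gene_ids

  is_doublet <- c(rep(FALSE, n_cells), rep(TRUE, n_dbl))
  lab1 <- c(cell_class, rep(NA_character_, n_dbl))
  lab2 <- c(cell_sub, rep(NA_character_, n_dbl))
  samp <- c(sample_id,
            if (n_dbl > 0) sample_id[i1] else character(0))
  donor <- paste0("D", match(samp, rownames(batch)))
  published <- ifelse(is_doublet, "doublet", lab1)
  published2 <- ifelse(is_doublet, "doublet", lab2)

  md <- data.frame(
    cell_ID = cell_ids, sample_ID = samp, donor_ID = donor,
    donor_sex = ifelse(match(samp, rownames(batch)) %% 2 == 0,
                       "female", "male"),
    donor_age = as.character(30 + 5 * match(samp, rownames(batch))),
    donor_status = "healthy", sample_status = "healthy",
    if_patient = "healthy",
    original_name = published, original_name2 = published2,
    region = "hippocampus", subregion = "N/A", treatment = "N/A",
    ethnicity = "N/A", seq_method = "10x", reference = "synthetic",
    stringsAsFactors = FALSE)

  ds <- annotated_dataset(as(counts, "CsparseMatrix"), md,
                          labels1 = lab1, labels2 = lab2)
  truth_tree <- if (cfg$npc_fraction > 0)
    label_tree(c(tree$classes, list(NPC = "NPC"))) else tree
  truth <- list(
    class_markers = lapply(class_markers, function(i) gene_ids[i]),
    subtype_markers = lapply(subtype_markers, function(i) gene_ids[i]),
    is_doublet = is_doublet, libsize = libsize, mito_fraction = mito_frac,
    type_weights = type_w, batch_factors = batch, gene_weights = w,
    tree = truth_tree, config = cfg)
  list(dataset = ds, truth = truth)
}

#' Configuration for a pseudobulk DE cohort simulation
#'
#' @param n_samples_per_group samples per group (two groups, `g1` vs `g2`).
#' @param cells_per_sample cells simulated per sample.
#' @param n_genes total genes.
#' @param effect_genes number of genes carrying the group effect.
#' @param effect_log2fc log2 fold change applied to affected genes in `g2`
#'   (0 = null simulation).
#' @param confounded_donors if TRUE each donor contributes to exactly one
#'   group (donor confounded with group, as for cross-region comparisons);
#'   if FALSE each donor contributes one sample per group.
#' @param nb_dispersion,batch_effect_sd,lib_size_meanlog,lib_size_sdlog
#'   count model parameters as in [synth_config()].
#' @param seed integer seed.
#' @return a `DECohortConfig` list.
#' @export
de_cohort_config <- function(n_samples_per_group = 10,
                             cells_per_sample = 50,
                             n_genes = 500,
                             effect_genes = 50,
                             effect_log2fc = 0,
                             confounded_donors = FALSE,
                             nb_dispersion = 0.1,
                             batch_effect_sd = 0.05,
                             lib_size_meanlog = log(2000),
                             lib_size_sdlog = 0.3,
                             seed = 0) {
  cfg <- as.list(environment())
  stopifnot(effect_genes <= n_genes, n_samples_per_group >= 1)
  class(cfg) <- "DECohortConfig"
  cfg
}

#' Simulate a two-group cohort with known per-gene group effects
#'
#' Produces an `AnnotatedDataset` ready for [aggregate_pseudobulk()]:
#' two groups of samples whose cells share NB count structure except for a
#' specified log2 fold change on a known gene subset, with per-sample batch
#' factors and a donor layout that is either crossed with the group (each
#' donor one sample in each group) or confounded (each donor in exactly one
#' group), the latter exercising the automatic covariate choice of
#' [build_design()].
#'
#' @param cfg a [de_cohort_config()].
#' @return list with `dataset` and `truth` (affected genes, group map,
#'   donor map).
#' @export
simulate_de_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "DECohortConfig"))
  set.seed(cfg$seed)
  npg <- cfg$n_samples_per_group
  n_samples <- 2L * npg
  samples <- sprintf("S%02d", seq_len(n_samples))
  group <- rep(c("g1", "g2"), each = npg)
  donor <- if (cfg$confounded_donors) paste0("D", seq_len(n_samples)) else
    paste0("D", rep(seq_len(npg), times = 2))
  donor_age <- 30 + 2 * as.integer(factor(donor))
  donor_sex <- ifelse(as.integer(factor(donor)) %% 2 == 0, "female", "male")

  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  affected <- gene_ids[seq_len(cfg$effect_genes)]
  w <- stats::rlnorm(cfg$n_genes, 0, 1)
  # stable, modest baseline for effect genes: keeps the compositional shift
  # of the fold change negligible so the generative log2FC is the nominal one
  w[seq_len(cfg$effect_genes)] <- 0.2
  fc <- rep(1, cfg$n_genes)
  fc[seq_len(cfg$effect_genes)] <- 2^cfg$effect_log2fc

  counts <- NULL; cell_meta <- NULL
  for (si in seq_len(n_samples)) {
    b <- stats::rlnorm(cfg$n_genes, 0, cfg$batch_effect_sd)
    v <- w * b
    if (group[si] == "g2") v <- v * fc
    p <- v / sum(v)
    l <- stats::rlnorm(cfg$cells_per_sample, cfg$lib_size_meanlog,
                       cfg$lib_size_sdlog)
    mu <- outer(l, p)
    x <- .rnbinom_matrix(mu, size = 1 / cfg$nb_dispersion)
    counts <- rbind(counts, x)
    cell_meta <- rbind(cell_meta, data.frame(
      sample_ID = rep(samples[si], cfg$cells_per_sample),
      donor_ID = donor[si], donor_sex = donor_sex[si],
      donor_age = as.character(donor_age[si]),
      group = group[si], stringsAsFactors = FALSE))
  }
  cell_ids <- sprintf("cell%05d", seq_len(nrow(counts)))
  rownames(counts) <- cell_ids
  colnames(counts) <- gene_ids
  md <- cbind(data.frame(cell_ID = cell_ids, stringsAsFactors = FALSE),
              cell_meta)
  md$if_patient <- "healthy"
  ds <- annotated_dataset(as(counts, "CsparseMatrix"), md)
  list(dataset = ds,
       truth = list(affected_genes = affected,
                    effect_log2fc = cfg$effect_log2fc,
                    group = stats::setNames(group, samples),
                    donor = stats::setNames(donor, samples)))
}
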