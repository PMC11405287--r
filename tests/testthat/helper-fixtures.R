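# In-code fixtures shared across the suite.

# random sparse integer count matrix with named axes
random_counts <- function(n_cells, n_genes, seed = 1, max_count = 20,
                          density = 0.3) {
  set.seed(seed)
  m <- matrix(0L, n_cells, n_genes)
  nz <- round(density * n_cells * n_genes)
  idx <- sample.int(n_cells * n_genes, nz)
  m[idx] <- sample.int(max_count, nz, replace = TRUE)
  rownames(m) <- sprintf("c%03d", seq_len(n_cells))
  colnames(m) <- sprintf("g%03d", seq_len(n_genes))
  as_count_matrix(m)
}

random_dataset <- function(n_cells = 30, n_genes = 20, seed = 1, ...) {
  annotated_dataset(random_counts(n_cells, n_genes, seed = seed, ...))
}

# minimal conformant metadata table
conformant_metadata <- function(n = 5) {
  md <- data.frame(cell_ID = sprintf("c%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (f in setdiff(scAtlasKit:::ATLAS_METADATA_FIELDS, "cell_ID"))
    md[[f]] <- "N/A"
  md$if_patient <- "healthy"
  md
}

# two well-separated expression clusters (for doublet / embedding tests)
two_cluster_dataset <- function(n_per = 150, n_genes = 60, seed = 0,
                                mean_high = 50, mean_low = 1) {
  set.seed(seed)
  half <- n_genes / 2
  mk <- function(hi_first) {
    mu <- c(rep(if (hi_first) mean_high else mean_low, half),
            rep(if (hi_first) mean_low else mean_high, half))
    matrix(rpois(n_per * n_genes, rep(mu, each = n_per)), n_per, n_genes)
  }
  m <- rbind(mk(TRUE), mk(FALSE))
  rownames(m) <- sprintf("c%04d", seq_len(2 * n_per))
  colnames(m) <- sprintf("g%03d", seq_len(n_genes))
  annotated_dataset(as_count_matrix(m),
                    labels1 = rep(c("clusterA", "clusterB"), each = n_per))
}

# small well-separated synthetic atlas for model tests
small_atlas <- function(classes = 4, subtypes = 1, cells = 200,
                        genes = 400, seed = 0, markers_per_type = 5, ...) {
  cls <- sprintf("K%02d", seq_len(classes))
  tree <- label_tree(setNames(lapply(cls, function(k)
    if (subtypes == 1) k else paste0(k, letters[seq_len(subtypes)])), cls))
  simulate_atlas(synth_config(tree = tree, n_cells_per_subtype = cells,
                              n_genes = genes, seed = seed,
                              markers_per_type = markers_per_type, ...))
}

quick_cfg <- function(...) {
  args <- utils::modifyList(list(latent_dim = 10, hidden_dim = 32,
                                 max_epochs = 60, learning_rate = 3e-3,
                                 seed = 0), list(...))
  do.call(latent_model_config, args)
}
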