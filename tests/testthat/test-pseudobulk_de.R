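test_that("pseudobulk aggregation sums counts per sample with hand-checkable totals", {
  m <- matrix(1:12, 4, 3,
              dimnames = list(sprintf("c%d", 1:4), sprintf("g%d", 1:3)))
  md <- data.frame(cell_ID = rownames(m),
                   sample_ID = c("s1", "s1", "s2", "s2"),
                   donor_ID = c("d1", "d1", "d2", "d2"),
                   donor_age = "40", donor_sex = "male",
                   group = c("a", "a", "b", "b"),
                   stringsAsFactors = FALSE)
  ds <- annotated_dataset(as_count_matrix(m), md)
  pb <- aggregate_pseudobulk(ds, min_cells = 1)
  expect_equal(unname(pb$counts["s1", ]), unname(colSums(m[1:2, ])))
  expect_equal(unname(pb$counts["s2", ]), unname(colSums(m[3:4, ])))
  expect_equal(pb$samples$n_cells, c(2, 2))

  # cell order never matters
  perm <- c(3, 1, 4, 2)
  pb2 <- aggregate_pseudobulk(subset_dataset(ds, cells = perm), min_cells = 1)
  expect_equal(pb2$counts, pb$counts)

  # min_cells filter drops small samples with a warning
  md4 <- md; md4$sample_ID <- c("s1", "s1", "s1", "s2")
  md4$donor_ID <- c("d1", "d1", "d1", "d2")
  md4$group <- c("a", "a", "a", "b")
  ds4 <- annotated_dataset(as_count_matrix(m), md4)
  expect_warning(pb3 <- aggregate_pseudobulk(ds4, min_cells = 3),
                 "fewer than 3")
  expect_identical(rownames(pb3$counts), "s1")
  # a covariate varying within a sample is an error
  md_bad <- md; md_bad$donor_ID[2] <- "dX"
  expect_error(aggregate_pseudobulk(annotated_dataset(as_count_matrix(m),
                                                      md_bad), min_cells = 1),
               "varies")
})

test_that("aggregation is linear: pseudobulk of a concatenation is the sum", {
  sim <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 2,
                                             cells_per_sample = 20,
                                             n_genes = 50, seed = 3))
  ds <- sim$dataset
  half1 <- subset_dataset(ds, cells = seq(1, nrow(ds$counts), by = 2))
  half2 <- subset_dataset(ds, cells = seq(2, nrow(ds$counts), by = 2))
  pb_all <- aggregate_pseudobulk(ds, min_cells = 1)
  pb1 <- aggregate_pseudobulk(half1, min_cells = 1)
  pb2 <- aggregate_pseudobulk(half2, min_cells = 1)
  expect_equal(pb_all$counts, pb1$counts + pb2$counts)
})

test_that("design selection detects donor/group confounding", {
  crossed <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 3,
                                                 cells_per_sample = 15,
                                                 n_genes = 40,
                                                 effect_genes = 5, seed = 1))
  pb <- aggregate_pseudobulk(crossed$dataset)
  d <- build_design(pb, "auto")
  expect_false(d$confounded)
  expect_identical(d$full_terms, c("donor_ID", "group"))

  conf <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 3,
                                              cells_per_sample = 15,
                                              n_genes = 40, effect_genes = 5,
                                              confounded_donors = TRUE,
                                              seed = 2))
  pbc <- aggregate_pseudobulk(conf$dataset)
  dc <- build_design(pbc, "auto")
  expect_true(dc$confounded)
  expect_identical(dc$full_terms, c("donor_age", "donor_sex", "group"))

  # one group level is an error
  pb1g <- pb
  pb1g$samples$group <- "a"
  expect_error(build_design(pb1g), "2 levels")
})

test_that("the NB LRT approaches the Poisson GLM LRT as dispersion vanishes", {
  sim <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 5,
                                             cells_per_sample = 20,
                                             n_genes = 30, effect_genes = 5,
                                             effect_log2fc = 1,
                                             nb_dispersion = 0.01, seed = 4))
  pb <- aggregate_pseudobulk(sim$dataset)
  design <- build_design(pb, "donor_covariate")
  res <- fit_nb_glm_lrt(pb, design, dispersion = 1e-8)
  df <- data.frame(pb$samples, stringsAsFactors = TRUE)
  off <- log(rowSums(pb$counts))
  for (g in sample(colnames(pb$counts)[res$tested], 6)) {
    full <- glm(pb$counts[, g] ~ donor_ID + group, data = df,
                family = poisson(), offset = off)
    redu <- glm(pb$counts[, g] ~ donor_ID, data = df,
                family = poisson(), offset = off)
    lr_ref <- as.numeric(2 * (logLik(full) - logLik(redu)))
    expect_equal(res$LR[res$gene == g], lr_ref, tolerance = 1e-3)
  }
})

test_that("p-values are recomputable from the LR statistic and BH from p", {
  sim <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 4,
                                             cells_per_sample = 20,
                                             n_genes = 60, effect_genes = 10,
                                             effect_log2fc = 1.5, seed = 5))
  pb <- aggregate_pseudobulk(sim$dataset)
  res <- fit_nb_glm_lrt(pb, build_design(pb, "donor_covariate"))
  t <- res$tested
  expect_true(all(res$LR[t] >= 0))
  expect_equal(res$p_value[t],
               pchisq(res$LR[t], df = attr(res, "df_test"),
                      lower.tail = FALSE))
  expect_equal(res$q_value[t], p.adjust(res$p_value[t], "BH"))
  # q-values invariant to gene order
  perm <- sample(ncol(pb$counts))
  pb2 <- pb
  pb2$counts <- pb2$counts[, perm]
  res2 <- fit_nb_glm_lrt(pb2, build_design(pb2, "donor_covariate"))
  expect_equal(res2$q_value[match(res$gene, res2$gene)], res$q_value)
})

test_that("simulated fold changes are recovered and agree with edgeR", {
  sim <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 6,
                                             cells_per_sample = 40,
                                             n_genes = 150, effect_genes = 25,
                                             effect_log2fc = 1, seed = 6))
  pb <- aggregate_pseudobulk(sim$dataset)
  design <- build_design(pb, "donor_covariate")
  res <- fit_nb_glm_lrt(pb, design)
  aff <- res$gene %in% sim$truth$affected_genes
  expect_lt(abs(mean(res$log2FC[aff & res$tested]) - 1), 0.15)
  # affected genes dominate the significant set
  sig <- significant_degs(res)
  expect_gte(mean(sig %in% sim$truth$affected_genes), 0.9)

  skip_if_not_installed("edgeR")
  df <- data.frame(pb$samples, stringsAsFactors = TRUE)
  mm <- model.matrix(~ donor_ID + group, df)
  y <- edgeR::DGEList(counts = t(pb$counts))
  y <- edgeR::estimateDisp(y, mm)
  fit <- edgeR::glmFit(y, mm)
  lrt <- edgeR::glmLRT(fit)
  tab <- lrt$table[res$gene[res$tested], ]
  expect_gt(cor(tab$logFC, res$log2FC[res$tested]), 0.95)
  expect_gt(cor(rank(tab$PValue), rank(res$p_value[res$tested])), 0.9)
})

test_that("significance cutoffs are strict on both criteria", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FC = c(0.6, 0.5, -0.7, 2.0),
                    LR = 1, p_value = 0.01,
                    q_value = c(0.04, 0.04, 0.04, 0.05),
                    tested = TRUE)
  expect_identical(significant_degs(res), c("a", "c"))
  expect_identical(significant_degs(res[0, ]), character(0))
})

test_that("a fully confounded donor design is rejected as singular", {
  sim <- simulate_de_cohort(de_cohort_config(n_samples_per_group = 3,
                                             cells_per_sample = 15,
                                             n_genes = 30, effect_genes = 5,
                                             confounded_donors = TRUE,
                                             seed = 7))
  pb <- aggregate_pseudobulk(sim$dataset)
  d <- build_design(pb, "donor_covariate")  # force donor despite confounding
  expect_error(fit_nb_glm_lrt(pb, d), "singular")
})
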