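#' @importFrom Matrix readMM writeMM rowSums colSums t sparseMatrix Diagonal
#' @importFrom methods as is new
#' @importFrom stats median prcomp rnorm runif setNames var sd quantile
#' @importFrom utils read.delim write.table head
NULL

## Curated metadata schema: the consistent field naming used across the atlas.
ATLAS_METADATA_FIELDS <- c(
  "cell_ID", "sample_ID", "donor_ID", "donor_sex", "donor_age",
  "donor_status", "sample_status", "if_patient", "original_name",
  "original_name2", "region", "subregion", "treatment", "ethnicity",
  "seq_method", "reference"
)

#' Validate and normalize a raw count matrix
#'
#' Coerces `counts` to a column-compressed sparse matrix oriented cells x
#' genes and enforces the count-matrix invariants: non-negative integer
#' entries and unique cell/gene identifiers on the dimnames.
#'
#' @param counts matrix or sparse Matrix, cells in rows, genes in columns.
#' @param cell_ids,gene_ids optional character vectors overriding dimnames.
#' @return a `dgCMatrix` with cell ids as rownames and gene ids as colnames.
#' @export
as_count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!is.null(cell_ids)) rownames(m) <- cell_ids
  if (!is.null(gene_ids)) colnames(m) <- gene_ids
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    stop("count matrix needs cell ids (rownames) and gene ids (colnames)")
  if (is.null(rownames(m))) rownames(m) <- character(0)
  if (is.null(colnames(m))) colnames(m) <- character(0)
  if (anyDuplicated(rownames(m))) stop("duplicate cell IDs")
  if (anyDuplicated(colnames(m))) stop("duplicate gene IDs")
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    stop("counts must be non-negative integers")
  m
}

#' Construct an annotated single-cell dataset
#'
#' The universal unit of exchange in the toolkit: sparse raw counts plus
#' per-cell metadata, optional two-level labels, an optional latent
#' embedding and optional doublet scores, all aligned to the cell ids.
#'
#' @param counts cells x genes count matrix (see [as_count_matrix()]).
#' @param metadata data.frame with one row per cell and a `cell_ID` column;
#'   if missing, a minimal metadata table is created. Missing values are
#'   encoded as the literal string `"N/A"`.
#' @param labels1,labels2 optional per-cell level-1 / level-2 labels.
#' @param latent optional cells x D numeric embedding.
#' @param doublet_score optional per-cell score in `[0, 1]`.
#' @return an object of class `AnnotatedDataset`.
#' @export
annotated_dataset <- function(counts, metadata = NULL, labels1 = NULL,
                              labels2 = NULL, latent = NULL,
                              doublet_score = NULL) {
  counts <- as_count_matrix(counts)
  n <- nrow(counts)
  if (is.null(metadata)) {
    metadata <- data.frame(cell_ID = rownames(counts),
                           stringsAsFactors = FALSE)
  }
  if (!"cell_ID" %in% names(metadata)) stop("metadata must have a cell_ID column")
  if (anyDuplicated(metadata$cell_ID)) stop("duplicate cell_ID in metadata")
  if (!setequal(metadata$cell_ID, rownames(counts)))
    stop("metadata cell_IDs do not match count matrix cells")
  metadata <- metadata[match(rownames(counts), metadata$cell_ID), , drop = FALSE]
  rownames(metadata) <- NULL
  chk_len <- function(x, what) {
    if (!is.null(x) && length(x) != n && !(is.matrix(x) && nrow(x) == n))
      stop(sprintf("%s not aligned to cells (%d)", what, n))
    x
  }
  ds <- structure(list(
    counts = counts,
    metadata = metadata,
    labels1 = chk_len(labels1, "labels1"),
    labels2 = chk_len(labels2, "labels2"),
    latent = chk_len(latent, "latent"),
    doublet_score = chk_len(doublet_score, "doublet_score")
  ), class = "AnnotatedDataset")
  ds
}

#' @export
print.AnnotatedDataset <- function(x, ...) {
  cat(sprintf("AnnotatedDataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  metadata fields: %s\n",
              paste(utils::head(names(x$metadata), 8), collapse = ", ")))
  if (!is.null(x$labels1))
    cat(sprintf("  level-1 labels: %d classes\n",
                length(unique(stats::na.omit(x$labels1)))))
  if (!is.null(x$labels2))
    cat(sprintf("  level-2 labels: %d subtypes\n",
                length(unique(stats::na.omit(x$labels2)))))
  if (!is.null(x$latent)) cat(sprintf("  latent embedding: %d dims\n",
                                      ncol(x$latent)))
  invisible(x)
}

#' @export
dim.AnnotatedDataset <- function(x) dim(x$counts)

#' Subset an annotated dataset by cells and/or genes
#'
#' @param ds an `AnnotatedDataset`.
#' @param cells logical/integer/character index over cells (default all).
#' @param genes index over genes (default all).
#' @return the subset `AnnotatedDataset`; per-cell arrays stay aligned.
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  if (is.null(cells)) cells <- seq_len(nrow(ds$counts))
  if (is.character(cells)) cells <- match(cells, rownames(ds$counts))
  if (is.logical(cells)) cells <- which(cells)
  if (is.null(genes)) genes <- seq_len(ncol(ds$counts))
  sub1 <- function(x) if (is.null(x)) NULL else
    if (is.matrix(x)) x[cells, , drop = FALSE] else x[cells]
  annotated_dataset(
    counts = ds$counts[cells, genes, drop = FALSE],
    metadata = ds$metadata[cells, , drop = FALSE],
    labels1 = sub1(ds$labels1), labels2 = sub1(ds$labels2),
    latent = sub1(ds$latent), doublet_score = sub1(ds$doublet_score)
  )
}

#' Read a 10x-style Matrix Market count triplet
#'
#' Reads `matrix.mtx` + `barcodes.tsv` + `genes.tsv` and returns a count
#' matrix oriented cells x genes. On-disk orientation (genes x cells vs
#' cells x genes) is resolved by matching the MTX dimensions against the
#' barcode and gene file lengths; a square matrix with equally many barcodes
#' and genes is ambiguous and defaults to rows = cells with a warning.
#'
#' @param mtx_path path to the MTX file.
#' @param barcodes_path path to the barcode file (one id per line, no header).
#' @param genes_path path to the gene file (first column = gene id, no header).
#' @return a cells x genes `dgCMatrix` of integer counts.
#' @export
read_count_triplet <- function(mtx_path, barcodes_path, genes_path) {
  for (p in c(mtx_path, barcodes_path, genes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  first_col <- function(p) {
    lines <- readLines(p)
    vapply(strsplit(lines, "\t", fixed = TRUE),
           function(x) x[1], character(1))
  }
  barcodes <- first_col(barcodes_path)
  genes <- first_col(genes_path)
  nb <- length(barcodes); ng <- length(genes)
  if (nrow(m) == nb && ncol(m) == ng) {
    if (nb == ng)
      warning("square matrix with equal barcode/gene counts; ",
              "assuming rows = cells")
  } else if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "MTX dimensions %dx%d match neither %d barcodes x %d genes nor its transpose",
      nrow(m), ncol(m), nb, ng))
  }
  as_count_matrix(m, cell_ids = barcodes, gene_ids = genes)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Inverse of [read_count_triplet()]: writes `matrix.mtx`, `barcodes.tsv`
#' and `genes.tsv` (cells x genes on disk) such that reading the files back
#' reproduces an entrywise-identical matrix.
#'
#' @param cm cells x genes count matrix.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_count_triplet <- function(cm, out_dir) {
  cm <- as_count_matrix(cm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("matrix.mtx", "barcodes.tsv", "genes.tsv"))
  Matrix::writeMM(cm, paths[1])
  writeLines(as.character(rownames(cm)), paths[2])
  writeLines(as.character(colnames(cm)), paths[3])
  invisible(paths)
}

#' Validate a curated cell metadata table
#'
#' Report-only check of a metadata table against the curated field schema:
#' missing required fields, duplicated `cell_ID`s and out-of-vocabulary
#' values (by default `if_patient` must be one of healthy/patient/N/A).
#'
#' @param md data.frame of per-cell metadata.
#' @param schema list with elements `required_fields` (character) and
#'   `vocabularies` (named list field -> allowed values). Defaults to the
#'   curated atlas schema.
#' @return list with `passed` (logical) and `errors` (data.frame with
#'   columns type, field, value, message).
#' @export
validate_metadata <- function(md, schema = NULL) {
  if (is.null(schema)) {
    schema <- list(
      required_fields = ATLAS_METADATA_FIELDS,
      vocabularies = list(if_patient = c("healthy", "patient", "N/A"))
    )
  }
  errs <- list()
  add <- function(type, field, value, message) {
    errs[[length(errs) + 1L]] <<- data.frame(
      type = type, field = field, value = value, message = message,
      stringsAsFactors = FALSE)
  }
  if (!"cell_ID" %in% names(md)) {
    add("missing_field", "cell_ID", "", "table has no cell_ID column")
  } else if (anyDuplicated(md$cell_ID)) {
    dup <- unique(md$cell_ID[duplicated(md$cell_ID)])
    for (d in dup) add("duplicate_cell_ID", "cell_ID", d, "duplicated cell_ID")
  }
  for (f in setdiff(schema$required_fields, names(md)))
    add("missing_field", f, "", sprintf("required field '%s' is absent", f))
  for (f in names(schema$vocabularies)) {
    if (!f %in% names(md)) next
    bad <- setdiff(unique(as.character(md[[f]])), schema$vocabularies[[f]])
    for (b in bad)
      add("vocabulary", f, b,
          sprintf("value '%s' not allowed for field '%s'", b, f))
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(type = character(), field = character(), value = character(),
               message = character(), stringsAsFactors = FALSE)
  list(passed = nrow(errors) == 0L, errors = errors)
}

#' Normalize raw donor-age strings to canonical age records
#'
#' Parses the curated age grammar into `(value, unit)` records. Units follow
#' the atlas convention: fetal samples are recorded in gestational weeks
#' (`"6 GW"`), organoids in culture days (`"D60"` or `"60 days"`), postnatal
#' donors in months when younger than one year (`"3 months"`) and in years
#' otherwise (`"47"` or `"47 years"`). A month value of 12 or more is
#' converted to years so the months-only-under-one-year rule always holds.
#' `"N/A"` yields a missing record.
#'
#' @param raw_age character vector of raw age strings.
#' @param sample_type one of `"adult"`, `"fetal"`, `"organoid"`, `"tumor"`;
#'   decides the unit of bare numbers (fetal -> gestational weeks,
#'   organoid -> culture days, adult/tumor -> years).
#' @return data.frame with columns `value` (numeric, NA for missing) and
#'   `unit` (one of gestational_week, month, year, culture_day, or NA).
#' @export
normalize_age <- function(raw_age,
                          sample_type = c("adult", "fetal", "organoid", "tumor")) {
  sample_type <- match.arg(sample_type)
  parse1 <- function(s) {
    s0 <- trimws(s)
    if (is.na(s0) || s0 == "" || toupper(s0) == "N/A")
      return(list(value = NA_real_, unit = NA_character_))
    num <- "([0-9]+\\.?[0-9]*)"
    if (grepl(paste0("^", num, "\\s*GW$"), s0, ignore.case = TRUE)) {
      v <- as.numeric(sub("\\s*GW$", "", s0, ignore.case = TRUE))
      return(list(value = v, unit = "gestational_week"))
    }
    if (grepl(paste0("^D", num, "$"), s0, ignore.case = TRUE)) {
      v <- as.numeric(sub("^D", "", s0, ignore.case = TRUE))
      return(list(value = v, unit = "culture_day"))
    }
    if (grepl(paste0("^", num, "\\s*(culture\\s+)?days?$"), s0, ignore.case = TRUE)) {
      v <- as.numeric(sub("\\s*(culture\\s+)?days?$", "", s0, ignore.case = TRUE))
      return(list(value = v, unit = "culture_day"))
    }
    if (grepl(paste0("^", num, "\\s*months?$"), s0, ignore.case = TRUE)) {
      v <- as.numeric(sub("\\s*months?$", "", s0, ignore.case = TRUE))
      if (v >= 12) return(list(value = v / 12, unit = "year"))
      return(list(value = v, unit = "month"))
    }
    if (grepl(paste0("^", num, "\\s*years?$"), s0, ignore.case = TRUE)) {
      v <- as.numeric(sub("\\s*years?$", "", s0, ignore.case = TRUE))
      return(list(value = v, unit = "year"))
    }
    if (grepl(paste0("^", num, "$"), s0)) {
      v <- as.numeric(s0)
      unit <- switch(sample_type,
                     fetal = "gestational_week",
                     organoid = "culture_day",
                     "year")
      return(list(value = v, unit = unit))
    }
    stop(sprintf("unparseable age token: '%s'", s0))
  }
  recs <- lapply(as.character(raw_age), parse1)
  out <- data.frame(value = vapply(recs, `[[`, numeric(1), "value"),
                    unit = vapply(recs, `[[`, character(1), "unit"),
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$value) & out$value < 0)) stop("negative age value")
  out
}

#' Merge two datasets on 1:1 orthologous genes
#'
#' Restricts both datasets to the shared one-to-one orthologs of a mapping
#' table, renames the second dataset's genes into the first's namespace and
#' concatenates the cells. Rows of the table in which either gene occurs
#' more than once (1:many or many:many) are dropped before joining, and
#' gene matching is case-sensitive exact string match.
#'
#' @param ds_a,ds_b `AnnotatedDataset`s to combine.
#' @param ortholog_table data.frame whose first column holds gene ids of
#'   `ds_a` and second column gene ids of `ds_b`.
#' @param source_a,source_b labels (e.g. species) recorded in the combined
#'   metadata column `species`.
#' @return combined `AnnotatedDataset` over the shared ortholog genes.
#' @export
merge_orthologs <- function(ds_a, ds_b, ortholog_table,
                            source_a = "a", source_b = "b") {
  stopifnot(inherits(ds_a, "AnnotatedDataset"),
            inherits(ds_b, "AnnotatedDataset"))
  tab <- data.frame(a = as.character(ortholog_table[[1]]),
                    b = as.character(ortholog_table[[2]]),
                    stringsAsFactors = FALSE)
  dup <- tab$a %in% tab$a[duplicated(tab$a)] | tab$b %in% tab$b[duplicated(tab$b)]
  if (any(dup)) {
    message(sprintf("merge_orthologs: dropping %d non-1:1 ortholog rows",
                    sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  keep <- tab$a %in% colnames(ds_a$counts) & tab$b %in% colnames(ds_b$counts)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no shared 1:1 orthologs between the datasets")
  ca <- ds_a$counts[, tab$a, drop = FALSE]
  cb <- ds_b$counts[, tab$b, drop = FALSE]
  colnames(cb) <- tab$a
  if (any(rownames(cb) %in% rownames(ca)))
    rownames(cb) <- paste0(source_b, ":", rownames(cb))
  counts <- rbind(ca, cb)
  fill_meta <- function(md, ids, source) {
    md <- md[, intersect(names(md), names(md)), drop = FALSE]
    md$cell_ID <- ids
    md$species <- source
    md
  }
  ma <- fill_meta(ds_a$metadata, rownames(ca), source_a)
  mb <- fill_meta(ds_b$metadata, rownames(cb), source_b)
  all_fields <- union(names(ma), names(mb))
  for (f in setdiff(all_fields, names(ma))) ma[[f]] <- "N/A"
  for (f in setdiff(all_fields, names(mb))) mb[[f]] <- "N/A"
  md <- rbind(ma[all_fields], mb[all_fields])
  cat_or_null <- function(xa, xb) {
    if (is.null(xa) && is.null(xb)) return(NULL)
    c(if (is.null(xa)) rep(NA_character_, nrow(ca)) else as.character(xa),
      if (is.null(xb)) rep(NA_character_, nrow(cb)) else as.character(xb))
  }
  annotated_dataset(counts, md,
                    labels1 = cat_or_null(ds_a$labels1, ds_b$labels1),
                    labels2 = cat_or_null(ds_a$labels2, ds_b$labels2))
}

#' Construct a two-level label hierarchy
#'
#' @param classes named list mapping level-1 class names to character
#'   vectors of level-2 subtype names.
#' @return object of class `LabelTree`.
#' @export
label_tree <- function(classes) {
  stopifnot(is.list(classes), length(classes) > 0, !is.null(names(classes)))
  if (anyDuplicated(names(classes))) stop("duplicate class names")
  subs <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(subs)) stop("duplicate subtype names across classes")
  structure(list(classes = classes), class = "LabelTree")
}

#' @export
print.LabelTree <- function(x, ...) {
  cat(sprintf("LabelTree: %d classes, %d subtypes\n",
              length(x$classes), length(unlist(x$classes))))
  invisible(x)
}

#' Read / write a label hierarchy as JSON
#'
#' JSON layout: `{"classes": [{"name": ..., "subtypes": [...]}]}`.
#'
#' @param path JSON file path.
#' @return `read_label_tree` returns a `LabelTree`.
#' @export
read_label_tree <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- stats::setNames(
    lapply(j$classes, function(c) unlist(c$subtypes)),
    vapply(j$classes, function(c) c$name, character(1)))
  label_tree(cls)
}

#' @rdname read_label_tree
#' @param tree a `LabelTree`.
#' @export
write_label_tree <- function(tree, path) {
  stopifnot(inherits(tree, "LabelTree"))
  j <- list(classes = lapply(names(tree$classes), function(n)
    list(name = n, subtypes = as.list(tree$classes[[n]]))))
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  invisible(path)
}

#' Check two-level labels against a hierarchy
#'
#' @param tree a `LabelTree`.
#' @param labels1,labels2 aligned per-cell label vectors (NA allowed).
#' @return TRUE invisibly; errors if any labeled cell's subtype does not
#'   belong to its class.
#' @export
check_labels_against_tree <- function(tree, labels1, labels2) {
  stopifnot(inherits(tree, "LabelTree"), length(labels1) == length(labels2))
  ok <- is.na(labels1) | is.na(labels2) |
    mapply(function(c, s) c %in% names(tree$classes) &&
             s %in% tree$classes[[c]], labels1, labels2)
  if (!all(ok))
    stop(sprintf("%d cells carry a level-2 label outside their level-1 class",
                 sum(!ok)))
  invisible(TRUE)
}

#' Write / read an AnnotatedDataset as a directory of text files
#'
#' Directory layout: the MTX triplet plus `metadata.tsv` (tab-separated,
#' header row, missing values as `"N/A"`); labels and doublet scores, when
#' present, are stored as extra metadata columns `label_level1`,
#' `label_level2`, `doublet_score`; a latent embedding is stored as
#' `latent.tsv`.
#'
#' @param ds an `AnnotatedDataset`.
#' @param dir directory to write to / read from.
#' @return `read_dataset` returns an `AnnotatedDataset`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "AnnotatedDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_triplet(ds$counts, dir)
  md <- ds$metadata
  if (!is.null(ds$labels1)) md$label_level1 <- as.character(ds$labels1)
  if (!is.null(ds$labels2)) md$label_level2 <- as.character(ds$labels2)
  if (!is.null(ds$doublet_score)) md$doublet_score <- ds$doublet_score
  md[] <- lapply(md, function(x) {
    x <- as.character(x); x[is.na(x)] <- "N/A"; x
  })
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(ds$latent))
    write.table(ds$latent, file.path(dir, "latent.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  cm <- read_count_triplet(file.path(dir, "matrix.mtx"),
                           file.path(dir, "barcodes.tsv"),
                           file.path(dir, "genes.tsv"))
  mp <- file.path(dir, "metadata.tsv")
  md <- if (file.exists(mp))
    read.delim(mp, stringsAsFactors = FALSE, colClasses = "character")
  else data.frame(cell_ID = rownames(cm), stringsAsFactors = FALSE)
  take <- function(col, num = FALSE) {
    if (!col %in% names(md)) return(NULL)
    x <- md[[col]]; x[x == "N/A"] <- NA
    if (num) as.numeric(x) else x
  }
  labels1 <- take("label_level1"); labels2 <- take("label_level2")
  dscore <- take("doublet_score", num = TRUE)
  md <- md[, setdiff(names(md), c("label_level1", "label_level2",
                                  "doublet_score")), drop = FALSE]
  lp <- file.path(dir, "latent.tsv")
  latent <- if (file.exists(lp))
    as.matrix(read.delim(lp, header = FALSE)) else NULL
  if (!is.null(latent)) rownames(latent) <- rownames(cm)
  annotated_dataset(cm, md, labels1 = labels1, labels2 = labels2,
                    latent = latent, doublet_score = dscore)
}
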