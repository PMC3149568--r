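#' Read a labeled expression matrix from delimited text
#'
#' Reads a complete (no missing values) numeric matrix with a header row
#' and row names, normalizes it to samples-in-rows, and maps the class
#' labels onto -1/+1 with an explicitly declared coding (the mapping is
#' reported with a message, never inferred).
#'
#' @param path matrix file, tab-delimited with a header row and an id
#'   column first.
#' @param labels class labels: a vector (one per sample, in matrix order)
#'   or the path of a two-column TSV `sample_id`, `label`.
#' @param positive_class,negative_class the label values mapped to +1 and
#'   -1 respectively.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"variables_in_rows"` (the matrix is transposed after reading).
#' @param sep field separator (default tab).
#' @return A [labeled_dataset()].
#' @export
read_expression <- function(path, labels, positive_class, negative_class,
                            orientation = c("samples_in_rows",
                                            "variables_in_rows"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  tab <- read.delim(path, sep = sep, row.names = 1, check.names = FALSE)
  X <- as.matrix(tab)
  if (!is.numeric(X)) {
    stop("matrix file contains non-numeric cells", call. = FALSE)
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 rownames(X)[bad[1]], colnames(X)[bad[2]]), call. = FALSE)
  }
  if (orientation == "variables_in_rows") X <- t(X)
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    ltab <- read.delim(labels, sep = sep, colClasses = "character")
    if (!all(c("sample_id", "label") %in% names(ltab))) {
      stop("labels file must have columns sample_id and label",
           call. = FALSE)
    }
    idx <- match(rownames(X), ltab$sample_id)
    if (anyNA(idx)) {
      stop("labels missing for sample(s): ",
           paste(rownames(X)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    labels <- ltab$label[idx]
  }
  if (length(labels) != nrow(X)) {
    stop("need one label per sample", call. = FALSE)
  }
  labels <- as.character(labels)
  known <- labels %in% c(positive_class, negative_class)
  if (!all(known)) {
    stop("unknown label value(s): ",
         paste(unique(labels[!known]), collapse = ", "), call. = FALSE)
  }
  y <- ifelse(labels == positive_class, 1, -1)
  message(sprintf("label coding: '%s' -> +1 (%d), '%s' -> -1 (%d)",
                  positive_class, sum(y == 1),
                  negative_class, sum(y == -1)))
  labeled_dataset(X, y)
}

#' Write a labeled dataset's raw matrix and labels as TSV
#'
#' Samples in rows, header row of variable ids, `sample_id` as the first
#' column; labels in a companion two-column TSV. Written uncentered, so
#' reading back through [read_expression()] round-trips the dataset.
#'
#' @param data a [labeled_dataset()].
#' @param matrix_path,labels_path output file paths.
#' @param positive_class,negative_class label strings to write for +1 / -1.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(data, matrix_path, labels_path,
                             positive_class = "case",
                             negative_class = "control") {
  stopifnot(inherits(data, "labeled_dataset"))
  raw <- dataset_raw(data)
  out <- data.frame(sample_id = data$sample_ids, raw, check.names = FALSE)
  write.table(out, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lab <- data.frame(
    sample_id = data$sample_ids,
    label = ifelse(data$y == 1, positive_class, negative_class))
  write.table(lab, labels_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Write a signature table as TSV
#'
#' Columns `variable_id`, `gene_symbol`, `entrez_id`, `frequency`
#' (annotation columns are NA when no map is given), mirroring the
#' standard published signature-table layout.
#'
#' @param sig a `signature`.
#' @param path output TSV path.
#' @param annotation optional [read_annotation()] map.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path, annotation = NULL) {
  stopifnot(inherits(sig, "signature"))
  genes <- if (nrow(sig) > 0) signature_genes(sig, annotation) else
    data.frame(entrez_id = character(0), gene_symbol = character(0))
  out <- data.frame(variable_id = sig$variable_id,
                    gene_symbol = genes$gene_symbol,
                    entrez_id = genes$entrez_id,
                    frequency = sig$frequency,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature table written by [write_signature()]
#'
#' Also reads the published-style signature tables shipped under
#' `inst/extdata` (columns `variable_id`/probeset, `gene_symbol`,
#' `entrez_id`, `frequency`).
#'
#' @param path TSV path.
#' @param threshold frequency threshold recorded on the object
#'   (default 40).
#' @return A `signature` with the annotation columns attached as an
#'   `annotation` attribute.
#' @export
read_signature <- function(path, threshold = 40) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("variable_id", "frequency")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("signature table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  freq <- as.numeric(tab$frequency)
  names(freq) <- tab$variable_id
  sig <- extract_signature(freq, threshold = threshold, source = path)
  if (all(c("gene_symbol", "entrez_id") %in% names(tab))) {
    attr(sig, "annotation") <- structure(
      data.frame(probeset_id = tab$variable_id,
                 gene_symbol = as.character(tab$gene_symbol),
                 entrez_id = as.character(tab$entrez_id),
                 stringsAsFactors = FALSE),
      class = c("annotation_map", "data.frame"))
  }
  sig
}

#' Pipeline configuration
#'
#' Validated bundle of everything [run_pipeline()] needs: a data source
#' (either a [synthetic_spec()] or matrix/label paths), the
#' cross-validation settings, the signature threshold, the enrichment
#' parameters and a mandatory seed.
#'
#' @param data_spec a [synthetic_spec()] to simulate from, or `NULL` when
#'   reading from files.
#' @param matrix_path,labels_path input files (used when `data_spec` is
#'   `NULL`); validated to exist at configuration time.
#' @param positive_class,negative_class label coding for file input.
#' @param gmt_path optional GMT file for enrichment (validated to exist).
#' @param annotation_path optional probeset annotation TSV.
#' @param mu_values,K_outer,K_inner,threshold,alpha,min_genes,seed pipeline
#'   parameters (see [mu_path()], [extract_signature()], [enrich()]).
#' @param out_dir output directory (created if needed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_spec = NULL, matrix_path = NULL,
                            labels_path = NULL, positive_class = "case",
                            negative_class = "control", gmt_path = NULL,
                            annotation_path = NULL,
                            mu_values = c(0.01, 0.1, 0.5, 1),
                            K_outer = 10, K_inner = 10, threshold = 40,
                            alpha = 0.05, min_genes = 3, seed = NULL,
                            out_dir = "sparsesig_run") {
  if (is.null(seed)) {
    stop("seed is mandatory: every stochastic stage derives from it",
         call. = FALSE)
  }
  if (is.null(data_spec)) {
    if (is.null(matrix_path) || is.null(labels_path)) {
      stop("either data_spec or matrix_path + labels_path must be given",
           call. = FALSE)
    }
    for (p in c(matrix_path, labels_path)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  } else {
    stopifnot(inherits(data_spec, "synthetic_spec"))
  }
  for (p in c(gmt_path, annotation_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(
    list(data_spec = data_spec, matrix_path = matrix_path,
         labels_path = labels_path, positive_class = positive_class,
         negative_class = negative_class, gmt_path = gmt_path,
         annotation_path = annotation_path, mu_values = mu_values,
         K_outer = K_outer, K_inner = K_inner, threshold = threshold,
         alpha = alpha, min_genes = min_genes, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config")
}

#' Run the full signature-discovery pipeline
#'
#' Chains every stage: load or simulate the dataset; nested stratified
#' cross-validation along the mu path; signature extraction at mu = 1 with
#' the frequency threshold; final RLS model at the median per-fold lambda;
#' k-means clustering of the signature profiles under correlation distance
#' (cluster count = minimal-mu list size); hypergeometric enrichment when a
#' gene-set collection is configured. Writes, under `out_dir`:
#' `signature.tsv`, `cv_report.tsv` (per-fold parameters and errors),
#' `clusters.tsv`, `enrichment.tsv` (when applicable) and `manifest.json`
#' (seed, configuration and stage summaries, for re-run reproducibility).
#' Given the same configuration and seed, the deterministic outputs are
#' byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`data`, `path`, `signature`, `model`, `clusters`, `enrichment`,
#'   `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  say("[%s] stage: data", format(Sys.time(), "%H:%M:%S"))
  truth <- NULL
  if (!is.null(config$data_spec)) {
    sim <- generate_dataset(config$data_spec)
    data <- sim$data
    truth <- sim$truth
  } else {
    data <- read_expression(config$matrix_path, config$labels_path,
                            config$positive_class, config$negative_class)
  }

  say("[%s] stage: nested cross-validation (mu path)",
      format(Sys.time(), "%H:%M:%S"))
  path <- mu_path(data, mu_values = config$mu_values,
                  K_outer = config$K_outer, K_inner = config$K_inner,
                  seed = config$seed, threshold = config$threshold)
  sig <- path$signature
  cv <- path$levels[[length(path$levels)]]$cv

  annotation <- if (!is.null(config$annotation_path)) {
    read_annotation(config$annotation_path)
  } else NULL

  files <- list(signature = file.path(config$out_dir, "signature.tsv"),
                cv_report = file.path(config$out_dir, "cv_report.tsv"),
                manifest = file.path(config$out_dir, "manifest.json"))
  write_signature(sig, files$signature, annotation)
  cv_report <- do.call(rbind, lapply(seq_along(cv$folds), function(k) {
    f <- cv$folds[[k]]
    data.frame(fold = k, tau = f$tau, lambda = f$lambda,
               n_selected = length(f$selected),
               TP = f$confusion$TP, FN = f$confusion$FN,
               FP = f$confusion$FP, TN = f$confusion$TN,
               error = f$error)
  }))
  write.table(cv_report, files$cv_report, sep = "\t", quote = FALSE,
              row.names = FALSE)

  model <- NULL
  if (nrow(sig) > 0) {
    say("[%s] stage: final model", format(Sys.time(), "%H:%M:%S"))
    model <- final_model(data, sig, cv = cv)
  } else {
    say("empty signature at mu = 1: no final model or clustering")
  }

  clusters <- NULL
  if (nrow(sig) > 1 && path$k_min >= 1) {
    say("[%s] stage: clustering (k = %d)", format(Sys.time(), "%H:%M:%S"),
        min(path$k_min, nrow(sig)))
    profiles <- t(dataset_raw(data)[, sig$variable_id, drop = FALSE])
    clusters <- kmeans_correlation(profiles,
                                   k = min(path$k_min, nrow(sig)),
                                   seed = config$seed)
    files$clusters <- file.path(config$out_dir, "clusters.tsv")
    ctab <- data.frame(variable_id = names(clusters$cluster),
                       cluster = unname(clusters$cluster))
    write.table(ctab, files$clusters, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  enrichment <- NULL
  if (!is.null(config$gmt_path) && nrow(sig) > 0) {
    say("[%s] stage: enrichment", format(Sys.time(), "%H:%M:%S"))
    collection <- read_gmt(config$gmt_path)
    genes <- if (is.null(annotation)) sig$variable_id else
      signature_genes(sig, annotation)$gene_symbol
    enrichment <- enrich(genes, collection, alpha = config$alpha,
                         min_genes = config$min_genes)
    files$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    write.table(as.data.frame(enrichment), files$enrichment, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "sparsesig",
    version = as.character(utils::packageVersion("sparsesig")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "data_spec")],
    data_spec = if (!is.null(config$data_spec)) {
      unclass(config$data_spec)
    },
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mean_cv_error = cv$mean_error,
    signature_size = nrow(sig),
    k_min = path$k_min,
    files = lapply(files, basename))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)

  say("[%s] done: signature of %d variables, mean CV error %.4f",
      format(Sys.time(), "%H:%M:%S"), nrow(sig), cv$mean_error)
  invisible(list(data = data, truth = truth, path = path, cv = cv,
                 signature = sig, model = model, clusters = clusters,
                 enrichment = enrichment, files = files))
}
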