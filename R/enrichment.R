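#' Gene-set collection
#'
#' Named sets of gene identifiers with optional category labels and a
#' reference universe, as used for over-representation analysis. Members
#' falling outside the universe are dropped (with a message) so that the
#' invariant `members %in% universe` holds after construction.
#'
#' @param sets named list of character vectors of gene ids; names unique.
#' @param categories optional character vector of category labels, one per
#'   set.
#' @param universe reference gene universe; defaults to the union of all
#'   set members.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = NULL, universe = NULL) {
  if (length(sets) == 0) stop("sets must be nonempty", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == "")) {
    stop("sets must have unique nonempty names", call. = FALSE)
  }
  if (is.null(categories)) categories <- rep(NA_character_, length(sets))
  if (length(categories) != length(sets)) {
    stop("categories must have one entry per set", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(as.character(universe))
    dropped <- sum(vapply(sets, function(s) sum(!s %in% universe),
                          numeric(1)))
    if (dropped > 0) {
      message(dropped, " set member(s) outside the universe were dropped")
      sets <- lapply(sets, function(s) s[s %in% universe])
    }
  }
  names(categories) <- names(sets)
  structure(list(sets = sets, categories = categories, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Membership is parsed with [fgsea::gmtPathways()];
#' the description column is kept as the set's category label.
#'
#' @param path GMT file path.
#' @param universe optional reference universe (default: union of members).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  categories <- vapply(fields, function(f) {
    if (length(f) >= 2) f[2] else NA_character_
  }, character(1))
  names(categories) <- vapply(fields, `[[`, character(1), 1)
  gene_set_collection(sets, categories = unname(categories[names(sets)]),
                      universe = universe)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    desc <- collection$categories[i]
    if (is.na(desc)) desc <- "na"
    paste(c(names(collection$sets)[i], desc, collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` members of a size-`K` set in a size-`n` draw from a
#' universe of `N` genes. This is the over-representation test used for
#' gene-set enrichment. Vectorized over its arguments.
#'
#' @param N universe size.
#' @param K set size within the universe.
#' @param n signature size within the universe.
#' @param k observed overlap, `k <= min(K, n)`.
#' @return P-value in `(0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_p(10, 5, 2, 2)  # choose(5,2)/choose(10,2) = 10/45
#' @export
hypergeom_p <- function(N, K, n, k) {
  args <- cbind(N, K, n, k)
  N <- args[, 1]; K <- args[, 2]; n <- args[, 3]; k <- args[, 4]
  if (any(args < 0) || any(args != round(args))) {
    stop("N, K, n, k must be nonnegative integers", call. = FALSE)
  }
  if (any(K > N) || any(n > N)) {
    stop("K and n must not exceed the universe size N", call. = FALSE)
  }
  if (any(k > pmin(K, n))) {
    stop("overlap k must not exceed min(K, n)", call. = FALSE)
  }
  unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Significance and enrichment flags for over-representation results
#'
#' The two-level criterion: a set is *significant* when its p-value is at or
#' below `alpha`, and *enriched* when it is significant **and** the overlap
#' contains at least `min_genes` signature genes. A set can therefore be
#' significant without being enriched when too few genes drive its small
#' p-value.
#'
#' @param k overlap count(s).
#' @param p p-value(s).
#' @param alpha significance level (default 0.05).
#' @param min_genes minimum overlap for enrichment (default 3).
#' @return data.frame with logical columns `significant` and `enriched`.
#' @examples
#' enrichment_flags(k = c(14, 2, 1), p = c(9.69e-26, 6.66e-4, 7.59e-2))
#' @export
enrichment_flags <- function(k, p, alpha = 0.05, min_genes = 3) {
  significant <- p <= alpha
  data.frame(significant = significant,
             enriched = significant & k >= min_genes)
}

#' Hypergeometric gene-set enrichment of a signature
#'
#' Over-representation analysis of a signature's genes against every set of
#' a collection: for each set with nonzero overlap, the upper-tail
#' hypergeometric p-value is computed on the counts restricted to the
#' collection's universe, and the significant / enriched flags are assigned
#' by [enrichment_flags()]. Raw p-values are used for the flags; a
#' Benjamini-Hochberg column (`p_bh`) is attached as a clearly-separate
#' extra and plays no role in the flags. Signature genes outside the
#' universe are excluded from all counts and reported in the
#' `outside_universe` attribute.
#'
#' @param genes character vector of signature gene ids (already in the
#'   collection's id space; map probesets first if needed).
#' @param collection a [gene_set_collection()].
#' @param alpha significance level (default 0.05).
#' @param min_genes minimum overlap for the enriched flag (default 3).
#' @return An object of class `enrichment_result`: data.frame sorted by
#'   p-value with columns `set`, `category`, `set_size`, `overlap`,
#'   `overlap_genes` (comma-joined), `p_value`, `p_bh`, `significant`,
#'   `enriched`.
#' @export
enrich <- function(genes, collection, alpha = 0.05, min_genes = 3) {
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- unique(as.character(genes))
  inside <- genes[genes %in% collection$universe]
  outside <- setdiff(genes, inside)
  if (length(inside) == 0) {
    stop("no signature genes fall inside the collection's universe",
         call. = FALSE)
  }
  N <- length(collection$universe)
  n <- length(inside)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    hit <- intersect(inside, members)
    if (length(hit) == 0) return(NULL)
    data.frame(set = nm,
               category = unname(collection$categories[nm]),
               set_size = length(members),
               overlap = length(hit),
               overlap_genes = paste(sort(hit), collapse = ","),
               p_value = hypergeom_p(N, length(members), n, length(hit)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(set = character(0), category = character(0),
                      set_size = integer(0), overlap = integer(0),
                      overlap_genes = character(0), p_value = numeric(0))
  }
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  flags <- enrichment_flags(res$overlap, res$p_value, alpha, min_genes)
  res$significant <- flags$significant
  res$enriched <- flags$enriched
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            alpha = alpha, min_genes = min_genes,
            n_signature = n, universe_size = N,
            outside_universe = outside)
}

#' Read a probeset-to-gene annotation table
#'
#' Tab-delimited table with header columns `probeset_id`, `gene_symbol`,
#' `entrez_id`, mapping platform probesets to genes.
#'
#' @param path TSV file path.
#' @return data.frame of class `annotation_map`.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("probeset_id", "gene_symbol", "entrez_id")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotation is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(ann, class = c("annotation_map", "data.frame"))
}

# Map a signature (or character vector of probeset/variable ids) to genes:
# a data.frame with entrez_id and gene_symbol. Without an annotation the
# ids are taken to be gene ids already.
signature_genes <- function(sig, annotation = NULL) {
  ids <- if (inherits(sig, "signature")) sig$variable_id
         else as.character(sig)
  if (is.null(annotation)) {
    return(data.frame(entrez_id = NA_character_, gene_symbol = ids,
                      stringsAsFactors = FALSE))
  }
  idx <- match(ids, annotation$probeset_id)
  if (anyNA(idx)) {
    stop("unmapped probesets: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(entrez_id = annotation$entrez_id[idx],
             gene_symbol = annotation$gene_symbol[idx],
             stringsAsFactors = FALSE)
}

#' Gene-level intersection of signatures
#'
#' Intersects signatures at the *gene* level (probesets mapping to the same
#' gene count as one), using Entrez ids as the primary identity and gene
#' symbols as fallback. Reports the all-way intersection together with
#' every pairwise intersection. Commutative, associative and idempotent in
#' its inputs.
#'
#' @param signatures named list of `signature` objects or character vectors
#'   of ids.
#' @param annotation optional [read_annotation()] map translating probesets
#'   to genes (ids are taken as genes when absent).
#' @return List with `all` (character vector of gene symbols common to
#'   every signature) and `pairwise` (named list of pairwise intersections).
#' @examples
#' intersect_signatures(list(a = c("XIST", "CD44"), b = c("CD44", "TAC1")))
#' @export
intersect_signatures <- function(signatures, annotation = NULL) {
  if (length(signatures) < 1) stop("no signatures given", call. = FALSE)
  if (is.null(names(signatures))) {
    names(signatures) <- paste0("signature_", seq_along(signatures))
  }
  maps <- lapply(signatures, signature_genes, annotation = annotation)
  # gene identity: entrez when available, else symbol
  keys <- lapply(maps, function(m) {
    unique(ifelse(is.na(m$entrez_id), m$gene_symbol, m$entrez_id))
  })
  symbol_of <- do.call(rbind, maps)
  key_all <- ifelse(is.na(symbol_of$entrez_id), symbol_of$gene_symbol,
                    symbol_of$entrez_id)
  lookup <- symbol_of$gene_symbol[!duplicated(key_all)]
  names(lookup) <- key_all[!duplicated(key_all)]
  to_symbols <- function(k) sort(unname(lookup[k]))
  all_keys <- Reduce(intersect, keys)
  pairs <- list()
  nm <- names(signatures)
  if (length(signatures) >= 2) {
    for (i in seq_len(length(signatures) - 1)) {
      for (j in seq((i + 1), length(signatures))) {
        pairs[[paste(nm[i], nm[j], sep = " & ")]] <-
          to_symbols(intersect(keys[[i]], keys[[j]]))
      }
    }
  }
  list(all = to_symbols(all_keys), pairwise = pairs)
}

#' Pathway-level overlap table across signatures
#'
#' Late integration at the pathway level: rows are the union of sets that
#' are significant or enriched in at least one signature's enrichment
#' result; each cell marks the set's status in that signature —
#' `"enriched"`, `"significant"` (significant but not enriched) or `""`
#' (absent). The summary lists sets shared by all signatures and by each
#' pair.
#'
#' @param results named list (>= 2) of `enrichment_result` objects.
#' @return data.frame of class `overlap_table` with columns `set`,
#'   `category` and one marker column per signature; attributes
#'   `shared_all` and `shared_pairs`.
#' @export
overlap_table <- function(results) {
  if (length(results) < 2) {
    stop("at least two enrichment results are required", call. = FALSE)
  }
  if (is.null(names(results))) {
    names(results) <- paste0("signature_", seq_along(results))
  }
  marked <- lapply(results, function(r) {
    r[r$significant | r$enriched, c("set", "category", "enriched"),
      drop = FALSE]
  })
  all_sets <- do.call(rbind, lapply(marked, function(m) {
    m[, c("set", "category")]
  }))
  all_sets <- all_sets[!duplicated(all_sets$set), , drop = FALSE]
  all_sets <- all_sets[order(all_sets$set), , drop = FALSE]
  tab <- all_sets
  for (nm in names(marked)) {
    m <- marked[[nm]]
    status <- character(nrow(tab))
    idx <- match(tab$set, m$set)
    status[!is.na(idx)] <- ifelse(m$enriched[idx[!is.na(idx)]],
                                  "enriched", "significant")
    tab[[nm]] <- status
  }
  rownames(tab) <- NULL
  present <- lapply(names(marked), function(nm) tab$set[tab[[nm]] != ""])
  names(present) <- names(marked)
  shared_all <- Reduce(intersect, present)
  shared_pairs <- list()
  nm <- names(marked)
  for (i in seq_len(length(nm) - 1)) {
    for (j in seq((i + 1), length(nm))) {
      shared_pairs[[paste(nm[i], nm[j], sep = " & ")]] <-
        intersect(present[[i]], present[[j]])
    }
  }
  structure(tab, class = c("overlap_table", "data.frame"),
            shared_all = shared_all, shared_pairs = shared_pairs)
}
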