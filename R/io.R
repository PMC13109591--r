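#' Construct a validated count matrix
#'
#' The universal input of the pipeline: an integer gene-by-sample matrix with
#' unique gene and sample identifiers. Invariants (non-negative integer
#' entries, no duplicated identifiers, consistent dimensions) are enforced at
#' construction so every downstream stage can assume them.
#'
#' @param counts numeric matrix (genes x samples) with rownames (gene ids) and
#'   colnames (sample ids); entries must be non-negative integers.
#' @return the validated matrix with class `count_matrix` prepended.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix requires gene rownames and sample colnames", call. = FALSE)
  dup_g <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s' (must be a non-negative integer)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  storage.mode(counts) <- "double"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Non-integer, negative or missing entries and duplicated
#' identifiers are format errors naming the offender.
#'
#' @param path path to a tab-separated file.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count TSV needs a gene id column plus >=1 sample", call. = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count TSV: ", path, call. = FALSE)
  rownames(m) <- genes
  count_matrix(m)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]; round-trips are identities.
#'
#' @param counts a count matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), unclass(counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Seven columns describe each sample: `sample_id`, `condition`
#' (healthy/PD), `mutation` (healthy/LRRK2/Parkin), `place` (the two
#' differentiation laboratories), `replicate`, `gender`, `reprogramming`.
#' Condition must be the deterministic image of mutation (healthy mutation ->
#' healthy condition, any PD mutation -> PD).
#'
#' @param path TSV path.
#' @param counts optional count matrix; if given, sample sets must match.
#' @return data.frame with factor columns.
#' @export
read_metadata <- function(path, counts = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df, counts)
}

#' @rdname read_metadata
#' @param metadata a data.frame with the seven metadata columns.
#' @export
validate_metadata <- function(metadata, counts = NULL) {
  need <- c("sample_id", "condition", "mutation", "place", "replicate",
            "gender", "reprogramming")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  expected <- ifelse(metadata$mutation == "healthy", "healthy", "PD")
  if (!all(metadata$condition == expected))
    stop("condition must be a deterministic function of mutation", call. = FALSE)
  for (f in c("condition", "mutation", "place", "gender", "reprogramming"))
    metadata[[f]] <- factor(metadata[[f]])
  metadata$replicate <- factor(metadata$replicate)
  metadata$mutation <- stats::relevel(factor(as.character(metadata$mutation)),
                                      ref = "healthy")
  metadata$condition <- stats::relevel(factor(as.character(metadata$condition)),
                                       ref = "healthy")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), metadata$sample_id))
      stop("metadata samples do not match count matrix samples", call. = FALSE)
    metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  metadata
}

#' Write sample metadata to TSV
#' @param metadata metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard dialect: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Blank lines are ignored; lines with fewer than three fields are format
#' errors reported with the line number; empty sets (after de-duplication)
#' are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(fields)), call. = FALSE)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("dropping empty gene set '", fields[1], "'", call. = FALSE)
      next
    }
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style protein interaction edge list
#'
#' TSV with columns `node1`, `node2`, `combined_score`. Scores may be on the
#' 0-1000 STRING download scale or the 0-1 website scale; `scale = "auto"`
#' treats files whose maximum score is <= 1 as 0-1 and rescales to 0-1000.
#' Self-loops are dropped (count reported via message); edges below
#' `score_threshold` (0-1000 scale) are removed; duplicate undirected pairs
#' keep the maximum score.
#'
#' @param path TSV path.
#' @param score_threshold integer in [0, 1000]; edges with lower scores drop.
#' @param scale one of "auto", "0-1000", "0-1".
#' @return data.frame(node1, node2, combined_score) with node1 < node2.
#' @export
read_edges <- function(path, score_threshold = 400,
                       scale = c("auto", "0-1000", "0-1")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node1", "node2", "combined_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("edge list missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  edge_list(df, score_threshold = score_threshold, scale = scale)
}

#' @rdname read_edges
#' @param edges data.frame with node1, node2, combined_score.
#' @export
edge_list <- function(edges, score_threshold = 0,
                      scale = c("auto", "0-1000", "0-1")) {
  scale <- match.arg(scale)
  s <- edges$combined_score
  if (scale == "0-1" || (scale == "auto" && length(s) && max(s) <= 1))
    s <- s * 1000
  if (any(s < 0 | s > 1000))
    stop("combined_score outside [0, 1000] after scaling", call. = FALSE)
  edges$combined_score <- s
  loops <- edges$node1 == edges$node2
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- edges[edges$combined_score >= score_threshold, , drop = FALSE]
  if (!nrow(edges))
    return(data.frame(node1 = character(), node2 = character(),
                      combined_score = numeric()))
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  key <- paste(a, b, sep = "\r")
  score <- tapply(edges$combined_score, key, max)
  parts <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(node1 = vapply(parts, `[`, "", 1),
                    node2 = vapply(parts, `[`, "", 2),
                    combined_score = as.numeric(score))
  rownames(out) <- NULL
  out[order(out$node1, out$node2), , drop = FALSE]
}

#' Write an edge list to TSV
#' @param edges edge-list data.frame.
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format pathway weight matrix
#'
#' TSV with columns `pathway`, `gene`, `weight`; (pathway, gene) pairs must
#' be unique. Used by the pathway-activity module in place of a live
#' footprint-weight download.
#'
#' @param path TSV path.
#' @return data.frame(pathway, gene, weight).
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway", "gene", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weight table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("pathway", "gene")]))
    stop("duplicate (pathway, gene) pair in weight table", call. = FALSE)
  if (any(!is.finite(df$weight))) stop("non-finite weight", call. = FALSE)
  df
}

#' @rdname read_weights
#' @param weights weight data.frame.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' Flat YAML holding thresholds, seeds and permutation counts; values not
#' present fall back to [default_config()].
#'
#' @param path YAML path, or NULL for the defaults.
#' @return named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}
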