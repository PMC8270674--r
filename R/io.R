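# On-disk formats: tab-separated OTU/taxonomy/metadata tables, correlation
# matrices, edge lists and GraphML networks. Readers validate strictly and
# report the location of the first malformed value instead of coercing.

#' Construct an OTU count table with domain and lineage labels
#'
#' The canonical container for every analysis stage: an integer count
#' matrix with OTUs in rows and samples in columns, plus per-OTU domain
#' (bacteria / archaea / eukaryota) and semicolon-delimited lineage
#' (domain;phylum at minimum).
#'
#' @param counts integer matrix, OTUs x samples, with row and column names.
#' @param domain named character vector mapping every OTU id to a domain.
#' @param lineage named character vector mapping every OTU id to a lineage
#'   string; defaults to the bare domain name.
#' @return object of class `otu_table`.
#' @export
otu_table <- function(counts, domain, lineage = NULL) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must be a matrix with OTU row names and sample column names")
  }
  if (!is_count_vector(as.vector(counts))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate OTU ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  missing <- setdiff(rownames(counts), names(domain))
  if (length(missing)) {
    stop("OTUs without a domain label: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  domain <- domain[rownames(counts)]
  if (!all(domain %in% DOMAINS)) {
    stop("domain labels must be one of: ", paste(DOMAINS, collapse = ", "))
  }
  if (is.null(lineage)) {
    lineage <- stats::setNames(as.character(domain), rownames(counts))
  }
  lineage <- lineage[rownames(counts)]
  mode(counts) <- "integer"
  structure(list(counts = counts, domain = domain, lineage = lineage),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  tab <- table(factor(x$domain, DOMAINS))
  cat(sprintf("otu_table: %d OTUs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset an OTU table to one domain
#' @param table an [otu_table()].
#' @param domain domain name.
#' @return an [otu_table()] restricted to that domain's OTUs.
#' @export
subset_domain <- function(table, domain) {
  domain <- match.arg(domain, DOMAINS)
  keep <- names(table$domain)[table$domain == domain]
  if (!length(keep)) stop("no OTUs with domain ", domain)
  otu_table(table$counts[keep, , drop = FALSE], table$domain[keep],
            table$lineage[keep])
}

#' Write an OTU table to counts + taxonomy TSV files
#'
#' @param table an [otu_table()].
#' @param counts_path counts TSV (first column `otu_id`, then sample ids).
#' @param taxonomy_path taxonomy TSV with columns `otu_id`, `domain`,
#'   `lineage`.
#' @return invisibly, `counts_path`.
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path) {
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- data.frame(otu_id = rownames(table$counts),
                    domain = as.character(table$domain),
                    lineage = as.character(table$lineage),
                    stringsAsFactors = FALSE)
  utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read an OTU table from counts + taxonomy TSV files
#'
#' Expects OTUs in rows (the usual amplicon convention). A table whose
#' column header looks like OTU ids while its row ids look like samples is
#' rejected as transposed rather than silently fixed. Any non-integer or
#' negative cell is a hard error naming the offending row and column.
#'
#' @inheritParams write_otu_table
#' @return an [otu_table()].
#' @export
read_otu_table <- function(counts_path, taxonomy_path) {
  raw <- utils::read.delim(counts_path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("counts file needs an otu_id column plus sample columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate OTU ids in counts file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in counts header")
  tax <- utils::read.delim(taxonomy_path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("otu_id", "domain", "lineage")
  if (!all(need %in% colnames(tax))) {
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tax$otu_id)) stop("duplicate OTU ids in taxonomy file")
  # transposition heuristic: header matches taxonomy ids but row ids do not
  if (mean(ids %in% tax$otu_id) < 0.5 && mean(samples %in% tax$otu_id) > 0.5) {
    stop("counts table appears transposed (samples in rows); expected OTUs in rows")
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  ok <- matrix(grepl("^[0-9]+$", cells), nrow = nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed count '%s' at OTU '%s', sample '%s' (must be a non-negative integer)",
                 cells[bad[1], bad[2]], ids[bad[1]], samples[bad[2]]))
  }
  counts <- matrix(as.integer(cells), nrow = length(ids),
                   dimnames = list(ids, samples))
  missing <- setdiff(ids, tax$otu_id)
  if (length(missing)) {
    stop("OTUs missing from taxonomy: ", paste(missing, collapse = ", "))
  }
  otu_table(counts,
            stats::setNames(tax$domain, tax$otu_id),
            stats::setNames(tax$lineage, tax$otu_id))
}

#' Write sample metadata to a TSV file
#'
#' Floats carry 6 significant digits, except the TC/TN ratio: it is
#' recomputed from the rounded TC and TN and stored at 9 significant
#' digits, so the stored ratio stays consistent with the stored values to
#' well within the 1e-6 relative tolerance the reader enforces.
#'
#' @param metadata a `sample_metadata` data frame.
#' @param path output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  md <- as.data.frame(metadata)
  md$TC <- signif(md$TC, 6)
  md$TN <- signif(md$TN, 6)
  md$TC_TN <- formatC(md$TC / md$TN, digits = 9, format = "g")
  write_tsv(md, path)
}

#' Read and validate sample metadata
#'
#' Requires the full covariate set (geography, MAT/MAP climate, and the
#' edaphic variables) and checks that the stored TC/TN ratio agrees with
#' TC / TN to 1e-6 relative tolerance and that elevations are positive.
#'
#' @param path metadata TSV path.
#' @return a `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "latitude", "longitude", "elevation", "MAT", "MAP",
            "pH", "EC", "TC", "TN", "TC_TN")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  for (v in setdiff(need, "sample_id")) {
    if (!is.numeric(md[[v]])) stop("metadata column ", v, " is not numeric")
  }
  if (any(md$elevation <= 0)) stop("elevations must be positive")
  pos <- md$TN > 0
  rel <- abs(md$TC_TN[pos] - md$TC[pos] / md$TN[pos]) /
    pmax(abs(md$TC_TN[pos]), .Machine$double.eps)
  if (any(rel > 1e-6)) {
    stop("TC_TN inconsistent with TC / TN for sample(s): ",
         paste(md$sample_id[pos][rel > 1e-6], collapse = ", "))
  }
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Write a correlation matrix to TSV files
#'
#' Emits `<prefix>_r.tsv` and `<prefix>_p.tsv`, each a square matrix with an
#' `otu_id` lead column, plus a `# method=... n_samples=...` header line.
#'
#' @param corr a `corr_matrix` (see [spearman_matrix()]).
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_correlation <- function(corr, prefix) {
  paths <- paste0(prefix, c("_r.tsv", "_p.tsv"))
  for (k in 1:2) {
    m <- if (k == 1) corr$r else corr$p
    con <- file(paths[k], "w")
    writeLines(sprintf("# method=%s n_samples=%d", corr$method, corr$n_samples), con)
    df <- data.frame(otu_id = corr$otu_ids,
                     formatC(m, digits = 6, format = "g"),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("otu_id", corr$otu_ids)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read a correlation matrix written by [write_correlation()]
#' @param prefix path prefix used when writing.
#' @return a `corr_matrix`.
#' @export
read_correlation <- function(prefix) {
  read_one <- function(path) {
    hdr <- readLines(path, n = 1)
    df <- utils::read.delim(path, skip = 1, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    list(m = m, hdr = hdr)
  }
  r <- read_one(paste0(prefix, "_r.tsv"))
  p <- read_one(paste0(prefix, "_p.tsv"))
  method <- sub(".*method=(\\S+).*", "\\1", r$hdr)
  n <- as.integer(sub(".*n_samples=(\\d+).*", "\\1", r$hdr))
  corr_matrix(r$m, p$m, method = method, n_samples = n)
}

#' Write a co-occurrence network
#'
#' `edge_tsv` writes one data row per edge with columns `source`, `target`,
#' `r`, `p`, `sign`, `link_class`; `graphml` serializes the full graph
#' (including isolated nodes) with node attributes `domain` and `abundance`.
#'
#' @param network a `coocc_network` (see [build_network()]).
#' @param path output path.
#' @param dialect `"edge_tsv"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, dialect = c("edge_tsv", "graphml")) {
  dialect <- match.arg(dialect)
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("refusing to write an empty network")
  if (dialect == "edge_tsv") {
    write_tsv(network_edges(network), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML co-occurrence network written by [write_network()]
#' @param path GraphML path.
#' @return a `coocc_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ga <- igraph::graph_attr(g)
  structure(list(graph = g,
                 r_threshold = ga$r_threshold %||% NA_real_,
                 p_threshold = ga$p_threshold %||% NA_real_,
                 method = ga$method %||% NA_character_),
            class = "coocc_network")
}

#' Write generator ground truth (edge list + parameter echo)
#' @param truth a `ground_truth` from [generate_otu_tables()].
#' @param edges_path TSV for the planted edge list.
#' @param params_path key=value echo of the generative parameters.
#' @export
write_ground_truth <- function(truth, edges_path, params_path) {
  write_tsv(truth$edges, edges_path)
  lines <- c(sprintf("seed=%d", truth$params$seed),
             sprintf("fraction_negative=%.6f", truth$fraction_negative),
             unlist(lapply(truth$params$domain_configs, function(dc) {
               sprintf("%s.%s=%s", dc$domain,
                       c("pool_size", "richness_intercept", "richness_slope",
                         "richness_sd", "depth", "lognormal_sigma"),
                       c(dc$pool_size, dc$richness_intercept, dc$richness_slope,
                         dc$richness_sd, dc$depth, dc$lognormal_sigma))
             })))
  writeLines(lines, params_path)
  invisible(edges_path)
}
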