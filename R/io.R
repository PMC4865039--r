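#' Read an expression matrix from tab-separated text
#'
#' Two dialects are supported.  `"generic"`: first row holds sample
#' identifiers (an optional corner label is ignored), first column holds gene
#' identifiers, body is numeric; `transpose = TRUE` reads the samples-by-genes
#' orientation instead.  `"dream3_null_mutants"`: rows are strains and
#' columns are genes, as in steady-state null-mutant compendia; the strain
#' whose label matches `wild_type_labels` (case-insensitive) becomes the
#' designated wild-type sample, and every other strain label must name the
#' deleted gene (an optional trailing `"(-)"` is stripped), populating the
#' knockout annotations.
#'
#' Ragged rows and non-numeric cells raise parse errors naming the offending
#' line; duplicate gene identifiers raise a validation error.
#'
#' @param path file path of a UTF-8, tab-separated file.
#' @param dialect input layout, see Details.
#' @param transpose for `"generic"`: input is samples x genes.
#' @param wild_type_labels strain labels recognized as wild type.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path,
                            dialect = c("generic", "dream3_null_mutants"),
                            transpose = FALSE,
                            wild_type_labels = c("wt", "wild-type")) {
  dialect <- match.arg(dialect)
  tab <- read_tsv_table(path)
  header <- tab$header; rows <- tab$rows; labels <- tab$labels
  vals <- parse_numeric_body(rows, tab$line_numbers, path)
  rownames(vals) <- labels
  colnames(vals) <- header

  if (dialect == "generic") {
    if (transpose) vals <- t(vals)
    return(expression_matrix(vals))
  }

  # dream3_null_mutants: rows = strains, columns = genes
  genes <- header
  strains <- labels
  is_wt <- tolower(strains) %in% tolower(wild_type_labels)
  if (sum(is_wt) != 1)
    stop("dream3_null_mutants dialect requires exactly one wild-type strain (",
         paste(wild_type_labels, collapse = "/"), "); found ", sum(is_wt))
  ko_strains <- strains[!is_wt]
  ko_genes <- sub("\\(-\\)$", "", ko_strains)
  unknown <- setdiff(ko_genes, genes)
  if (length(unknown))
    stop("knockout strain label(s) do not match any gene: ",
         paste(unknown, collapse = ", "))
  expression_matrix(t(vals),
                    knockout_of = stats::setNames(ko_genes, ko_strains),
                    wild_type = strains[is_wt])
}

# shared TSV scaffolding: header row + labeled numeric rows, ragged-row checks
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[seq_len(max(which(nzchar(lines)), 0))]
  if (length(lines) < 2) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  header <- fields[[1]]
  # corner cell: header may carry one label per data column, or one extra
  body_width <- widths[2]
  if (length(header) == body_width) header <- header[-1]
  else if (length(header) != body_width - 1)
    stop(sprintf("parse error in %s: header has %d fields but line 2 has %d",
                 path, widths[1], body_width))
  bad <- which(widths[-1] != body_width) + 1L
  if (length(bad))
    stop(sprintf("parse error in %s: line %d has %d fields, expected %d",
                 path, bad[1], widths[bad[1]], body_width))
  rows <- lapply(fields[-1], `[`, -1L)
  labels <- vapply(fields[-1], `[[`, character(1), 1L)
  list(header = header, labels = labels, rows = rows,
       line_numbers = seq_along(lines)[-1])
}

parse_numeric_body <- function(rows, line_numbers, path) {
  out <- matrix(NA_real_, length(rows), length(rows[[1]]))
  for (i in seq_along(rows)) {
    x <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(x))
      stop(sprintf("parse error in %s: non-numeric value '%s' on line %d",
                   path, rows[[i]][which(is.na(x))[1]], line_numbers[i]))
    out[i, ] <- x
  }
  out
}

#' Read a gold-standard edge list as an undirected network
#'
#' Reads a DREAM-style three-column tab-separated edge list
#' (regulator, target, 0/1 label; no header).  Because the inferred skeleton
#' is undirected, directed records are collapsed by OR: an unordered pair is
#' present iff any directed record between the two genes carries label 1.
#' The operation is idempotent under record duplication.
#'
#' @param path file path.
#' @param genes character vector, the gene universe; records naming genes
#'   outside it raise a validation error.
#' @return a binary [gene_network()] over `genes`.
#' @export
read_gold_standard <- function(path, genes) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  net <- gene_network(genes)
  if (!length(lines)) return(net)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad))
    stop(sprintf("parse error in %s: line %d has %d fields, expected 3",
                 path, bad[1], lengths(fields)[bad[1]]))
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  lab <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(lab)) stop("parse error in ", path, ": non-numeric edge label")
  unknown <- setdiff(c(a, b), genes)
  if (length(unknown))
    stop("unknown gene identifier(s) in gold standard: ",
         paste(unique(unknown), collapse = ", "))
  if (any(a == b & lab == 1)) stop("self-pair in gold standard")
  keep <- lab == 1
  for (k in which(keep)) {
    net$adjacency[a[k], b[k]] <- net$adjacency[b[k], a[k]] <- TRUE
    net$strength[a[k], b[k]] <- net$strength[b[k], a[k]] <- 1
  }
  net
}

#' Write / read an inferred network as a tab-separated edge list
#'
#' `write_network` writes one row per surviving undirected edge
#' (`gene_a`, `gene_b`, `strength`), in deterministic lexicographic order,
#' preceded by a header row (an empty network therefore yields a stable
#' header-only file).  Strengths are printed with 10 significant digits so a
#' round-trip preserves them well beyond 6 significant digits.
#' `read_network` reads the same format back over a gene universe.
#'
#' @param net a [gene_network()].
#' @param path output (input) file path.
#' @param genes gene universe for `read_network`.
#' @return `write_network`: invisibly, `path`; `read_network`: a
#'   [gene_network()].
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  ed <- network_edges(net)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tstrength", con)
  if (nrow(ed))
    writeLines(sprintf("%s\t%s\t%.10g", ed$gene_a, ed$gene_b, ed$strength), con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, genes) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines) || lines[1] != "gene_a\tgene_b\tstrength")
    stop("parse error in ", path, ": missing edge-list header")
  lines <- lines[-1]
  if (!length(lines)) return(gene_network(genes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3))
    stop("parse error in ", path, ": expected 3 tab-separated fields per row")
  gene_network(genes, data.frame(
    gene_a = vapply(fields, `[[`, character(1), 1),
    gene_b = vapply(fields, `[[`, character(1), 2),
    strength = as.numeric(vapply(fields, `[[`, character(1), 3)),
    stringsAsFactors = FALSE))
}
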