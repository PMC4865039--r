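#' Undirected gene network
#'
#' An undirected, optionally weighted graph over a fixed gene universe.  This
#' is the object the path-consistency loop thins: it starts complete and loses
#' edges as conditional independences are found.  Edge strengths (in nats) are
#' defined exactly on the present edges.
#'
#' @param genes character vector of gene identifiers (the universe).
#' @param edges optional data frame with columns `gene_a`, `gene_b` and
#'   optionally `strength`; each row one undirected edge.  Self-pairs are
#'   rejected.
#' @return An object of class `"gene_network"`: list with `gene_ids`,
#'   logical symmetric `adjacency` matrix and numeric `strength` matrix
#'   (`NA` off the edge set).
#' @examples
#' net <- gene_network(c("A", "B", "C"),
#'                     data.frame(gene_a = "A", gene_b = "B", strength = 0.4))
#' network_edges(net)
#' @export
gene_network <- function(genes, edges = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  n <- length(genes)
  adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  str <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  net <- structure(list(gene_ids = genes, adjacency = adj, strength = str),
                   class = "gene_network")
  if (!is.null(edges) && nrow(edges)) {
    a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
    bad <- setdiff(c(a, b), genes)
    if (length(bad)) stop("unknown gene identifier(s): ",
                          paste(unique(bad), collapse = ", "))
    if (any(a == b)) stop("self-pairs are not allowed")
    w <- if ("strength" %in% names(edges)) as.numeric(edges$strength) else
      rep(1, length(a))
    for (k in seq_along(a)) {
      net$adjacency[a[k], b[k]] <- net$adjacency[b[k], a[k]] <- TRUE
      net$strength[a[k], b[k]] <- net$strength[b[k], a[k]] <- w[k]
    }
  }
  net
}

#' @rdname gene_network
#' @param x a `gene_network`.
#' @export
complete_network <- function(genes) {
  genes <- as.character(genes)
  net <- gene_network(genes)
  net$adjacency[] <- TRUE
  diag(net$adjacency) <- FALSE
  net$strength[net$adjacency] <- Inf   # no evidence recorded yet
  net
}

#' @rdname gene_network
#' @export
n_edges <- function(x) sum(x$adjacency[upper.tri(x$adjacency)])

#' Edge table of a gene network
#'
#' Rows are the present undirected edges in deterministic lexicographic order
#' (`gene_a < gene_b` by C-locale string order).
#'
#' @param net a `gene_network`.
#' @return data frame with columns `gene_a`, `gene_b`, `strength`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  g <- net$gene_ids
  a <- g[idx[, 1]]; b <- g[idx[, 2]]
  swap <- lex_gt(a, b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- net$strength[idx]
  o <- order(a, b, method = "radix")
  data.frame(gene_a = a[o], gene_b = b[o], strength = w[o],
             stringsAsFactors = FALSE)
}

# locale-independent string comparison helpers
lex_sort <- function(x) sort(x, method = "radix")
lex_gt <- function(a, b) {
  if (!length(a)) return(logical(0))
  o <- order(c(a, b), method = "radix")
  pos <- integer(length(o)); pos[o] <- seq_along(o)
  pos[seq_along(a)] > pos[length(a) + seq_along(b)]
}

# all unordered pairs over sorted gene ids, in lexicographic order
gene_pairs <- function(genes) {
  g <- lex_sort(genes)
  n <- length(g)
  if (n < 2) return(data.frame(gene_a = character(), gene_b = character()))
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  data.frame(gene_a = g[i], gene_b = g[j], stringsAsFactors = FALSE)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d genes, %d undirected edges\n",
              length(x$gene_ids), n_edges(x)))
  invisible(x)
}
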