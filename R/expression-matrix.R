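#' Expression matrix with optional knockout annotations
#'
#' Container for a genes-by-samples matrix of expression values.  Samples may
#' optionally be annotated as single-gene knockout (null-mutant) strains, with
#' one designated wild-type sample, which is the layout of steady-state
#' null-mutant compendia: one wild-type profile plus one profile per deleted
#' gene.
#'
#' @param values numeric matrix, rows = genes, columns = samples.  Row and
#'   column names are used as gene and sample identifiers; default identifiers
#'   are generated when absent.
#' @param knockout_of optional named character vector mapping a sample
#'   identifier to the gene deleted in that strain.
#' @param wild_type optional sample identifier of the wild-type profile.
#' @return An object of class `"expr_mat"`: a list with elements `values`
#'   (the named matrix), `knockout_of` and `wild_type`.
#' @examples
#' x <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' em <- expression_matrix(x)
#' n_genes(em); n_samples(em)
#' @export
expression_matrix <- function(values, knockout_of = NULL, wild_type = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  em <- structure(list(values = values,
                       knockout_of = knockout_of,
                       wild_type = wild_type),
                  class = "expr_mat")
  validate_expr_mat(em)
}

validate_expr_mat <- function(em) {
  v <- em$values
  g <- rownames(v); s <- colnames(v)
  if (anyDuplicated(g)) stop("duplicate gene identifiers: ",
                             paste(unique(g[duplicated(g)]), collapse = ", "))
  if (anyDuplicated(s)) stop("duplicate sample identifiers")
  if (!all(is.finite(v))) stop("expression values must all be finite")
  ko <- em$knockout_of
  if (!is.null(ko)) {
    if (is.null(names(ko)) || !all(names(ko) %in% s))
      stop("names of 'knockout_of' must be sample identifiers")
    bad <- setdiff(ko, g)
    if (length(bad)) stop("knockout_of refers to unknown gene(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(em$wild_type) && !em$wild_type %in% s)
    stop("wild_type sample '", em$wild_type, "' not found")
  em
}

#' @rdname expression_matrix
#' @param x object to coerce or query.
#' @export
as_expression_matrix <- function(x) {
  if (inherits(x, "expr_mat")) return(x)
  if (is.matrix(x)) return(expression_matrix(x))
  stop("cannot coerce object of class '", class(x)[1], "' to expression_matrix")
}

#' @rdname expression_matrix
#' @export
n_genes <- function(x) nrow(as_expression_matrix(x)$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) ncol(as_expression_matrix(x)$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) rownames(as_expression_matrix(x)$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$knockout_of))
    cat(sprintf("  knockout strains: %d%s\n", length(x$knockout_of),
                if (!is.null(x$wild_type))
                  sprintf(" (wild type: %s)", x$wild_type) else ""))
  invisible(x)
}
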