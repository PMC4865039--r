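#' Direction hints from knockout z-tests
#'
#' For every knockout strain (gene `k` deleted) and every readout gene `g`,
#' the z-score `z = (x[g, ko_k] - mean_wt(g)) / sd(g)` compares the strain's
#' expression of `g` against the wild-type level.  `sd(g)` is estimated per
#' gene across all strains (a single wild-type profile carries no spread of
#' its own).  Readout genes whose two-sided normal p-value falls below
#' `alpha` are taken as perturbed by the deletion, yielding the ordered
#' regulator-to-target pair `k -> g`: knocking out `k` moved `g`, so `k` acts
#' upstream of `g`.  No multiple-testing correction is applied.
#'
#' The scale `sd(g)` is a robust estimate of the measurement-noise standard
#' deviation: `1.4826 * median(|x - wild type|)` pooled over all gene-strain
#' cells of the compendium.  A per-gene spread cannot be estimated from a
#' single profile per strain -- a gene downstream of many regulators is
#' genuinely shifted in most strains, so any per-strain-ensemble scale
#' (plain or robust) absorbs the regulatory signal itself and masks true
#' regulations.  Pooling across genes under the sparsity assumption that
#' most gene-strain cells are unperturbed recovers the noise floor; see the
#' vignette for the limitation this implies for strongly heteroscedastic
#' data.  A compendium identical to wild type everywhere yields no
#' detections (the scale degenerates and genes are excluded with a warning).
#'
#' @param expr an [expression_matrix()] carrying `knockout_of` annotations and
#'   a designated wild-type sample.
#' @param alpha two-sided significance level in `[0, 1]`; `alpha = 0` yields
#'   an empty hint set.
#' @return object of class `"direction_hints"`: list with `pairs` (data frame
#'   `regulator`, `target`), `alpha`, and the full `z_scores` matrix
#'   (knockout gene x readout gene).
#' @seealso [classify_patterns()] which consumes the hints.
#' @export
infer_directions <- function(expr, alpha = 0.05) {
  em <- as_expression_matrix(expr)
  if (is.null(em$knockout_of) || !length(em$knockout_of))
    stop("no knockout annotations present; run inference with fallback = \"neighbors\" instead")
  if (is.null(em$wild_type))
    stop("no wild-type sample designated")
  stopifnot(alpha >= 0, alpha <= 1)
  v <- em$values
  genes <- rownames(v)
  wt <- v[, em$wild_type]
  dev <- abs(v[, setdiff(colnames(v), em$wild_type), drop = FALSE] - wt)
  scale <- 1.4826 * stats::median(dev)
  sds <- rep(scale, nrow(v))
  names(sds) <- rownames(v)
  usable <- sds > 0 & apply(v, 1, function(r) stats::sd(r) > 0)
  if (any(!usable))
    warning("excluding constant gene(s) from z-tests: ",
            paste(genes[!usable], collapse = ", "))
  ko_samples <- names(em$knockout_of)
  ko_genes <- unname(em$knockout_of)
  z <- matrix(NA_real_, length(ko_genes), length(genes),
              dimnames = list(ko_genes, genes))
  reg <- character(0); tgt <- character(0)
  for (i in seq_along(ko_samples)) {
    k <- ko_genes[i]
    zi <- (v[, ko_samples[i]] - wt) / sds
    zi[!usable] <- NA_real_
    z[i, ] <- zi
    p <- 2 * stats::pnorm(-abs(zi))
    hit <- genes[usable & genes != k & !is.na(p) & p < alpha]
    reg <- c(reg, rep(k, length(hit)))
    tgt <- c(tgt, hit)
  }
  structure(list(pairs = data.frame(regulator = reg, target = tgt,
                                    stringsAsFactors = FALSE),
                 alpha = alpha, z_scores = z),
            class = "direction_hints")
}

#' @export
print.direction_hints <- function(x, ...) {
  cat(sprintf("Direction hints: %d regulator->target pairs (alpha = %g)\n",
              nrow(x$pairs), x$alpha))
  invisible(x)
}

#' @export
as.data.frame.direction_hints <- function(x, ...) x$pairs

has_hint <- function(hints, from, to) {
  if (is.null(hints) || !nrow(hints$pairs)) return(FALSE)
  any(hints$pairs$regulator == from & hints$pairs$target == to)
}

#' Common neighbors of an edge
#'
#' Genes adjacent to both endpoints of an edge in the current network,
#' excluding the endpoints, in deterministic lexicographic order.  These are
#' the only genes eligible as conditioning candidates for that edge.
#'
#' @param net a [gene_network()].
#' @param i,j gene identifiers of the edge's endpoints.
#' @return character vector (possibly empty).
#' @export
common_neighbors <- function(net, i, j) {
  stopifnot(inherits(net, "gene_network"))
  g <- net$gene_ids
  if (!i %in% g || !j %in% g)
    stop("gene not in network: ", paste(setdiff(c(i, j), g), collapse = ", "))
  nb <- g[net$adjacency[i, ] & net$adjacency[j, ]]
  lex_sort(setdiff(nb, c(i, j)))
}

#' Classify conditioning candidates for an edge by regulation pattern
#'
#' Each common neighbor `A` of the edge `(i, j)` is classified against the
#' direction hints:
#' \itemize{
#'   \item co-regulator if `A -> i` and `A -> j` (the endpoints share the
#'     upstream gene `A`; the single-/multi-input co-regulation pattern);
#'   \item chain intermediate if `i -> A -> j` or `j -> A -> i` (one endpoint
#'     reaches the other both directly and through `A`; the indirect-regulation
#'     / regulator-chain pattern).
#' }
#' A neighbor may satisfy both roles (the mix pattern).  The candidate gene
#' set is the union of the two lists and its size `T` caps the conditioning
#' order at which the edge can still be tested.
#'
#' Neighbors with no orientation evidence at all (no hint pair linking them
#' to either endpoint) are handled by the `fallback` policy:
#' `"neighbors"` admits them as candidates (with no hints whatsoever this
#' reduces the method to classical neighborhood conditioning),
#' `"none"` excludes them, leaving only pattern-classified candidates.
#' A neighbor with partial evidence that fails to complete any pattern is
#' always excluded.
#'
#' @inheritParams common_neighbors
#' @param hints a `direction_hints` object or `NULL`.
#' @param fallback behavior without orientation evidence, see Details.
#' @return object of class `"candidate_patterns"`: list with `edge`,
#'   `co_regulators`, `chain_intermediates`, `mixed` (the union) and `T`.
#' @export
classify_patterns <- function(net, hints, i, j,
                              fallback = c("neighbors", "none")) {
  fallback <- match.arg(fallback)
  cn <- common_neighbors(net, i, j)
  no_hints <- is.null(hints) || !nrow(hints$pairs)
  if (no_hints) {
    cand <- if (fallback == "neighbors") cn else character(0)
    co <- chain <- cand
  } else {
    co <- cn[vapply(cn, function(a)
      has_hint(hints, a, i) && has_hint(hints, a, j), logical(1))]
    chain <- cn[vapply(cn, function(a)
      (has_hint(hints, i, a) && has_hint(hints, a, j)) ||
      (has_hint(hints, j, a) && has_hint(hints, a, i)), logical(1))]
    if (fallback == "neighbors") {
      unoriented <- cn[vapply(cn, function(a)
        !(has_hint(hints, a, i) || has_hint(hints, i, a) ||
          has_hint(hints, a, j) || has_hint(hints, j, a)), logical(1))]
      co <- lex_sort(union(co, unoriented))
      chain <- lex_sort(union(chain, unoriented))
    }
  }
  mixed <- lex_sort(union(co, chain))
  structure(list(edge = c(i, j), co_regulators = co,
                 chain_intermediates = chain, mixed = mixed,
                 T = length(mixed)),
            class = "candidate_patterns")
}

#' @export
print.candidate_patterns <- function(x, ...) {
  cat(sprintf("Edge (%s, %s): %d candidate gene(s)\n", x$edge[1], x$edge[2], x$T))
  if (length(x$co_regulators))
    cat("  co-regulators:      ", paste(x$co_regulators, collapse = ", "), "\n")
  if (length(x$chain_intermediates))
    cat("  chain intermediates:", paste(x$chain_intermediates, collapse = ", "), "\n")
  invisible(x)
}
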