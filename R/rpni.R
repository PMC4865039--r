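#' Infer a gene regulatory network skeleton by pattern-guided path consistency
#'
#' Fits an undirected regulatory network to steady-state expression data.
#' Starting from the complete graph, edges are deleted in rounds of
#' increasing conditioning order `L`:
#' \itemize{
#'   \item Order 0: every pair's Gaussian mutual information is computed and
#'     edges with `MI < theta` are deleted.
#'   \item Order `L >= 1`: for each surviving edge `(i, j)` the candidate
#'     conditioning genes are the common neighbors classified into
#'     co-regulation / indirect-regulation / mix patterns
#'     ([classify_patterns()]); with `T` candidates and `T >= L`, all
#'     `choose(T, L)` size-`L` subsets are scored with CMI2 and the edge is
#'     deleted iff the maximal score falls below `theta`.  Edges with
#'     `T < L` are skipped at that order.
#' }
#' The loop stops after the first full pass that deletes no edge (which
#' includes the case where no surviving edge has enough candidates).
#' Deletions act on a live graph: an edge removed earlier in a pass no longer
#' contributes common neighbors to edges tested later in the same pass.
#' Inference is fully deterministic: edges and candidate subsets are
#' enumerated in lexicographic gene-id order and no randomness is used.
#'
#' When the data carry knockout (null-mutant) annotations, regulator-target
#' direction hints are first inferred by z-tests ([infer_directions()]) and
#' candidate genes are restricted to the detected patterns; without such
#' annotations the `fallback` policy applies.
#'
#' The reported strength of a surviving edge is the minimum over orders of
#' the evidence that retained it (its MI at order 0, its maximal CMI2 at each
#' higher order) -- the binding, weakest link of the evidence chain.
#'
#' @param x an [expression_matrix()] (optionally with knockout annotations)
#'   or a plain genes-by-samples numeric matrix.  At least 2 genes and 3
#'   samples.
#' @param theta dependence threshold in nats (`>= 0`).  Default: 0.03 for
#'   networks of up to 20 genes, 0.05 for larger ones.
#' @param alpha significance level of the knockout z-tests.
#' @param fallback candidate policy when no direction hints are available:
#'   `"neighbors"` conditions on all common neighbors (classical
#'   neighborhood conditioning), `"none"` disables conditioning.
#' @param max_order optional cap on the conditioning order (default
#'   unbounded; the loop terminates naturally).
#' @param measure dependence measure at orders `>= 1`: `"cmi2"` (the
#'   package's estimator) or `"cmi"` (classical conditional mutual
#'   information, provided as a comparison mode).
#' @param hints `"auto"` (infer from knockout annotations when present), a
#'   [infer_directions()] result, or `NULL` to force the fallback policy.
#' @param verbose emit a `message()` per order and per edge under test
#'   (debug aid; default off).
#' @return Object of class `"rpni"` with components `network` (a
#'   [gene_network()] of surviving edges and strengths), `trace` (per-order
#'   deletion records, see Details), `theta`, `alpha`, `measure`,
#'   `fallback`, `hints`, `n`, `m` and `call`.  Methods: `print`, `summary`,
#'   `coef` (edge table) and `plot`.
#' @examples
#' net <- simulate_network(8, density = 0.25, seed = 1)
#' expr <- simulate_steady_state(net, m = 300, seed = 2)
#' fit <- rpni(expr, theta = 0.03)
#' fit
#' coef(fit)
#' @export
rpni <- function(x, theta = NULL, alpha = 0.05,
                 fallback = c("neighbors", "none"), max_order = Inf,
                 measure = c("cmi2", "cmi"), hints = "auto", verbose = FALSE) {
  cl <- match.call()
  fallback <- match.arg(fallback)
  measure <- match.arg(measure)
  em <- as_expression_matrix(x)
  n <- n_genes(em); m <- n_samples(em)
  if (n < 2) stop("need at least 2 genes")
  if (m < 3) stop("need at least 3 samples")
  if (is.null(theta)) theta <- if (n <= 20) 0.03 else 0.05
  if (theta < 0) stop("theta must be >= 0")
  if (identical(hints, "auto")) {
    hints <- if (!is.null(em$knockout_of) && length(em$knockout_of) &&
                 !is.null(em$wild_type))
      infer_directions(em, alpha) else NULL
  } else if (!is.null(hints) && !inherits(hints, "direction_hints")) {
    stop("'hints' must be \"auto\", NULL, or a direction_hints object")
  }

  S <- gene_covariance(em)
  genes <- gene_ids(em)
  net <- complete_network(genes)
  kernel <- if (measure == "cmi2") cmi2_cov else cmi_cov

  orders <- list()
  # ---- order 0: marginal mutual information --------------------------------
  prs <- gene_pairs(genes)
  calls0 <- 0L
  del <- empty_deletions()
  if (verbose) message("L=0 testing all ", nrow(prs), " pairs by MI")
  for (r in seq_len(nrow(prs))) {
    a <- prs$gene_a[r]; b <- prs$gene_b[r]
    v <- mi_cov(S, a, b); calls0 <- calls0 + 1L
    if (v < theta) {
      net$adjacency[a, b] <- net$adjacency[b, a] <- FALSE
      net$strength[a, b] <- net$strength[b, a] <- NA_real_
      del <- rbind(del, data.frame(gene_a = a, gene_b = b, max_value = v,
                                   cond_set = "", stringsAsFactors = FALSE))
    } else {
      net$strength[a, b] <- net$strength[b, a] <- v
    }
  }
  orders[[1]] <- list(L = 0L, edges_tested = nrow(prs),
                      edges_deleted = del, cmi2_calls = calls0,
                      edges_remaining = n_edges(net))

  # ---- orders L >= 1: pattern-conditioned CMI2 -----------------------------
  L <- 0L
  while (nrow(orders[[length(orders)]]$edges_deleted) > 0 && L < max_order) {
    L <- L + 1L
    live <- network_edges(net)[, c("gene_a", "gene_b")]
    calls <- 0L; tested <- 0L
    del <- empty_deletions()
    for (r in seq_len(nrow(live))) {
      a <- live$gene_a[r]; b <- live$gene_b[r]
      pat <- classify_patterns(net, hints, a, b, fallback)
      if (pat$T < L) next
      tested <- tested + 1L
      if (verbose)
        message(sprintf("L=%d testing edge (%s,%s), T=%d candidates",
                        L, a, b, pat$T))
      combos <- utils::combn(pat$mixed, L, simplify = FALSE)
      best <- -Inf; best_k <- NULL
      for (k in combos) {
        v <- tryCatch(kernel(S, a, b, k), error = function(e) {
          warning(sprintf("skipping conditioning set {%s} for edge (%s,%s): %s",
                          paste(k, collapse = ","), a, b, conditionMessage(e)),
                  call. = FALSE)
          NA_real_
        })
        if (is.na(v)) next
        calls <- calls + 1L
        if (v > best) { best <- v; best_k <- k }
      }
      if (!is.finite(best)) next  # no computable subset: edge retained
      if (best < theta) {
        net$adjacency[a, b] <- net$adjacency[b, a] <- FALSE
        net$strength[a, b] <- net$strength[b, a] <- NA_real_
        del <- rbind(del, data.frame(gene_a = a, gene_b = b, max_value = best,
                                     cond_set = paste(best_k, collapse = ","),
                                     stringsAsFactors = FALSE))
      } else {
        s <- min(net$strength[a, b], best)
        net$strength[a, b] <- net$strength[b, a] <- s
      }
    }
    orders[[length(orders) + 1]] <- list(L = L, edges_tested = tested,
                                         edges_deleted = del,
                                         cmi2_calls = calls,
                                         edges_remaining = n_edges(net))
    if (tested == 0) break  # no edge has enough candidate genes
  }

  trace <- structure(list(orders = orders,
                          final_order = orders[[length(orders)]]$L,
                          cmi2_calls = sum(vapply(orders, `[[`, integer(1),
                                                  "cmi2_calls"))),
                     class = "rpni_trace")
  structure(list(network = net, trace = trace, theta = theta, alpha = alpha,
                 measure = measure, fallback = fallback, hints = hints,
                 n = n, m = m, call = cl),
            class = "rpni")
}

empty_deletions <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             max_value = numeric(), cond_set = character(),
             stringsAsFactors = FALSE)
}

#' Worst-case count of CMI2 evaluations
#'
#' Upper bound `n^2 (n-1)^(k-1) / (k-1)!` on the number of dependence
#' evaluations the inference loop can perform on a graph with `n` genes and
#' maximal degree `k`.  Used to flag configurations whose worst case is
#' infeasible; every recorded trace satisfies
#' `trace$cmi2_calls <= cmi2_call_bound(n, k)`.
#'
#' @param n number of genes (`>= 2`).
#' @param k maximal vertex degree (`1 <= k < n`).
#' @return the bound as a double (may be astronomically large).
#' @examples
#' cmi2_call_bound(10, 2)  # 900
#' @export
cmi2_call_bound <- function(n, k) {
  stopifnot(n >= 2, k >= 1, k < n)
  n^2 * exp((k - 1) * log(n - 1) - lgamma(k))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.rpni <- function(x, ...) {
  cat("Pattern-guided path-consistency network inference\n")
  cat(sprintf("  %d genes, %d samples; theta = %g nats, measure = %s\n",
              x$n, x$m, x$theta, toupper(x$measure)))
  if (!is.null(x$hints))
    cat(sprintf("  direction hints: %d knockout-derived pairs (alpha = %g)\n",
                nrow(x$hints$pairs), x$alpha))
  else
    cat(sprintf("  no knockout data; candidate fallback = \"%s\"\n", x$fallback))
  cat(sprintf("  final order L = %d; %d of %d possible edges retained\n",
              x$trace$final_order, n_edges(x$network), choose(x$n, 2)))
  invisible(x)
}

#' @export
summary.rpni <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$trace$orders, function(o)
    data.frame(order = o$L, edges_tested = o$edges_tested,
               edges_deleted = nrow(o$edges_deleted),
               dependence_calls = o$cmi2_calls,
               edges_remaining = o$edges_remaining)))
  structure(list(fit = object, per_order = tab), class = "summary.rpni")
}

#' @export
print.summary.rpni <- function(x, ...) {
  print(x$fit)
  cat("\nPer-order trace:\n")
  print(x$per_order, row.names = FALSE)
  invisible(x)
}

#' @export
coef.rpni <- function(object, ...) network_edges(object$network)

#' Plot an inferred network
#'
#' Draws the surviving edges with igraph (circular layout, deterministic).
#' Edge widths scale with inferred strength.
#'
#' @param x an `rpni` fit.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.rpni <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the 'igraph' package")
  ed <- coef(x)
  g <- igraph::graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = lex_sort(x$network$gene_ids))
  w <- ed$strength
  width <- if (length(w) && any(is.finite(w)))
    0.5 + 2.5 * w / max(w[is.finite(w)]) else 1
  igraph::plot.igraph(g, layout = igraph::layout_in_circle(g),
                      edge.width = width, ...)
  invisible(x)
}

#' @export
print.rpni_trace <- function(x, ...) {
  cat(sprintf("Inference trace: final order %d, %d dependence evaluations\n",
              x$final_order, x$cmi2_calls))
  invisible(x)
}
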