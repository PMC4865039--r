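#' Simulate a ground-truth regulatory network with planted motifs
#'
#' Generates a directed acyclic network over `n` genes.  Gene indices define
#' the topological order; all edges point from lower to higher index.  The
#' requested numbers of regulatory motifs are planted first and recorded:
#' \itemize{
#'   \item `single_input`: one regulator with (at least) two targets -- the
#'     co-regulation pattern;
#'   \item `chain`: a three-gene cascade `X -> A -> Y` -- the
#'     indirect-regulation pattern.
#' }
#' Additional random forward edges are then added until the requested edge
#' density (fraction of the `choose(n, 2)` possible pairs) is reached.
#' Effect sizes are drawn uniformly from `[effect_range[1], effect_range[2]]`
#' with random sign; each gene also receives a basal expression level drawn
#' from `Uniform(1, 3)`.  Basal levels are then raised, in topological
#' order, just enough that every gene's steady-state mean is at least 0.5:
#' expression levels are concentrations, and a "regulator" silenced at
#' steady state (which signed effects can otherwise produce by cancellation)
#' would make its own knockout undetectable.  The adjustment only shifts
#' means; the covariance structure the inference consumes is unaffected.
#'
#' @param n number of genes (`>= 3` when motifs are requested).
#' @param density target edge density in `(0, 1]` as a fraction of all pairs.
#' @param motifs named integer vector with entries `single_input` and
#'   `chain`: how many instances of each motif to plant.
#' @param effect_range magnitude range of regulatory effects.
#' @param seed integer seed; the generator is fully reproducible.
#' @return object of class `"true_network"`: list with `gene_ids`, `edges`
#'   (data frame `regulator`, `target`, `effect`), `basal`, `motifs` (list of
#'   `kind`/`members` records) and `n`.
#' @examples
#' net <- simulate_network(10, density = 0.2, seed = 1)
#' net$edges
#' @export
simulate_network <- function(n, density = 0.2,
                             motifs = c(single_input = 1, chain = 1),
                             effect_range = c(0.5, 1.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q_si <- if ("single_input" %in% names(motifs)) motifs[["single_input"]] else 0
  q_ch <- if ("chain" %in% names(motifs)) motifs[["chain"]] else 0
  if ((q_si > 0 || q_ch > 0) && n < 3)
    stop("motif quota infeasible: need at least 3 genes")
  if (n < 2) stop("need at least 2 genes")
  ids <- sprintf("G%0*d", nchar(n), seq_len(n))
  edge_from <- integer(0); edge_to <- integer(0)
  motif_list <- list()
  add_edge <- function(i, j) {
    if (!any(edge_from == i & edge_to == j)) {
      edge_from <<- c(edge_from, i); edge_to <<- c(edge_to, j)
    }
  }
  for (s in seq_len(q_si)) {
    r <- sample.int(n - 2, 1)
    tg <- sort(sample((r + 1):n, 2))
    add_edge(r, tg[1]); add_edge(r, tg[2])
    motif_list[[length(motif_list) + 1]] <-
      list(kind = "single_input", members = ids[c(r, tg)])
  }
  for (s in seq_len(q_ch)) {
    tri <- sort(sample.int(n, 3))
    add_edge(tri[1], tri[2]); add_edge(tri[2], tri[3])
    motif_list[[length(motif_list) + 1]] <-
      list(kind = "chain", members = ids[tri])
  }
  target <- max(length(edge_from), round(density * choose(n, 2)))
  all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)  # i < j
  have <- paste(edge_from, edge_to)
  pool <- which(!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have))
  extra <- target - length(edge_from)
  if (extra > 0 && length(pool)) {
    pick <- all_pairs[sample(pool, min(extra, length(pool))), , drop = FALSE]
    edge_from <- c(edge_from, pick[, 1]); edge_to <- c(edge_to, pick[, 2])
  }
  ne <- length(edge_from)
  effects <- stats::runif(ne, effect_range[1], effect_range[2]) *
    sample(c(-1, 1), ne, replace = TRUE)
  o <- order(edge_from, edge_to)
  net <- structure(list(gene_ids = ids,
                        edges = data.frame(regulator = ids[edge_from[o]],
                                           target = ids[edge_to[o]],
                                           effect = effects[o],
                                           stringsAsFactors = FALSE),
                        basal = stats::setNames(stats::runif(n, 1, 3), ids),
                        motifs = motif_list, n = n),
                   class = "true_network")
  # positivity floor on steady-state means (see Details); in topological
  # order, raising basal_g lifts mu_g one-to-one before descendants are seen
  for (g in ids) {
    inc <- net$edges[net$edges$target == g, , drop = FALSE]
    mu_g <- net$basal[g] + sum(inc$effect * structural_means(net)[inc$regulator])
    if (mu_g < 0.5) net$basal[g] <- net$basal[g] + (0.5 - mu_g)
  }
  net
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf("True network: %d genes, %d directed edges, %d planted motif(s)\n",
              x$n, nrow(x$edges), length(x$motifs)))
  invisible(x)
}

#' Undirected skeleton of a true network
#'
#' @param net a `true_network`.
#' @return binary [gene_network()] with one undirected edge per regulated pair.
#' @export
as_gene_network <- function(net) {
  stopifnot(inherits(net, "true_network"))
  gene_network(net$gene_ids,
               data.frame(gene_a = net$edges$regulator,
                          gene_b = net$edges$target, strength = 1,
                          stringsAsFactors = FALSE))
}

# expected steady-state expression, optionally under a single-gene knockout
structural_means <- function(net, knockout = NULL) {
  ids <- net$gene_ids
  mu <- stats::setNames(numeric(net$n), ids)
  for (g in ids) {           # ids are in topological order by construction
    if (!is.null(knockout) && g == knockout) { mu[g] <- 0; next }
    inc <- net$edges[net$edges$target == g, , drop = FALSE]
    mu[g] <- net$basal[g] + sum(inc$effect * mu[inc$regulator])
  }
  mu
}

#' Simulate steady-state expression samples
#'
#' Draws `m` independent samples from the linear-Gaussian structural model:
#' in topological order, `x_g = basal_g + sum(effect * x_parent) + eps`,
#' `eps ~ Normal(0, noise_sd^2)`.  The joint distribution over genes is
#' multivariate Gaussian, matching the distributional assumption of the
#' inference model.
#'
#' @param net a [simulate_network()] result.
#' @param m number of samples.
#' @param noise_sd standard deviation of the structural noise; either a
#'   scalar or a per-gene vector (recycled in gene order), so individual
#'   genes can be made nearly deterministic given their parents.
#' @param seed integer seed.
#' @return an [expression_matrix()] (genes x samples, no knockout annotations).
#' @export
simulate_steady_state <- function(net, m, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(net, "true_network"))
  if (!is.null(seed)) set.seed(seed)
  ids <- net$gene_ids
  sds <- stats::setNames(rep_len(noise_sd, net$n), ids)
  X <- matrix(0, net$n, m, dimnames = list(ids, sprintf("S%d", seq_len(m))))
  for (g in ids) {
    inc <- net$edges[net$edges$target == g, , drop = FALSE]
    reg <- if (nrow(inc))
      drop(crossprod(inc$effect, X[inc$regulator, , drop = FALSE])) else 0
    X[g, ] <- net$basal[g] + reg + stats::rnorm(m, 0, sds[g])
  }
  expression_matrix(X)
}

#' Simulate a null-mutant (knockout) compendium
#'
#' Produces the steady-state null-mutant layout: one wild-type profile equal
#' to the noise-free structural means, plus one profile per gene in which
#' that gene is clamped to 0 (its deletion) and the interventional means are
#' propagated to its descendants.  Observation noise
#' `Normal(0, noise_sd^2)` is added to the knockout profiles (the clamped
#' gene stays exactly 0) so that downstream z-tests have a well-defined
#' spread; pass `noise_sd = 0` for the exact interventional means.
#'
#' @inheritParams simulate_steady_state
#' @return an [expression_matrix()] with `knockout_of` mapping each mutant
#'   strain to its deleted gene and wild type designated, matching the
#'   `"dream3_null_mutants"` reading dialect.
#' @export
simulate_knockouts <- function(net, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(net, "true_network"))
  if (!is.null(seed)) set.seed(seed)
  ids <- net$gene_ids
  strains <- c("wt", ids)
  X <- matrix(0, net$n, length(strains), dimnames = list(ids, strains))
  X[, "wt"] <- structural_means(net)
  for (k in ids) {
    prof <- structural_means(net, knockout = k) +
      stats::rnorm(net$n, 0, noise_sd)
    prof[match(k, ids)] <- 0
    X[, k] <- prof
  }
  expression_matrix(X, knockout_of = stats::setNames(ids, ids),
                    wild_type = "wt")
}

#' Corrupt an expression matrix with a noise model
#'
#' Three corruption models for robustness analysis:
#' \itemize{
#'   \item `"gaussian"` (measurement error): adds to gene `k` independent
#'     `Normal(0, var_k)` noise, `var_k` the gene's own sample variance, so
#'     each gene's variance doubles in expectation;
#'   \item `"outlier"` (recording/instrument error): replaces
#'     `floor(fraction * n * m)` uniformly chosen cells with draws from
#'     `Normal(mean, var)` with the mean and variance of the whole
#'     pre-corruption matrix;
#'   \item `"permute"` (position perturbation): chooses
#'     `floor(fraction * n * m)` cells and randomly reassigns their values
#'     among the chosen positions (`mode = "shuffle"`, value-conserving), or
#'     swaps each chosen cell with a uniformly chosen partner cell
#'     (`mode = "swap"`).
#' }
#'
#' @param expr an [expression_matrix()] (annotations are preserved).
#' @param kind noise model.
#' @param fraction fraction of cells affected (outlier/permute), in `[0, 1]`.
#' @param seed integer seed; corruption is deterministic under a seed.
#' @param mode permutation variant, see above.
#' @return a corrupted [expression_matrix()].
#' @export
corrupt_expression <- function(expr,
                               kind = c("gaussian", "outlier", "permute"),
                               fraction = 0.1, seed = NULL,
                               mode = c("shuffle", "swap")) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  em <- as_expression_matrix(expr)
  if (!is.null(seed)) set.seed(seed)
  v <- em$values
  nm <- length(v)
  if (kind == "gaussian") {
    sds <- apply(v, 1, stats::sd)
    v <- v + matrix(stats::rnorm(nm, 0, rep(sds, ncol(v))), nrow(v), ncol(v))
  } else {
    ncell <- floor(fraction * nm)
    if (ncell > 0) {
      cells <- sample.int(nm, ncell)
      if (kind == "outlier") {
        v[cells] <- stats::rnorm(ncell, mean(em$values), stats::sd(em$values))
      } else if (mode == "shuffle") {
        v[cells] <- v[cells][sample.int(ncell)]
      } else {
        for (c1 in cells) {
          c2 <- sample.int(nm, 1)
          tmp <- v[c1]; v[c1] <- v[c2]; v[c2] <- tmp
        }
      }
    }
  }
  em$values <- v
  em
}

#' Robustness of inference under noise corruption
#'
#' Repeats, `repeats` times with fresh simulated data, a full threshold
#' sweep of the inference under each noise specification, and aggregates the
#' operating points per threshold: mean FPR on the x axis, median TPR on the
#' y axis, plus the TPR spread (min / quartiles / max) that a box-and-whisker
#' overlay needs.  A specification with `kind = "none"` evaluates the clean
#' data and serves as the paired reference.
#'
#' @param net a [simulate_network()] truth.
#' @param m samples per simulated dataset.
#' @param specs list of noise specifications, each a list with `kind`
#'   (`"none"`, `"gaussian"`, `"outlier"`, `"permute"`) and optional
#'   `fraction`.
#' @param repeats number of repetitions (`>= 2`).
#' @param theta_grid thresholds swept at each repetition.
#' @param noise_sd structural noise of the simulated data.
#' @param seed base seed; all per-repeat and per-spec seeds derive from it.
#' @param ... further arguments to [rpni()].
#' @return object of class `"robustness_result"`: `per_theta` (data frame
#'   `spec`, `theta`, `mean_fpr`, `median_tpr`, `tpr_min`, `tpr_q1`,
#'   `tpr_q3`, `tpr_max`) and `auc` (repeats x specs matrix of per-repeat
#'   sweep AUCs).
#' @export
robustness_experiment <- function(net, m, specs, repeats = 10, theta_grid,
                                  noise_sd = 1, seed = 1, ...) {
  stopifnot(inherits(net, "true_network"), repeats >= 2)
  gold <- as_gene_network(net)
  labels <- vapply(specs, function(s)
    if (s$kind == "none") "clean" else
      paste0(s$kind, if (!is.null(s$fraction)) sprintf("_%g", s$fraction) else ""),
    character(1))
  auc <- matrix(NA_real_, repeats, length(specs),
                dimnames = list(NULL, labels))
  recs <- list()
  for (r in seq_len(repeats)) {
    base <- simulate_steady_state(net, m, noise_sd,
                                  seed = (seed + 7919L * r) %% 2147483647L)
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      dat <- if (sp$kind == "none") base else
        corrupt_expression(base, kind = sp$kind,
                           fraction = if (is.null(sp$fraction)) 0.1 else sp$fraction,
                           seed = (seed + 104729L * r + si) %% 2147483647L)
      roc <- roc_sweep(dat, gold, theta_grid, ...)
      auc[r, si] <- roc$auc
      recs[[length(recs) + 1]] <-
        cbind(spec = labels[si], rep = r, roc$points)
    }
  }
  pts <- do.call(rbind, recs)
  agg <- do.call(rbind, lapply(split(pts, list(pts$spec, pts$theta)), function(d)
    data.frame(spec = d$spec[1], theta = d$theta[1],
               mean_fpr = mean(d$FPR, na.rm = TRUE),
               median_tpr = stats::median(d$TPR, na.rm = TRUE),
               tpr_min = suppressWarnings(min(d$TPR, na.rm = TRUE)),
               tpr_q1 = stats::quantile(d$TPR, 0.25, na.rm = TRUE, names = FALSE),
               tpr_q3 = stats::quantile(d$TPR, 0.75, na.rm = TRUE, names = FALSE),
               tpr_max = suppressWarnings(max(d$TPR, na.rm = TRUE)))))
  agg <- agg[order(agg$spec, agg$theta), ]
  rownames(agg) <- NULL
  structure(list(per_theta = agg, auc = auc, specs = specs),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("Robustness experiment (", nrow(x$auc), " repeats):\n", sep = "")
  print(round(colMeans(x$auc), 4))
  invisible(x)
}
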