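## Downstream quantitative biology on the integrated single-cell feature
## table: feature-set recipes, treatment classification (standard scaling ->
## PCA -> SVM under stratified k-fold CV), deterministic manifold embedding,
## k-node principal-curve pseudotime, and z-scored marker-dynamics curves.

#' Feature-set recipe
#'
#' Selects which feature blocks enter an analysis: the morphology/
#' neighbourhood block and per-marker blocks identified by `(marker,
#' provenance)` pairs, where provenance is the column prefix used when the
#' table was built (e.g. `real_DNA`, `virt_Ecad`). Manifold recipes must
#' exclude morphology (cell spatial context and shape are linked to EM
#' state and would confound state-sensitive manifolds).
#'
#' @param name Recipe label.
#' @param markers Character vector of prefixed marker block names.
#' @param morphology Include the morphology/neighbourhood block.
#' @return A `pb_recipe`.
#' @export
feature_recipe <- function(name, markers, morphology = TRUE) {
  structure(list(name = name, markers = markers, morphology = isTRUE(morphology)),
            class = "pb_recipe")
}

.recipe_columns <- function(table, recipe) {
  cols <- character()
  if (recipe$morphology) cols <- grep("^Morph_", names(table), value = TRUE)
  for (m in recipe$markers) {
    mc <- grep(paste0("^", m, "_(Int|Rad|Tex)_"), names(table), value = TRUE)
    if (!length(mc)) stop("recipe references absent feature block: ", m)
    cols <- c(cols, mc)
  }
  cols
}

# standard scaling + PCA with enough components for >= `var_kept` variance
.fit_reducer <- function(x, var_kept = 0.95) {
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- max(2L, min(which(ve >= var_kept)))
  list(mu = mu, sd = sdv, rot = pc$rotation[, seq_len(ncomp), drop = FALSE], ncomp = ncomp)
}
.apply_reducer <- function(red, x) {
  xs <- sweep(sweep(x, 2, red$mu), 2, red$sd, "/")
  xs %*% red$rot
}

#' Classify treatment condition from a feature recipe
#'
#' Stratified k-fold cross-validated pipeline: per fold, standard scaling
#' and PCA are fitted on the training folds only (components retaining 95%
#' of the training variance), then an SVM classifies condition. Reports the
#' macro-averaged F1 per fold and the pooled confusion matrix.
#'
#' @param table Feature table with a `condition` column.
#' @param recipe A `pb_recipe` (morphology is included in classification
#'   recipes).
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed.
#' @param kernel SVM kernel (default `"radial"`).
#' @return List: `f1` per fold, `mean_f1`, `confusion` (pooled), `recipe`.
#' @export
classify_treatments <- function(table, recipe, k = 5L, seed = 0L, kernel = "radial") {
  cols <- .recipe_columns(table, recipe)
  y <- factor(table$condition)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  x <- as.matrix(table[, cols, drop = FALSE])
  fold <- stratified_kfold(y, k = k, seed = seed)
  f1s <- numeric(k)
  conf <- table(y[0], y[0])
  conf <- matrix(0L, nlevels(y), nlevels(y), dimnames = list(levels(y), levels(y)))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    red <- .fit_reducer(x[tr, , drop = FALSE])
    xtr <- .apply_reducer(red, x[tr, , drop = FALSE])
    xte <- .apply_reducer(red, x[te, , drop = FALSE])
    fit <- e1071::svm(xtr, y[tr], kernel = kernel, scale = FALSE)
    pr <- stats::predict(fit, xte)
    cm <- table(factor(y[te], levels(y)), factor(pr, levels(y)))
    conf <- conf + cm
    f1s[f] <- .macro_f1(cm)
  }
  list(f1 = f1s, mean_f1 = mean(f1s), confusion = conf, recipe = recipe$name)
}

.macro_f1 <- function(cm) {
  f1 <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]; fp <- sum(cm[, i]) - tp; fn <- sum(cm[i, ]) - tp
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, 0)
  mean(f1)
}

#' Embed cells on a 2-D manifold
#'
#' Standard-scales the recipe's features, reduces with PCA (95% variance)
#' and hands the result to the embedding backend. The deterministic `pca2`
#' backend (first two principal components) is built in; nonlinear backends
#' can be plugged in as a `function(x) -> n x 2 matrix`. Manifold recipes
#' must exclude morphology; recipes with `morphology = TRUE` are rejected.
#'
#' @param table Feature table.
#' @param recipe A `pb_recipe` with `morphology = FALSE`.
#' @param method `"pca2"` or a plugin function.
#' @return `n x 2` coordinate matrix, rows aligned with `table`.
#' @export
embed_manifold <- function(table, recipe, method = "pca2") {
  if (recipe$morphology)
    stop("manifold recipes must exclude morphology/spatial-context features")
  cols <- .recipe_columns(table, recipe)
  x <- as.matrix(table[, cols, drop = FALSE])
  red <- .fit_reducer(x)
  z <- .apply_reducer(red, x)
  if (is.function(method)) return(method(z))
  if (identical(method, "pca2")) return(z[, 1:2, drop = FALSE])
  stop("unknown embedding method")
}

#' Pseudotime configuration
#'
#' @param n_nodes Number of principal-curve nodes (default 25).
#' @param max_iter Refinement iterations (default 50).
#' @param tol Convergence: node movement below `tol` times the data
#'   diameter (default 1e-4).
#' @param root_neighbors Cells nearest each endpoint used for root
#'   determination (default 50).
#' @param n_bins Pseudotime bins for dynamics curves (default 10).
#' @return A `pb_pseudotime_config`.
#' @export
pseudotime_config <- function(n_nodes = 25L, max_iter = 50L, tol = 1e-4,
                              root_neighbors = 50L, n_bins = 10L) {
  if (n_nodes < 2L) stop("need >= 2 nodes")
  structure(list(n_nodes = as.integer(n_nodes), max_iter = as.integer(max_iter),
                 tol = tol, root_neighbors = as.integer(root_neighbors),
                 n_bins = as.integer(n_bins)),
            class = "pb_pseudotime_config")
}

# project points onto a polyline; returns arc-length parameter and segment
.project_polyline <- function(x, nodes) {
  nseg <- nrow(nodes) - 1L
  seg_len <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-nrow(nodes), , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, nrow(x)); best_t <- numeric(nrow(x))
  for (s in seq_len(nseg)) {
    a <- nodes[s, ]; b <- nodes[s + 1L, ]
    ab <- b - a
    denom <- sum(ab^2)
    tt <- if (denom > 0) pmin(pmax((sweep(x, 2, a) %*% ab) / denom, 0), 1) else matrix(0, nrow(x), 1)
    proj <- sweep(tt %*% t(ab), 2, a, `+`)
    d2 <- rowSums((x - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- cum0[s] + tt[upd] * seg_len[s]
  }
  list(arc = best_t, total = cum0[nseg + 1L], d2 = best_d2)
}

#' Fit a k-node principal curve and pseudotime
#'
#' Polygonal-line principal curve: nodes are initialised along the first
#' principal component (bin means over the PC1 ordering), then refined by
#' iterated projection (cells assigned to arc-length bins) and local
#' averaging with light neighbour smoothing, until node movement falls
#' below `tol` times the data diameter or `max_iter` iterations. Pseudotime
#' is the normalised arc length from the root, chosen as the curve endpoint
#' whose nearest-cell neighbourhood is most enriched for the control
#' condition.
#'
#' @param coords Cell coordinates (embedding or reduced feature space).
#' @param condition Condition label per cell.
#' @param config A `pb_pseudotime_config`.
#' @param control Control condition label (default `"control"`).
#' @return A `pb_pseudotime`: `nodes`, `pseudotime` in `[0,1]`, `root`
#'   (1 or `n_nodes`), `config`.
#' @export
fit_pseudotime <- function(coords, condition, config = pseudotime_config(),
                           control = "control") {
  x <- as.matrix(coords)
  if (nrow(x) < config$n_nodes) stop("need at least n_nodes cells")
  diam <- sqrt(sum((apply(x, 2, max) - apply(x, 2, min))^2))
  if (diam == 0) stop("degenerate point cloud (zero variance)")
  k <- config$n_nodes
  pc1 <- stats::prcomp(x, rank. = 1L)$x[, 1]
  qs <- stats::quantile(pc1, probs = seq(0, 1, length.out = k + 1L), names = FALSE)
  bin <- cut(pc1, unique(qs), include.lowest = TRUE, labels = FALSE)
  nodes <- matrix(NA_real_, k, ncol(x))
  for (b in seq_len(max(bin))) nodes[b, ] <- colMeans(x[bin == b, , drop = FALSE])
  nodes <- nodes[stats::complete.cases(nodes), , drop = FALSE]
  ord <- order(stats::prcomp(nodes, rank. = 1L)$x[, 1])
  nodes <- nodes[ord, , drop = FALSE]
  while (nrow(nodes) < k) { # re-split the longest segment if bins collapsed
    sl <- sqrt(rowSums(diff(nodes)^2))
    s <- which.max(sl)
    nodes <- rbind(nodes[1:s, , drop = FALSE], (nodes[s, ] + nodes[s + 1, ]) / 2,
                   nodes[(s + 1):nrow(nodes), , drop = FALSE])
  }
  for (it in seq_len(config$max_iter)) {
    pr <- .project_polyline(x, nodes)
    edges <- seq(0, pr$total, length.out = k + 1L)
    asg <- pmin(pmax(findInterval(pr$arc, edges, rightmost.closed = TRUE), 1L), k)
    newn <- nodes
    for (b in seq_len(k)) {
      inb <- asg == b
      if (any(inb)) newn[b, ] <- colMeans(x[inb, , drop = FALSE])
    }
    # light smoothing keeps the polyline from zig-zagging
    sm <- newn
    if (k > 2) sm[2:(k - 1), ] <- 0.5 * newn[2:(k - 1), , drop = FALSE] +
      0.25 * (newn[1:(k - 2), , drop = FALSE] + newn[3:k, , drop = FALSE])
    move <- max(sqrt(rowSums((sm - nodes)^2)))
    nodes <- sm
    if (move < config$tol * diam) break
  }
  pr <- .project_polyline(x, nodes)
  pt <- pr$arc / max(pr$total, 1e-12)
  # root: endpoint with the highest control fraction among nearest cells
  nn <- min(config$root_neighbors, nrow(x))
  frac_ctrl <- function(node) {
    d <- sqrt(rowSums(sweep(x, 2, node)^2))
    mean(condition[order(d)[seq_len(nn)]] == control)
  }
  root <- if (frac_ctrl(nodes[1, ]) >= frac_ctrl(nodes[k, ])) 1L else k
  if (root == k) pt <- 1 - pt
  structure(list(nodes = nodes, pseudotime = pt, root = root, config = config),
            class = "pb_pseudotime")
}

#' @export
print.pb_pseudotime <- function(x, ...) {
  cat(sprintf("<pb_pseudotime> %d-node curve, root at node %d, %d cells\n",
              nrow(x$nodes), if (x$root == 1L) 1L else nrow(x$nodes),
              length(x$pseudotime)))
  invisible(x)
}

#' Marker dynamics along pseudotime
#'
#' Per marker: the per-cell mean-intensity feature is z-scored across cells
#' and averaged within equal-count pseudotime bins (deciles by default, so
#' endpoint bins are never dominated by a handful of extreme cells) on a
#' common grid. Real and virtual series are computed separately by passing
#' the corresponding prefixed block names; a constant marker yields an
#' all-zero curve (with a warning).
#'
#' @param table Feature table.
#' @param pseudotime Per-cell pseudotime (aligned with `table` rows, or a
#'   `pb_pseudotime`).
#' @param markers Prefixed marker block names (e.g. `"virt_Ecad"`).
#' @param n_bins Number of pseudotime bins (default 10).
#' @param subset Optional logical/integer row filter per marker: a list
#'   named by marker (e.g. real series restricted to experimentally
#'   labelled wells).
#' @return List with `centers` (bin midpoints) and `curves` (matrix
#'   markers x bins of z-scored mean intensity; NA for empty bins).
#' @export
marker_dynamics <- function(table, pseudotime, markers, n_bins = 10L, subset = NULL) {
  if (inherits(pseudotime, "pb_pseudotime")) pseudotime <- pseudotime$pseudotime
  if (length(pseudotime) != nrow(table)) stop("pseudotime not aligned with table")
  edges <- unique(stats::quantile(pseudotime, seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE))
  if (length(edges) < 3) edges <- seq(0, 1, length.out = n_bins + 1L)
  n_bins <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  curves <- matrix(NA_real_, length(markers), n_bins,
                   dimnames = list(markers, NULL))
  for (m in markers) {
    col <- paste0(m, "_Int_MeanIntensity")
    if (!col %in% names(table)) stop("marker feature absent: ", col)
    rows <- seq_len(nrow(table))
    if (!is.null(subset) && !is.null(subset[[m]])) rows <- which(subset[[m]])
    v <- table[[col]][rows]
    pt <- pseudotime[rows]
    if (stats::sd(v) == 0) {
      warning("constant marker ", m, ": z-curve defined as 0")
      z <- rep(0, length(v))
    } else z <- (v - mean(v)) / stats::sd(v)
    b <- pmin(pmax(findInterval(pt, edges, rightmost.closed = TRUE), 1L), n_bins)
    for (bb in seq_len(n_bins)) {
      inb <- b == bb
      if (any(inb)) curves[m, bb] <- mean(z[inb])
    }
  }
  list(centers = centers, curves = curves)
}
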