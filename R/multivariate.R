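# PCA and OPLS-DA with Pareto scaling, S-plot statistics, differential-ion
# panel selection, and hierarchical clustering of panel-restricted z-scores.
#
# The OPLS-DA follows the orthogonal-signal-correction PLS formulation
# (NIPALS inner loop): orthogonal components are stripped from X before a
# single predictive PLS component is fitted against the class vector.

#' Pareto scaling
#'
#' Centres each column and divides by the square root of its (population)
#' standard deviation — intermediate between no scaling and unit-variance
#' scaling, the convention for MS intensity data. Zero-variance columns are
#' centred only and flagged.
#'
#' @param X Numeric matrix with at least two rows.
#' @return List with `X` (scaled matrix), `center`, `divisor` and
#'   `flagged` (zero-variance column names).
#' @export
pareto_scale <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2)
  mu <- colMeans(X)
  ctr <- sweep(X, 2, mu)
  sd <- sqrt(colMeans(ctr^2))
  zero <- sd == 0
  div <- sqrt(sd)
  div[zero] <- 1
  list(X = sweep(ctr, 2, div, "/"), center = mu, divisor = div,
       flagged = colnames(X)[zero] %||% which(zero))
}

#' Principal component analysis on Pareto-scaled data
#'
#' @param X Numeric matrix (observations x ions).
#' @param n_components Number of components, at most `min(nrow - 1, ncol)`.
#' @return `PcaModel`: list with `scores`, `loadings` (orthonormal columns),
#'   `explained_variance_pct`, `scaling`.
#' @export
fit_pca <- function(X, n_components = 2) {
  stopifnot(is.matrix(X))
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax) {
    stop("n_components must be <= min(rows - 1, ions) = ", kmax)
  }
  sc <- pareto_scale(X)
  sv <- svd(sc$X)
  ev <- sv$d^2 / sum(sv$d^2) * 100
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  structure(list(
    scores = scores,
    loadings = sv$v[, k, drop = FALSE],
    explained_variance_pct = ev[k],
    scaling = sc[c("center", "divisor")]
  ), class = "PcaModel")
}

# one NIPALS PLS component for a single y
pls1_component <- function(X, y) {
  w <- drop(crossprod(X, y)) / drop(crossprod(y))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / drop(crossprod(t))
  c_ <- drop(crossprod(y, t)) / drop(crossprod(t))
  list(w = w, t = t, p = p, c = c_)
}

#' Fit OPLS-DA with Pareto scaling
#'
#' Two-group orthogonal projections to latent structures discriminant
#' analysis: the class vector is coded -1/+1, `n_orth` y-orthogonal components
#' are iteratively removed from the Pareto-scaled matrix, and one predictive
#' PLS component is fitted to the deflated matrix. With `n_orth = 0` the
#' predictive component equals a one-component NIPALS-PLS fit. The predictive
#' score is oriented so the `positive_class` group has positive mean score.
#'
#' S-plot statistics are computed against the scaled, centred matrix that
#' entered the fit: `splot_cov[j] = cov(t_pred, X_j)` (denominator n - 1) and
#' `splot_corr[j]` the Pearson correlation.
#'
#' @param X Numeric matrix (observations x ions).
#' @param y Two-level grouping (factor or character/labels).
#' @param n_orth Number of orthogonal components (default 1).
#' @param positive_class Group coded +1; default the second sorted level.
#' @return `OplsModel`: predictive score `t_pred`, orthogonal scores `t_orth`,
#'   weights/loadings `w_pred`, `p_pred`, per-ion `splot_cov` / `splot_corr`,
#'   diagnostics `r2y`, `q2`, the group coding, and the scaling record.
#' @export
fit_oplsda <- function(X, y, n_orth = 1, positive_class = NULL) {
  stopifnot(is.matrix(X), n_orth >= 0)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("y must have exactly two groups, got ",
                             length(lev))
  if (is.null(positive_class)) positive_class <- lev[2]
  stopifnot(positive_class %in% lev)
  yv <- ifelse(y == positive_class, 1, -1)
  yv <- yv - mean(yv)
  if (all(yv == 0)) stop("constant y")
  if (n_orth >= min(nrow(X) - 1L, ncol(X))) {
    stop("n_orth must be below the rank bound min(rows - 1, ions)")
  }

  sc <- pareto_scale(X)
  X0 <- sc$X
  Xd <- X0
  t_orth <- NULL; w_orth <- NULL; p_orth <- NULL
  for (i in seq_len(n_orth)) {
    comp <- pls1_component(Xd, yv)
    wo <- comp$p - drop(crossprod(comp$w, comp$p)) * comp$w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break   # no y-orthogonal variation left
    wo <- wo / nrm
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / drop(crossprod(to))
    Xd <- Xd - tcrossprod(to, po)
    t_orth <- cbind(t_orth, to)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
  }
  fin <- pls1_component(Xd, yv)
  flip <- if (mean(fin$t[yv > 0]) < 0) -1 else 1
  t_pred <- flip * fin$t
  w_pred <- flip * fin$w
  p_pred <- flip * fin$p

  n <- nrow(X0)
  ctr <- sweep(X0, 2, colMeans(X0))
  tc <- t_pred - mean(t_pred)
  cov_j <- drop(crossprod(tc, ctr)) / (n - 1)
  sd_t <- sqrt(sum(tc^2) / (n - 1))
  sd_j <- sqrt(colSums(ctr^2) / (n - 1))
  corr_j <- rep(0, length(sd_j))
  nz <- sd_j > 0
  corr_j[nz] <- cov_j[nz] / (sd_t * sd_j[nz])

  yhat <- t_pred * drop(crossprod(yv, t_pred)) / drop(crossprod(t_pred))
  r2y <- 1 - sum((yv - yhat)^2) / sum(yv^2)
  q2 <- oplsda_q2(X, y, n_orth, positive_class)

  structure(list(
    t_pred = t_pred, t_orth = t_orth,
    w_pred = stats::setNames(w_pred, colnames(X)),
    p_pred = stats::setNames(p_pred, colnames(X)),
    w_orth = w_orth, p_orth = p_orth,
    splot_cov = stats::setNames(cov_j, colnames(X)),
    splot_corr = stats::setNames(corr_j, colnames(X)),
    r2y = r2y, q2 = q2,
    groups = y, positive_class = positive_class,
    n_orth = if (is.null(t_orth)) 0L else ncol(t_orth),
    scaling = sc[c("center", "divisor")]
  ), class = "OplsModel")
}

# leave-one-out Q2 for the y-prediction of the fitted model
oplsda_q2 <- function(X, y, n_orth, positive_class) {
  n <- nrow(X)
  if (n > 60) return(NA_real_)   # diagnostics only; skip for large fits
  yv <- ifelse(as.character(y) == positive_class, 1, -1)
  press <- 0; ss <- sum((yv - mean(yv))^2)
  for (i in seq_len(n)) {
    yi <- yv[-i]
    if (length(unique(yi)) < 2) return(NA_real_)
    fit <- try(suppressWarnings(
      fit_oplsda_raw(X[-i, , drop = FALSE], yi, n_orth)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    xnew <- (X[i, ] - fit$center) / fit$divisor
    for (k in seq_len(fit$n_orth)) {
      to <- sum(xnew * fit$w_orth[, k])
      xnew <- xnew - to * fit$p_orth[, k]
    }
    tp <- sum(xnew * fit$w)
    press <- press + (yv[i] - mean(yi) - tp * fit$c)^2
  }
  1 - press / ss
}

# minimal OPLS fit on a numeric +-1 y (internal, used by cross-validation)
fit_oplsda_raw <- function(X, yv, n_orth) {
  yv <- yv - mean(yv)
  sc <- pareto_scale(X)
  Xd <- sc$X
  w_orth <- NULL; p_orth <- NULL
  k <- 0L
  for (i in seq_len(n_orth)) {
    comp <- pls1_component(Xd, yv)
    wo <- comp$p - drop(crossprod(comp$w, comp$p)) * comp$w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break
    wo <- wo / nrm
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / drop(crossprod(to))
    Xd <- Xd - tcrossprod(to, po)
    w_orth <- cbind(w_orth, wo); p_orth <- cbind(p_orth, po)
    k <- k + 1L
  }
  fin <- pls1_component(Xd, yv)
  list(w = fin$w, c = fin$c, w_orth = w_orth, p_orth = p_orth, n_orth = k,
       center = sc$center, divisor = sc$divisor)
}

#' Select a differential-ion panel from an S-plot
#'
#' Ions whose chosen S-plot statistic exceeds the threshold in absolute value
#' are selected; direction is the statistic's sign (positive = enriched in the
#' model's positive class). An explicit exclusion list makes any post-hoc
#' visual-inspection removals auditable.
#'
#' @param m An `OplsModel`.
#' @param stat `"cov"` (S-plot covariance, the default, threshold 0.04 as used
#'   for tissue panels), `"corr"` (p(corr)) or `"loading"` (normalised
#'   predictive weight, for |p1|-style thresholds).
#' @param threshold Positive selection threshold on |stat|.
#' @param exclude Character vector of bin ids to drop post hoc (logged).
#' @param contrast Label for the panel's contrast.
#' @return `DiffPanel`: data.frame `bin_id`, `direction`, `cov`, `corr`,
#'   `stat`, `source`, with threshold/exclusions in attributes.
#' @export
select_panel <- function(m, stat = c("cov", "corr", "loading"),
                         threshold = 0.04, exclude = character(),
                         contrast = "contrast") {
  stopifnot(inherits(m, "OplsModel"), threshold > 0)
  stat <- match.arg(stat)
  s <- switch(stat, cov = m$splot_cov, corr = m$splot_corr,
              loading = m$w_pred)
  sel <- which(abs(s) >= threshold)
  panel <- data.frame(
    bin_id = names(s)[sel],
    direction = ifelse(s[sel] > 0, m$positive_class,
                       setdiff(sort(unique(m$groups)), m$positive_class)[1]),
    cov = unname(m$splot_cov[sel]),
    corr = unname(m$splot_corr[sel]),
    stat = unname(s[sel]),
    source = rep(contrast, length(sel)),
    stringsAsFactors = FALSE
  )
  dropped <- panel$bin_id[panel$bin_id %in% exclude]
  panel <- panel[!panel$bin_id %in% exclude, , drop = FALSE]
  rownames(panel) <- NULL
  if (!nrow(panel)) message("select_panel: empty panel for ", contrast)
  structure(panel, threshold = threshold, stat_used = stat,
            excluded = dropped, contrast = contrast,
            class = c("DiffPanel", "data.frame"))
}

#' Merge differential-ion panels
#'
#' Set union keyed by bin id; per-ion provenance lists every contributing
#' panel, and pairwise overlap counts are reported. Ions selected with
#' conflicting directions within one contrast are kept and flagged.
#'
#' @param panels List of `DiffPanel` objects sharing a bin-id namespace.
#' @return Merged `DiffPanel` with an `overlap` attribute (pairwise overlap
#'   count matrix) and a `conflicted` column.
#' @export
merge_panels <- function(panels) {
  stopifnot(length(panels) >= 1)
  all_df <- do.call(rbind, lapply(panels, as.data.frame))
  ids <- unique(all_df$bin_id)
  first <- all_df[match(ids, all_df$bin_id), , drop = FALSE]
  src <- vapply(ids, function(b)
    paste(unique(all_df$source[all_df$bin_id == b]), collapse = ";"), "")
  conf <- vapply(ids, function(b) {
    sub <- all_df[all_df$bin_id == b, ]
    any(tapply(sub$direction, sub$source,
               function(d) length(unique(d)) > 1))
  }, TRUE)
  merged <- data.frame(first[, c("bin_id", "direction", "cov", "corr",
                                 "stat")],
                       source = src, conflicted = unname(conf),
                       stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  k <- length(panels)
  ov <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ov[i, j] <- length(intersect(panels[[i]]$bin_id, panels[[j]]$bin_id))
  }
  structure(merged, overlap = ov, class = c("DiffPanel", "data.frame"))
}

#' Hierarchical clustering of panel-restricted z-scores
#'
#' Clusters ROIs (rows) and ions (columns) of a z-scored feature matrix,
#' optionally restricted to a panel's ions. Defaults are correlation distance
#' with average linkage, conventional for z-scored omics heat maps.
#'
#' @param fm A [feature_matrix()] (z-scoring is applied internally when the
#'   matrix is not already z-scored row-wise).
#' @param panel Optional `DiffPanel`; restricts the columns.
#' @param k Number of row clusters to cut (default: number of distinct tissue
#'   labels).
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `row_hclust`, `col_hclust`, `row_clusters`, `heatmap`
#'   (z-scored matrix in dendrogram leaf order), `rois`, and the parameters.
#' @export
hierarchical_cluster <- function(fm, panel = NULL, k = NULL,
                                 metric = c("correlation", "euclidean"),
                                 linkage = "average") {
  stopifnot(inherits(fm, "FeatureMatrix"))
  metric <- match.arg(metric)
  if (!is.null(panel)) {
    keep <- intersect(panel$bin_id, colnames(fm$values))
    if (length(keep) < 2) stop("panel leaves fewer than 2 ions")
    fm$values <- fm$values[, keep, drop = FALSE]
  }
  if (nrow(fm$values) < 2 || ncol(fm$values) < 2) {
    stop("hierarchical_cluster needs >= 2 rows and >= 2 ions")
  }
  z <- suppressWarnings(zscore_columns(fm))$values
  dist_of <- function(m) {
    if (metric == "correlation") {
      cr <- suppressWarnings(stats::cor(t(m)))
      cr[!is.finite(cr)] <- 0
      stats::as.dist(1 - cr)
    } else stats::dist(m)
  }
  rh <- stats::hclust(dist_of(z), method = linkage)
  ch <- stats::hclust(dist_of(t(z)), method = linkage)
  if (is.null(k)) k <- length(unique(fm$rois$tissue))
  clusters <- stats::cutree(rh, k = k)
  list(row_hclust = rh, col_hclust = ch, row_clusters = clusters,
       heatmap = z[rh$order, ch$order, drop = FALSE],
       rois = fm$rois, k = k, metric = metric, linkage = linkage)
}

#' Agreement between cluster labels and reference labels
#'
#' Adjusted Rand index via \pkg{mclust}, used to score recovery of known
#' tissue labels by the clustering.
#'
#' @param clusters,labels Two label vectors of equal length.
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
cluster_agreement <- function(clusters, labels) {
  mclust::adjustedRandIndex(clusters, labels)
}
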