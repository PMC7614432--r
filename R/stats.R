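# Subject- and group-level statistics: ROI-level Spearman correlation of lag
# and CVR with Wilcoxon signed-rank group inference, cross-condition spatial
# correlation, longitudinal paired comparison, voxelwise two-factor OLS
# ANOVA, and Benjamini-Hochberg FDR control.

#' Spearman correlation of lag and CVR within an ROI
#'
#' Rank correlation (average-rank tie handling) over the voxels of `roi`
#' that are valid in both maps (lag peak r >= 0.1 and a normal CVR
#' response, fit r >= 0.1). ROIs with too few jointly valid voxels, or
#' with all-tied values in either field, are flagged rather than computed.
#'
#' @param lag a `lag_map`.
#' @param cvr a `cvr_map`.
#' @param roi logical volume.
#' @param min_voxels minimum jointly valid voxels (default 10).
#' @return List with `r`, `n_voxels` and `ok` (whether `r` is usable).
#' @export
roi_spearman <- function(lag, cvr, roi, min_voxels = 10) {
  roi <- as_mask(roi, dim(lag$lag_s), "roi")
  sel <- roi & lag$valid & cvr$valid
  n <- sum(sel)
  if (n < min_voxels) {
    return(list(r = NA_real_, n_voxels = n, ok = FALSE))
  }
  x <- lag$lag_s[sel]
  y <- cvr$cvr[sel]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(r = NA_real_, n_voxels = n, ok = FALSE))
  }
  list(r = stats::cor(x, y, method = "spearman"), n_voxels = n, ok = TRUE)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha family-wise error level (e.g. 0.05).
#' @param n_tests number of tests (e.g. 6 ROIs, giving 0.0083).
#' @return Per-test alpha `family_alpha / n_tests`.
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  if (n_tests < 1) stop("`n_tests` must be at least 1")
  family_alpha / n_tests
}

# Exact two-sided signed-rank p-value by convolution over the (possibly
# tied, average-rank) absolute ranks: the null distribution of V = sum of
# positive ranks is the convolution of fair coin flips over each rank.
# Ranks are doubled so average ranks (multiples of 0.5) become integers.
signed_rank_exact_p <- function(v_stat, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- c(1, rep(0, total)) # P(V2 = 0..total), unnormalised by 2^n
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v2 <- round(2 * v_stat)
  p_le <- sum(dist[seq_len(v2 + 1)])
  p_ge <- sum(dist[(v2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test of per-subject values against zero
#'
#' Two-sided test that the per-subject correlation coefficients have median
#' zero. Zero values are dropped (standard convention). The exact null
#' distribution (enumerating sign assignments by convolution, which handles
#' tied absolute values) is used for n <= `exact_max_n`; a normal
#' approximation with continuity and tie correction is used above.
#'
#' @param values per-subject values (e.g. Spearman r per subject).
#' @param alpha significance level (default the Bonferroni-corrected
#'   0.05/6).
#' @param exact_max_n largest n for the exact distribution (default 25).
#' @return List with `statistic` (V), `p`, `significant` (strict
#'   `p < alpha`), and `n` after dropping zeros.
#' @export
group_wilcoxon_vs_zero <- function(values, alpha = 0.05 / 6,
                                   exact_max_n = 25) {
  v <- values[!is.na(values)]
  v <- v[v != 0]
  n <- length(v)
  if (n == 0L) {
    return(list(statistic = NA_real_, p = 1, significant = FALSE, n = 0L))
  }
  ranks <- rank(abs(v))
  V <- sum(ranks[v > 0])
  if (n <= exact_max_n) {
    p <- signed_rank_exact_p(V, ranks)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p = p, significant = p < alpha, n = n)
}

#' Spatial Pearson correlation between two lag maps
#'
#' Pearson correlation of the lag values over the voxels jointly valid in
#' both maps (optionally restricted to `mask`); used to quantify the
#' consistency of lag maps across conditions.
#'
#' @param map_a,map_b `lag_map` objects on the same grid.
#' @param mask optional logical volume.
#' @param min_voxels minimum jointly valid voxels (default 10).
#' @return List with `r`, `n_voxels` and `ok`.
#' @export
spatial_pearson <- function(map_a, map_b, mask = NULL, min_voxels = 10) {
  sel <- map_a$valid & map_b$valid
  if (!is.null(mask)) sel <- sel & as_mask(mask, dim(map_a$lag_s), "mask")
  n <- sum(sel)
  if (n < min_voxels) return(list(r = NA_real_, n_voxels = n, ok = FALSE))
  x <- map_a$lag_s[sel]
  y <- map_b$lag_s[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n_voxels = n, ok = FALSE))
  }
  list(r = stats::cor(x, y), n_voxels = n, ok = TRUE)
}

#' One-tailed paired t-test
#'
#' Paired t-test of `v1` against `v2` in the stated direction
#' (`"greater"`: mean of `v1 - v2` is positive, i.e. values decreased from
#' `v1` to `v2`). Identical pairs (t = 0) return p = 0.5 by the boundary
#' convention; zero-variance non-zero differences are flagged degenerate.
#'
#' @param v1,v2 paired per-subject values (n >= 3).
#' @param alternative `"greater"` or `"less"` for the mean of `v1 - v2`.
#' @return List with `t`, `df`, `p` and `degenerate`.
#' @export
paired_onetailed_ttest <- function(v1, v2,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(v1) != length(v2)) stop("`v1` and `v2` must be paired")
  d <- v1 - v2
  n <- length(d)
  if (n < 3L) stop("need at least 3 pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 0.5, degenerate = TRUE))
    }
    ok_dir <- (mean(d) > 0) == (alternative == "greater")
    return(list(t = if (ok_dir) Inf else -Inf, df = n - 1,
                p = if (ok_dir) 0 else 1, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- if (alternative == "greater") {
    stats::pt(t, n - 1, lower.tail = FALSE)
  } else {
    stats::pt(t, n - 1)
  }
  list(t = t, df = n - 1, p = p, degenerate = FALSE)
}

#' Voxelwise two-factor OLS ANOVA on lag maps
#'
#' Per voxel, ordinary-least-squares fit of lag on group, timepoint and
#' their interaction (effect coding), with an F-test per term against the
#' full model and Benjamini-Hochberg FDR control at level `q` per term.
#' The analysis mask is restricted to voxels valid in at least
#' `valid_fraction` of subjects; at each voxel only the subjects valid
#' there enter the fit, and voxels where the design becomes rank-deficient
#' are dropped from the mask.
#'
#' @param maps list of `lag_map` objects (one per scan).
#' @param group factor (or vector) of group labels, one per map.
#' @param timepoint factor of timepoint labels, one per map.
#' @param valid_fraction minimum per-voxel valid-subject fraction
#'   (default 0.8).
#' @param q FDR level (default 0.1).
#' @return A `group_anova` object: per-term 3D arrays of `F`, `p` and
#'   FDR-significance masks, plus the analysis `mask` and degrees of
#'   freedom.
#' @export
voxelwise_group_anova <- function(maps, group, timepoint,
                                  valid_fraction = 0.8, q = 0.1) {
  ns <- length(maps)
  group <- factor(group)
  timepoint <- factor(timepoint)
  if (length(group) != ns || length(timepoint) != ns) {
    stop("`group` and `timepoint` must have one label per map")
  }
  if (nlevels(group) < 2L || nlevels(timepoint) < 2L) {
    stop("single-cell design: need at least 2 levels of group and timepoint")
  }
  if (min(table(group, timepoint)) < 2L) {
    stop("need at least 2 subjects in every group x timepoint cell")
  }
  dims <- dim(maps[[1]]$lag_s)
  L <- do.call(rbind, lapply(maps, function(m) as.vector(m$lag_s))) # subjects x voxels
  Vd <- sapply(maps, function(m) as.vector(m$valid)) # voxels x subjects
  in_any <- as.vector(Reduce(`|`, lapply(maps, function(m) m$mask)))
  mask_vec <- in_any & rowMeans(Vd) >= valid_fraction
  vox <- which(mask_vec)

  old_contr <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_contr))
  X <- stats::model.matrix(~ group * timepoint)
  asg <- attr(X, "assign") # 0 = intercept, 1 = group, 2 = timepoint, 3 = interaction
  terms <- c(group = 1L, timepoint = 2L, interaction = 3L)
  p_full <- ncol(X)

  n_vox <- length(vox)
  Fm <- matrix(NA_real_, n_vox, 3)
  Pm <- matrix(NA_real_, n_vox, 3)
  df2v <- rep(NA_real_, n_vox)
  drop_vox <- rep(FALSE, n_vox)

  fit_block <- function(rows, cols) {
    # returns F and p (3 terms each) for the voxel columns `cols`, using
    # subject rows `rows`; all columns share the same row set
    Xs <- X[rows, , drop = FALSE]
    qrf <- qr(Xs)
    if (qrf$rank < p_full) return(NULL)
    Ys <- L[rows, cols, drop = FALSE]
    rss_f <- colSums(qr.resid(qrf, Ys)^2)
    df2 <- length(rows) - p_full
    out_F <- matrix(NA_real_, length(cols), 3)
    out_P <- matrix(NA_real_, length(cols), 3)
    for (tt in 1:3) {
      keep <- asg != terms[tt]
      qrr <- qr(Xs[, keep, drop = FALSE])
      rss_r <- colSums(qr.resid(qrr, Ys)^2)
      df1 <- sum(!keep)
      Fv <- ((rss_r - rss_f) / df1) / (rss_f / df2)
      Fv[rss_f <= 1e-12 * pmax(colSums(Ys^2), 1)] <- NA_real_ # degenerate fit
      out_F[, tt] <- Fv
      out_P[, tt] <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    list(F = out_F, p = out_P, df2 = df2)
  }

  # fit voxels sharing the same valid-subject pattern in one vectorised block
  valid_pat <- apply(Vd[vox, , drop = FALSE], 1, function(z) paste(which(z), collapse = ","))
  for (pat in unique(valid_pat)) {
    cols <- which(valid_pat == pat)
    rows <- as.integer(strsplit(pat, ",")[[1]])
    res <- fit_block(rows, vox[cols])
    if (is.null(res)) {
      drop_vox[cols] <- TRUE
    } else {
      Fm[cols, ] <- res$F
      Pm[cols, ] <- res$p
      df2v[cols] <- res$df2
    }
  }
  drop_vox <- drop_vox | apply(is.na(Pm), 1, all)
  mask_vec[vox[drop_vox]] <- FALSE
  keep_vox <- !drop_vox

  to_vol <- function(vals) {
    out <- array(NA_real_, dim = dims)
    out[vox[keep_vox]] <- vals[keep_vox]
    out
  }
  term_names <- names(terms)
  result <- list(mask = array(mask_vec, dim = dims), q = q,
                 df1 = c(group = nlevels(group) - 1L,
                         timepoint = nlevels(timepoint) - 1L,
                         interaction = (nlevels(group) - 1L) * (nlevels(timepoint) - 1L)),
                 terms = term_names)
  for (tt in seq_along(term_names)) {
    pvol <- to_vol(Pm[, tt])
    sig <- array(FALSE, dim = dims)
    pv <- Pm[keep_vox, tt]
    rej <- fdr_bh(pv, q)
    sig[vox[keep_vox]] <- rej
    result[[paste0("F_", term_names[tt])]] <- to_vol(Fm[, tt])
    result[[paste0("p_", term_names[tt])]] <- pvol
    result[[paste0("sig_", term_names[tt])]] <- sig
  }
  structure(result, class = "group_anova")
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, find
#' the largest `k` with `p_(k) <= k q / m` and reject the `k` smallest
#' p-values. `NA` p-values are never rejected and do not count toward `m`.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.1).
#' @return Logical rejection mask, same length as `p_values`.
#' @export
fdr_bh <- function(p_values, q = 0.1) {
  out <- rep(FALSE, length(p_values))
  ok <- which(!is.na(p_values))
  m <- length(ok)
  if (m == 0L) return(out)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  if (length(below)) {
    k <- max(below)
    out[ok[o[seq_len(k)]]] <- TRUE
  }
  out
}
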