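#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of alternate-allele dosages over the
#' samples called at both sites — the r-squared linkage measure used
#' for pruning. When either site has zero dosage variance, r-squared is
#' defined as 1 if the two dosage vectors are identical over the
#' shared samples and `NA` otherwise.
#'
#' @param dosage_i,dosage_j Numeric dosage vectors (0/1/2, `NA`
#'   missing) of equal length.
#' @return A single numeric r-squared (or `NA`).
#' @export
pairwise_r2 <- function(dosage_i, dosage_j) {
  stopifnot(length(dosage_i) == length(dosage_j))
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) {
    warn("fewer than two samples called at both sites")
    return(NA_real_)
  }
  x <- dosage_i[ok]
  y <- dosage_j[ok]
  if (var(x) == 0 || var(y) == 0) {
    return(if (all(x == y)) 1 else NA_real_)
  }
  cor(x, y)^2
}

# r2 matrix for a window of dosage columns, with the same zero-variance
# convention as pairwise_r2 (identical columns -> 1, otherwise NA)
window_r2 <- function(sub) {
  r2 <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))^2
  if (anyNA(r2)) {
    na_idx <- which(is.na(r2), arr.ind = TRUE)
    for (k in seq_len(nrow(na_idx))) {
      i <- na_idx[k, 1]
      j <- na_idx[k, 2]
      ok <- !is.na(sub[, i]) & !is.na(sub[, j])
      if (sum(ok) >= 2 && all(sub[ok, i] == sub[ok, j])) r2[i, j] <- 1
    }
  }
  r2
}

#' LD pruning of a dosage matrix
#'
#' Sliding-window pruning in the style of plink's `--indep-pairwise`:
#' within each window (at most `window_bp` wide on one chromosome),
#' site pairs are scanned in position order and the later site of any
#' pair with r-squared above `r2_max` is removed; the window start
#' then advances by `step` retained sites. Passes repeat until no site
#' is removed, so the retained set never contains a within-window pair
#' above the threshold and re-running is idempotent.
#'
#' @param dosage Wide dosage tibble from [dosage_matrix()]; sites must
#'   be sorted by (chrom, pos), as that constructor guarantees.
#' @param window_bp Window span in bp (default 50,000).
#' @param step Window step in retained sites (default 10).
#' @param r2_max Linkage threshold (default 0.2).
#' @return Character vector of retained site names (columns of
#'   `dosage`).
#' @export
ld_prune <- function(dosage, window_bp = 50000, step = 10, r2_max = 0.2) {
  sites <- dosage_sites(dosage)
  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_along(ord))) {
    abort("sites must be sorted by (chrom, pos)")
  }
  mat <- as.matrix(dosage[, sites$site, drop = FALSE])

  retained <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    keep <- rep(TRUE, length(idx))
    pos <- sites$pos[idx]
    repeat {
      removed <- FALSE
      kept_idx <- which(keep)
      s <- 1L
      while (s <= length(kept_idx)) {
        w_first <- kept_idx[s]
        in_win <- kept_idx[kept_idx >= w_first &
                             pos[kept_idx] <= pos[w_first] + window_bp]
        if (length(in_win) > 1) {
          r2m <- window_r2(mat[, idx[in_win], drop = FALSE])
          for (ii in seq_along(in_win)[-length(in_win)]) {
            if (!keep[in_win[ii]]) next
            for (jj in (ii + 1):length(in_win)) {
              j <- in_win[jj]
              if (!keep[j]) next
              if (!is.na(r2m[ii, jj]) && r2m[ii, jj] > r2_max) {
                keep[j] <- FALSE
                removed <- TRUE
              }
            }
          }
        }
        kept_idx <- which(keep)
        s <- s + step
      }
      if (!removed) break
    }
    idx[keep]
  })
  sites$site[sort(unlist(retained, use.names = FALSE))]
}

#' Principal component analysis of a dosage matrix
#'
#' Missing dosages are mean-imputed per site, columns are centred
#' (optionally unit-scaled) and the sample configuration is obtained by
#' singular value decomposition. Percent variance per axis is the
#' eigenvalue as a share of the total variance.
#'
#' @param dosage Wide dosage tibble from [dosage_matrix()].
#' @param k Number of axes to keep (default 2).
#' @param scale Unit-scale columns? Default `FALSE`.
#' @return A `geno_pca` object; see [tidy.geno_pca()],
#'   [glance.geno_pca()] and [autoplot.geno_pca()].
#' @export
pca_genotypes <- function(dosage, k = 2, scale = FALSE) {
  mat <- as.matrix(dosage[, setdiff(names(dosage), "sample_id"), drop = FALSE])
  rownames(mat) <- dosage$sample_id
  if (any(rowSums(!is.na(mat)) == 0)) abort("sample with no called sites")
  if (k > min(dim(mat))) abort("k exceeds min(samples, sites)")
  # per-site mean imputation
  mu <- colMeans(mat, na.rm = TRUE)
  idx <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(idx) > 0) mat[idx] <- mu[idx[, 2]]
  mat <- scale(mat, center = TRUE, scale = scale)
  if (scale) mat[, attr(mat, "scaled:scale") == 0] <- 0
  sv <- svd(mat, nu = k, nv = 0)
  ev <- sv$d^2 / max(1, nrow(mat) - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = bind_cols(tibble(sample_id = dosage$sample_id),
                         as_tibble(scores)),
      eigenvalues = ev,
      percent_var = if (sum(ev) > 0) 100 * ev / sum(ev) else rep(0, length(ev)),
      k = k, n_samples = nrow(mat), n_sites = ncol(mat)
    ),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d samples x %d sites, %d axes kept\n",
              x$n_samples, x$n_sites, x$k))
  pv <- paste0(sprintf("%.1f%%", x$percent_var[seq_len(x$k)]), collapse = ", ")
  cat("  percent variance:", pv, "\n")
  invisible(x)
}

#' Tidy a genotype PCA
#'
#' @param x A `geno_pca`.
#' @param matrix `"scores"` (per-sample axis coordinates) or
#'   `"eigenvalues"` (per-axis variance shares).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, matrix = c("scores", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") return(x$scores)
  tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         percent_var = x$percent_var)
}

#' One-row summary of a genotype PCA
#'
#' @param x A `geno_pca`.
#' @param ... Unused.
#' @return One-row tibble with dimensions and the variance explained by
#'   the first two axes.
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_sites = x$n_sites, k = x$k,
         pc1_pct = x$percent_var[1],
         pc2_pct = if (length(x$percent_var) > 1) x$percent_var[2] else NA_real_)
}

#' Plot the first two axes of a genotype PCA
#'
#' @param object A `geno_pca` (with k >= 2).
#' @param groups Optional tibble `sample_id`, `group` used to colour
#'   points (e.g. metadata taxon labels).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, groups = NULL, ...) {
  dat <- object$scores
  if (!is.null(groups)) dat <- left_join(dat, groups, by = "sample_id")
  aes <- if (!is.null(groups)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$percent_var[1]),
      y = sprintf("PC2 (%.1f%%)", object$percent_var[2])
    ) +
    ggplot2::theme_minimal()
}

#' Nei's genetic distance between two individuals
#'
#' Individual-level Nei distance over shared (both-called) biallelic
#' loci using within-individual allele frequencies in \{0, 0.5, 1\}:
#' with per-locus identities `Jxy = mean_l sum_a x_a y_a`,
#' `Jx = mean_l sum_a x_a^2`, `Jy = mean_l sum_a y_a^2`, the distance
#' is `-ln(Jxy / sqrt(Jx Jy))`. Individuals sharing no alleles at any
#' locus (Jxy = 0) are at infinite distance, returned as `Inf` with a
#' warning.
#'
#' @param dosage_x,dosage_y Dosage vectors (0/1/2, `NA` missing) over
#'   the same loci.
#' @return A single non-negative numeric distance.
#' @export
nei_distance <- function(dosage_x, dosage_y) {
  stopifnot(length(dosage_x) == length(dosage_y))
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  if (!any(ok)) abort("no shared called loci")
  x <- dosage_x[ok] / 2 # alt-allele frequency within the individual
  y <- dosage_y[ok] / 2
  jxy <- mean(x * y + (1 - x) * (1 - y))
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  if (jxy == 0) {
    warn("no shared alleles at any locus: Nei distance is infinite")
    return(Inf)
  }
  -log(jxy / sqrt(jx * jy))
}

#' Pairwise Nei distance matrix
#'
#' @param dosage Wide dosage tibble from [dosage_matrix()].
#' @return Symmetric matrix of Nei distances with sample ids as
#'   dimnames.
#' @export
nei_dist_matrix <- function(dosage) {
  mat <- as.matrix(dosage[, setdiff(names(dosage), "sample_id"),
                          drop = FALSE])
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(dosage$sample_id,
                                         dosage$sample_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- nei_distance(mat[i, ], mat[j, ])
    }
  }
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees
#'   (vectorised).
#' @return Numeric distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Pairwise geographic distance matrix from metadata
#'
#' @param metadata Tibble with `sample_id`, `latitude`, `longitude`.
#' @return Symmetric matrix of great-circle distances (km).
#' @export
geo_dist_matrix <- function(metadata) {
  n <- nrow(metadata)
  out <- matrix(0, n, n,
                dimnames = list(metadata$sample_id, metadata$sample_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- great_circle_km(metadata$latitude[i], metadata$longitude[i],
                         metadata$latitude[j], metadata$longitude[j])
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Mantel test of isolation by distance
#'
#' Monte-Carlo Mantel test of the correlation between a genetic and a
#' geographic distance matrix: the observed statistic is the Pearson
#' correlation of the off-diagonal entries, the null distribution is
#' obtained by permuting the sample labels of one matrix, and the
#' one-sided (greater) p-value is
#' `(number of permuted r >= observed r + 1) / (n_perm + 1)`.
#' Implemented with `vegan::mantel`; the seed makes the permutation
#' stream, and hence the p-value, reproducible bitwise.
#'
#' @param genetic_dist,geographic_dist Square symmetric matrices with
#'   matching sample order and zero diagonals.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `mantel_ibd` object; see [glance.mantel_ibd()].
#' @export
mantel_ibd <- function(genetic_dist, geographic_dist, n_perm = 999,
                       seed = 1) {
  check_dist <- function(m, what) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
        any(diag(m) != 0)) {
      abort(paste0(what, " must be a square symmetric matrix with zero diagonal"))
    }
    m
  }
  gd <- check_dist(genetic_dist, "genetic_dist")
  gg <- check_dist(geographic_dist, "geographic_dist")
  if (nrow(gd) != nrow(gg)) abort("matrices must match in dimension")

  fit <- withr::with_seed(seed, {
    vegan::mantel(stats::as.dist(gd), stats::as.dist(gg),
                  method = "pearson", permutations = n_perm)
  })
  structure(
    list(r_observed = unname(fit$statistic), p_value = fit$signif,
         n_permutations = n_perm, seed = seed,
         n_samples = nrow(gd), n_pairs = nrow(gd) * (nrow(gd) - 1) / 2),
    class = "mantel_ibd"
  )
}

#' @export
print.mantel_ibd <- function(x, ...) {
  cat(sprintf(
    "Mantel isolation-by-distance test: r = %.4f, p = %.4g (%d permutations, %d pairs)\n",
    x$r_observed, x$p_value, x$n_permutations, x$n_pairs
  ))
  invisible(x)
}

#' One-row summary of a Mantel IBD test
#'
#' @param x A `mantel_ibd`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance mantel_ibd
#' @export
glance.mantel_ibd <- function(x, ...) {
  tibble(r_observed = x$r_observed, p_value = x$p_value,
         n_permutations = x$n_permutations, n_pairs = x$n_pairs,
         n_samples = x$n_samples, seed = x$seed)
}

#' @rdname glance.mantel_ibd
#' @method tidy mantel_ibd
#' @export
tidy.mantel_ibd <- function(x, ...) glance(x)

#' Isolation-by-distance scatter plot
#'
#' @param genetic_dist,geographic_dist Distance matrices as in
#'   [mantel_ibd()].
#' @return A ggplot of pairwise genetic vs geographic distance with a
#'   least-squares line.
#' @export
plot_ibd <- function(genetic_dist, geographic_dist) {
  gd <- as.matrix(genetic_dist)
  gg <- as.matrix(geographic_dist)
  ut <- upper.tri(gd)
  dat <- tibble(geographic_km = gg[ut], genetic = gd[ut])
  ggplot2::ggplot(dat, ggplot2::aes(.data$geographic_km, .data$genetic)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "geographic distance (km)",
                  y = "Nei genetic distance") +
    ggplot2::theme_minimal()
}
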