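test_that("pairwise r2 is squared Pearson correlation of dosages", {
  expect_equal(pairwise_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  # perfect negative correlation still counts as full linkage
  expect_equal(pairwise_r2(c(0, 1, 2, 1), c(2, 1, 0, 1)), 1)
  # hand Pearson: orthogonal half-half patterns
  expect_equal(pairwise_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # zero variance: identical -> 1, different -> flagged
  expect_equal(pairwise_r2(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_true(is.na(pairwise_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_warning(r <- pairwise_r2(c(NA, NA, 1), c(1, 2, NA)), "fewer")
  expect_true(is.na(r))
})

# build a wide dosage tibble from a samples x sites matrix
dosage_from_matrix <- function(mat, chrom = "chr1",
                               pos = seq_len(ncol(mat)) * 1000) {
  colnames(mat) <- paste(chrom, pos, "G", sep = ":")
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(mat)))),
    tibble::as_tibble(mat)
  )
}

test_that("LD pruning removes the later of any linked pair and is idempotent", {
  # two duplicated sites 1 kb apart: keep the first
  base <- c(0, 1, 2, 0, 1, 2, 0, 1)
  dup <- dosage_from_matrix(cbind(base, base), pos = c(1000, 2000))
  expect_equal(ld_prune(dup), "chr1:1000:G")

  # five perfectly correlated sites + five sites mutually orthogonal (and
  # orthogonal to the correlated pattern, Hadamard-style) -> six retained
  corr <- c(0, 0, 0, 0, 1, 1, 1, 1)
  h <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
             c(0, 0, 1, 1, 0, 0, 1, 1),
             c(0, 1, 1, 0, 0, 1, 1, 0),
             c(0, 1, 0, 1, 1, 0, 1, 0),
             c(0, 0, 1, 1, 1, 1, 0, 0))
  corr_block <- matrix(rep(corr, 5), ncol = 5)
  dm <- dosage_from_matrix(cbind(corr_block, h), pos = (1:10) * 100)
  kept <- ld_prune(dm)
  expect_equal(kept, paste("chr1", c(1, 6:10) * 100, "G", sep = ":"))

  # orthogonal sites all survive
  indep <- dosage_from_matrix(h, pos = (1:5) * 100)
  expect_equal(length(ld_prune(indep)), 5)

  # idempotent, and no retained within-window pair exceeds the threshold
  set.seed(14)
  noisy <- matrix(sample(0:2, 20 * 30, replace = TRUE), nrow = 20)
  noisy[, 2] <- noisy[, 1] # plant one linked pair
  dn <- dosage_from_matrix(noisy)
  k1 <- ld_prune(dn)
  k2 <- ld_prune(dn[, c("sample_id", k1)])
  expect_equal(k1, k2)
  mat <- as.matrix(dn[, k1])
  ps <- dosage_sites(dn[, c("sample_id", k1)])$pos
  for (i in seq_along(k1)) {
    for (j in seq_along(k1)) {
      if (j > i && ps[j] - ps[i] <= 50000) {
        expect_lte(pairwise_r2(mat[, i], mat[, j]), 0.2)
      }
    }
  }

  unsorted <- dn[, c("sample_id", rev(setdiff(names(dn), "sample_id")))]
  expect_error(ld_prune(unsorted), "sorted")
})

test_that("PCA separates clusters and keeps axes orthogonal", {
  # two homogeneous clusters: PC1 carries all the variance
  mat <- rbind(matrix(0, 4, 10), matrix(2, 4, 10))
  p <- pca_genotypes(dosage_from_matrix(mat), k = 2)
  expect_equal(p$percent_var[1], 100)
  expect_true(all(sign(p$scores$PC1[1:4]) != sign(p$scores$PC1[5:8])))

  # identical rows: zero variance, zero coordinates
  flat <- pca_genotypes(dosage_from_matrix(matrix(1, 5, 8)), k = 2)
  expect_true(all(abs(unlist(flat$scores[, -1])) < 1e-12))
  expect_true(all(flat$percent_var == 0))

  # admixed individuals land between the two parental clusters on PC1
  mid <- rbind(matrix(0, 4, 10), matrix(2, 4, 10), matrix(1, 2, 10))
  pm <- pca_genotypes(dosage_from_matrix(mid), k = 2)
  pc1 <- pm$scores$PC1
  expect_true(all(pc1[9:10] > min(pc1[1:8]) & pc1[9:10] < max(pc1[1:8])))

  # orthogonal score axes, variance shares bounded
  set.seed(5)
  rnd <- matrix(sample(0:2, 12 * 40, TRUE), nrow = 12)
  rnd[3, 5] <- NA # exercise mean imputation
  pr <- pca_genotypes(dosage_from_matrix(rnd), k = 3)
  g <- crossprod(as.matrix(pr$scores[, -1]))
  expect_true(all(abs(g[upper.tri(g)]) < 1e-8))
  expect_lte(sum(pr$percent_var), 100 + 1e-8)
  expect_error(pca_genotypes(dosage_from_matrix(rnd), k = 50), "exceeds")
})

test_that("Nei distance matches hand arithmetic and its axioms", {
  expect_equal(nei_distance(c(0, 2, 1), c(0, 2, 1)), 0)
  # single locus, x fixed alt, y heterozygous: -ln(0.5 / sqrt(0.5))
  expect_equal(nei_distance(2, 1), -log(0.5 / sqrt(1 * 0.5)))
  expect_equal(round(nei_distance(2, 1), 4), 0.3466)
  # fixed opposite alleles at every locus: infinite, flagged
  expect_warning(d_inf <- nei_distance(c(0, 0), c(2, 2)), "infinite")
  expect_equal(d_inf, Inf)
  # symmetry and sensitivity to fixed differences
  x <- c(0, 1, 2, 2, 0)
  y <- c(0, 1, 2, 0, 1)
  expect_equal(nei_distance(x, y), nei_distance(y, x))
  y_worse <- c(2, 1, 2, 0, 1) # shared fixed locus 1 becomes a fixed difference
  expect_gt(nei_distance(x, y_worse), nei_distance(x, y))
  expect_error(nei_distance(NA_real_, 1), "shared")
})

test_that("great-circle distances use the haversine closed form", {
  expect_equal(great_circle_km(-12, 142, -12, 142), 0)
  # one degree of longitude on the equator
  expect_equal(great_circle_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(round(great_circle_km(0, 0, 0, 1), 2), 111.19)
  expect_equal(great_circle_km(-12, 142, -14, 143),
               great_circle_km(-14, 143, -12, 142))
})

test_that("the Mantel test recovers perfect isolation by distance", {
  set.seed(9)
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:15),
                         latitude = runif(15, -16, -11),
                         longitude = runif(15, 141, 146))
  gg <- geo_dist_matrix(meta)
  gd <- gg * 2 # genetic distance exactly proportional to geography
  m <- mantel_ibd(gd, gg, n_perm = 999, seed = 1)
  expect_equal(m$r_observed, 1)
  expect_equal(m$p_value, 1 / 1000)
  expect_equal(m$n_pairs, 105)

  # bitwise reproducible under the seed
  m2 <- mantel_ibd(gd, gg, n_perm = 999, seed = 1)
  expect_identical(glance(m), glance(m2))

  # anti-correlated matrices
  anti <- max(gg) - gg
  diag(anti) <- 0
  expect_equal(mantel_ibd(anti, gg, n_perm = 99, seed = 1)$r_observed, -1,
               tolerance = 1e-12)

  bad <- gg
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(mantel_ibd(bad, gg), "symmetric")
})
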