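test_that("site patterns are recognised column by column", {
  expect_equal(count_site_patterns(as_four_taxon(c("G", "T", "T", "G")))$n_abba, 1)
  expect_equal(count_site_patterns(as_four_taxon(c("T", "G", "T", "G")))$n_baba, 1)
  bbaa <- count_site_patterns(as_four_taxon(c("T", "T", "G", "G")))
  expect_equal(bbaa$n_abba + bbaa$n_baba, 0)
  expect_equal(bbaa$n_informative, 1)

  # hand-enumerated six-column alignment:
  # ABBA, ABBA, BABA, BBAA, monomorphic, gapped -> counts (2, 1)
  aln <- aln_from_columns(list(
    c("G", "T", "T", "G"), c("A", "C", "C", "A"), c("T", "G", "T", "G"),
    c("T", "T", "G", "G"), c("A", "A", "A", "A"), c("A", "-", "A", "A")
  ))
  cs <- count_site_patterns(aln)
  expect_equal(cs$n_abba, 2)
  expect_equal(cs$n_baba, 1)
  expect_equal(cs$n_informative, 4)

  # third-allele outgroup columns are skipped, identical sequences count nothing
  third <- count_site_patterns(as_four_taxon(c("G", "T", "T", "C")))
  expect_equal(third$n_informative, 0)
  same <- count_site_patterns(as_four_taxon(rep("ACGT", 4)))
  expect_equal(same$n_abba + same$n_baba + same$n_informative, 0)

  # region restriction
  expect_equal(count_site_patterns(aln, region = c(5, 6))$n_informative, 0)
  expect_error(as_four_taxon(c("AC", "AC", "AC", "A")), "equal")
})

test_that("Patterson's D is the normalised ABBA-BABA contrast", {
  expect_equal(patterson_d(7, 7), 0)
  # block-1 counts of the first published four-taxon test
  expect_equal(patterson_d(168, 10), (168 - 10) / (168 + 10))
  expect_equal(round(patterson_d(168, 10), 4), 0.8876)
  expect_equal(patterson_d(0, 8), -1)
  expect_warning(d0 <- patterson_d(0, 0), "undefined")
  expect_true(is.na(d0))
})

test_that("block partitioning reproduces the published boundaries and tiles", {
  b <- partition_blocks(4473, n_blocks = 4)
  expect_equal(b$start, c(1L, 1119L, 2237L, 3355L))
  expect_equal(b$end, c(1118L, 2236L, 3354L, 4473L))

  b2 <- partition_blocks(100, block_len = 30)
  expect_equal(b2$start, c(1L, 31L, 61L, 91L))
  expect_equal(b2$end, c(30L, 60L, 90L, 100L))

  expect_equal(partition_blocks(10, n_blocks = 1),
               tibble::tibble(block = 1L, start = 1L, end = 10L))
  expect_warning(b3 <- partition_blocks(10, block_len = 50), "single block")
  expect_equal(nrow(b3), 1)

  # property: any partition tiles [1, L] without overlap
  set.seed(21)
  for (i in 1:20) {
    L <- sample(10:5000, 1)
    n <- sample(1:8, 1)
    bb <- partition_blocks(L, n_blocks = n)
    expect_equal(bb$start[1], 1L)
    expect_equal(bb$end[nrow(bb)], L)
    if (nrow(bb) > 1) expect_equal(bb$start[-1], bb$end[-nrow(bb)] + 1L)
  }
  expect_error(partition_blocks(100, n_blocks = 4, block_len = 10),
               "exactly one")
})

test_that("the block jackknife matches a hand-computed delete-one oracle", {
  # four 12-column blocks engineered to give per-block (ABBA, BABA) counts
  # (3,1), (2,2), (4,0), (1,3); the rest of each block is monomorphic
  abba <- c("G", "T", "T", "G")
  baba <- c("T", "G", "T", "G")
  mono <- c("A", "A", "A", "A")
  block_cols <- function(n_abba, n_baba) {
    c(rep(list(abba), n_abba), rep(list(baba), n_baba),
      rep(list(mono), 12 - n_abba - n_baba))
  }
  aln <- aln_from_columns(c(block_cols(3, 1), block_cols(2, 2),
                            block_cols(4, 0), block_cols(1, 3)))
  res <- block_jackknife_d(aln, partition_blocks(48, block_len = 12))

  counts <- list(c(3, 1), c(2, 2), c(4, 0), c(1, 3))
  tot <- Reduce(`+`, counts)
  d_exp <- (tot[1] - tot[2]) / sum(tot)
  # brute-force delete-one pseudo-estimates
  d_loo <- vapply(1:4, function(j) {
    rest <- Reduce(`+`, counts[-j])
    (rest[1] - rest[2]) / sum(rest)
  }, numeric(1))
  m <- 4
  se_exp <- sqrt((m - 1) / m * sum((d_loo - mean(d_loo))^2))

  expect_equal(res$n_abba, 10)
  expect_equal(res$n_baba, 6)
  expect_equal(res$d, d_exp)
  expect_equal(res$d, 0.25)
  expect_equal(res$se, se_exp)
  expect_equal(res$z, d_exp / se_exp)
  expect_equal(res$p, 2 * stats::pnorm(-abs(res$z)))
  expect_equal(tidy(res)$n_abba, c(3, 2, 4, 1))
  expect_equal(glance(res)$n_blocks_used, 4)
})

test_that("degenerate jackknives are flagged, not faked", {
  abba <- c("G", "T", "T", "G")
  mono <- c("A", "A", "A", "A")
  # identical per-block counts: zero jackknife variance
  aln <- aln_from_columns(rep(c(list(abba), rep(list(mono), 9)), 4))
  expect_warning(res <- block_jackknife_d(aln, partition_blocks(40, block_len = 10)),
                 "zero jackknife variance")
  expect_equal(res$d, 1)
  expect_true(is.na(res$z))

  # blocks without informative sites are dropped with a warning
  aln2 <- aln_from_columns(c(list(abba, abba, c("T", "G", "T", "G")),
                             rep(list(mono), 17)))
  expect_warning(res2 <- block_jackknife_d(aln2, partition_blocks(20, block_len = 5)),
                 "dropped")
  expect_equal(res2$n_blocks_used, 1)
  expect_true(is.na(res2$se))
})

test_that("D is antisymmetric in P1 and P2 and counts pool across blocks", {
  for (r in 1:5) {
    aln <- simulate_four_taxon(4000, f_introgression = 0.2, donor = "P2",
                               seed = 300 + r)
    swapped <- as_four_taxon(unname(unclass(aln))[c(2, 1, 3, 4)])
    cs <- count_site_patterns(aln)
    cw <- count_site_patterns(swapped)
    expect_equal(patterson_d(cs$n_abba, cs$n_baba),
                 -patterson_d(cw$n_abba, cw$n_baba))

    res <- block_jackknife_d(aln, partition_blocks(4000, n_blocks = 7))
    expect_equal(sum(res$per_block$n_abba), res$n_abba)
    expect_equal(sum(res$per_block$n_baba), res$n_baba)
    expect_equal(c(res$n_abba, res$n_baba), c(cs$n_abba, cs$n_baba))
  }
})

test_that("direction labels follow the sign of significant D", {
  expect_equal(infer_direction(0.5, TRUE), "P2_P3")
  expect_equal(infer_direction(-0.5, TRUE), "P1_P3")
  expect_equal(infer_direction(0.9, FALSE), "none")
  expect_true(is.na(infer_direction(NA_real_, TRUE)))
})

test_that("the null simulation yields well-behaved Z scores", {
  z <- purrr::map_dbl(1:20, function(r) {
    aln <- simulate_four_taxon(20000, seed = 400 + r)
    suppressWarnings(block_jackknife_d(aln, partition_blocks(20000, n_blocks = 20))$z)
  })
  expect_true(all(is.finite(z)))
  expect_true(mean(abs(z) < 3) >= 0.9)
})
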