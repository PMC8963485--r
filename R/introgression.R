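#' Coerce four aligned sequences to a four-taxon alignment
#'
#' @param seqs Named or ordered character vector of four equal-length
#'   aligned sequences in the order P1, P2, P3, outgroup (names `P1`,
#'   `P2`, `P3`, `outgroup` are honoured when present).
#' @return A `four_taxon_aln` object.
#' @export
as_four_taxon <- function(seqs) {
  if (length(seqs) != 4L) abort("a four-taxon alignment needs exactly 4 sequences")
  roles <- c("P1", "P2", "P3", "outgroup")
  if (!is.null(names(seqs)) && all(roles %in% names(seqs))) {
    seqs <- seqs[roles]
  } else {
    names(seqs) <- roles
  }
  if (length(unique(nchar(seqs))) != 1L) {
    abort("the four sequences must have equal aligned length")
  }
  structure(toupper(seqs), class = c("four_taxon_aln", "character"))
}

# integer-coded alignment matrix: rows P1, P2, P3, outgroup
# (A/C/G/T -> 1..4; gaps, N and ambiguity codes -> 0)
aln_matrix <- function(aln) {
  aln <- as_four_taxon(unclass(aln))
  m <- matrix(0L, nrow = 4, ncol = nchar(aln[[1]]))
  for (i in 1:4) {
    v <- utf8ToInt(chartr("ACGT", "\1\2\3\4", aln[[i]]))
    v[v > 4L] <- 0L
    m[i, ] <- v
  }
  m
}

#' Count ABBA and BABA site patterns
#'
#' A column is informative when it has no gap or ambiguous base,
#' carries exactly two distinct nucleotides across the four sequences,
#' and the outgroup (ancestral, "A" state) differs from the derived
#' ("B") allele carried by some ingroup taxa. Columns where P2 and P3
#' share the derived allele (pattern ABBA) and columns where P1 and P3
#' share it (BABA) are the two discordant patterns contrasted by
#' Patterson's D; other biallelic patterns (e.g. BBAA) are informative
#' but contribute to neither count.
#'
#' @param aln A `four_taxon_aln` (see [as_four_taxon()],
#'   [simulate_four_taxon()]).
#' @param region Optional 1-based inclusive `c(start, end)` restriction.
#' @return One-row tibble: `n_abba`, `n_baba`, `n_informative`.
#' @export
count_site_patterns <- function(aln, region = NULL) {
  m <- aln_matrix(aln)
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] >= 1, region[2] <= ncol(m),
              region[1] <= region[2])
    m <- m[, region[1]:region[2], drop = FALSE]
  }
  count_patterns_m(m)
}

count_patterns_m <- function(m) {
  ok <- m[1, ] > 0L & m[2, ] > 0L & m[3, ] > 0L & m[4, ] > 0L
  o <- m[4, ]
  b1 <- m[1, ] != o
  b2 <- m[2, ] != o
  b3 <- m[3, ] != o
  # single derived state: every non-outgroup allele that differs must agree
  dv <- ifelse(b1, m[1, ], ifelse(b2, m[2, ], m[3, ]))
  biallelic <- ok & (b1 | b2 | b3) &
    (!b1 | m[1, ] == dv) & (!b2 | m[2, ] == dv) & (!b3 | m[3, ] == dv)
  tibble(
    n_abba = sum(biallelic & !b1 & b2 & b3),
    n_baba = sum(biallelic & b1 & !b2 & b3),
    n_informative = sum(biallelic)
  )
}

#' Patterson's D from ABBA/BABA counts
#'
#' `D = (n_ABBA - n_BABA) / (n_ABBA + n_BABA)`. Positive D indicates
#' an excess of P2-P3 allele sharing (introgression between P2 and
#' P3); negative D an excess of P1-P3 sharing. When both counts are
#' zero D is undefined and `NA` is returned with a warning.
#'
#' @param n_abba,n_baba Non-negative pattern counts.
#' @return Numeric D in \[-1, 1\], or `NA` when undefined.
#' @export
patterson_d <- function(n_abba, n_baba) {
  stopifnot(n_abba >= 0, n_baba >= 0)
  denom <- n_abba + n_baba
  if (denom == 0) {
    warn("no ABBA or BABA sites: D is undefined")
    return(NA_real_)
  }
  (n_abba - n_baba) / denom
}

#' Partition an alignment into jackknife blocks
#'
#' Either a fixed number of blocks (the first `n - 1` of length
#' `floor(L / n)`, the last absorbing the remainder) or fixed-length
#' blocks (the last possibly shorter). Blocks are 1-based inclusive,
#' tile `[1, L]` and do not overlap.
#'
#' @param aln_length Alignment length L.
#' @param n_blocks Number of blocks (mutually exclusive with
#'   `block_len`).
#' @param block_len Block length in bp.
#' @return Tibble with columns `block`, `start`, `end`.
#' @export
partition_blocks <- function(aln_length, n_blocks = NULL, block_len = NULL) {
  stopifnot(aln_length >= 1)
  if (is.null(n_blocks) == is.null(block_len)) {
    abort("specify exactly one of n_blocks or block_len")
  }
  if (!is.null(n_blocks)) {
    stopifnot(n_blocks >= 1)
    if (n_blocks > aln_length) {
      warn("more blocks than sites requested; using a single block")
      n_blocks <- 1L
    }
    len <- floor(aln_length / n_blocks)
    start <- (seq_len(n_blocks) - 1L) * len + 1L
    end <- c(start[-1L] - 1L, aln_length)
  } else {
    stopifnot(block_len >= 1)
    if (block_len > aln_length) {
      warn("block length exceeds alignment length; using a single block")
      block_len <- aln_length
    }
    start <- seq(1L, aln_length, by = block_len)
    end <- pmin(start + block_len - 1L, aln_length)
  }
  tibble(block = seq_along(start), start = as.integer(start),
         end = as.integer(end))
}

#' Patterson's D with a block-jackknife significance test
#'
#' Computes the overall D from pooled ABBA/BABA counts, then
#' delete-one-block pseudo-estimates over the blocks containing
#' informative sites. The jackknife variance is
#' `SE^2 = ((m - 1) / m) * sum_j (D_(-j) - mean(D_(-j)))^2`, `Z = D / SE`,
#' and the p-value is the two-sided normal tail probability, testing
#' deviation from the lineage-sorting null D = 0. Blocks without
#' informative sites are dropped from the jackknife with a warning.
#'
#' @param aln A `four_taxon_aln`.
#' @param blocks Block table from [partition_blocks()]; default four
#'   equal blocks.
#' @param alpha Significance level used for the direction call.
#' @return A `dstat_result` object; see [tidy.dstat_result()] and
#'   [glance.dstat_result()].
#' @export
block_jackknife_d <- function(aln, blocks = NULL, alpha = 0.05) {
  aln <- as_four_taxon(unclass(aln))
  L <- nchar(aln[[1]])
  if (is.null(blocks)) blocks <- partition_blocks(L, n_blocks = 4)
  stopifnot(all(blocks$start >= 1), all(blocks$end <= L))

  mat <- aln_matrix(aln)
  per_block <- blocks %>%
    mutate(counts = map2(.data$start, .data$end, function(s, e) {
      count_patterns_m(mat[, s:e, drop = FALSE])
    })) %>%
    unnest("counts")

  n_abba <- sum(per_block$n_abba)
  n_baba <- sum(per_block$n_baba)
  d <- patterson_d(n_abba, n_baba)

  keep <- per_block$n_informative > 0
  if (any(!keep)) {
    warn(paste0(sum(!keep), " block(s) without informative sites dropped",
                " from the jackknife"))
  }
  m <- sum(keep)
  if (is.na(d) || m < 2) {
    se <- z <- p <- NA_real_
  } else {
    d_loo <- vapply(which(keep), function(j) {
      a <- n_abba - per_block$n_abba[j]
      b <- n_baba - per_block$n_baba[j]
      if (a + b == 0) NA_real_ else (a - b) / (a + b)
    }, numeric(1))
    if (anyNA(d_loo)) {
      se <- z <- p <- NA_real_
    } else {
      se <- sqrt((m - 1) / m * sum((d_loo - mean(d_loo))^2))
      if (se == 0) {
        warn("zero jackknife variance: Z undefined")
        z <- p <- NA_real_
      } else {
        z <- d / se
        p <- 2 * pnorm(-abs(z))
      }
    }
  }

  significant <- !is.na(p) && p < alpha
  structure(
    list(
      n_abba = n_abba, n_baba = n_baba,
      n_informative = sum(per_block$n_informative),
      d = d, se = se, z = z, p = p,
      n_blocks = nrow(blocks), n_blocks_used = m,
      per_block = per_block, alpha = alpha,
      direction = infer_direction(d, significant)
    ),
    class = "dstat_result"
  )
}

#' Infer the geneflow direction from D
#'
#' Not significant (consistent with lineage sorting) gives `"none"`;
#' significant positive D gives `"P2_P3"` (geneflow between P2 and the
#' hybrid), significant negative D gives `"P1_P3"`.
#'
#' @param d Patterson's D (may be `NA`).
#' @param significant Logical: did the jackknife test reject D = 0?
#' @return One of `"P2_P3"`, `"P1_P3"`, `"none"` (or `NA` for
#'   undefined D).
#' @export
infer_direction <- function(d, significant) {
  if (is.na(d)) return(NA_character_)
  if (!isTRUE(significant) || d == 0) return("none")
  if (d > 0) "P2_P3" else "P1_P3"
}

#' @export
print.dstat_result <- function(x, ...) {
  cat("Four-taxon ABBA-BABA test (Patterson's D, block jackknife)\n")
  cat(sprintf("  ABBA %d  BABA %d  (informative sites: %d)\n",
              x$n_abba, x$n_baba, x$n_informative))
  cat(sprintf("  D = %.4f  SE = %.4f  Z = %.3f  p = %.3g\n",
              x$d, x$se, x$z, x$p))
  cat(sprintf("  blocks used %d/%d  direction: %s\n",
              x$n_blocks_used, x$n_blocks, x$direction))
  invisible(x)
}

#' Tidy per-block ABBA/BABA counts of a D-statistic result
#'
#' @param x A `dstat_result`.
#' @param ... Unused.
#' @return Tibble with one row per block: boundaries, counts and
#'   per-block D.
#' @method tidy dstat_result
#' @export
tidy.dstat_result <- function(x, ...) {
  x$per_block %>%
    mutate(d_block = if_else(.data$n_abba + .data$n_baba > 0,
                             (.data$n_abba - .data$n_baba) /
                               (.data$n_abba + .data$n_baba), NA_real_))
}

#' One-row summary of a D-statistic result
#'
#' @param x A `dstat_result`.
#' @param ... Unused.
#' @return One-row tibble: counts, D, jackknife SE, Z, p-value, blocks
#'   used and the direction label.
#' @method glance dstat_result
#' @export
glance.dstat_result <- function(x, ...) {
  tibble(
    n_abba = x$n_abba, n_baba = x$n_baba,
    n_informative = x$n_informative,
    d = x$d, se = x$se, z = x$z, p_value = x$p,
    n_blocks = x$n_blocks, n_blocks_used = x$n_blocks_used,
    direction = x$direction
  )
}

#' Plot per-block D of a four-taxon test
#'
#' @param object A `dstat_result`.
#' @param ... Unused.
#' @return A ggplot: per-block D with the pooled estimate as a line.
#' @method autoplot dstat_result
#' @export
autoplot.dstat_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$block), y = .data$d_block)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$d, linetype = 2, colour = "red") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "block", y = "Patterson's D",
                  title = sprintf("D = %.3f, Z = %.2f (%s)", object$d,
                                  object$z, object$direction)) +
    ggplot2::theme_minimal()
}
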