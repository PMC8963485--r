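#' Published whole-genome characterisation of five natural wild-rice hybrids
#'
#' Reported six-gene diagnostic-locus calls (AB = heterozygous with one
#' allele from each parental taxon, BB = homozygous for the
#' *O. meridionalis*-type allele), genome-wide SNP and heterozygous-SNP
#' counts, heterozygosity percentages and plausible generation class for
#' the five natural hybrids found among 26 resequenced Australian wild
#' rice accessions. The heterozygosity percentage uses the
#' *O. rufipogon*-type genome size for the one hybrid with an
#' *O. rufipogon*-type nuclear genome (WR62) and the *O. meridionalis*
#' genome size for the others.
#'
#' @return Tibble with one row per hybrid.
#' @export
oryza_hybrid_table <- function() {
  tibble(
    sample_id = c("WR44", "WR52", "WR62", "WR153", "WR161"),
    sh4    = c("AB", "BB", "AB", "BB", "AB"),
    GBSSI  = c("BB", "BB", "AB", "BB", "BB"),
    SSI    = c("BB", "BB", "AB", "BB", "AB"),
    SBEI   = c("AB", "AB", "AB", "AB", "AB"),
    ALK    = c("BB", "BB", "AB", "AB", "BB"),
    GBSSII = c("AB", "AB", "AB", "AB", "AB"),
    total_snps = c(6910977, 5291708, 5917274, 4764266, 5295508),
    n_het_snps = c(2464823, 1137527, 2318878, 1111890, 1189627),
    nuclear_type = c("B", "B", "A", "B", "B"),
    het_genome_pct = c(0.69, 0.32, 0.60, 0.31, 0.34),
    generation = c("early", "later", "early", "later", "later")
  )
}

#' Published per-sample variant summaries for the 21 parental accessions
#'
#' Reported whole-genome variant totals, SNP and InDel percentages,
#' heterozygous SNV position counts, genome-wide heterozygosity
#' percentages and unique heterozygous SNP percentages for the
#' twenty-one putative parental accessions (one *O. rufipogon*-type,
#' WR24, and twenty *O. meridionalis*).
#'
#' @return Tibble with one row per parental accession.
#' @export
oryza_parental_table <- function() {
  tibble(
    sample_id = c("WR24", "WR37", "WR81", "WR100", "WR103", "WR111", "WR126",
                  "WR133", "WR143", "WR171", "WR184", "WR195", "WR207",
                  "WR219", "WR230", "WR233", "WR242", "WR256", "WR265",
                  "WR280", "WR287"),
    taxon = c("A", rep("B", 20)),
    total_variants = c(1918262, 3745572, 7310928, 6007510, 6256551, 3899236,
                       5194396, 6545660, 5611030, 3852279, 5421763, 5985028,
                       6520874, 6951983, 6694713, 3623110, 6849045, 5991356,
                       6625636, 6621409, 5722665),
    snv_pct = c(90, 87, 87, 87, 87, 88, 87, 87, 87, 88, 87, 87, 87, 87, 87,
                88, 87, 87, 87, 87, 87),
    indel_pct = c(6, 8, 8, 8, 8, 7, 8, 8, 8, 7, 8, 8, 8, 8, 8, 7, 8, 8, 8,
                  8, 8),
    n_het_snps = c(632272, 827689, 1365802, 1175173, 1198555, 894765,
                   1125277, 1227038, 1109062, 966368, 1074882, 1168776,
                   1210794, 1312291, 1261074, 876065, 1299754, 1119055,
                   1255312, 1249681, 1105062),
    het_genome_pct = c(0.16, 0.23, 0.38, 0.33, 0.34, 0.25, 0.32, 0.35, 0.31,
                       0.27, 0.30, 0.33, 0.34, 0.37, 0.36, 0.25, 0.37, 0.32,
                       0.35, 0.35, 0.31),
    unique_het_pct = c(48, 6, 8, 4, 5, 5, 10, 4, 5, 6, 5, 6, 12, 6, 5, 4, 6,
                       6, 5, 5, 5)
  )
}

#' Published per-block ABBA/BABA counts of the five four-taxon tests
#'
#' Reported per-block ABBA and BABA site counts for the five four-taxon
#' tests (P1 = WR24, the *O. rufipogon*-type parent; P2 = WR81,
#' *O. meridionalis*; P3 = one hybrid; outgroup = *O. sativa* cv.
#' Nipponbare) on a 4,473-bp alignment of four starch-synthesis genes
#' split into four blocks. The published per-block D and Z values are
#' included verbatim for reference, but they are not reproducible from
#' the published counts with the standard estimator
#' `D = (ABBA - BABA) / (ABBA + BABA)`; analyses in this package
#' recompute D from the counts. A fourth-block row for WR161 was not
#' printed for block 2,237–3,354.
#'
#' @return Tibble with one row per (hybrid, block).
#' @export
oryza_dstat_table <- function() {
  hyb5 <- c("WR44", "WR52", "WR62", "WR153", "WR161")
  tibble(
    p3 = c(hyb5, hyb5, hyb5[1:4], hyb5),
    block = c(rep(1L, 5), rep(2L, 5), rep(3L, 4), rep(4L, 5)),
    start = c(rep(1L, 5), rep(1119L, 5), rep(2237L, 4), rep(3355L, 5)),
    end = c(rep(1118L, 5), rep(2236L, 5), rep(3354L, 4), rep(4472L, 5)),
    n_abba = c(168, 133, 66, 73, 55, 0, 0, 0, 0, 0, 9, 9, 9, 9,
               19, 19, 19, 19, 19),
    n_baba = c(10, 6, 18, 18, 0, 8, 13, 27, 15, 14, 19, 16, 19, 19,
               21, 21, 21, 21, 21),
    published_d = c(0.47, 0.38, 0.06, 0.03, 0.33, -0.28, -0.49, -0.69,
                    -0.49, -0.43, -0.57, -0.65, -0.66, -0.68, -0.06, -0.12,
                    -0.16, -0.31, -0.14),
    published_z = c(0.35, -0.38, -1.81, -2.14, -0.78, 0.35, -0.38, -1.81,
                    -2.14, -0.78, 0.35, -0.38, -1.81, -2.14, 0.35, -0.38,
                    -1.81, -2.14, -0.78)
  )
}

#' Genome sizes of the two parental taxa
#'
#' Assembly sizes used in the genome-wide heterozygosity formula:
#' 384.8 Mb for the *O. rufipogon*-type taxon (A) and 354.9 Mb for
#' *O. meridionalis* (B).
#'
#' @return Named numeric vector `c(A = ..., B = ...)` in bp.
#' @export
oryza_genome_sizes <- function() {
  c(A = 384800000, B = 354900000)
}
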