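#' Classify a variant from its REF and ALT alleles
#'
#' Follows the variant-caller convention with five classes: equal-length
#' alleles are `SNV` (length 1) or `MNV` (length > 1); length-changing
#' alleles where the shorter is a prefix or suffix of the longer are
#' `insertion` (alt longer) or `deletion` (ref longer); any other
#' length-changing pair is a `replacement`.
#'
#' @param ref,alt Character vectors of alleles over \{A, C, G, T\}
#'   (recycled to a common length).
#' @return Character vector of classes: `"SNV"`, `"MNV"`, `"insertion"`,
#'   `"deletion"` or `"replacement"`.
#' @export
classify_variant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    abort("alleles must be non-empty strings over {A, C, G, T}")
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  nested <- function(short, long) {
    startsWith(long, short) | endsWith(long, short)
  }
  dplyr::case_when(
    lr == la & lr == 1L ~ "SNV",
    lr == la ~ "MNV",
    la > lr & nested(ref, alt) ~ "insertion",
    lr > la & nested(alt, ref) ~ "deletion",
    TRUE ~ "replacement"
  )
}

#' SNV and InDel percentages of a variant-class tally
#'
#' Computes the share of single-nucleotide variants and of insertions
#' plus deletions among all variants:
#' `snv_pct = 100 * n_SNV / total` and
#' `indel_pct = 100 * (n_insertion + n_deletion) / total`.
#'
#' @param class_counts Named numeric vector or tibble with (a subset of)
#'   names `SNV`, `MNV`, `insertion`, `deletion`, `replacement`.
#' @return One-row tibble with `total`, `snv_pct`, `indel_pct`
#'   (`NA` with a warning when `total` is zero).
#' @export
snp_indel_percentages <- function(class_counts) {
  if (is.data.frame(class_counts)) {
    class_counts <- setNames(class_counts$n, class_counts$variant_class)
  }
  get <- function(k) if (k %in% names(class_counts)) as.numeric(class_counts[[k]]) else 0
  total <- sum(vapply(c("SNV", "MNV", "insertion", "deletion", "replacement"),
                      get, numeric(1)))
  if (total == 0) {
    warn("no variants: SNV/InDel percentages undefined")
    return(tibble(total = 0, snv_pct = NA_real_, indel_pct = NA_real_))
  }
  tibble(
    total = total,
    snv_pct = 100 * get("SNV") / total,
    indel_pct = 100 * (get("insertion") + get("deletion")) / total
  )
}

#' Heterozygous SNV positions per sample
#'
#' A position is heterozygous for a sample when its diploid genotype
#' carries two distinct alleles and, when a read fraction is available,
#' the minor allele fraction is at least `min_het_allele_freq`
#' (mirroring a caller minimum variant frequency of 25%). Only SNV rows
#' are considered; positions are deduplicated per sample, so a
#' multi-allelic heterozygote counts one position.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param min_het_allele_freq Minimum minor-allele read fraction
#'   (default 0.25).
#' @return Tibble of `sample_id`, `chrom`, `pos`.
#' @export
call_heterozygous_positions <- function(variants, min_het_allele_freq = 0.25) {
  variants %>%
    filter(.data$variant_class == "SNV", .data$called, .data$a1 != .data$a2) %>%
    mutate(minor_af = pmin(.data$af, 1 - .data$af)) %>%
    filter(is.na(.data$minor_af) | .data$minor_af >= min_het_allele_freq) %>%
    distinct(.data$sample_id, .data$chrom, .data$pos)
}

#' Genome-wide heterozygosity percentage
#'
#' `100 * n_het_positions / genome_size_bp`: the number of heterozygous
#' SNP positions as a percentage of the whole genome size. Values are
#' returned at full precision; reports round to 2 decimals.
#'
#' @param n_het_positions Count(s) of heterozygous SNV positions.
#' @param genome_size_bp Genome size(s) in bp; must be positive.
#' @return Numeric vector of percentages.
#' @export
heterozygosity_percent <- function(n_het_positions, genome_size_bp) {
  if (any(genome_size_bp <= 0)) abort("genome_size_bp must be positive")
  100 * n_het_positions / genome_size_bp
}

#' Unique heterozygous SNPs per sample
#'
#' A sample's unique heterozygous SNPs are the heterozygous positions
#' (chrom, pos) present in no other sample's heterozygous set; the
#' percentage is relative to the sample's own heterozygous total.
#'
#' @param het_positions Tibble of `sample_id`, `chrom`, `pos` as from
#'   [call_heterozygous_positions()]; at least two samples required.
#' @return Tibble of `sample_id`, `n_het`, `n_unique_het`,
#'   `unique_het_pct`.
#' @export
unique_heterozygous_snps <- function(het_positions) {
  if (n_distinct(het_positions$sample_id) < 2) {
    abort("uniqueness is undefined with fewer than two samples")
  }
  shared <- het_positions %>%
    distinct(.data$sample_id, .data$chrom, .data$pos) %>%
    group_by(.data$chrom, .data$pos) %>%
    mutate(n_carriers = n()) %>%
    ungroup()
  shared %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_het = n(),
      n_unique_het = sum(.data$n_carriers == 1L),
      .groups = "drop"
    ) %>%
    mutate(unique_het_pct = 100 * .data$n_unique_het / .data$n_het)
}

#' Per-sample variant summary table
#'
#' Assembles, for each sample, the total variant count, SNV and InDel
#' percentages, heterozygous-position count, genome-wide heterozygosity
#' percentage, and (with two or more samples) unique heterozygous SNP
#' counts and percentages.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param genome_size_bp Either a single genome size in bp or a named
#'   vector / tibble (`sample_id`, `genome_size_bp`) giving one per
#'   sample (the size of the taxon the sample's nuclear genome matches).
#' @param min_het_allele_freq Passed to [call_heterozygous_positions()].
#' @return Tibble with one row per sample, Table-3-shaped.
#' @export
summarize_sample_variants <- function(variants, genome_size_bp,
                                      min_het_allele_freq = 0.25) {
  counts <- variants %>%
    filter(.data$called) %>%
    count(.data$sample_id, .data$variant_class)
  pct <- counts %>%
    group_by(.data$sample_id) %>%
    summarise(snp_indel_percentages(setNames(.data$n, .data$variant_class)),
              .groups = "drop")

  het <- call_heterozygous_positions(variants, min_het_allele_freq)
  het_n <- het %>% count(.data$sample_id, name = "n_het_positions")

  out <- left_join(pct, het_n, by = "sample_id") %>%
    mutate(n_het_positions = dplyr::coalesce(.data$n_het_positions, 0L))

  if (is.data.frame(genome_size_bp)) {
    out <- left_join(out, genome_size_bp, by = "sample_id")
  } else if (!is.null(names(genome_size_bp)) && length(genome_size_bp) > 1) {
    out$genome_size_bp <- unname(genome_size_bp[out$sample_id])
  } else {
    out$genome_size_bp <- as.numeric(genome_size_bp)
  }
  out <- out %>%
    mutate(het_genome_pct = heterozygosity_percent(.data$n_het_positions,
                                                   .data$genome_size_bp))

  if (n_distinct(het$sample_id) >= 2) {
    uh <- unique_heterozygous_snps(het)
    out <- left_join(out, select(uh, "sample_id", "n_unique_het",
                                 "unique_het_pct"), by = "sample_id")
  } else {
    out$n_unique_het <- NA_integer_
    out$unique_het_pct <- NA_real_
  }
  out
}
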