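#' Default diagnostic gene panel
#'
#' Six genes whose alleles distinguish the two parental taxa: the seed
#' shattering gene *sh4* on chromosome 4 and five starch-synthesis
#' genes (*GBSSI*, *SSI*, *SBEI*, *ALK* on chromosome 6; *GBSSII* on
#' chromosome 7). Intervals are 1-based inclusive. The *sh4*, *ALK*
#' and *GBSSII* intervals are the annotated gene coordinates; the
#' *GBSSI*, *SSI* and *SBEI* intervals are configurable placeholders
#' on chromosome 6.
#'
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
default_diagnostic_panel <- function() {
  tibble(
    gene = c("sh4", "GBSSI", "SSI", "SBEI", "ALK", "GBSSII"),
    chrom = c("chr4", "chr6", "chr6", "chr6", "chr6", "chr7"),
    start = c(34231186L, 1765000L, 3070000L, 20800000L, 6748398L, 12916883L),
    end = c(34233221L, 1770000L, 3077000L, 20806000L, 6753302L, 12924202L)
  )
}

# collapse a logical vector of mismatch columns into event counts,
# where a run of gap columns counts as a single variant event
count_variant_events <- function(s, r) {
  both_gap <- s == "-" & r == "-"
  s <- s[!both_gap]
  r <- r[!both_gap]
  mism <- s != r
  gap <- (s == "-" | r == "-") & mism
  point <- mism & !gap
  runs <- rle(gap)
  sum(point) + sum(runs$values)
}

#' Assign a chloroplast type by nearest reference
#'
#' Counts variant events between the sample's chloroplast sequence and
#' each of the two reference plastomes (inputs must be aligned to equal
#' length; a run of gap columns counts as one event) and assigns the
#' type of the closer reference. Equidistant samples are unassigned.
#'
#' @param sample_seq,cp_ref_A,cp_ref_B Equal-length aligned sequences.
#' @return One-row tibble: `cp_type` (`"A"`, `"B"` or `NA`),
#'   `count_vs_A`, `count_vs_B`.
#' @export
assign_chloroplast_type <- function(sample_seq, cp_ref_A, cp_ref_B) {
  ls <- nchar(sample_seq)
  if (ls != nchar(cp_ref_A) || ls != nchar(cp_ref_B)) {
    abort("sequences must be aligned to equal length")
  }
  s <- strsplit(toupper(sample_seq), "")[[1]]
  a <- strsplit(toupper(cp_ref_A), "")[[1]]
  b <- strsplit(toupper(cp_ref_B), "")[[1]]
  ca <- count_variant_events(s, a)
  cb <- count_variant_events(s, b)
  type <- if (ca < cb) "A" else if (cb < ca) "B" else NA_character_
  if (is.na(type)) {
    warn("sample chloroplast equidistant from both references; unassigned")
  }
  tibble(cp_type = type, count_vs_A = ca, count_vs_B = cb)
}

# per-site diagnostic genotype labels for one sample's panel genotypes:
# "het", "homA", "homB" or NA (missing / allele outside {A-allele, B-allele})
diag_site_label <- function(a1, a2, allele_A, allele_B, called) {
  dplyr::case_when(
    !called ~ NA_character_,
    a1 == allele_A & a2 == allele_A ~ "homA",
    a1 == allele_B & a2 == allele_B ~ "homB",
    (a1 == allele_A & a2 == allele_B) |
      (a1 == allele_B & a2 == allele_A) ~ "het",
    TRUE ~ NA_character_
  )
}

#' Assign a nuclear type from diagnostic-allele dosage
#'
#' Computes the fraction of taxon-A alleles across called diagnostic
#' sites and classifies the nuclear genome as `A` when the fraction is
#' at least `min_frac_A`, `B` when at most `max_frac_A`, and `admixed`
#' otherwise. Sites whose genotype carries an allele outside the two
#' parental alleles are ignored.
#'
#' @param genotypes Tibble of one sample's genotypes at diagnostic
#'   sites, with columns `a1`, `a2`, `called`, `allele_A`, `allele_B`.
#' @param min_frac_A,max_frac_A Classification thresholds (0.9 / 0.1).
#' @param min_sites Minimum called diagnostic sites (default 20).
#' @return One-row tibble: `nuclear_type` (`"A"`, `"B"`, `"admixed"` or
#'   `NA` when inconclusive), `fraction_A`, `n_sites_used`.
#' @export
assign_nuclear_type <- function(genotypes, min_frac_A = 0.9,
                                max_frac_A = 0.1, min_sites = 20) {
  lab <- diag_site_label(genotypes$a1, genotypes$a2, genotypes$allele_A,
                         genotypes$allele_B, genotypes$called)
  lab <- lab[!is.na(lab)]
  n <- length(lab)
  if (n < min_sites) {
    return(tibble(nuclear_type = NA_character_, fraction_A = NA_real_,
                  n_sites_used = n))
  }
  n_a <- 2 * sum(lab == "homA") + sum(lab == "het")
  frac <- n_a / (2 * n)
  type <- if (frac >= min_frac_A) "A" else if (frac <= max_frac_A) "B" else "admixed"
  tibble(nuclear_type = type, fraction_A = frac, n_sites_used = n)
}

#' Classify cytonuclear concordance
#'
#' A sample is concordant when its chloroplast type matches its nuclear
#' side; an admixed nuclear genome is reported as discordant against
#' the chloroplast donor (the maternal parent). Unassigned inputs
#' propagate as inconclusive (`NA`).
#'
#' @param cp_type `"A"`, `"B"` or `NA`.
#' @param nuclear_type `"A"`, `"B"`, `"admixed"` or `NA`.
#' @return One-row tibble: `cytonuclear_status` (`"concordant"`,
#'   `"discordant"` or `NA`) and `maternal_parent` (the chloroplast
#'   donor, for discordant samples).
#' @export
classify_cytonuclear <- function(cp_type, nuclear_type) {
  if (is.na(cp_type) || is.na(nuclear_type)) {
    return(tibble(cytonuclear_status = NA_character_,
                  maternal_parent = NA_character_))
  }
  concordant <- nuclear_type %in% c("A", "B") && cp_type == nuclear_type
  tibble(
    cytonuclear_status = if (concordant) "concordant" else "discordant",
    maternal_parent = if (concordant) cp_type else cp_type
  )
}

#' Call a diagnostic locus from panel-site genotypes
#'
#' Labels each called panel site within the gene interval as
#' heterozygous (one allele from each taxon), homozygous-A or
#' homozygous-B, then calls the locus `AB` when at least
#' `het_site_fraction` of called sites are heterozygous, otherwise
#' `AA`/`BB` by majority of the homozygous sites. Ties and loci with
#' no informative sites are `inconclusive`.
#'
#' @param genotypes One sample's genotypes at the gene's panel sites
#'   (columns `a1`, `a2`, `called`, `allele_A`, `allele_B`).
#' @param het_site_fraction Minimum heterozygous-site fraction for an
#'   `AB` call (default 0.5).
#' @return A single character: `"AA"`, `"AB"`, `"BB"` or
#'   `"inconclusive"`.
#' @export
call_diagnostic_locus <- function(genotypes, het_site_fraction = 0.5) {
  lab <- diag_site_label(genotypes$a1, genotypes$a2, genotypes$allele_A,
                         genotypes$allele_B, genotypes$called)
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0L) return("inconclusive")
  if (mean(lab == "het") >= het_site_fraction) return("AB")
  n_a <- sum(lab == "homA")
  n_b <- sum(lab == "homB")
  if (n_a > n_b) "AA" else if (n_b > n_a) "BB" else "inconclusive"
}

#' Classify a hybrid's generation from genome-wide heterozygosity
#'
#' A two-class rule anchored to the heterozygosity observed in the
#' parental reference samples: `early` (F1/F2) when the sample's
#' genome-wide heterozygosity percentage is at least
#' `early_factor` times the maximum parental value, `later` otherwise.
#' The default factor 1.5 separates early hybrids (about 1.6–1.8 times
#' the parental maximum in the study populations) from repeatedly
#' backcrossed ones.
#'
#' @param het_genome_pct Sample heterozygosity percentage(s).
#' @param parental_reference_het_max Maximum heterozygosity percentage
#'   among labelled parental samples; must be positive.
#' @param early_factor Relative threshold (default 1.5).
#' @return Character vector of `"early"` / `"later"`.
#' @export
classify_generation <- function(het_genome_pct, parental_reference_het_max,
                                early_factor = 1.5) {
  if (length(parental_reference_het_max) == 0 ||
      any(!is.finite(parental_reference_het_max)) ||
      any(parental_reference_het_max <= 0)) {
    abort("parental_reference_het_max must be positive (no parental reference samples?)")
  }
  if_else(het_genome_pct >= early_factor * parental_reference_het_max,
          "early", "later")
}

#' Per-sample hybrid report
#'
#' Runs the full diagnosis for every sample: chloroplast typing against
#' the two reference plastomes, nuclear typing from diagnostic-allele
#' dosage, cytonuclear-concordance classification, per-gene diagnostic
#' locus calls, genome-wide heterozygosity and generation class.
#' Samples with no hybrid evidence (concordant cytonuclear status and
#' no `AB` locus) are classed `non_hybrid`.
#'
#' @param variants Variant tibble for all samples (see [read_vcf()]).
#' @param panel_sites Tibble `gene`, `chrom`, `pos`, `allele_A`,
#'   `allele_B` of diagnostic panel sites.
#' @param cp_seqs Named character vector of per-sample chloroplast
#'   sequences (aligned to the references).
#' @param cp_ref_A,cp_ref_B Reference chloroplast sequences.
#' @param genome_size_bp Named vector `c(A=, B=)` of genome sizes in bp
#'   used for the heterozygosity percentage (taxon-A size for nuclear
#'   type A, taxon-B size otherwise).
#' @param diagnostic_sites Optional tibble `chrom`, `pos`, `allele_A`,
#'   `allele_B` of additional genome-wide diagnostic sites for nuclear
#'   typing; defaults to the panel sites.
#' @param min_het_allele_freq,early_factor,het_site_fraction
#'   Thresholds, see the individual classifiers.
#' @return Tibble with one row per sample: chloroplast type and
#'   variant counts, nuclear type and A-allele fraction, cytonuclear
#'   status, one column per panel gene, `het_genome_pct` and
#'   `generation_class`.
#' @export
hybrid_report <- function(variants, panel_sites, cp_seqs, cp_ref_A, cp_ref_B,
                          genome_size_bp = oryza_genome_sizes(),
                          diagnostic_sites = NULL,
                          min_het_allele_freq = 0.25, early_factor = 1.5,
                          het_site_fraction = 0.5) {
  samples <- unique(variants$sample_id)
  if (is.null(diagnostic_sites)) {
    diagnostic_sites <- panel_sites %>%
      select("chrom", "pos", "allele_A", "allele_B")
  }

  cp <- map_dfr(samples, function(s) {
    if (!s %in% names(cp_seqs)) {
      return(tibble(sample_id = s, cp_type = NA_character_,
                    count_vs_A = NA_integer_, count_vs_B = NA_integer_))
    }
    bind_cols(tibble(sample_id = s),
              assign_chloroplast_type(cp_seqs[[s]], cp_ref_A, cp_ref_B))
  })

  diag_geno <- variants %>%
    inner_join(diagnostic_sites, by = c("chrom", "pos"))
  nuc <- map_dfr(samples, function(s) {
    bind_cols(tibble(sample_id = s),
              assign_nuclear_type(filter(diag_geno, .data$sample_id == s)))
  })

  panel_geno <- variants %>%
    inner_join(panel_sites, by = c("chrom", "pos"))
  locus <- tidyr::expand_grid(sample_id = samples,
                              gene = unique(panel_sites$gene)) %>%
    mutate(call = purrr::map2_chr(.data$sample_id, .data$gene, function(s, g) {
      call_diagnostic_locus(
        filter(panel_geno, .data$sample_id == s, .data$gene == g),
        het_site_fraction = het_site_fraction
      )
    })) %>%
    pivot_wider(names_from = "gene", values_from = "call")

  cyto <- map_dfr(seq_along(samples), function(i) {
    bind_cols(tibble(sample_id = samples[i]),
              classify_cytonuclear(cp$cp_type[i], nuc$nuclear_type[i]))
  })

  het <- call_heterozygous_positions(variants, min_het_allele_freq) %>%
    count(.data$sample_id, name = "n_het_positions")

  out <- cp %>%
    left_join(nuc, by = "sample_id") %>%
    left_join(cyto, by = "sample_id") %>%
    left_join(locus, by = "sample_id") %>%
    left_join(het, by = "sample_id") %>%
    mutate(
      n_het_positions = dplyr::coalesce(.data$n_het_positions, 0L),
      genome_size_bp = if_else(!is.na(.data$nuclear_type) &
                                 .data$nuclear_type == "A",
                               genome_size_bp[["A"]], genome_size_bp[["B"]]),
      het_genome_pct = heterozygosity_percent(.data$n_het_positions,
                                              .data$genome_size_bp)
    )

  gene_cols <- unique(panel_sites$gene)
  has_ab <- apply(as.matrix(out[, gene_cols]), 1, function(x) any(x == "AB"))
  evidence <- has_ab |
    (!is.na(out$cytonuclear_status) & out$cytonuclear_status == "discordant")
  parental_max <- out %>%
    filter(!evidence) %>%
    pull(.data$het_genome_pct) %>%
    max(na.rm = TRUE)
  if (!is.finite(parental_max) || parental_max <= 0) {
    abort("no parental reference samples to anchor generation classification")
  }
  out %>%
    mutate(generation_class = if_else(
      evidence,
      classify_generation(.data$het_genome_pct, parental_max, early_factor),
      "non_hybrid"
    ))
}
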