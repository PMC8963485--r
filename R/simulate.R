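#' Simulated site map for a two-taxon system
#'
#' Lays out biallelic SNV sites for the simulators: a set of background
#' sites (polymorphic within taxa) plus a set of diagnostic sites
#' carrying fixed allele differences between the two parental taxa
#' (ref = taxon-A allele, alt = taxon-B allele). A subset of the
#' diagnostic sites is placed inside the six diagnostic-panel gene
#' intervals (see [default_diagnostic_panel()]); the remainder, and all
#' background sites, lie on chromosome 1.
#'
#' @param n_sites Total number of sites.
#' @param n_diagnostic Number of diagnostic (fixed-difference) sites;
#'   the default 1% of sites is a realistic fixed-difference density
#'   for two divergent AA-genome taxa.
#' @param seed Integer seed; the map is reproducible bitwise.
#' @param panel Panel gene table (`gene`, `chrom`, `start`, `end`).
#' @param panel_sites_per_gene Diagnostic sites placed in each panel gene.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `diagnostic`, `gene`.
#' @export
sim_site_map <- function(n_sites = 20000, n_diagnostic = round(0.01 * n_sites),
                         seed = 1, panel = default_diagnostic_panel(),
                         panel_sites_per_gene = 10) {
  stopifnot(n_sites >= 1, n_diagnostic >= nrow(panel) * panel_sites_per_gene,
            n_diagnostic <= n_sites)
  nt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    in_panel <- panel %>%
      mutate(pos = map2(.data$start, .data$end, function(s, e) {
        sort(sample(seq(s, e), panel_sites_per_gene))
      })) %>%
      select("gene", "chrom", "pos") %>%
      unnest("pos")

    n_free <- n_sites - nrow(in_panel)
    free_pos <- sort(sample.int(40000000L, n_free))
    free <- tibble(gene = NA_character_, chrom = "chr1", pos = free_pos)
    n_diag_free <- n_diagnostic - nrow(in_panel)
    diag_free <- sort(sample.int(n_free, n_diag_free))

    sites <- bind_rows(
      mutate(in_panel, diagnostic = TRUE),
      mutate(free, diagnostic = dplyr::row_number() %in% diag_free)
    )
    sites$ref <- sample(nt, nrow(sites), replace = TRUE)
    shift <- sample.int(3L, nrow(sites), replace = TRUE)
    sites$alt <- nt[(match(sites$ref, nt) - 1L + shift) %% 4L + 1L]
    sites %>%
      select("chrom", "pos", "ref", "alt", "diagnostic", "gene") %>%
      arrange(.data$chrom, .data$pos)
  })
}

#' Parental taxon model
#'
#' Bundles a shared site map with a taxon's own parameters: which of
#' the two fixed diagnostic alleles it carries (`taxon`), its
#' background heterozygosity (fraction of non-diagnostic sites
#' heterozygous within an individual) and its chloroplast haplotype.
#' The defaults for the two background rates mirror the observed
#' genome-wide heterozygosity contrast between the *O. rufipogon*-type
#' taxon (~0.16%) and *O. meridionalis* (~0.38%).
#'
#' @param sites Site map from [sim_site_map()].
#' @param taxon `"A"` or `"B"`.
#' @param background_het_rate Fraction in \[0, 1\]; default 0.0016 for
#'   taxon A and 0.0038 for taxon B.
#' @param cp_haplotype Chloroplast haplotype label, default `"cpA"` or
#'   `"cpB"` to match `taxon`.
#' @return An object of class `taxon_model`.
#' @export
taxon_model <- function(sites, taxon = c("A", "B"),
                        background_het_rate = NULL, cp_haplotype = NULL) {
  taxon <- match.arg(taxon)
  if (nrow(sites) == 0L) abort("empty site map")
  if (any(sites$diagnostic & sites$ref == sites$alt)) {
    abort("diagnostic sites must carry different fixed alleles in the two taxa")
  }
  if (is.null(background_het_rate)) {
    background_het_rate <- if (taxon == "A") 0.0016 else 0.0038
  }
  stopifnot(background_het_rate >= 0, background_het_rate <= 1)
  if (is.null(cp_haplotype)) cp_haplotype <- paste0("cp", taxon)
  structure(
    list(sites = sites, taxon = taxon,
         background_het_rate = background_het_rate,
         cp_haplotype = cp_haplotype),
    class = "taxon_model"
  )
}

# one individual's genotype rows from per-site heterozygosity flags;
# hom_allele gives the allele carried when homozygous
geno_rows <- function(sites, sample_id, het, hom_allele) {
  tibble(
    sample_id = sample_id,
    chrom = sites$chrom, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    variant_class = "SNV",
    a1 = ifelse(het, sites$ref, hom_allele),
    a2 = ifelse(het, sites$alt, hom_allele),
    called = TRUE,
    af = ifelse(het, 0.5, ifelse(hom_allele == sites$alt, 1, 0))
  )
}

#' Simulate parental individuals
#'
#' Each individual is homozygous for its taxon's fixed allele at every
#' diagnostic site and heterozygous at each non-diagnostic site
#' independently with probability `background_het_rate`; its
#' chloroplast carries the taxon haplotype.
#'
#' @param model A [taxon_model()].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param prefix Sample-id prefix.
#' @return List with `geno` (long variant tibble over all individuals)
#'   and `cp` (tibble `sample_id`, `cp_haplotype`).
#' @export
simulate_parentals <- function(model, n, seed = 1,
                               prefix = paste0("P", model$taxon)) {
  stopifnot(inherits(model, "taxon_model"), n >= 1)
  sites <- model$sites
  # fixed taxon allele at diagnostic sites; background homozygotes carry
  # the reference allele in both taxa (polymorphism there is within-taxon)
  own <- ifelse(sites$diagnostic,
                if (model$taxon == "A") sites$ref else sites$alt,
                sites$ref)
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  geno <- withr::with_seed(seed, {
    map_dfr(ids, function(id) {
      het <- !sites$diagnostic &
        runif(nrow(sites)) < model$background_het_rate
      geno_rows(sites, id, het, own)
    })
  })
  list(geno = geno,
       cp = tibble(sample_id = ids, cp_haplotype = model$cp_haplotype))
}

#' Specification of a hybrid cross
#'
#' @param kind `"F1"`, `"F2"` (an F1 selfed once) or `"BC"` (an F1
#'   backcrossed `n_backcrosses` times to the recurrent parent).
#' @param n_backcrosses Number of backcross generations (`BC` only,
#'   must be >= 1).
#' @param recurrent_parent `"A"` or `"B"`; the backcross parent.
#' @param maternal_parent `"A"` or `"B"`; fixes the chloroplast donor.
#' @param selfing_generations Extra selfing generations applied after
#'   the cross (each halves heterozygosity in expectation).
#' @param seed Integer seed for the meiosis draws.
#' @return An object of class `cross_spec`.
#' @export
cross_spec <- function(kind = c("F1", "F2", "BC"), n_backcrosses = 0,
                       recurrent_parent = c("B", "A"),
                       maternal_parent = c("A", "B"),
                       selfing_generations = 0, seed = 1) {
  kind <- match.arg(kind)
  recurrent_parent <- match.arg(recurrent_parent)
  maternal_parent <- match.arg(maternal_parent)
  if (kind == "BC" && n_backcrosses < 1) {
    abort("BC crosses require n_backcrosses >= 1")
  }
  if (kind != "BC") n_backcrosses <- 0
  if (kind == "F2") selfing_generations <- selfing_generations + 1
  stopifnot(selfing_generations >= 0)
  structure(
    list(kind = kind, n_backcrosses = n_backcrosses,
         recurrent_parent = recurrent_parent,
         maternal_parent = maternal_parent,
         selfing_generations = selfing_generations, seed = seed),
    class = "cross_spec"
  )
}

#' Simulate one hybrid individual
#'
#' Starts from an F1 that is heterozygous (one allele from each taxon)
#' at every diagnostic site. Each backcross to the recurrent parent
#' resolves each still-heterozygous diagnostic site to the recurrent
#' homozygote with probability 1/2 (Mendelian transmission, sites
#' unlinked); each selfing generation resolves a heterozygous site with
#' probability 1/2 (to either homozygote equally). Background
#' (non-diagnostic) sites are heterozygous at the mean parental rate
#' for an F1 and at the recurrent parent's rate for backcrosses, with
#' selfing halving the rate per generation. The chloroplast haplotype
#' is that of the maternal parent, independent of the nuclear genotype.
#'
#' @param model_a,model_b The two parental [taxon_model()]s (taxa A, B).
#' @param cross A [cross_spec()].
#' @param sample_id Sample identifier.
#' @return List with `geno` (one-sample variant tibble),
#'   `cp_haplotype`, and `generation` label (`"F1"`, `"F2"`, `"BCn"`).
#' @export
simulate_hybrid <- function(model_a, model_b, cross, sample_id = "HYB") {
  stopifnot(inherits(model_a, "taxon_model"), inherits(model_b, "taxon_model"),
            inherits(cross, "cross_spec"), model_a$taxon == "A",
            model_b$taxon == "B")
  sites <- model_a$sites
  diag <- sites$diagnostic
  rec_model <- if (cross$recurrent_parent == "A") model_a else model_b
  rec_allele <- if (cross$recurrent_parent == "A") sites$ref else sites$alt

  withr::with_seed(cross$seed, {
    # diagnostic sites: 0 = het, 1 = hom-A, 2 = hom-B
    state <- rep(0L, sum(diag))
    for (g in seq_len(cross$n_backcrosses)) {
      resolve <- state == 0L & runif(length(state)) < 0.5
      state[resolve] <- if (cross$recurrent_parent == "A") 1L else 2L
    }
    for (g in seq_len(cross$selfing_generations)) {
      u <- runif(length(state))
      homA <- state == 0L & u < 0.25
      homB <- state == 0L & u >= 0.75
      state[homA] <- 1L
      state[homB] <- 2L
    }
    bg_rate <- if (cross$n_backcrosses == 0) {
      mean(c(model_a$background_het_rate, model_b$background_het_rate))
    } else {
      rec_model$background_het_rate
    }
    bg_rate <- bg_rate * 0.5^cross$selfing_generations

    het <- logical(nrow(sites))
    het[diag] <- state == 0L
    het[!diag] <- runif(sum(!diag)) < bg_rate
    hom <- sites$ref # background homozygotes carry the reference allele
    hom[diag] <- ifelse(state == 1L, sites$ref[diag], sites$alt[diag])
    geno <- geno_rows(sites, sample_id, het, hom)
  })

  maternal <- if (cross$maternal_parent == "A") model_a else model_b
  label <- switch(cross$kind,
    F1 = "F1", F2 = "F2",
    BC = paste0("BC", cross$n_backcrosses)
  )
  list(geno = geno, cp_haplotype = maternal$cp_haplotype, generation = label)
}

#' Simulate the two reference chloroplast haplotypes
#'
#' Generates a random plastome-like reference for taxon A and derives
#' the taxon-B reference from it by a fixed number of substitutions
#' (default 36, the reported divergence between the two taxa's
#' plastomes), so nearest-reference typing is unambiguous.
#'
#' @param length Sequence length in bp (a compact stand-in for a full
#'   plastome).
#' @param n_diff Number of substitutions separating cpA and cpB.
#' @param seed Integer seed.
#' @return Named list with elements `cpA` and `cpB`.
#' @export
simulate_cp_references <- function(length = 5000, n_diff = 36, seed = 1) {
  stopifnot(length >= n_diff)
  nt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    a <- sample(nt, length, replace = TRUE)
    b <- a
    idx <- sample.int(length, n_diff)
    b[idx] <- nt[(match(a[idx], nt) + sample.int(3L, n_diff, TRUE) - 1L) %% 4L + 1L]
    list(cpA = paste(a, collapse = ""), cpB = paste(b, collapse = ""))
  })
}

#' Simulate per-sample chloroplast sequences
#'
#' Each sample's sequence is its haplotype's reference plus a few
#' private substitutions.
#'
#' @param cp Tibble `sample_id`, `cp_haplotype` (`"cpA"`/`"cpB"`).
#' @param refs List with `cpA` and `cpB` reference sequences.
#' @param n_private Private substitutions per sample.
#' @param seed Integer seed.
#' @return Named character vector of sequences (one per sample).
#' @export
simulate_cp_sequences <- function(cp, refs, n_private = 2, seed = 1) {
  nt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(nrow(cp)), function(i) {
      s <- strsplit(refs[[cp$cp_haplotype[i]]], "")[[1]]
      idx <- sample.int(length(s), n_private)
      s[idx] <- nt[(match(s[idx], nt) + sample.int(3L, n_private, TRUE) - 1L) %% 4L + 1L]
      paste(s, collapse = "")
    }, character(1))
  })
  setNames(seqs, cp$sample_id)
}

#' Simulate a four-taxon alignment with optional introgression
#'
#' Generates independent columns under a (((P1, P2), P3), outgroup)
#' topology with single-origin derived alleles: the outgroup always
#' carries the ancestral state; each of the four branches (P1, P2, P3
#' terminal branches and the P1P2 internal branch) carries the derived
#' allele independently with probability `per_branch_substitution_prob`.
#' A fraction `f_introgression` of sites then has P3's state replaced
#' by the donor lineage's state. With `f_introgression = 0` the
#' construction is exchangeable in (P1, P2), so E\[D\] = 0.
#'
#' @param length Alignment length in bp.
#' @param per_branch_substitution_prob Per-branch derived-allele
#'   probability; default 0.1 mimics interspecific divergence at the
#'   scale of the analysed gene alignments.
#' @param f_introgression Fraction of P3 sites copied from the donor.
#' @param donor `"P1"` or `"P2"`.
#' @param seed Integer seed.
#' @return Named character vector `c(P1=, P2=, P3=, outgroup=)` of
#'   equal-length sequences, class `four_taxon_aln`.
#' @export
simulate_four_taxon <- function(length = 50000,
                                per_branch_substitution_prob = 0.1,
                                f_introgression = 0, donor = c("P2", "P1"),
                                seed = 1) {
  donor <- match.arg(donor)
  p <- per_branch_substitution_prob
  stopifnot(length >= 1, p >= 0, p <= 1,
            f_introgression >= 0, f_introgression <= 1)
  nt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    anc <- sample(nt, length, replace = TRUE)
    der <- nt[(match(anc, nt) + sample.int(3L, length, TRUE) - 1L) %% 4L + 1L]
    b_int <- runif(length) < p
    b1 <- runif(length) < p
    b2 <- runif(length) < p
    b3 <- runif(length) < p
    p1 <- ifelse(b_int | b1, der, anc)
    p2 <- ifelse(b_int | b2, der, anc)
    p3 <- ifelse(b3, der, anc)
    if (f_introgression > 0) {
      idx <- runif(length) < f_introgression
      src <- if (donor == "P2") p2 else p1
      p3[idx] <- src[idx]
    }
    structure(
      c(P1 = paste(p1, collapse = ""), P2 = paste(p2, collapse = ""),
        P3 = paste(p3, collapse = ""), outgroup = paste(anc, collapse = "")),
      class = c("four_taxon_aln", "character")
    )
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' The default `"two_taxa_plus_hybrids"` scenario emulates the study
#' design: 26 samples comprising 1 taxon-A parental, 20 taxon-B
#' parentals and 5 hybrids of mixed generations (two F1s with opposite
#' chloroplast donors, one BC3 and two BC4s backcrossed to taxon B with
#' a taxon-A chloroplast — all cytonuclear-discordant, as natural
#' chloroplast-capture hybrids are). Emits a multi-sample VCF, a
#' chloroplast FASTA (two references plus one sequence per sample), a
#' metadata TSV with coordinates in northern Queensland, the
#' diagnostic-panel site table, a four-taxon alignment FASTA with
#' introgression, and a truth table. Re-running with the same seed
#' reproduces every file byte for byte.
#'
#' @param outdir Output directory (created if needed).
#' @param scenario Scenario name; only `"two_taxa_plus_hybrids"` is
#'   defined.
#' @param seed Integer seed governing every random draw.
#' @param n_sites,n_diagnostic Site-map dimensions (see
#'   [sim_site_map()]).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_set <- function(outdir, scenario = "two_taxa_plus_hybrids",
                              seed = 1, n_sites = 20000,
                              n_diagnostic = round(0.01 * n_sites)) {
  if (!identical(scenario, "two_taxa_plus_hybrids")) {
    abort(paste0("unknown scenario: ", scenario))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_scenario(seed = seed, n_sites = n_sites,
                           n_diagnostic = n_diagnostic)

  paths <- list(
    vcf = file.path(outdir, "variants.vcf"),
    cp_fasta = file.path(outdir, "chloroplast.fasta"),
    metadata = file.path(outdir, "metadata.tsv"),
    panel = file.path(outdir, "panel_sites.tsv"),
    four_taxon = file.path(outdir, "four_taxon.fasta"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_vcf(sim$geno, paths$vcf)
  write_fasta(c(cpA_ref = sim$cp_refs$cpA, cpB_ref = sim$cp_refs$cpB,
                sim$cp_seqs), paths$cp_fasta)
  readr::write_tsv(sim$metadata, paths$metadata, progress = FALSE)
  readr::write_tsv(sim$panel_sites, paths$panel, progress = FALSE)
  write_fasta(unclass(sim$four_taxon), paths$four_taxon)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  invisible(paths)
}

#' Simulate the default two-taxon + hybrids scenario in memory
#'
#' Same construction as [write_fixture_set()] but returning the
#' objects instead of writing files.
#'
#' @inheritParams write_fixture_set
#' @param f_introgression Introgression fraction of the bundled
#'   four-taxon alignment.
#' @return List with `geno`, `cp` (haplotype labels), `cp_refs`,
#'   `cp_seqs`, `metadata`, `panel_sites`, `sites`, `four_taxon`,
#'   `truth`, and the two taxon models.
#' @export
simulate_scenario <- function(seed = 1, n_sites = 20000,
                              n_diagnostic = round(0.01 * n_sites),
                              f_introgression = 0.3) {
  seeds <- derive_seeds(seed, 10)
  sites <- sim_site_map(n_sites, n_diagnostic, seed = seeds[1])
  model_a <- taxon_model(sites, "A")
  model_b <- taxon_model(sites, "B")

  par_a <- simulate_parentals(model_a, 1, seed = seeds[2], prefix = "WRA")
  par_b <- simulate_parentals(model_b, 20, seed = seeds[3], prefix = "WRB")

  hyb_specs <- list(
    HYB01 = cross_spec("F1", maternal_parent = "B", seed = seeds[4]),
    HYB02 = cross_spec("F1", maternal_parent = "A", seed = seeds[4] + 1L),
    HYB03 = cross_spec("BC", n_backcrosses = 3, recurrent_parent = "B",
                       maternal_parent = "A", seed = seeds[4] + 2L),
    HYB04 = cross_spec("BC", n_backcrosses = 4, recurrent_parent = "B",
                       maternal_parent = "A", seed = seeds[4] + 3L),
    HYB05 = cross_spec("BC", n_backcrosses = 4, recurrent_parent = "B",
                       maternal_parent = "A", seed = seeds[4] + 4L)
  )
  hybs <- imap(hyb_specs, function(sp, id) {
    simulate_hybrid(model_a, model_b, sp, sample_id = id)
  })

  geno <- bind_rows(par_a$geno, par_b$geno, map_dfr(hybs, "geno"))
  cp <- bind_rows(
    par_a$cp, par_b$cp,
    tibble(sample_id = names(hybs),
           cp_haplotype = unname(map_chr(hybs, "cp_haplotype")))
  )
  cp_refs <- simulate_cp_references(seed = seeds[5])
  cp_seqs <- simulate_cp_sequences(cp, cp_refs, seed = seeds[6])

  n <- nrow(cp)
  metadata <- withr::with_seed(seeds[7], tibble(
    sample_id = cp$sample_id,
    latitude = round(runif(n, -16.5, -11.0), 4),
    longitude = round(runif(n, 141.0, 145.5), 4),
    year = sample(c(2015L, 2016L), n, replace = TRUE, prob = c(0.85, 0.15)),
    taxon_label = c("parental_A", rep("parental_B", 20),
                    rep("putative_hybrid", 5))
  ))

  panel_sites <- sites %>%
    filter(!is.na(.data$gene)) %>%
    select("gene", "chrom", "pos", allele_A = "ref", allele_B = "alt")

  four_taxon <- simulate_four_taxon(length = 10000,
                                    f_introgression = f_introgression,
                                    donor = "P2", seed = seeds[8])

  truth <- tibble(
    sample_id = cp$sample_id,
    true_taxon = c("A", rep("B", 20), rep("hybrid", 5)),
    true_generation = c(rep(NA_character_, 21), map_chr(hybs, "generation")),
    true_cp = cp$cp_haplotype,
    true_maternal_parent = c("A", rep("B", 20),
                             unname(map_chr(hyb_specs, "maternal_parent")))
  )

  list(geno = geno, cp = cp, cp_refs = cp_refs, cp_seqs = cp_seqs,
       metadata = metadata, panel_sites = panel_sites, sites = sites,
       four_taxon = four_taxon, truth = truth,
       model_a = model_a, model_b = model_b)
}

# independent sub-seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2^31 - 100, n))
}
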