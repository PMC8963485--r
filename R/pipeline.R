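#' Pipeline run configuration
#'
#' Collects input paths, analysis toggles and thresholds for
#' [run_pipeline()]. Threshold defaults are the study's stated
#' parameters: 25% minimum heterozygote allele frequency, 50 kb /
#' 10-site / r-squared 0.2 LD pruning, 999 Mantel permutations, four
#' jackknife blocks.
#'
#' @param vcf,cp_fasta,metadata,panel Paths to the variant VCF, the
#'   chloroplast FASTA (references `cpA_ref`/`cpB_ref` plus one
#'   sequence per sample), the sample metadata TSV and the
#'   diagnostic-panel site TSV (`gene`, `chrom`, `pos`, `allele_A`,
#'   `allele_B`).
#' @param four_taxon Optional path to an aligned four-sequence FASTA
#'   (order/names P1, P2, P3, outgroup) for the ABBA-BABA stage.
#' @param outdir Output directory.
#' @param genome_size_bp Named vector `c(A=, B=)` of genome sizes used
#'   in heterozygosity percentages; defaults to the two taxa's assembly
#'   sizes ([oryza_genome_sizes()]).
#' @param run_varstats,run_diagnosis,run_dstat,run_structure Stage
#'   toggles.
#' @param min_het_allele_freq,early_factor,het_site_fraction,
#'   prune_window_bp,prune_step,prune_r2,n_perm,n_blocks Thresholds
#'   (see the stage functions).
#' @param seed Integer seed recorded in all outputs and used for every
#'   random draw.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, cp_fasta, metadata, panel,
                            four_taxon = NULL, outdir = tempfile("htrun"),
                            genome_size_bp = oryza_genome_sizes(),
                            run_varstats = TRUE, run_diagnosis = TRUE,
                            run_dstat = TRUE, run_structure = TRUE,
                            min_het_allele_freq = 0.25, early_factor = 1.5,
                            het_site_fraction = 0.5,
                            prune_window_bp = 50000, prune_step = 10,
                            prune_r2 = 0.2, n_perm = 999, n_blocks = 4,
                            seed = 1) {
  stopifnot(
    min_het_allele_freq >= 0, min_het_allele_freq <= 0.5,
    early_factor > 0, het_site_fraction >= 0, het_site_fraction <= 1,
    prune_window_bp >= 1, prune_step >= 1, prune_r2 >= 0, prune_r2 <= 1,
    n_perm >= 1, n_blocks >= 1
  )
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full hybrid-detection pipeline
#'
#' Orchestrates ingest, per-sample variant statistics, hybrid
#' diagnosis, the four-taxon ABBA-BABA test and population-structure
#' analyses into one seeded run, writing TSV/JSON reports plus a
#' machine-readable manifest to the output directory. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the result tables/objects and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  results <- list()

  ing <- stage("ingest", {
    variants <- read_vcf(config$vcf)
    cp_seqs <- read_fasta(config$cp_fasta)
    meta <- read_sample_metadata(config$metadata)
    panel <- readr::read_tsv(config$panel, show_col_types = FALSE,
                             progress = FALSE)
    stopifnot(all(c("gene", "chrom", "pos", "allele_A", "allele_B") %in%
                    names(panel)))
    if (!all(c("cpA_ref", "cpB_ref") %in% names(cp_seqs))) {
      abort("chloroplast FASTA must contain cpA_ref and cpB_ref")
    }
    list(variants = variants, cp_seqs = cp_seqs, meta = meta, panel = panel)
  })
  results$metadata <- ing$meta

  if (config$run_varstats) {
    results$variant_summary <- stage("varstats", {
      # genome size by labelled taxon: A for parental_A, B otherwise
      # (the B size is also used for hybrids unless diagnosis says A)
      sizes <- setNames(
        if_else(ing$meta$taxon_label == "parental_A",
                config$genome_size_bp[["A"]], config$genome_size_bp[["B"]]),
        ing$meta$sample_id
      )
      summarize_sample_variants(
        ing$variants,
        genome_size_bp = sizes,
        min_het_allele_freq = config$min_het_allele_freq
      )
    })
    paths$variant_summary <- file.path(config$outdir, "variant_summary.tsv")
    readr::write_tsv(results$variant_summary, paths$variant_summary,
                     progress = FALSE)
  }

  if (config$run_diagnosis) {
    results$hybrid_report <- stage("diagnose", {
      hybrid_report(
        ing$variants, ing$panel,
        cp_seqs = ing$cp_seqs[setdiff(names(ing$cp_seqs),
                                      c("cpA_ref", "cpB_ref"))],
        cp_ref_A = ing$cp_seqs[["cpA_ref"]],
        cp_ref_B = ing$cp_seqs[["cpB_ref"]],
        genome_size_bp = config$genome_size_bp,
        min_het_allele_freq = config$min_het_allele_freq,
        early_factor = config$early_factor,
        het_site_fraction = config$het_site_fraction
      )
    })
    paths$hybrid_report <- file.path(config$outdir, "hybrid_report.tsv")
    readr::write_tsv(results$hybrid_report, paths$hybrid_report,
                     progress = FALSE)
  }

  if (config$run_dstat && !is.null(config$four_taxon)) {
    results$dstat <- stage("dstat", {
      aln <- as_four_taxon(read_fasta(config$four_taxon))
      blocks <- partition_blocks(nchar(aln[[1]]), n_blocks = config$n_blocks)
      block_jackknife_d(aln, blocks)
    })
    paths$dstat <- file.path(config$outdir, "dstat.tsv")
    readr::write_tsv(glance(results$dstat), paths$dstat, progress = FALSE)
    paths$dstat_blocks <- file.path(config$outdir, "dstat_blocks.tsv")
    readr::write_tsv(tidy(results$dstat), paths$dstat_blocks,
                     progress = FALSE)
  }

  if (config$run_structure) {
    str_res <- stage("structure", {
      dosage <- dosage_matrix(ing$variants)
      retained <- ld_prune(dosage, window_bp = config$prune_window_bp,
                           step = config$prune_step, r2_max = config$prune_r2)
      pruned <- dosage[, c("sample_id", retained)]
      pca <- pca_genotypes(pruned, k = 2)
      gd <- nei_dist_matrix(pruned)
      meta_ord <- ing$meta[match(dosage$sample_id, ing$meta$sample_id), ]
      gg <- geo_dist_matrix(meta_ord)
      mant <- mantel_ibd(gd, gg, n_perm = config$n_perm, seed = config$seed)
      list(n_sites = ncol(dosage) - 1L, n_retained = length(retained),
           pca = pca, nei = gd, geo = gg, mantel = mant)
    })
    results$structure <- str_res
    paths$pca_scores <- file.path(config$outdir, "pca_scores.tsv")
    readr::write_tsv(tidy(str_res$pca), paths$pca_scores, progress = FALSE)
    paths$pca_variance <- file.path(config$outdir, "pca_variance.tsv")
    readr::write_tsv(tidy(str_res$pca, matrix = "eigenvalues"),
                     paths$pca_variance, progress = FALSE)
    paths$nei_dist <- file.path(config$outdir, "nei_dist.tsv")
    readr::write_tsv(as_tibble(str_res$nei, rownames = "sample_id"),
                     paths$nei_dist, progress = FALSE)
    paths$geo_dist <- file.path(config$outdir, "geo_dist.tsv")
    readr::write_tsv(as_tibble(str_res$geo, rownames = "sample_id"),
                     paths$geo_dist, progress = FALSE)
    paths$mantel <- file.path(config$outdir, "mantel.json")
    jsonlite::write_json(as.list(glance(str_res$mantel)), paths$mantel,
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "hybridtrace",
    version = as.character(utils::packageVersion("hybridtrace")),
    seed = config$seed,
    inputs = list(vcf = config$vcf, cp_fasta = config$cp_fasta,
                  metadata = config$metadata, panel = config$panel,
                  four_taxon = config$four_taxon),
    parameters = config[c("min_het_allele_freq", "early_factor",
                          "het_site_fraction", "prune_window_bp",
                          "prune_step", "prune_r2", "n_perm", "n_blocks")],
    stages_run = c(
      varstats = config$run_varstats, diagnosis = config$run_diagnosis,
      dstat = config$run_dstat && !is.null(config$four_taxon),
      structure = config$run_structure
    ),
    outputs = paths
  )
  paths$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  results$paths <- paths
  invisible(results)
}
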