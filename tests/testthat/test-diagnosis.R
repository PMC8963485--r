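test_that("chloroplast typing picks the nearest reference plastome", {
  refs <- simulate_cp_references(length = 500, n_diff = 10, seed = 4)

  # identical to cpB: type B with zero B-distance and the full divergence to A
  out <- assign_chloroplast_type(refs$cpB, refs$cpA, refs$cpB)
  expect_equal(out$cp_type, "B")
  expect_equal(out$count_vs_B, 0)
  expect_equal(out$count_vs_A, 10)

  # cpA with one extra substitution: type A, counts (1, ~divergence)
  s <- strsplit(refs$cpA, "")[[1]]
  pos <- which(s == strsplit(refs$cpB, "")[[1]])[1] # a site shared by A and B
  s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[1]
  out <- assign_chloroplast_type(paste(s, collapse = ""), refs$cpA, refs$cpB)
  expect_equal(out$cp_type, "A")
  expect_equal(out$count_vs_A, 1)
  expect_equal(out$count_vs_B, 11)

  # equidistant sample is unassigned
  expect_warning(
    tie <- assign_chloroplast_type("AAGG", "AAGC", "AATG"),
    "equidistant"
  )
  expect_true(is.na(tie$cp_type))

  expect_error(assign_chloroplast_type("ACGT", "ACG", "ACGT"), "equal length")
})

test_that("a gap run counts as a single variant event", {
  #      ref: ACGTACGT          sample: AC--ACGA
  # events: one 2-column gap run + one terminal substitution = 2
  out <- assign_chloroplast_type("AC--ACGA", "ACGTACGT", "AC--ACGA")
  expect_equal(out$count_vs_A, 2)
  expect_equal(out$count_vs_B, 0)
})

test_that("nuclear typing thresholds the diagnostic A-allele fraction", {
  expect_equal(assign_nuclear_type(panel_geno(rep("homA", 25)))$nuclear_type, "A")
  expect_equal(assign_nuclear_type(panel_geno(rep("homA", 25)))$fraction_A, 1)

  all_het <- assign_nuclear_type(panel_geno(rep("het", 30)))
  expect_equal(all_het$nuclear_type, "admixed")
  expect_equal(all_het$fraction_A, 0.5)

  # 75% A alleles: admixed under the 0.9/0.1 defaults
  mix <- assign_nuclear_type(panel_geno(c(rep("homA", 20), rep("het", 10),
                                          rep("homB", 2))))
  expect_equal(mix$nuclear_type, "admixed")

  few <- assign_nuclear_type(panel_geno(rep("homB", 10)))
  expect_true(is.na(few$nuclear_type))
})

test_that("cytonuclear classification flags chloroplast capture both ways", {
  # captured meridionalis-type chloroplast in a rufipogon-type nucleus
  d1 <- classify_cytonuclear("B", "A")
  expect_equal(d1$cytonuclear_status, "discordant")
  expect_equal(d1$maternal_parent, "B")

  # the opposite capture direction
  d2 <- classify_cytonuclear("A", "B")
  expect_equal(d2$cytonuclear_status, "discordant")
  expect_equal(d2$maternal_parent, "A")

  expect_equal(classify_cytonuclear("B", "B")$cytonuclear_status, "concordant")
  expect_equal(classify_cytonuclear("A", "admixed")$cytonuclear_status,
               "discordant")
  expect_true(is.na(classify_cytonuclear(NA, "A")$cytonuclear_status))

  # symmetric under relabelling A <-> B of both inputs
  flip <- function(x) c(A = "B", B = "A", admixed = "admixed")[[x]]
  for (cp in c("A", "B")) {
    for (nuc in c("A", "B", "admixed")) {
      expect_equal(
        classify_cytonuclear(cp, nuc)$cytonuclear_status,
        classify_cytonuclear(flip(cp), flip(nuc))$cytonuclear_status
      )
    }
  }
})

test_that("diagnostic locus calls follow the site-majority rule", {
  expect_equal(call_diagnostic_locus(panel_geno(rep("het", 5))), "AB")
  expect_equal(call_diagnostic_locus(panel_geno(rep("homB", 5))), "BB")
  expect_equal(call_diagnostic_locus(panel_geno(rep("homA", 4))), "AA")
  # heterozygous fraction at exactly the threshold calls AB
  expect_equal(call_diagnostic_locus(panel_geno(c("het", "het", "homB",
                                                  "homB"))), "AB")
  # below the het threshold: majority of homozygous sites
  expect_equal(call_diagnostic_locus(panel_geno(c("het", "homB", "homB",
                                                  "homB"))), "BB")
  # tied homozygotes, no het majority: inconclusive
  expect_equal(call_diagnostic_locus(panel_geno(c("homA", "homB"))),
               "inconclusive")
  expect_equal(call_diagnostic_locus(panel_geno(character(0))), "inconclusive")
})

test_that("generation classification is anchored to parental heterozygosity", {
  expect_equal(classify_generation(0.69, 0.38), "early")
  expect_equal(classify_generation(0.31, 0.38), "later")
  # boundary value classifies early (>= rule)
  expect_equal(classify_generation(1.5 * 0.38, 0.38), "early")
  expect_error(classify_generation(0.5, numeric(0)), "parental")
  expect_error(classify_generation(0.5, 0), "parental")
})

test_that("the full report recovers the simulated truth on a small scenario", {
  sim <- small_scenario()
  rep <- hybrid_report(
    sim$geno, sim$panel_sites,
    cp_seqs = sim$cp_seqs,
    cp_ref_A = sim$cp_refs$cpA, cp_ref_B = sim$cp_refs$cpB,
    genome_size_bp = c(A = 3000, B = 3000),
    diagnostic_sites = dplyr::select(
      dplyr::filter(sim$sites, diagnostic),
      chrom, pos, allele_A = ref, allele_B = alt
    )
  )
  rep <- dplyr::left_join(rep, sim$truth, by = "sample_id")

  # chloroplast donor recovered everywhere
  expect_equal(paste0("cp", rep$cp_type), rep$true_cp)

  hyb <- dplyr::filter(rep, true_taxon == "hybrid")
  par <- dplyr::filter(rep, true_taxon != "hybrid")
  expect_true(all(hyb$cytonuclear_status == "discordant"))
  expect_true(all(par$cytonuclear_status == "concordant"))
  expect_true(all(par$generation_class == "non_hybrid"))

  f1 <- dplyr::filter(hyb, true_generation == "F1")
  expect_true(all(f1$generation_class == "early"))
  gene_calls <- as.matrix(f1[, unique(sim$panel_sites$gene)])
  expect_true(all(gene_calls == "AB"))

  bc <- dplyr::filter(hyb, grepl("^BC", true_generation))
  expect_true(all(bc$generation_class == "later"))
  expect_true(all(bc$nuclear_type == "B"))
})
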