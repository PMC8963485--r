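# shared in-code fixtures for the test suite

# write VCF body rows (list of tab-joined strings) with a standard header
write_mini_vcf <- function(rows, samples = c("S1", "S2"), format = "GT",
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

# a one-sample variant tibble from terse specs: list(c(chrom,pos,ref,alt,a1,a2))
toy_variants <- function(calls, sample_id = "S1", af = NA_real_) {
  purrr::map_dfr(calls, function(x) {
    tibble::tibble(
      sample_id = sample_id, chrom = x[[1]], pos = as.integer(x[[2]]),
      ref = x[[3]], alt = x[[4]],
      variant_class = hybridtrace::classify_variant(x[[3]], x[[4]]),
      a1 = x[[5]], a2 = x[[6]], called = !is.na(x[[5]]), af = af
    )
  })
}

# four-taxon alignment from explicit columns: a 4-row character matrix
aln_from_columns <- function(cols) {
  m <- do.call(cbind, cols)
  as_four_taxon(apply(m, 1, paste, collapse = ""))
}

# panel-site genotype tibble for locus-call tests: lab in {"het","homA","homB"}
panel_geno <- function(labs, allele_A = "A", allele_B = "G") {
  tibble::tibble(
    a1 = dplyr::case_when(labs == "het" ~ allele_A, labs == "homA" ~ allele_A,
                          TRUE ~ allele_B),
    a2 = dplyr::case_when(labs == "het" ~ allele_B, labs == "homA" ~ allele_A,
                          TRUE ~ allele_B),
    called = TRUE, allele_A = allele_A, allele_B = allele_B
  )
}

# small scenario shared across diagnosis/pipeline tests (cached per session)
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scenario(seed = 42, n_sites = 3000, n_diagnostic = 80)
    }
    cache
  }
})
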