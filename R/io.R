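#' Read a VCF file into a per-sample variant table
#'
#' Parses a VCF 4.x file and returns one row per biallelic variant per
#' sample. Multi-allelic records are split into one row per alternate
#' allele; the sample genotype is stored as an unordered allele pair of
#' actual nucleotide strings (phase, if present, is discarded). Each
#' variant is classified as SNV, MNV, insertion, deletion or replacement
#' from its REF/ALT alleles (see [classify_variant()]).
#'
#' The alternate-allele read fraction is taken from the per-sample `AF`
#' FORMAT field when present, otherwise computed from `AD`; it is `NA`
#' when neither is available.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @return A tibble with columns `sample_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `variant_class`, `a1`, `a2` (the unordered genotype;
#'   `NA` when the call is missing), `called` (logical) and `af`.
#' @export
read_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(paste0("malformed VCF '", path, "': ", conditionMessage(e)))
    }
  )
  if (nrow(vcf@fix) == 0L) {
    abort(paste0("VCF '", path, "' contains no variant records"))
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) {
    abort(paste0("VCF '", path, "' has records without a GT FORMAT field"))
  }

  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  ref <- vcf@fix[, "REF"]
  alt_str <- vcf@fix[, "ALT"]
  if (any(is.na(chrom) | is.na(pos) | is.na(ref) | is.na(alt_str))) {
    bad <- which(is.na(chrom) | is.na(pos) | is.na(ref) | is.na(alt_str))[1L]
    abort(paste0("malformed VCF record at row ", bad, " of '", path, "'"))
  }

  gt <- vcfR::extract.gt(vcf)
  samples <- colnames(gt)
  n_site <- length(pos)
  n_samp <- length(samples)

  fmt_keys <- unique(unlist(strsplit(fmt, ":", fixed = TRUE)))
  ad <- if ("AD" %in% fmt_keys) vcfR::extract.gt(vcf, "AD") else NULL
  afm <- if ("AF" %in% fmt_keys) vcfR::extract.gt(vcf, "AF") else NULL

  # cell-level parse (site-major vectors of length n_site * n_samp)
  site_idx <- rep(seq_len(n_site), times = n_samp)
  sample_id <- rep(samples, each = n_site)
  gtv <- as.vector(gt)
  parts <- stringr::str_split_fixed(gtv, "[/|]", 2)
  i1 <- suppressWarnings(as.integer(parts[, 1]))
  i2 <- suppressWarnings(as.integer(parts[, 2]))
  i2[is.na(i2) & !is.na(i1)] <- i1[is.na(i2) & !is.na(i1)] # haploid-style calls
  called <- !is.na(i1) & !is.na(i2)

  # map allele indices to nucleotides through a flattened per-site allele list
  alt_list <- strsplit(alt_str, ",", fixed = TRUE)
  alleles <- mapply(function(r, a) c(r, a), ref, alt_list, SIMPLIFY = FALSE)
  n_allele <- lengths(alleles)
  offset <- cumsum(c(0L, n_allele[-n_site]))
  flat <- unlist(alleles, use.names = FALSE)
  idx_ok <- called & i1 < n_allele[site_idx] + 1L & i2 < n_allele[site_idx] + 1L
  if (any(called & !idx_ok)) {
    abort(paste0("genotype allele index out of range in '", path, "'"))
  }
  a1 <- ifelse(called, flat[offset[site_idx] + i1 + 1L], NA_character_)
  a2 <- ifelse(called, flat[offset[site_idx] + i2 + 1L], NA_character_)

  cells <- tibble(
    site = site_idx, sample_id = sample_id,
    a1 = a1, a2 = a2, called = called,
    gt_i1 = i1, gt_i2 = i2
  )
  if (!is.null(afm)) {
    cells$af_str <- as.vector(afm)
  } else if (!is.null(ad)) {
    cells$ad_str <- as.vector(ad)
  }

  alts <- tibble(
    site = rep(seq_len(n_site), lengths(alt_list)),
    alt_index = unlist(lapply(lengths(alt_list), seq_len)),
    alt = unlist(alt_list, use.names = FALSE)
  )
  sites <- tibble(site = seq_len(n_site), chrom = chrom, pos = pos, ref = ref)

  out <- inner_join(inner_join(alts, sites, by = "site"), cells,
    by = "site", relationship = "many-to-many"
  )

  out$af <- NA_real_
  if (!is.null(afm)) {
    af_parts <- strsplit(out$af_str, ",", fixed = TRUE)
    out$af <- suppressWarnings(as.numeric(mapply(
      function(p, k) if (length(p) >= k) p[k] else NA_character_,
      af_parts, out$alt_index
    )))
  } else if (!is.null(ad)) {
    ad_parts <- lapply(strsplit(out$ad_str, ",", fixed = TRUE),
                       function(p) suppressWarnings(as.numeric(p)))
    tot <- vapply(ad_parts, sum, numeric(1))
    altd <- mapply(function(p, k) if (length(p) > k) p[k + 1L] else NA_real_,
                   ad_parts, out$alt_index)
    out$af <- ifelse(tot > 0, altd / tot, NA_real_)
  }

  out %>%
    mutate(variant_class = classify_variant(.data$ref, .data$alt)) %>%
    select("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
           "a1", "a2", "called", "af") %>%
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

#' Write a variant table to a plain-text VCF
#'
#' Writes one VCF record per distinct (chrom, pos, ref, alt) in the
#' table, with per-sample `GT` (and `AF` when any read fractions are
#' present). Genotypes whose alleles are not both in {ref, alt} of a row
#' (multi-allelic content) are emitted as missing on that row. Output is
#' deterministic: sites sorted by (chrom, pos, alt), samples in first
#' order of appearance.
#'
#' @param variants A variant tibble as returned by [read_vcf()] (columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `a1`, `a2`, `called`,
#'   optionally `af`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  stopifnot(all(c("sample_id", "chrom", "pos", "ref", "alt", "a1", "a2",
                  "called") %in% names(variants)))
  samples <- unique(variants$sample_id)
  has_af <- "af" %in% names(variants) && any(!is.na(variants$af))

  sites <- variants %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    arrange(.data$chrom, .data$pos, .data$alt)

  enc <- variants %>%
    mutate(
      gt = dplyr::case_when(
        !.data$called ~ "./.",
        .data$a1 == .data$ref & .data$a2 == .data$ref ~ "0/0",
        .data$a1 == .data$ref & .data$a2 == .data$alt ~ "0/1",
        .data$a2 == .data$ref & .data$a1 == .data$alt ~ "0/1",
        .data$a1 == .data$alt & .data$a2 == .data$alt ~ "1/1",
        TRUE ~ "./."
      )
    )
  if (has_af) {
    enc <- enc %>% mutate(cell = paste0(
      .data$gt, ":", ifelse(is.na(.data$af), ".", formatC(.data$af, format = "g"))
    ))
  } else {
    enc <- enc %>% mutate(cell = .data$gt)
  }

  wide <- enc %>%
    select("chrom", "pos", "ref", "alt", "sample_id", "cell") %>%
    pivot_wider(names_from = "sample_id", values_from = "cell",
                values_fill = "./.")
  wide <- left_join(sites, wide, by = c("chrom", "pos", "ref", "alt"))
  miss <- if (has_af) "./.:." else "./."
  for (s in samples) {
    if (!s %in% names(wide)) wide[[s]] <- miss
    wide[[s]][is.na(wide[[s]])] <- miss
  }

  fmt <- if (has_af) "GT:AF" else "GT"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridtrace",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_af) '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Alternate allele read fraction">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", "PASS", ".", fmt,
    sep = "\t"
  )
  for (s in samples) body <- paste(body, wide[[s]], sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased and RNA `U` is converted to `T`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("cannot read FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) abort(paste0("FASTA '", path, "' is empty"))
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate sequence name in '", path, "': ",
                 nm[duplicated(nm)][1L]))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  setNames(seqs, nm)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Expects a TSV with header columns `sample_id`, `latitude`,
#' `longitude`, `year`, `taxon_label`. Latitude must lie in \[-90, 90\],
#' longitude in \[-180, 180\], taxon labels in `parental_A`,
#' `parental_B`, `putative_hybrid`, `unknown`, and sample ids must be
#' unique.
#'
#' @param path Path to the metadata TSV.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "latitude", "longitude", "year", "taxon_label")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata '", path, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata")
  }
  if (any(!is.finite(meta$latitude)) || any(abs(meta$latitude) > 90)) {
    abort("latitude out of range [-90, 90]")
  }
  if (any(!is.finite(meta$longitude)) || any(abs(meta$longitude) > 180)) {
    abort("longitude out of range [-180, 180]")
  }
  valid_labels <- c("parental_A", "parental_B", "putative_hybrid", "unknown")
  bad <- setdiff(unique(meta$taxon_label), valid_labels)
  if (length(bad) > 0) {
    abort(paste0("unknown taxon_label: ", paste(bad, collapse = ", ")))
  }
  meta %>%
    mutate(year = as.integer(.data$year)) %>%
    select(all_of(required), dplyr::everything())
}

#' Alternate-allele dosage matrix from a variant table
#'
#' Restricts to biallelic SNV rows and returns a wide samples-by-sites
#' tibble of alternate-allele dosages (0, 1, 2 or `NA` for missing
#' calls and genotypes carrying an allele outside \{ref, alt\}).
#' Site columns are named `chrom:pos:alt` so coordinates remain
#' recoverable (see [dosage_sites()]).
#'
#' @param variants A variant tibble from [read_vcf()] or the simulators.
#' @return Wide tibble: `sample_id` plus one numeric column per site,
#'   ordered by (chrom, pos, alt).
#' @export
dosage_matrix <- function(variants) {
  snv <- variants %>%
    filter(.data$variant_class == "SNV") %>%
    mutate(
      dosage = dplyr::case_when(
        !.data$called ~ NA_real_,
        (.data$a1 == .data$ref | .data$a1 == .data$alt) &
          (.data$a2 == .data$ref | .data$a2 == .data$alt) ~
          (.data$a1 == .data$alt) + (.data$a2 == .data$alt),
        TRUE ~ NA_real_
      ),
      site = paste(.data$chrom, .data$pos, .data$alt, sep = ":")
    )
  ord <- snv %>%
    distinct(.data$chrom, .data$pos, .data$alt, .data$site) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  snv %>%
    select("sample_id", "site", "dosage") %>%
    pivot_wider(names_from = "site", values_from = "dosage") %>%
    select("sample_id", all_of(ord$site))
}

#' Site coordinates of a dosage matrix
#'
#' @param dosage A wide dosage tibble from [dosage_matrix()].
#' @return Tibble with columns `site`, `chrom`, `pos`, `alt`.
#' @export
dosage_sites <- function(dosage) {
  site <- setdiff(names(dosage), "sample_id")
  parts <- stringr::str_split_fixed(site, ":", 3)
  tibble(site = site, chrom = parts[, 1], pos = as.integer(parts[, 2]),
         alt = parts[, 3])
}
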