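#' Write a simulated cohort to disk as a VCF + TSV fixture bundle
#'
#' Emits a sorted VCF v4.2 (FORMAT `GT:DP:GQ:AD`, site annotations in INFO,
#' VQSR tranche in FILTER), the sample manifest, kinship pairs, the domain
#' annotation table and the truth tables. The files round-trip through
#' [read_cohort()].
#'
#' @param cohort An `rc_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rc_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(sprintf("cannot write to directory '%s'", dir))
  }
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    manifest = file.path(dir, "samples.tsv"),
    kinship = file.path(dir, "kinship.tsv"),
    domains = file.path(dir, "domains.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv")
  )
  write_cohort_vcf(cohort, paths["vcf"])
  readr::write_tsv(cohort$samples, paths["manifest"])
  readr::write_tsv(cohort$kinship, paths["kinship"])
  readr::write_tsv(cohort$domains, paths["domains"])
  readr::write_tsv(cohort$truth$genes, paths["truth_genes"])
  readr::write_tsv(cohort$truth$sites, paths["truth_sites"])
  invisible(paths)
}

VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##source=rarecollapse_simulator",
  "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Sequence Ontology effect term\">",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
  "##INFO=<ID=TR,Number=1,Type=String,Description=\"Transcript id\">",
  "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
  "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
  "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
  "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"Read position rank sum\">",
  "##INFO=<ID=MQRS,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
  "##INFO=<ID=AF_AFR,Number=1,Type=Float,Description=\"gnomAD AF African\">",
  "##INFO=<ID=AF_AMR,Number=1,Type=Float,Description=\"gnomAD AF Latino\">",
  "##INFO=<ID=AF_EAS,Number=1,Type=Float,Description=\"gnomAD AF East Asian\">",
  "##INFO=<ID=AF_NFE,Number=1,Type=Float,Description=\"gnomAD AF Non-Finnish European\">",
  "##INFO=<ID=AF_SAS,Number=1,Type=Float,Description=\"gnomAD AF South Asian\">",
  "##INFO=<ID=CCDS,Number=1,Type=Integer,Description=\"1 if inside CCDS or 2bp canonical splice sites\">",
  "##INFO=<ID=EXTFAIL,Number=1,Type=Integer,Description=\"1 if flagged as failure by EVS/ExAC/gnomAD\">",
  "##FILTER=<ID=VQSRTrancheSNP90.00to99.00,Description=\"VQSR tranche\">",
  "##FILTER=<ID=VQSRTrancheSNP99.00to99.90,Description=\"VQSR tranche\">",
  "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"VQSR tranche\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
)

fmt_num <- function(x) {
  # fixed, locale-free numeric formatting so identical seeds give
  # byte-identical files
  out <- formatC(x, format = "fg", digits = 15)
  gsub(" ", "", out)
}

write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants |>
    arrange(as.integer(.data$chrom), .data$pos)
  sm <- cohort$samples$sample_id
  info <- sprintf(
    "EFFECT=%s;GENE=%s;TR=%s;QD=%s;MQ=%s;FS=%s;RPRS=%s;MQRS=%s;AF_AFR=%s;AF_AMR=%s;AF_EAS=%s;AF_NFE=%s;AF_SAS=%s;CCDS=%d;EXTFAIL=%d",
    v$effect, v$gene, v$transcript, fmt_num(v$qd), fmt_num(v$mq),
    fmt_num(v$fs), fmt_num(v$read_pos_rank_sum), fmt_num(v$mq_rank_sum),
    fmt_num(v$gnomad_af_afr), fmt_num(v$gnomad_af_amr),
    fmt_num(v$gnomad_af_eas), fmt_num(v$gnomad_af_nfe),
    fmt_num(v$gnomad_af_sas),
    as.integer(v$in_ccds_or_splice), as.integer(v$external_fail_flag)
  )
  fixed <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt,
                 fmt_num(v$qual), v$vqsr_tranche, info, sep = "\t")
  if (length(sm)) {
    gmat <- matrix("0/0:50:99:50,0", nrow = nrow(v), ncol = length(sm))
    ridx <- match(cohort$genotypes$variant_id, v$variant_id)
    cidx <- match(cohort$genotypes$sample_id, sm)
    g <- cohort$genotypes
    gmat[cbind(ridx, cidx)] <- sprintf(
      "%s:%d:%d:%d,%d", g$gt, g$dp, g$gq, g$dp - g$alt_reads, g$alt_reads
    )
    if (nrow(cohort$coverage)) {
      cv <- anti_join(cohort$coverage, cohort$genotypes,
                      by = c("variant_id", "sample_id"))
      if (nrow(cv)) {
        gmat[cbind(match(cv$variant_id, v$variant_id),
                   match(cv$sample_id, sm))] <-
          sprintf("0/0:%d:99:%d,0", cv$dp, cv$dp)
      }
    }
    body <- paste(fixed, "GT:DP:GQ:AD",
                  apply(gmat, 1, paste, collapse = "\t"), sep = "\t")
    cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sm), collapse = "\t")
  } else {
    body <- fixed
    cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO"), collapse = "\t")
  }
  if (nrow(v) == 0) body <- character()
  writeLines(c(VCF_HEADER, cols, body), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  m
}

pick_allele <- function(x, allele_no) {
  has_comma <- !is.na(x) & grepl(",", x, fixed = TRUE)
  if (!any(has_comma)) return(x)
  parts <- strsplit(x[has_comma], ",", fixed = TRUE)
  x[has_comma] <- purrr::map2_chr(parts, allele_no[has_comma],
                                  function(p, j) p[min(j, length(p))])
  x
}

#' Read a cohort: VCF, sample manifest, kinship pairs, domain annotations
#'
#' Parses a VCF v4.2 with the annotation keys emitted by
#' [write_fixture_bundle()] (or a GATK-annotated VCF using the same INFO
#' keys, VQSR tranche in FILTER, and FORMAT `GT:DP:GQ:AD`). Multi-allelic
#' records are split into biallelic records; genotype allele indices are
#' remapped per split allele. Genotype rows are returned for carriers
#' (genotypes containing the alternate allele); per-site low-coverage
#' indicators (DP < 10) are returned separately for coverage
#' harmonization.
#'
#' @param vcf_path Path to the VCF.
#' @param manifest_path Sample manifest TSV (`sample_id`, `phenotype`,
#'   `cluster`, `kit`, `contamination`, `ccds_coverage`).
#' @param kinship_path Optional kinship TSV (`id1`, `id2`, `degree`).
#' @param domain_path Optional domain TSV (`gene`, `transcript`, `chrom`,
#'   `start`, `end`, `subrvis_percentile`).
#' @return A list with tibbles `variants` (including `an_called`, twice
#'   the number of non-missing genotypes), `genotypes`, `samples`,
#'   `kinship`, `domains`, `coverage`.
#' @export
read_cohort <- function(vcf_path, manifest_path, kinship_path = NULL,
                        domain_path = NULL) {
  samples <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  assert_columns(samples, c("sample_id", "phenotype", "cluster"),
                 "sample manifest")
  if (!all(samples$phenotype %in% c("case", "control"))) {
    abort("manifest `phenotype` must be 'case' or 'control'")
  }
  validate_vcf_lines(vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  n_rec <- nrow(fix)
  has_gt <- ncol(vcf@gt) > 1
  if (has_gt) {
    vcf_samples <- colnames(vcf@gt)[-1]
    extra <- setdiff(vcf_samples, samples$sample_id)
    missing <- setdiff(samples$sample_id, vcf_samples)
    if (length(extra) || length(missing)) {
      abort(sprintf(
        "manifest/VCF sample mismatch: %d VCF-only (%s), %d manifest-only (%s)",
        length(extra), paste(head(extra, 3), collapse = ", "),
        length(missing), paste(head(missing, 3), collapse = ", ")))
    }
  }
  empty <- list(
    variants = empty_variants(),
    genotypes = tibble(variant_id = character(), sample_id = character(),
                       gt = character(), dp = integer(), gq = integer(),
                       alt_reads = integer(), ab = double()),
    samples = samples,
    kinship = read_kinship(kinship_path, samples),
    domains = read_domains(domain_path),
    coverage = tibble(variant_id = character(), chrom = character(),
                      pos = integer(), sample_id = character(),
                      depth10 = logical(), dp = integer())
  )
  if (is.null(n_rec) || n_rec == 0) return(empty)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  ridx <- rep(seq_len(n_rec), n_alt)
  allele_no <- sequence(n_alt)
  info <- fix[ridx, "INFO"]
  num_info <- function(key) {
    as.numeric(pick_allele(info_field(info, key), allele_no))
  }
  variants <- tibble(
    chrom = fix[ridx, "CHROM"],
    pos = as.integer(fix[ridx, "POS"]),
    ref = fix[ridx, "REF"],
    alt = unname(unlist(alts)),
    qual = as.numeric(fix[ridx, "QUAL"]),
    vqsr_tranche = fix[ridx, "FILTER"],
    effect = pick_allele(info_field(info, "EFFECT"), allele_no),
    gene = info_field(info, "GENE"),
    transcript = info_field(info, "TR"),
    qd = num_info("QD"),
    mq = num_info("MQ"),
    fs = num_info("FS"),
    read_pos_rank_sum = num_info("RPRS"),
    mq_rank_sum = num_info("MQRS"),
    gnomad_af_afr = num_info("AF_AFR"),
    gnomad_af_amr = num_info("AF_AMR"),
    gnomad_af_eas = num_info("AF_EAS"),
    gnomad_af_nfe = num_info("AF_NFE"),
    gnomad_af_sas = num_info("AF_SAS"),
    in_ccds_or_splice = {
      ccds <- info_field(info, "CCDS")
      is.na(ccds) | ccds == "1"   # absent annotation defaults to inside
    },
    external_fail_flag = info_field(info, "EXTFAIL") %in% "1"
  ) |>
    mutate(
      variant_class = ifelse(nchar(.data$ref) == nchar(.data$alt),
                             "SNV", "indel"),
      variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                         sep = ":")
    ) |>
    relocate("variant_id")

  if (!has_gt) {
    variants$an_called <- 0L
    out <- empty
    out$variants <- variants
    return(out)
  }
  gt <- vcfR::extract.gt(vcf, "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, "AD")
  sm <- colnames(gt)

  called <- !is.na(gt) & gt != "./." & gt != ".|."
  an_rec <- 2L * as.integer(rowSums(called))
  variants$an_called <- an_rec[ridx]

  # carrier rows: genotypes containing each split allele
  geno_rows <- vector("list", length(ridx))
  for (vi in seq_along(ridx)) {
    r <- ridx[vi]
    j <- allele_no[vi]
    gts <- unname(gt[r, ])
    idx <- which(!is.na(gts) &
                   vapply(strsplit(gts, "[/|]"), function(al) {
                     any(al == as.character(j))
                   }, TRUE))
    if (!length(idx)) next
    alleles <- strsplit(gts[idx], "[/|]")
    new_gt <- vapply(alleles, function(al) {
      paste(ifelse(al == as.character(j), "1", "0"), collapse = "/")
    }, "")
    ad_i <- strsplit(unname(ad[r, idx]), ",", fixed = TRUE)
    alt_reads <- vapply(ad_i, function(p) {
      if (length(p) > j) suppressWarnings(as.integer(p[j + 1])) else NA_integer_
    }, 1L)
    ref_reads <- vapply(ad_i, function(p) {
      suppressWarnings(as.integer(p[1]))
    }, 1L)
    geno_rows[[vi]] <- tibble(
      variant_id = variants$variant_id[vi],
      sample_id = sm[idx],
      gt = new_gt,
      dp = as.integer(unname(dp[r, idx])),
      gq = as.integer(unname(gq[r, idx])),
      alt_reads = alt_reads,
      ab = ifelse(is.na(alt_reads) | is.na(ref_reads) |
                    (alt_reads + ref_reads) == 0,
                  NA_real_, alt_reads / (alt_reads + ref_reads))
    )
  }
  genotypes <- bind_rows(geno_rows)
  low <- which(!is.na(dp) & dp < 10, arr.ind = TRUE)
  coverage <- if (nrow(low)) {
    first_split <- match(seq_len(n_rec), ridx)
    tibble(
      variant_id = variants$variant_id[first_split[low[, 1]]],
      chrom = variants$chrom[first_split[low[, 1]]],
      pos = variants$pos[first_split[low[, 1]]],
      sample_id = sm[low[, 2]],
      depth10 = FALSE,
      dp = as.integer(dp[low])
    )
  } else {
    empty$coverage
  }
  list(
    variants = variants,
    genotypes = arrange(genotypes, .data$variant_id, .data$sample_id),
    samples = samples,
    kinship = read_kinship(kinship_path, samples),
    domains = read_domains(domain_path),
    coverage = coverage
  )
}

empty_variants <- function() {
  tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), variant_class = character(),
    qual = double(), vqsr_tranche = character(), effect = character(),
    gene = character(), transcript = character(), qd = double(),
    mq = double(), fs = double(), read_pos_rank_sum = double(),
    mq_rank_sum = double(), gnomad_af_afr = double(),
    gnomad_af_amr = double(), gnomad_af_eas = double(),
    gnomad_af_nfe = double(), gnomad_af_sas = double(),
    in_ccds_or_splice = logical(), external_fail_flag = logical(),
    an_called = integer()
  )
}

read_kinship <- function(path, samples) {
  if (is.null(path) || !nzchar(path)) {
    return(tibble(id1 = character(), id2 = character(), degree = integer()))
  }
  kin <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(kin) == 0) {
    return(tibble(id1 = character(), id2 = character(), degree = integer()))
  }
  assert_columns(kin, c("id1", "id2", "degree"), "kinship table")
  kin
}

read_domains <- function(path) {
  if (is.null(path) || !nzchar(path)) {
    return(tibble(gene = character(), transcript = character(),
                  chrom = character(), start = integer(), end = integer(),
                  subrvis_percentile = double()))
  }
  dom <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           .default = readr::col_guess()))
  assert_columns(dom, c("gene", "chrom", "start", "end",
                        "subrvis_percentile"), "domain table")
  if (any(dom$start > dom$end)) abort("domain intervals must have start <= end")
  dom
}

validate_vcf_lines <- function(path) {
  fields <- utils::count.fields(path, sep = "\t", quote = "",
                                comment.char = "#")
  if (!length(fields)) return(invisible(TRUE))
  expected <- fields[1]
  bad <- which(fields != expected)
  if (length(bad)) {
    n_header <- 0L
    con <- file(path, "r")
    on.exit(close(con))
    while (length(l <- readLines(con, 1)) && startsWith(l, "#")) {
      n_header <- n_header + 1L
    }
    abort(sprintf("malformed VCF line %d in '%s': expected %d tab-separated fields, found %d",
                  n_header + bad[1], path, expected, fields[bad[1]]))
  }
  invisible(TRUE)
}
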