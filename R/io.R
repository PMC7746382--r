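# Genotype, phenotype and result IO, plus the post-imputation variant filters.

maf_from_dosage <- function(v) {
  m <- mean(v, na.rm = TRUE) / 2
  if (!is.finite(m)) return(NA_real_)
  min(m, 1 - m)
}

new_dosage_matrix <- function(samples, snps, values) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(snps), is.matrix(values))
  if (nrow(values) != length(samples) || ncol(values) != nrow(snps))
    stop_gcctwin("input_error", "dosage matrix dimensions do not match metadata")
  if (anyDuplicated(snps$snp_id))
    stop_gcctwin("integrity_error", "duplicate snp_id in dosage matrix")
  bad <- !is.na(values) & (values < 0 | values > 2)
  if (any(bad))
    stop_gcctwin("input_error",
                 sprintf("%d dosage values outside [0, 2]", sum(bad)))
  rownames(values) <- samples
  colnames(values) <- snps$snp_id
  structure(list(samples = samples, snps = snps, values = values),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("Dosage matrix: ", length(x$samples), " samples x ", nrow(x$snps),
      " SNPs\n", sep = "")
  if (nrow(x$snps) > 0)
    cat("  MAF range [", format(min(x$snps$maf), digits = 3), ", ",
        format(max(x$snps$maf), digits = 3), "], ",
        sum(!is.na(x$snps$info)), " SNPs with INFO\n", sep = "")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

subset_snps <- function(dm, keep) {
  new_dosage_matrix(dm$samples, dm$snps[keep, , drop = FALSE],
                    dm$values[, keep, drop = FALSE])
}

subset_samples <- function(dm, ids) {
  idx <- match(ids, dm$samples)
  if (anyNA(idx)) stop_gcctwin("join_error", "unknown sample ids")
  new_dosage_matrix(dm$samples[idx], dm$snps, dm$values[idx, , drop = FALSE])
}

#' Read genotype dosages from a VCF file
#'
#' Reads a VCF (v4.x) with a per-sample numeric dosage field (imputation
#' servers conventionally write `DS`), returning dosages in VCF sample order.
#' Per-SNP minor allele frequency is computed from the dosage means; the
#' imputation quality metric is taken from an INFO-column key when present
#' and left missing otherwise.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param dosage_field FORMAT key holding the dosage (default `"DS"`).
#' @param fallback_to_genotype when the dosage field is absent, derive
#'   dosages as alternate-allele counts from `GT` calls instead of failing.
#' @param info_key INFO-column key for the imputation quality metric.
#' @return A `dosage_matrix`: samples x SNPs dosages in \[0, 2\] (missing
#'   entries `NA`) with per-SNP metadata (`snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `maf`, `info`).
#' @export
read_dosage_vcf <- function(path, dosage_field = "DS",
                            fallback_to_genotype = FALSE, info_key = "INFO") {
  if (!file.exists(path))
    stop_gcctwin("parse_error", sprintf("file not found: %s", path))
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e)
      stop_gcctwin("parse_error", sprintf("malformed VCF %s: %s", path,
                                          conditionMessage(e))))
  fx <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) stop_gcctwin("parse_error", "VCF contains no records")
  fmt <- vcf@gt[, "FORMAT"]
  has_ds <- any(vapply(strsplit(fmt, ":"), function(k) dosage_field %in% k,
                       logical(1)))
  if (has_ds) {
    g <- suppressWarnings(
      vcfR::extract.gt(vcf, element = dosage_field, as.numeric = TRUE))
  } else if (fallback_to_genotype) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    g <- apply(gt, c(1, 2), function(s) {
      if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
      alleles <- strsplit(s, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles != "0")
    })
  } else {
    stop_gcctwin("field_error",
                 sprintf("dosage field '%s' absent and fallback disabled",
                         dosage_field))
  }
  values <- t(g)  # vcfR returns SNP x sample
  info <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = info_key)))
  ids <- fx$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fx$CHROM[noid], ":", fx$POS[noid])
  snps <- data.frame(
    snp_id = ids, chrom = as.character(fx$CHROM),
    pos = as.integer(fx$POS), ref_allele = fx$REF, alt_allele = fx$ALT,
    maf = apply(values, 2, maf_from_dosage),
    info = if (length(info)) info else NA_real_,
    stringsAsFactors = FALSE)
  new_dosage_matrix(colnames(g), snps, unname(values))
}

#' Read a delimited text dosage matrix
#'
#' Expects a header row of SNP ids, sample ids in the first column and a
#' numeric body of dosages in \[0, 2\]. MAF is computed from the column
#' means; chromosome/position metadata are unavailable in this format and
#' left missing.
#'
#' @param path file path.
#' @param sep field separator (tab default).
#' @return A `dosage_matrix`.
#' @export
read_dosage_matrix <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop_gcctwin("parse_error", sprintf("file not found: %s", path))
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2)
    stop_gcctwin("parse_error", "dosage matrix needs a sample-id column and at least one SNP column")
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- is.na(num) & !(body %in% c("NA", "", ".", "nan"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_gcctwin("parse_error",
                 sprintf("non-numeric dosage '%s' at row %d, column '%s'",
                         body[w[1], w[2]], w[1], colnames(body)[w[2]]))
  }
  snps <- data.frame(
    snp_id = colnames(body), chrom = NA_character_, pos = NA_integer_,
    ref_allele = NA_character_, alt_allele = NA_character_,
    maf = apply(num, 2, maf_from_dosage), info = NA_real_,
    stringsAsFactors = FALSE)
  new_dosage_matrix(ids, snps, num)
}

#' Write a dosage matrix as delimited text
#'
#' @param dm a `dosage_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_dosage_matrix <- function(dm, path, sep = "\t") {
  stopifnot(inherits(dm, "dosage_matrix"))
  out <- data.frame(sample_id = dm$samples, dm$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply post-imputation variant filters
#'
#' Retains SNPs with MAF at least `maf_min` and imputation INFO strictly
#' above `info_min`; SNPs without an INFO value (hard-typed variants) pass
#' the INFO filter. Column order is preserved and the operation is
#' idempotent.
#'
#' @param dm a `dosage_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param info_min INFO threshold, exclusive (default 0.6).
#' @return the filtered `dosage_matrix` (possibly with zero SNPs).
#' @export
filter_variants <- function(dm, maf_min = 0.05, info_min = 0.6) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (maf_min < 0 || maf_min > 1 || info_min < 0 || info_min > 1)
    stop_gcctwin("config_error", "filter thresholds must lie in [0, 1]")
  keep <- (!is.na(dm$snps$maf) & dm$snps$maf >= maf_min) &
    (is.na(dm$snps$info) | dm$snps$info > info_min)
  subset_snps(dm, keep)
}

#' Read a phenotype/covariate table
#'
#' Delimited text with required named columns `sample_id`, `phenotype`,
#' `age`, `sex`, `family_id`, `zygosity`. Sex is normalized to
#' `male`/`female`, zygosity to `MZ`/`DZ`/`singleton`. Families must group
#' one or two samples with constant zygosity.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a `pheno_table` (a validated data frame).
#' @export
read_pheno <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop_gcctwin("parse_error", sprintf("file not found: %s", path))
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  as_pheno_table(df)
}

#' Validate a phenotype/covariate data frame
#'
#' @param df data frame with the columns listed under [read_pheno()].
#' @return a `pheno_table`.
#' @export
as_pheno_table <- function(df) {
  required <- c("sample_id", "phenotype", "age", "sex", "family_id", "zygosity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_gcctwin("schema_error",
                 paste("missing required column(s):",
                       paste(missing_cols, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  df$family_id <- as.character(df$family_id)
  if (anyDuplicated(df$sample_id))
    stop_gcctwin("integrity_error", "duplicate sample_id in phenotype table")
  sex <- tolower(as.character(df$sex))
  sex[sex %in% c("m", "1")] <- "male"
  sex[sex %in% c("f", "2")] <- "female"
  if (!all(sex %in% c("male", "female")))
    stop_gcctwin("schema_error", "sex must be coded male/female (or M/F, 1/2)")
  df$sex <- factor(sex, levels = c("female", "male"))
  zyg <- as.character(df$zygosity)
  zyg[tolower(zyg) %in% c("mz", "monozygotic")] <- "MZ"
  zyg[tolower(zyg) %in% c("dz", "dizygotic")] <- "DZ"
  zyg[tolower(zyg) %in% c("singleton", "single", "s")] <- "singleton"
  if (!all(zyg %in% c("MZ", "DZ", "singleton")))
    stop_gcctwin("schema_error", "zygosity must be MZ, DZ or singleton")
  df$zygosity <- factor(zyg, levels = c("MZ", "DZ", "singleton"))
  fam_sizes <- table(df$family_id)
  if (any(fam_sizes > 2))
    stop_gcctwin("integrity_error",
                 sprintf("family %s has more than 2 members (twin design only)",
                         names(fam_sizes)[which(fam_sizes > 2)[1]]))
  zyg_per_fam <- tapply(as.character(df$zygosity), df$family_id,
                        function(z) length(unique(z)))
  if (any(zyg_per_fam > 1))
    stop_gcctwin("integrity_error",
                 sprintf("zygosity differs within family %s",
                         names(zyg_per_fam)[which(zyg_per_fam > 1)[1]]))
  df$phenotype <- as.numeric(df$phenotype)
  df$age <- as.numeric(df$age)
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Write an association result table
#'
#' Tab-delimited with fixed column order `snp_id`, `chrom`, `pos`, `model`,
#' `statistic`, `beta`, `se`, `pvalue`, `n_used`. Numeric values are written
#' with 12 significant digits so a write/read round trip is faithful.
#'
#' @param results data frame of association results (as in
#'   `gwas_scan$results`).
#' @param path output path.
#' @export
write_assoc <- function(results, path) {
  cols <- c("snp_id", "chrom", "pos", "model", "statistic", "beta", "se",
            "pvalue", "n_used")
  for (cc in setdiff(cols, names(results))) results[[cc]] <- NA
  out <- results[, cols]
  for (cc in c("statistic", "beta", "se", "pvalue"))
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA",
                        formatC(out[[cc]], digits = 12, format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association result table written by [write_assoc()]
#'
#' @param path file path.
#' @return data frame with the standard association columns.
#' @export
read_assoc <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("snp_id", "model", "statistic", "pvalue", "n_used")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_gcctwin("schema_error",
                 paste("missing required column(s):",
                       paste(missing_cols, collapse = ", ")))
  df
}

#' Write a phenotype table as delimited text
#'
#' @param pheno a `pheno_table` or compatible data frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_pheno <- function(pheno, path, sep = "\t") {
  write.table(as.data.frame(pheno), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
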