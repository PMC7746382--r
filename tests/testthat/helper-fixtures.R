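# In-code fixtures shared across test files.

toy_vcf_path <- function() {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t1000\trs1\tA\tG\t.\tPASS\tINFO=0.95\tGT:DS\t0/0:0.1\t0/1:1.0\t1/1:1.9",
    "1\t2000\trs2\tC\tT\t.\tPASS\tINFO=0.55\tGT:DS\t1/1:2.0\t0/0:0.0\t0/1:1.0",
    "2\t3000\trs3\tG\tA\t.\tPASS\tINFO=0.90\tGT:DS\t0/1:1.0\t./.:.\t0/0:0.0"
  ), p)
  p
}

toy_gt_vcf_path <- function() {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0/0\t0|1"
  ), p)
  p
}

toy_pheno_df <- function() {
  data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    phenotype = c(1.2, 0.7, -0.3, 0.1, 0.9, 1.4),
    age = c(60, 60, 55, 55, 70, 70),
    sex = c("male", "female", "male", "male", "female", "female"),
    family_id = c("f1", "f1", "f2", "f2", "f3", "f3"),
    zygosity = c("DZ", "DZ", "DZ", "DZ", "DZ", "DZ"),
    stringsAsFactors = FALSE)
}

# dosage_matrix built directly from a numeric matrix (test plumbing)
toy_dosage_matrix <- function(values, maf = NULL, info = NA_real_,
                              chrom = NA_character_) {
  snps <- data.frame(
    snp_id = paste0("snp", seq_len(ncol(values))),
    chrom = chrom, pos = seq_len(ncol(values)),
    ref_allele = "A", alt_allele = "G",
    maf = if (is.null(maf)) apply(values, 2, function(v)
      min(mean(v, na.rm = TRUE) / 2, 1 - mean(v, na.rm = TRUE) / 2)) else maf,
    info = info, stringsAsFactors = FALSE)
  gcctwin:::new_dosage_matrix(paste0("s", seq_len(nrow(values))), snps, values)
}

# small simulated twin dataset with phenotype filled in
toy_twin_data <- function(n_mz = 20, n_dz = 40, seed = 1,
                          effect_model = "null", effect_size = 0, ...) {
  cfg <- twin_sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz, seed = seed,
                         effect_model = effect_model,
                         effect_size = effect_size, ...)
  sim <- simulate_twin_genotypes(cfg)
  ph <- simulate_phenotype(sim$dosage$values[, 1], sim$pheno, cfg)
  list(cfg = cfg, dosage = sim$dosage, pheno = ph)
}
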