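## Oxytocin-pathway SNP coding: four SNPs, each dichotomised into a
## previously reported "risk" genotype group vs the rest, plus the
## cumulative 0-4 genetic risk score.

## risk groups and valid alleles per SNP; genotype strings are unordered
.sv_snp_panel <- list(
  rs1042778 = list(alleles = c("G", "T"), risk = "TT"),
  rs2254298 = list(alleles = c("A", "G"), risk = "GG"),
  rs53576   = list(alleles = c("A", "G"), risk = c("AA", "AG")),
  rs3796863 = list(alleles = c("A", "C"), risk = "CC")
)

#' The four-SNP oxytocin-pathway panel
#'
#' Names the SNPs used for the cumulative genetic risk score and, per SNP,
#' its valid alleles and the genotype group coded as "risk" (rs1042778 TT,
#' rs2254298 GG, rs53576 AA/AG, rs3796863 CC -- genotypes previously
#' associated with social difficulties).
#'
#' @return named list, one entry per SNP with elements `alleles` and `risk`.
#' @export
snp_panel <- function() .sv_snp_panel

## canonical unordered form: alphabetically sorted two-letter string
normalize_genotype <- function(genotype) {
  vapply(genotype, function(g) {
    if (is.na(g) || g == "") return(NA_character_)
    al <- strsplit(toupper(g), "")[[1]]
    if (length(al) != 2) return("!")  # caught by validation
    paste(sort(al), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Code a genotype into its 0/1 risk flag
#'
#' @param snp SNP identifier, one of `names(snp_panel())`.
#' @param genotype two-letter unordered allele pair (e.g. `"AG"` == `"GA"`),
#'   or `NA` for missing.
#' @return integer 0/1 (or `NA_integer_` for missing genotype).
#' @export
#' @examples
#' code_risk_allele("rs53576", "GA")  # carrier of A -> risk group -> 1
code_risk_allele <- function(snp, genotype) {
  if (!snp %in% names(.sv_snp_panel))
    stop_sv("unknown SNP '", snp, "'; panel: ",
            paste(names(.sv_snp_panel), collapse = ", "))
  info <- .sv_snp_panel[[snp]]
  g <- normalize_genotype(genotype)
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  alleles_ok <- ok & vapply(g, function(x)
    !is.na(x) && x != "!" && all(strsplit(x, "")[[1]] %in% info$alleles), TRUE)
  if (any(ok & !alleles_ok))
    stop_sv("invalid genotype '", genotype[which(ok & !alleles_ok)[1]],
            "' for SNP ", snp, " (valid alleles: ",
            paste(info$alleles, collapse = "/"), ")")
  out[ok] <- as.integer(g[ok] %in% info$risk)
  out
}

#' Cumulative genetic risk score
#'
#' Sum of the four per-SNP risk flags; ranges 0 (no risk genotype) to 4
#' (risk genotype at all four SNPs). Individuals missing any SNP get `NA`
#' and are excluded from genetic models downstream.
#'
#' @param flags numeric/integer vector (or one-row slice) of the four 0/1
#'   risk flags, ordered as `names(snp_panel())`.
#' @return integer 0..4 or `NA_integer_`.
#' @export
risk_score <- function(flags) {
  flags <- as.integer(flags)
  if (length(flags) != 4L) stop_sv("risk_score expects exactly 4 flags")
  if (anyNA(flags)) return(NA_integer_)
  if (!all(flags %in% 0:1)) stop_sv("risk flags must be 0 or 1")
  sum(flags)
}

#' Attach risk flags and the risk score to a genotype table
#'
#' @param genotypes data frame with columns `individual_id` and one column
#'   per SNP (`rs1042778`, `rs2254298`, `rs53576`, `rs3796863`) holding
#'   two-letter genotypes, empty or `NA` for missing.
#' @return the table with added `risk_<snp>` 0/1 columns and `risk_score`.
#' @export
add_risk_coding <- function(genotypes) {
  snps <- names(.sv_snp_panel)
  if (!all(c("individual_id", snps) %in% names(genotypes)))
    stop_sv("genotype table must have columns individual_id, ",
            paste(snps, collapse = ", "))
  for (s in snps)
    genotypes[[paste0("risk_", s)]] <- code_risk_allele(s, genotypes[[s]])
  flag_mat <- as.matrix(genotypes[paste0("risk_", snps)])
  genotypes$risk_score <- apply(flag_mat, 1, function(f)
    if (anyNA(f)) NA_integer_ else as.integer(sum(f)))
  genotypes
}

#' Read the canonical genotype CSV
#'
#' Header `individual_id,rs1042778,rs2254298,rs53576,rs3796863`; genotypes
#' are two-letter strings, empty for missing. Risk coding is attached.
#'
#' @param path CSV file path.
#' @return genotype data frame with risk flags and `risk_score`.
#' @export
read_genotypes <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(individual_id = "character"))
  for (s in names(.sv_snp_panel)) if (s %in% names(g)) {
    g[[s]][g[[s]] %in% c("", "NA")] <- NA_character_
    g[[s]] <- normalize_genotype(g[[s]])
  }
  add_risk_coding(g)
}

#' @rdname read_genotypes
#' @param genotypes genotype data frame.
#' @export
write_genotypes <- function(genotypes, path) {
  write.csv(genotypes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract panel genotypes from a VCF
#'
#' Convenience reader: pulls the four panel SNPs out of a VCF (v4.x) by ID
#' field (or a configured `chrom:pos` map), decodes per-sample `GT` fields
#' against REF/ALT, and returns the canonical genotype table. Requires the
#' suggested package \pkg{vcfR}. CSV remains the canonical interchange.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param id_map optional named character vector mapping VCF sample names to
#'   `individual_id`s; unmapped samples keep their VCF name.
#' @param loci optional named character vector `c(rs1042778 = "chrom:pos",
#'   ...)` used when the VCF ID column does not carry rs identifiers.
#' @return genotype data frame (with risk coding attached).
#' @export
extract_from_vcf <- function(vcf_path, id_map = NULL, loci = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_sv("extract_from_vcf requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  ids <- samples
  if (!is.null(id_map)) {
    hit <- samples %in% names(id_map)
    ids[hit] <- unname(id_map[samples[hit]])
  }
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  key <- paste(fix$CHROM, fix$POS, sep = ":")
  for (s in names(.sv_snp_panel)) {
    row <- which(fix$ID == s)
    if (!length(row) && !is.null(loci) && s %in% names(loci))
      row <- which(key == loci[[s]])
    if (!length(row)) {
      warning("locus ", s, " not found in ", vcf_path, call. = FALSE)
      out[[s]] <- NA_character_
      next
    }
    row <- row[1]
    alleles <- c(fix$REF[row], strsplit(fix$ALT[row], ",")[[1]])
    out[[s]] <- vapply(gt[row, ], function(call) {
      if (is.na(call)) return(NA_character_)
      idx <- suppressWarnings(as.integer(strsplit(call, "[/|]")[[1]]))
      if (length(idx) != 2 || anyNA(idx)) return(NA_character_)
      paste(sort(alleles[idx + 1]), collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  add_risk_coding(out)
}
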