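#' NAFLD risk and ALT-level variant panel
#'
#' Sixteen variants tagging eight loci repeatedly associated with NAFLD risk
#' and/or serum ALT (LYPLAL1, GCKR, HSD17B13, TRIB1, PPP1R3B, ERLIN1,
#' TM6SF2, PNPLA3), with hg19 positions, effect alleles and European
#' effect-allele frequencies. `beta` is the default planted additive
#' log-odds effect on case status used by the synthetic generator: the log
#' of the replicated case/control odds ratio where one is established
#' (e.g. PNPLA3 rs738409, OR 1.31 per G allele), zero for the variants
#' reported only for continuous ALT level.
#'
#' Frequencies can be made ancestry-specific by adding `eaf_<ancestry>`
#' columns (e.g. `eaf_AA`); [sampleGenotypes()] looks those up first and
#' falls back to `eaf`.
#'
#' @return data.frame with columns gene, rsid, chrom, pos, effect_allele,
#'   eaf, beta.
#' @examples
#' head(nafldVariantPanel())
#' @export
nafldVariantPanel <- function() {
  df <- data.frame(
    gene = c("LYPLAL1", "LYPLAL1", "GCKR", "HSD17B13", "HSD17B13", "TRIB1",
             "PPP1R3B", "ERLIN1", "ERLIN1", "ERLIN1", "ERLIN1", "TM6SF2",
             "TM6SF2", "PNPLA3", "PNPLA3", "PNPLA3"),
    rsid = c("rs12137855", "rs3001032", "rs780094", "rs6834314",
             "rs72613567", "rs2954021", "rs4240624", "rs10883437",
             "rs11597390", "rs11597086", "rs11591741", "rs2228603",
             "rs58542926", "rs738409", "rs2281135", "rs2143571"),
    chrom = c("1", "1", "2", "4", "4", "8", "8", "10", "10", "10", "10",
              "19", "19", "22", "22", "22"),
    pos = c(219448378L, 219727779L, 27741237L, 88213808L, 88231392L,
            126482077L, 9184231L, 101795361L, 101861435L, 101953705L,
            101976501L, 19329924L, 19379549L, 44324727L, 44332570L,
            44391686L),
    effect_allele = c("C", "T", "T", "A", "T", "A", "G", "T", "G", "A",
                      "G", "T", "T", "G", "A", "A"),
    eaf = c(0.80, 0.69, 0.40, 0.72, 0.73, 0.50, 0.09, 0.61, 0.64, 0.58,
            0.58, 0.08, 0.07, 0.23, 0.17, 0.18),
    or_case = c(1.00, 1.04, 1.02, NA, 1.09, NA, 1.12, NA, NA, NA, NA,
                1.19, 1.23, 1.31, NA, NA),
    stringsAsFactors = FALSE
  )
  df$beta <- ifelse(is.na(df$or_case), 0, log(df$or_case))
  df$or_case <- NULL
  df
}

#' Read a variant annotation table
#'
#' Accepts a delimited table with header columns
#' `rsid, chrom, pos, effect_allele, eaf, beta` (extra columns kept).
#'
#' @param path file path of a comma- or tab-delimited table.
#' @return data.frame of variant annotations.
#' @export
readVariantPanel <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("rsid", "chrom", "pos", "effect_allele", "eaf", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  .checkVariantPanel(df)
  df
}

.checkVariantPanel <- function(variants) {
  if (anyDuplicated(variants$rsid)) stop("duplicate rsid in variant panel")
  eafCols <- grep("^eaf", names(variants), value = TRUE)
  for (cc in eafCols) {
    v <- variants[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("effect-allele frequencies must lie in [0, 1] (column ", cc, ")")
  }
  if (!all(is.finite(variants$beta)))
    stop("planted beta must be finite for every variant")
  invisible(TRUE)
}
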