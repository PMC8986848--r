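# VCF v4.2 emission for variant calls. Coordinates become 1-based here;
# indels are left-anchored on the reference base preceding the event.

#' Write calls as VCF v4.2
#'
#' @param result a `variant_calls` object
#' @param path output VCF path
#' @param reference reference accepted by [as_reference()] (supplies contig
#'   headers and indel anchor bases)
#' @return `path`, invisibly
#' @export
write_calls_vcf <- function(result, path, reference) {
  reference <- as_reference(reference)
  calls <- result$calls
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=plasmacall-", pkg_version()),
    paste0("##contig=<ID=", names(reference), ",length=",
           nchar(reference), ">"),
    "##INFO=<ID=ALT_F,Number=1,Type=Integer,Description=\"Forward-strand alternative SSCS count\">",
    "##INFO=<ID=ALT_R,Number=1,Type=Integer,Description=\"Reverse-strand alternative SSCS count\">",
    "##INFO=<ID=COV,Number=1,Type=Integer,Description=\"Total SSCS coverage\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=P_RAW,Number=1,Type=Float,Description=\"Raw binomial tail p-value\">",
    "##INFO=<ID=P_ADJ,Number=1,Type=Float,Description=\"Bonferroni-adjusted p-value\">",
    "##FILTER=<ID=single_strand,Description=\"Alternative allele supported on one strand only\">",
    "##FILTER=<ID=strand_bias,Description=\"Exact strand-bias test below floor\">",
    "##FILTER=<ID=low_coverage,Description=\"SSCS coverage below minimum\">",
    "##FILTER=<ID=indel_too_short,Description=\"Indel shorter than the minimum tested length\">",
    "##FILTER=<ID=snp_masked,Description=\"Known-SNP position excluded from testing\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- character(0)
  if (nrow(calls) > 0L) {
    rows <- purrr::pmap_chr(calls, function(chrom, pos, ref, alt, type,
                                            length, seq, alt_f, alt_r,
                                            coverage, vaf, p_raw, p_adj,
                                            p_bias, filter) {
      if (type == "snv") {
        vpos <- pos + 1L; vref <- ref; valt <- alt
      } else if (type == "del") {
        # pos is the first deleted base; anchor on the base before it
        vpos <- pos
        vref <- ref_slice(reference, chrom, pos - 1L, pos + length)
        valt <- substr(vref, 1L, 1L)
      } else {
        # insertion anchored at pos (base preceding the inserted sequence)
        vpos <- pos + 1L
        vref <- ref_slice(reference, chrom, pos, pos + 1L)
        valt <- paste0(vref, seq)
      }
      info <- sprintf("ALT_F=%d;ALT_R=%d;COV=%d;VAF=%.6g;P_RAW=%.6g;P_ADJ=%.6g",
                      alt_f, alt_r, coverage, vaf,
                      ifelse(is.na(p_raw), -1, p_raw),
                      ifelse(is.na(p_adj), -1, p_adj))
      paste(chrom, vpos, ".", vref, valt, ".", filter, info, sep = "\t")
    })
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write calls as TSV (1-based positions)
#' @param result a `variant_calls` object
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_calls_tsv <- function(result, path) {
  out <- mutate(result$calls, pos = .data$pos + 1L)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write run metadata for a calling run
#'
#' Records the Bonferroni universe, alpha, profile checksum and tool
#' version — enough to reproduce the run bit-exactly together with the
#' inputs.
#'
#' @param result a `variant_calls` object
#' @param path output JSON path
#' @param profile the `error_profile` used (optional, for its checksum)
#' @param extra named list merged into the metadata
#' @return `path`, invisibly
#' @export
write_call_metadata <- function(result, path, profile = NULL, extra = list()) {
  meta <- c(list(
    tool_version = pkg_version(),
    m = result$m,
    alpha = result$alpha,
    n_tested_positions = result$n_tested_positions,
    n_pass = sum(result$calls$filter == "PASS"),
    profile_checksum = if (!is.null(profile))
      rlang::hash(paste(profile$chrom, profile$pos, profile$alt, profile$k,
                        profile$n))
  ), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
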