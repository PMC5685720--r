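#' Annotate the coding effect of a variant
#'
#' Classifies a normalized variant against a transcript model:
#' substitutions are translated through the standard genetic code on the
#' strand-corrected coding sequence; indels overlapping an exon are
#' frameshift when the length difference is not a multiple of 3, in-frame
#' otherwise; variants touching no exon are noncoding. "Amino-acid
#' changing" (the filter's AACHANGE rule) is any effect except
#' \code{synonymous} and \code{noncoding}.
#'
#' @param key one-row data.frame (chrom, pos, ref, alt), normalized
#' @param model \code{jak_transcript_model}
#' @param reference \code{jak_reference} covering the variant
#' @return list: effect (one of missense, nonsense, synonymous,
#'   frameshift, inframe_indel, noncoding), exon label, residue number,
#'   aa_ref, aa_alt (NA for indels/noncoding)
#' @export
annotate_effect <- function(key, model, reference) {
  stopifnot(nrow(key) == 1L)
  chrom <- key$chrom; pos <- key$pos; ref <- key$ref; alt <- key$alt
  na_out <- function(effect, exon = NA_character_, residue = NA_integer_,
                     aa_ref = NA_character_, aa_alt = NA_character_)
    list(effect = effect, exon = exon, residue = residue,
         aa_ref = aa_ref, aa_alt = aa_alt)
  if (chrom != model$chrom) return(na_out("noncoding"))
  seen <- ref_base(reference, chrom, pos, nchar(ref))
  if (seen != ref)
    stop(sprintf("annotation error: REF mismatch at %s:%d", chrom, pos), call. = FALSE)
  ex <- model$exons
  span_end <- pos + nchar(ref) - 1L
  ov <- which(ex$start <= span_end & ex$end >= pos)
  if (length(ov) == 0L) return(na_out("noncoding"))
  e <- ex[ov[1], ]
  if (is_indel(ref, alt)) {
    shift <- abs(nchar(ref) - nchar(alt))
    eff <- if (shift %% 3L == 0L) "inframe_indel" else "frameshift"
    return(na_out(eff, exon = e$label))
  }
  # equal-length substitution: translate the affected codons
  if (pos < e$start || span_end > e$end) return(na_out("noncoding"))
  exon_seq <- ref_base(reference, chrom, e$start, e$end - e$start + 1L)
  off0 <- pos - e$start                      # 0-based offset into exon (+ strand)
  mut_seq <- exon_seq
  substr(mut_seq, off0 + 1L, off0 + nchar(alt)) <- alt
  if (model$strand == "-") {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    exon_cds <- rc(exon_seq); mut_cds <- rc(mut_seq)
    off0 <- (e$end - e$start + 1L) - (off0 + nchar(ref))
  } else {
    exon_cds <- exon_seq; mut_cds <- mut_seq
  }
  c0 <- off0 %/% 3L
  c1 <- (off0 + nchar(ref) - 1L) %/% 3L
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, c0 * 3L + 1L, (c1 + 1L) * 3L)),
    no.init.codon = TRUE))
  aa_ref <- tr(exon_cds); aa_alt <- tr(mut_cds)
  changed <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
  residue <- e$first_residue + c0 + (if (length(changed)) changed[1] - 1L else 0L)
  if (aa_ref == aa_alt)
    return(na_out("synonymous", e$label, residue,
                  substr(aa_ref, 1L, 1L), substr(aa_alt, 1L, 1L)))
  i <- changed[1]
  eff <- if (substr(aa_alt, i, i) == "*") "nonsense" else "missense"
  na_out(eff, e$label, residue, substr(aa_ref, i, i), substr(aa_alt, i, i))
}

#' Is an effect amino-acid changing?
#' @param effect character vector of effect labels
#' @return logical
#' @export
aa_changing <- function(effect) {
  effect %in% c("missense", "nonsense", "frameshift", "inframe_indel")
}

#' Read the COSMIC-like variant whitelist
#'
#' @param path TSV with columns chrom, pos, ref, alt, cosmic_id
#' @param reference optional \code{jak_reference}; when given, keys are
#'   normalized on read so lookups match any representation.
#' @return data.frame keyed by normalized variant
#' @export
read_cosmic_table <- function(path = jak_extdata("cosmic_synthetic.tsv"),
                              reference = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  k <- variant_key(df$chrom, df$pos, df$ref, df$alt, reference)
  df$chrom <- k$chrom; df$pos <- k$pos; df$ref <- k$ref; df$alt <- k$alt
  if (anyDuplicated(key_id(df))) stop("duplicate key in COSMIC table", call. = FALSE)
  df
}

#' Read the population allele-frequency table
#' @inheritParams read_cosmic_table
#' @return data.frame with af_1000g_all, af_1000g_eur, af_esp_eur per key
#' @export
read_popfreq_table <- function(path = jak_extdata("popfreq_synthetic.tsv"),
                               reference = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  k <- variant_key(df$chrom, df$pos, df$ref, df$alt, reference)
  df$chrom <- k$chrom; df$pos <- k$pos; df$ref <- k$ref; df$alt <- k$alt
  af <- c("af_1000g_all", "af_1000g_eur", "af_esp_eur")
  stopifnot(all(af %in% names(df)))
  if (any(df[af] < 0 | df[af] > 1)) stop("allele frequencies must be in [0,1]", call. = FALSE)
  df
}

#' COSMIC membership of variant keys
#' @param key data.frame of normalized keys
#' @param cosmic table from \code{\link{read_cosmic_table}}
#' @return logical vector
#' @export
lookup_cosmic <- function(key, cosmic) {
  key_id(key) %in% key_id(cosmic)
}

#' Population allele frequencies of variant keys
#'
#' Absent keys get frequency 0 in all three databases (absence is a
#' value, not an error).
#' @param key data.frame of normalized keys
#' @param freqs table from \code{\link{read_popfreq_table}}
#' @return data.frame af_1000g_all, af_1000g_eur, af_esp_eur (one row per key)
#' @export
lookup_population_frequency <- function(key, freqs) {
  i <- match(key_id(key), key_id(freqs))
  out <- data.frame(af_1000g_all = numeric(nrow(key)),
                    af_1000g_eur = numeric(nrow(key)),
                    af_esp_eur = numeric(nrow(key)))
  hit <- !is.na(i)
  out[hit, ] <- freqs[i[hit], c("af_1000g_all", "af_1000g_eur", "af_esp_eur")]
  out
}
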