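#' Construct a normalized variant key
#'
#' A variant key is the canonical identity of a variant: chromosome
#' ("chr" prefix stripped), 1-based position, and uppercase REF/ALT
#' alleles in minimal left-aligned representation. All merging,
#' annotation and filtering joins on this key, so two callers reporting
#' the same indel in different representations compare equal.
#'
#' @param chrom chromosome name
#' @param pos 1-based position
#' @param ref,alt allele strings (uppercase DNA)
#' @param reference \code{jak_reference}; required for normalization
#'   (left alignment needs sequence context). If NULL the key is built
#'   without shifting (trim-only normalization).
#' @return data.frame with columns chrom, pos, ref, alt (one row per input)
#' @export
variant_key <- function(chrom, pos, ref, alt, reference = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(strip_chr(as.character(chrom)), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- normalize_variant(chrom[i], pos[i], ref[i], alt[i], reference)
    out$pos[i] <- v$pos; out$ref[i] <- v$ref; out$alt[i] <- v$alt
  }
  out
}

#' Normalize one variant to minimal left-aligned form
#'
#' Implements the standard normalization: (1) drop the shared suffix,
#' re-anchoring indels by prepending the reference base to the left when
#' an allele would become empty (this is what shifts indels left through
#' repeats); (2) drop the shared prefix down to the mandatory single
#' anchor base. Idempotent; SNVs pass through unchanged.
#'
#' @param chrom,pos,ref,alt one variant
#' @param reference \code{jak_reference} or NULL (no left shift possible)
#' @return list(chrom, pos, ref, alt)
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference = NULL) {
  chrom <- strip_chr(chrom)
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stop("empty allele", call. = FALSE)
  if (ref == alt) stop("ref == alt is not a variant", call. = FALSE)
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt))
    stop("alleles must be DNA strings", call. = FALSE)
  if (!is.null(reference)) {
    seen <- ref_base(reference, chrom, pos, nchar(ref))
    if (seen != ref)
      stop(sprintf("integrity error: REF '%s' at %s:%d does not match reference '%s'",
                   ref, chrom, pos, seen), call. = FALSE)
  }
  repeat {
    changed <- FALSE
    # shared last base -> trim; restore anchor from reference if emptied
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)) &&
           !(nchar(ref) == 1L && nchar(alt) == 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (is.null(reference) || pos <= 1L) {
          # cannot shift further; re-anchor with the base we just removed?
          # without sequence context we re-extend using the trimmed base
          stop("cannot left-align indel without reference context", call. = FALSE)
        }
        pos <- pos - 1L
        b <- ref_base(reference, chrom, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    }
    if (!changed) break
  }
  # trim shared prefix, keeping >= 1 base in each allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

key_id <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

is_indel <- function(ref, alt) nchar(ref) != nchar(alt)
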