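#' Path to a packaged fixture file
#'
#' @param file file name under the package's \code{extdata} directory;
#'   empty to list the directory.
#' @return absolute path
#' @export
jak_extdata <- function(file = "") {
  system.file("extdata", file, package = "jakscreen", mustWork = nzchar(file))
}

#' Load a reference sequence from FASTA
#'
#' Reads a (small) FASTA file into a named list of character strings, one
#' per contig. Contig names keep only the first word of the header; a
#' leading "chr" prefix is stripped so caller dialects agree.
#'
#' @param path FASTA file; defaults to the packaged synthetic JAK2-like
#'   fragment.
#' @return object of class \code{jak_reference}: named list of uppercase
#'   sequence strings.
#' @export
read_reference <- function(path = jak_extdata("reference_synthetic.fa")) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- strip_chr(vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L))
  ref <- as.list(toupper(as.character(ss)))
  class(ref) <- "jak_reference"
  ref
}

strip_chr <- function(x) sub("^chr", "", x)

ref_base <- function(reference, chrom, pos, len = 1L) {
  chrom <- strip_chr(chrom)
  s <- reference[[chrom]]
  if (is.null(s)) stop(sprintf("contig '%s' not in reference", chrom), call. = FALSE)
  if (pos < 1L || pos + len - 1L > nchar(s))
    stop(sprintf("position %d(+%d) outside contig '%s'", pos, len, chrom), call. = FALSE)
  substr(s, pos, pos + len - 1L)
}

#' Load a transcript model
#'
#' The model is a small JSON file: gene, chrom, strand and an exon table
#' with 1-based inclusive coordinates, a label and the residue number of
#' each exon's first codon. Exon lengths must be multiples of 3 (each
#' packaged amplicon exon starts in frame 0).
#'
#' @param path JSON file; defaults to the packaged synthetic model.
#' @return object of class \code{jak_transcript_model}
#' @export
read_transcript_model <- function(path = jak_extdata("transcript_model_synthetic.json")) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$chrom <- strip_chr(m$chrom)
  ex <- m$exons
  stopifnot(all(c("label", "start", "end", "first_residue") %in% names(ex)))
  if (any((ex$end - ex$start + 1L) %% 3L != 0L))
    stop("transcript model exon lengths must be multiples of 3", call. = FALSE)
  if (!m$strand %in% c("+", "-"))
    stop("transcript model strand must be '+' or '-'", call. = FALSE)
  ex$label <- as.character(ex$label)
  m$exons <- ex[order(ex$start), ]
  class(m) <- "jak_transcript_model"
  m
}

#' Reverse-complement a reference and transcript model
#'
#' Utility for strand-symmetry checks: maps the fixture onto the opposite
#' strand (coordinates flipped end-for-end) so annotation results can be
#' compared between representations.
#' @param reference \code{jak_reference}
#' @param model \code{jak_transcript_model} on the same contig
#' @return list with elements \code{reference}, \code{model}, and
#'   \code{map_pos}, a function mapping old 1-based positions to new ones.
#' @export
revcomp_fixture <- function(reference, model) {
  chrom <- model$chrom
  s <- reference[[chrom]]
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ref2 <- reference
  ref2[[chrom]] <- rc
  ex <- model$exons
  ex2 <- ex
  ex2$start <- L - ex$end + 1L
  ex2$end <- L - ex$start + 1L
  model2 <- model
  model2$strand <- if (model$strand == "+") "-" else "+"
  model2$exons <- ex2[order(ex2$start), ]
  list(reference = ref2, model = model2,
       map_pos = function(pos) L - pos + 1L)
}
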