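# validation helpers ------------------------------------------------------

is_valid_cds <- function(nt) {
  nchar(nt) >= 9 && !grepl("[^ACGT]", nt)
}

is_valid_protein <- function(aa) {
  nchar(aa) >= 1 && !grepl(paste0("[^", paste(AA_ORDER, collapse = ""), "*]"),
                           aa)
}

#' Read coding sequences from FASTA
#'
#' Records are normalized (upper case, `U` to `T`) and validated: any
#' record containing a non-canonical nucleotide, or shorter than 9 nt, is
#' skipped with a warning listing its id — sequences with non-canonical
#' characters are not analyzed.
#'
#' @param path Multi-FASTA file of nucleotide sequences.
#' @return Named character vector of validated coding sequences.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_nt(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  ok <- vapply(seqs, is_valid_cds, logical(1))
  if (any(!ok)) {
    warning("skipped ", sum(!ok), " invalid CDS record(s): ",
            paste(names(seqs)[!ok], collapse = ", "))
  }
  seqs[ok]
}

#' Read protein sequences from FASTA
#'
#' Records containing characters outside the 20 canonical amino acids plus
#' the `"*"` stop sentinel are skipped with a warning.
#'
#' @param path Multi-FASTA file of amino-acid sequences.
#' @return Named character vector.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  ok <- vapply(seqs, is_valid_protein, logical(1))
  if (any(!ok)) {
    warning("skipped ", sum(!ok), " invalid protein record(s): ",
            paste(names(seqs)[!ok], collapse = ", "))
  }
  seqs[ok]
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Translate a frameshifted variant of a coding sequence
#'
#' The +1 variant removes the first four bases of the wild-type coding
#' sequence, the -1 variant removes the first two; translation then
#' proceeds in the new frame with read-through of internal stop codons,
#' which are rendered as the `"*"` sentinel (they are masked later by the
#' profile machinery). A trailing incomplete codon and a terminal stop are
#' dropped.
#'
#' @param cds Nucleotide string (a validated coding sequence).
#' @param frame `"+1"` or `"-1"`.
#' @param code A `genetic_code`.
#' @return Amino-acid string possibly containing `"*"`.
#' @examples
#' frameshift_translate("ATGGCTTCTGGGTAA", "+1")  # "LLG"
#' frameshift_translate("ATGGCTTCTGGGTAA", "-1")  # "GFWV"
#' @export
frameshift_translate <- function(cds, frame = c("+1", "-1"),
                                 code = standard_code()) {
  frame <- match.arg(frame)
  drop_n <- if (frame == "+1") 4L else 2L
  nt <- normalize_nt(cds)
  if (nchar(nt) <= drop_n) stop("coding sequence too short to frameshift")
  aa <- translate(substr(nt, drop_n + 1L, nchar(nt)), code = code,
                  read_through_stops = TRUE)
  aa <- sub("\\*$", "", aa)
  if (nchar(aa) < 1) stop("frameshifted peptide is empty")
  aa
}

#' Wild-type protein from a coding sequence
#'
#' Translates in frame 0 and truncates at the first stop codon; the result
#' contains no stop sentinel.
#'
#' @param cds Nucleotide string.
#' @param code A `genetic_code`.
#' @export
wildtype_translate <- function(cds, code = standard_code()) {
  translate(cds, code = code, read_through_stops = FALSE)
}

#' Positional sequence identity
#'
#' Fraction of identical residues over the overlap, aligning position `i`
#' of `b` with position `i + offset` of `a` (no gaps). The stop sentinel
#' never matches. This is the alignment-free identity under which
#' frameshifted variants typically share only a few percent of residues
#' with the wild type.
#'
#' @param a,b Amino-acid strings.
#' @param offset Integer offset (default 0); for wild-type versus shifted
#'   comparisons the package convention is `offset = 1` (shifted residue
#'   `i` against wild-type residue `i + 1`, see [frameshift_offset()]).
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b, offset = 0L) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ia <- seq_along(bv) + offset
  keep <- ia >= 1 & ia <= length(av)
  if (!any(keep)) stop("empty overlap at offset ", offset)
  ai <- av[ia[keep]]
  bi <- bv[keep]
  mean(ai == bi & ai != "*")
}

#' Alignment offset between wild-type and frameshifted sequences
#'
#' Both frameshift variants drop the bases spanning the first wild-type
#' codon, so shifted residue `i` is compared with wild-type residue
#' `i + 1`: this registration maximizes per-position nucleotide overlap.
#' It is the package-wide default for profile and identity comparisons and
#' can be overridden wherever an `offset` argument is exposed.
#'
#' @return The integer 1.
#' @export
frameshift_offset <- function() 1L
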