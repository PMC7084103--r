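# canonical amino-acid order used everywhere in the package
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

ALL_CODONS <- sort(as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                   DNA_BASES, paste0)))

#' Construct a genetic code
#'
#' A genetic code maps each of the 64 DNA trinucleotides to one of the 20
#' canonical amino acids or to `"*"` (stop). Codons are stored in
#' lexicographic order.
#'
#' @param codon_to_aa Named character vector of length 64; names are codons
#'   over `ACGT`, values are one-letter amino acids or `"*"`.
#' @param name Label for the code (provenance).
#' @return An object of class `genetic_code`.
#' @export
genetic_code <- function(codon_to_aa, name = "custom") {
  if (length(codon_to_aa) != 64 || is.null(names(codon_to_aa))) {
    stop("codon_to_aa must be a named vector covering all 64 codons")
  }
  codon_to_aa <- codon_to_aa[order(names(codon_to_aa))]
  if (!identical(names(codon_to_aa), ALL_CODONS)) {
    stop("codon_to_aa must cover exactly the 64 codons over ACGT")
  }
  bad <- setdiff(unique(codon_to_aa), c(AA_ORDER, "*"))
  if (length(bad) > 0) {
    stop("unknown amino-acid symbols in code: ", paste(bad, collapse = ", "))
  }
  structure(list(codon_to_aa = codon_to_aa, name = name),
            class = "genetic_code")
}

#' The universal (standard) genetic code
#'
#' NCBI translation table 1, with 61 sense codons and the three stop codons
#' TAA, TAG, TGA.
#'
#' @return A `genetic_code` object.
#' @examples
#' code <- standard_code()
#' code$codon_to_aa[["ATG"]]  # "M"
#' @export
standard_code <- function() {
  genetic_code(Biostrings::GENETIC_CODE, name = "standard")
}

#' @export
print.genetic_code <- function(x, ...) {
  n_stop <- sum(x$codon_to_aa == "*")
  cat(sprintf("<genetic_code '%s'>: 64 codons, %d stop, %d sense\n",
              x$name, n_stop, 64L - n_stop))
  invisible(x)
}

stop_codons <- function(code) {
  names(code$codon_to_aa)[code$codon_to_aa == "*"]
}

normalize_nt <- function(nt) {
  nt <- toupper(nt)
  chartr("U", "T", nt)
}

#' Translate a coding sequence
#'
#' Translates a nucleotide sequence codon by codon. RNA input (`U`) is
#' normalized to DNA; a trailing incomplete codon is dropped. Sequences
#' containing non-canonical nucleotides are rejected, mirroring the rule
#' that such records are not analyzed.
#'
#' @param cds Nucleotide string over `ACGTU` (case-insensitive).
#' @param code A `genetic_code`; defaults to the standard code.
#' @param read_through_stops If `TRUE`, internal stops are rendered as the
#'   sentinel `"*"` and translation continues; if `FALSE` (default) the
#'   translation stops before the first stop codon.
#' @return Amino-acid string, possibly containing `"*"` when reading through.
#' @examples
#' translate("ATGGCTTCTGGGTAA", read_through_stops = TRUE)  # "MASG*"
#' @export
translate <- function(cds, code = standard_code(), read_through_stops = FALSE) {
  nt <- normalize_nt(cds)
  if (nchar(nt) == 0) return("")
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), DNA_BASES)
  if (length(bad) > 0) {
    stop("non-canonical nucleotide(s) in sequence: ",
         paste(bad, collapse = ", "))
  }
  n_codon <- length(chars) %/% 3L
  if (n_codon == 0) return("")
  codons <- paste0(chars[seq(1, 3 * n_codon, by = 3)],
                   chars[seq(2, 3 * n_codon, by = 3)],
                   chars[seq(3, 3 * n_codon, by = 3)])
  aa <- unname(code$codon_to_aa[codons])
  if (!read_through_stops) {
    first_stop <- which(aa == "*")
    if (length(first_stop) > 0) aa <- aa[seq_len(first_stop[1] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Enumerate frameshift amino-acid pairs of a genetic code
#'
#' Every codon plus one flanking base defines a context: for a +1 shift the
#' shifted codon reads the last two bases of the original codon plus the
#' downstream base; for a -1 shift it reads the upstream base plus the first
#' two bases. Contexts in which either codon is a stop are excluded. For the
#' standard code this leaves 232 of the 256 contexts in either direction.
#'
#' @param code A `genetic_code`.
#' @param direction `"+1"` or `"-1"`.
#' @param flank_weights Optional numeric vector of length 4 (names `A,C,G,T`)
#'   weighting the flanking-base distribution; default is uniform with each
#'   context counted once.
#' @return A `frameshift_pairs` object: a data frame with columns
#'   `original`, `shifted`, `codon`, `flank`, `weight`, and attributes
#'   `direction` and `code_name`. Row order is deterministic
#'   (codon lexicographic x flanking base lexicographic).
#' @examples
#' nrow(enumerate_frameshift_pairs(standard_code(), "+1"))  # 232
#' @export
enumerate_frameshift_pairs <- function(code, direction = c("+1", "-1"),
                                       flank_weights = NULL) {
  direction <- match.arg(direction)
  if (is.null(flank_weights)) {
    flank_weights <- stats::setNames(rep(1, 4), DNA_BASES)
  }
  if (!identical(sort(names(flank_weights)), DNA_BASES)) {
    stop("flank_weights must be named A, C, G, T")
  }
  codon <- rep(ALL_CODONS, each = 4L)
  flank <- rep(DNA_BASES, times = 64L)
  shifted_codon <- if (direction == "+1") {
    paste0(substr(codon, 2, 3), flank)
  } else {
    paste0(flank, substr(codon, 1, 2))
  }
  orig_aa <- unname(code$codon_to_aa[codon])
  shift_aa <- unname(code$codon_to_aa[shifted_codon])
  keep <- orig_aa != "*" & shift_aa != "*"
  out <- data.frame(original = orig_aa[keep],
                    shifted = shift_aa[keep],
                    codon = codon[keep],
                    flank = flank[keep],
                    weight = unname(flank_weights[flank[keep]]),
                    stringsAsFactors = FALSE)
  structure(out,
            direction = direction,
            code_name = code$name,
            class = c("frameshift_pairs", "data.frame"))
}

#' Randomize a genetic code
#'
#' Generates control codes used to test whether frameshift stability is tied
#' to the architecture of the standard code. Two modes:
#' \describe{
#'   \item{`block_preserving`}{synonymous-codon blocks are kept intact and
#'     the 20 amino acids are permuted uniformly at random across the 20
#'     sense blocks; stop codons are fixed.}
#'   \item{`unconstrained`}{the 61 sense codons are reassigned to amino
#'     acids uniformly at random, subject to every amino acid keeping at
#'     least one codon; stop codons are fixed. This is one reasonable
#'     reading of "abolishing the block structure", not a reproduction of a
#'     specific published scheme.}
#' }
#'
#' @param code A `genetic_code` in which all 20 amino acids are encoded.
#' @param mode `"block_preserving"` or `"unconstrained"`.
#' @param seed Optional integer; when supplied the draw is reproducible.
#' @return A new `genetic_code`.
#' @export
randomize_code <- function(code, mode = c("block_preserving", "unconstrained"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  map <- code$codon_to_aa
  sense <- names(map)[map != "*"]
  if (mode == "block_preserving") {
    perm <- sample(AA_ORDER)
    names(perm) <- AA_ORDER
    map[sense] <- perm[map[sense]]
  } else {
    aa <- character(length(sense))
    anchors <- sample(seq_along(sense), 20L)
    aa[anchors] <- sample(AA_ORDER)
    rest <- setdiff(seq_along(sense), anchors)
    aa[rest] <- sample(AA_ORDER, length(rest), replace = TRUE)
    map[sense] <- aa
  }
  genetic_code(map, name = paste0(code$name, "_", mode))
}

#' Write / read a genetic code as two-column TSV
#'
#' @param code A `genetic_code`.
#' @param path File path.
#' @return `read_genetic_code` returns a `genetic_code`.
#' @export
write_genetic_code <- function(code, path) {
  utils::write.table(data.frame(codon = names(code$codon_to_aa),
                                aa = unname(code$codon_to_aa)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_code
#' @param name Label for the code read from `path`.
#' @export
read_genetic_code <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  genetic_code(stats::setNames(tab$aa, tab$codon), name = name)
}
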