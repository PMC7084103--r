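SCALE_CATEGORIES <- c("alpha", "beta", "hydro", "nuc", "other")

#' Construct an amino-acid property scale
#'
#' A scale assigns one real value to each of the 20 canonical amino acids.
#' Scales carry a name and a category label; categories follow the usual
#' grouping of property scales (`alpha`: alpha/turn propensity, `beta`:
#' beta propensity, `hydro`: hydrophobicity, `nuc`: nucleobase affinity,
#' `other`).
#'
#' @param values Numeric vector of length 20. If named, names must be the
#'   20 canonical one-letter amino acids; if unnamed, the order
#'   `ACDEFGHIKLMNPQRSTVWY` is assumed.
#' @param name Scale identifier.
#' @param category Category label; free-form labels are accepted (synthetic
#'   libraries use their own), the conventional ones being
#'   `r paste(SCALE_CATEGORIES, collapse = ", ")`.
#' @return An `aa_scale` object: a named numeric vector with `name` and
#'   `category` attributes.
#' @export
aa_scale <- function(values, name = "scale", category = "other") {
  nm <- names(values)
  values <- as.numeric(values)
  names(values) <- nm
  if (length(values) != 20) stop("a scale needs exactly 20 values")
  if (!all(is.finite(values))) stop("scale '", name, "' has non-finite values")
  if (is.null(nm)) {
    names(values) <- AA_ORDER
  } else {
    if (!setequal(nm, AA_ORDER)) {
      stop("scale names must be the 20 canonical amino acids")
    }
    values <- values[AA_ORDER]
  }
  structure(values, name = name, category = category, class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat(sprintf("<aa_scale '%s'> category: %s\n", scale_name(x),
              scale_category(x)))
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' @rdname aa_scale
#' @param s An `aa_scale`.
#' @export
scale_name <- function(s) attr(s, "name")

#' @rdname aa_scale
#' @export
scale_category <- function(s) attr(s, "category")

#' @rdname aa_scale
#' @export
scale_values <- function(s) stats::setNames(as.numeric(s), names(unclass(s)))

#' Is a scale degenerate (zero variance)?
#'
#' Degenerate scales carry no ranking information and are excluded from
#' correlation statistics.
#'
#' @param s An `aa_scale`.
#' @export
is_degenerate <- function(s) {
  isTRUE(stats::sd(as.numeric(s)) == 0)
}

#' Normalize a scale to zero mean and unit Euclidean norm
#'
#' Pearson correlations are invariant to this transformation; it is applied
#' so that scales are comparable when projected into the principal-component
#' space of optimally frameshift-stable scales.
#'
#' @param s An `aa_scale`.
#' @return A normalized `aa_scale`.
#' @export
normalize_scale <- function(s) {
  v <- as.numeric(s)
  if (stats::sd(v) == 0) stop("cannot normalize a zero-variance scale")
  v <- v - mean(v)
  v <- v / sqrt(sum(v^2))
  aa_scale(stats::setNames(v, names(unclass(s))),
           name = scale_name(s), category = scale_category(s))
}

#' Invert a scale
#'
#' Negates all values (e.g. hydrophobicity becomes hydrophilicity). The
#' category label is preserved; frameshift-stability correlations are
#' unchanged under inversion.
#'
#' @param s An `aa_scale`.
#' @export
invert_scale <- function(s) {
  aa_scale(stats::setNames(-as.numeric(s), names(unclass(s))),
           name = paste0(scale_name(s), "_inv"),
           category = scale_category(s))
}

#' Integer side-chain charge scale
#'
#' Asp and Glu carry -1, Lys and Arg +1, all other residues 0. Histidine is
#' assigned 0 by convention (configurable by building a custom scale).
#'
#' @return An `aa_scale` named `"charge"`.
#' @export
builtin_charge_scale <- function() {
  v <- stats::setNames(rep(0, 20), AA_ORDER)
  v[c("D", "E")] <- -1
  v[c("K", "R")] <- 1
  aa_scale(v, name = "charge", category = "other")
}

#' Construct a scale library
#'
#' @param scales List of `aa_scale` objects with unique names.
#' @param provenance Free-text source description.
#' @return A `scale_library`: a named list of scales.
#' @export
scale_library <- function(scales, provenance = "") {
  nms <- vapply(scales, scale_name, character(1))
  if (anyDuplicated(nms)) stop("scale names must be unique")
  names(scales) <- nms
  structure(scales, provenance = provenance, class = "scale_library")
}

#' @export
print.scale_library <- function(x, ...) {
  cats <- table(vapply(x, scale_category, character(1)))
  cat(sprintf("<scale_library> %d scales (%s)\n", length(x),
              paste(names(cats), cats, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
`[.scale_library` <- function(x, i) {
  scale_library(unclass(x)[i], provenance = attr(x, "provenance"))
}

# 20-column matrix (scales x amino acids) from a library
library_matrix <- function(lib) {
  m <- do.call(rbind, lapply(lib, as.numeric))
  dimnames(m) <- list(vapply(lib, scale_name, character(1)), AA_ORDER)
  m
}

library_categories <- function(lib) {
  vapply(lib, scale_category, character(1))
}

# ---- AAindex1 flat-file format ------------------------------------------

# order of amino acids on the two I-record value rows
AAINDEX_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
AAINDEX_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read amino-acid scales from an AAindex1 flat file
#'
#' Parses the classic AAindex1 format: each entry starts with an `H`
#' accession record, has a free-text `D` description, and an `I` record
#' followed by two rows of ten values (A R N D C Q E G H I / L K M F P S T
#' W Y V), terminated by `//`. Entries containing `NA` values are skipped
#' with a warning.
#'
#' @param path Path to an AAindex1 flat file.
#' @param categories Optional named character vector mapping accession to
#'   category; unmapped entries get `"other"`.
#' @return A `scale_library`.
#' @export
read_aaindex <- function(path, categories = NULL) {
  lines <- readLines(path, warn = FALSE)
  scales <- list()
  skipped <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "H ")) { i <- i + 1L; next }
    acc <- trimws(sub("^H ", "", lines[i]))
    # find the I record of this entry
    j <- i + 1L
    while (j <= length(lines) && !startsWith(lines[j], "I ") &&
           !startsWith(lines[j], "//")) {
      j <- j + 1L
    }
    if (j > length(lines) || startsWith(lines[j], "//")) {
      stop("malformed AAindex entry (no I record): ", acc)
    }
    if (j + 2L > length(lines)) {
      stop("malformed AAindex entry (truncated values): ", acc)
    }
    row1 <- strsplit(trimws(lines[j + 1L]), "\\s+")[[1]]
    row2 <- strsplit(trimws(lines[j + 2L]), "\\s+")[[1]]
    if (length(row1) != 10 || length(row2) != 10) {
      stop("malformed AAindex entry (expected 2 x 10 values): ", acc)
    }
    tokens <- c(row1, row2)
    if (any(toupper(tokens) == "NA")) {
      skipped <- c(skipped, acc)
    } else {
      vals <- suppressWarnings(as.numeric(tokens))
      if (any(is.na(vals))) {
        stop("malformed AAindex entry (non-numeric value): ", acc)
      }
      names(vals) <- c(AAINDEX_ROW1, AAINDEX_ROW2)
      cat_label <- "other"
      if (!is.null(categories) && acc %in% names(categories)) {
        cat_label <- unname(categories[acc])
      }
      scales[[acc]] <- aa_scale(vals, name = acc, category = cat_label)
    }
    # advance past the // terminator
    k <- j + 3L
    while (k <= length(lines) && !startsWith(lines[k], "//")) k <- k + 1L
    i <- k + 1L
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " AAindex entr",
            if (length(skipped) == 1) "y" else "ies",
            " with NA values: ", paste(skipped, collapse = ", "))
  }
  scale_library(scales, provenance = path)
}

#' Write a scale library in AAindex1 flat format
#'
#' Values are written at full precision (whitespace-separated), so a
#' read/write round trip is lossless.
#'
#' @param lib A `scale_library`.
#' @param path Output path.
#' @export
write_aaindex <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in lib) {
    v <- scale_values(s)
    writeLines(c(paste("H", scale_name(s)),
                 paste("D", scale_category(s), "scale"),
                 paste("I   ", paste(AAINDEX_ROW1, AAINDEX_ROW2,
                                     sep = "/", collapse = "  ")),
                 paste(" ", paste(format(v[AAINDEX_ROW1], digits = 17),
                                  collapse = " ")),
                 paste(" ", paste(format(v[AAINDEX_ROW2], digits = 17),
                                  collapse = " ")),
                 "//"), con)
  }
  invisible(path)
}

#' Read / write custom scales as TSV
#'
#' Tabular format: columns `name`, `category`, then the 20 amino acids in
#' the fixed order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param path File path.
#' @return `read_scales_tsv` returns a `scale_library`.
#' @export
read_scales_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("name", "category", AA_ORDER) %in% colnames(tab))) {
    stop("scale TSV needs columns: name, category, ",
         paste(AA_ORDER, collapse = ", "))
  }
  scales <- lapply(seq_len(nrow(tab)), function(i) {
    aa_scale(stats::setNames(as.numeric(tab[i, AA_ORDER]), AA_ORDER),
             name = tab$name[i], category = tab$category[i])
  })
  scale_library(scales, provenance = path)
}

#' @rdname read_scales_tsv
#' @param lib A `scale_library`.
#' @export
write_scales_tsv <- function(lib, path) {
  m <- library_matrix(lib)
  tab <- data.frame(name = rownames(m),
                    category = unname(library_categories(lib)),
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(tab, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
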