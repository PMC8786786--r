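#' Sequence records
#'
#' A `seq_record` is the package's universal sequence currency: an identifier,
#' an optional free-text description, a declared alphabet (`"DNA"` or
#' `"PROTEIN"`), and an uppercase residue string. DNA records may contain
#' `A,C,G,T,N`; protein records the 20 standard residues plus `X`
#' (unknown) and `*` (stop).
#'
#' @param id Record identifier (non-empty, no whitespace).
#' @param residues Residue string; coerced to upper case.
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param description Optional free-text description.
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("tx1", "acgtacgt", "DNA")
#' @export
seq_record <- function(id, residues, alphabet = c("DNA", "PROTEIN"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("\\s", id)) stop("record id must not contain whitespace: ", id)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("record '", id, "' has empty residues")
  bad <- invalid_residues(residues, alphabet)
  if (length(bad)) {
    stop("record '", id, "' contains letters outside the ", alphabet,
         " alphabet: ", paste(bad, collapse = ", "))
  }
  structure(list(id = id, description = description,
                 alphabet = alphabet, residues = residues),
            class = "seq_record")
}

DNA_LETTERS <- c("A", "C", "G", "T", "N")
PROTEIN_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

invalid_residues <- function(residues, alphabet) {
  allowed <- if (alphabet == "DNA") DNA_LETTERS else c(PROTEIN_LETTERS, "X", "*")
  setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), allowed)
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<seq_record %s> %s, %d residues\n  %s\n",
              x$id, x$alphabet, n, shown))
  invisible(x)
}

#' @export
as.character.seq_record <- function(x, ...) x$residues

seq_len_aa <- function(x) nchar(x$residues)

#' A paired (or unpaired) sequencing read
#'
#' Holds a forward read and, optionally, its mate, each with a Sanger
#' Phred+33 quality string of the same length as the read.
#'
#' @param id Read (pair) identifier.
#' @param r1,q1 Forward read sequence and quality string.
#' @param r2,q2 Optional mate sequence and quality string.
#' @return An object of class `read_pair`.
#' @export
read_pair <- function(id, r1, q1, r2 = NULL, q2 = NULL) {
  if (nchar(r1) != nchar(q1))
    stop("read '", id, "': quality length does not match sequence length")
  if (!is.null(r2) && (is.null(q2) || nchar(r2) != nchar(q2)))
    stop("read '", id, "': mate quality length does not match sequence length")
  structure(list(id = id, r1 = toupper(r1), q1 = q1,
                 r2 = if (is.null(r2)) NULL else toupper(r2), q2 = q2),
            class = "read_pair")
}

#' Region annotation of a protein (and optionally its gene)
#'
#' Describes the secretion-related architecture of a candidate protein: the
#' N-terminal ER signal peptide (cleaved during secretion), the C-terminal
#' GPI-anchor signal (replaced by the glycolipid anchor at the omega
#' residue), the derived mature interval between them, and, for gene
#' records, intron intervals in nucleotide coordinates. All coordinates are
#' 1-based inclusive.
#'
#' @param er_end Last residue of the ER signal (cleavage occurs after it),
#'   or `NULL` if no ER signal.
#' @param gpi_omega The omega residue position (anchor attachment site; the
#'   propeptide from omega onwards is removed), or `NULL`.
#' @param length Protein length in residues; used to derive the mature
#'   interval when one or both signals are absent. May be `NA` if unknown.
#' @param introns List of `c(start, end)` nucleotide intervals.
#' @param provenance `"imported"` (external predictor) or `"heuristic"`
#'   (built-in approximation). Never mixed silently: the coarser of the two
#'   wins when annotations are merged.
#' @return An object of class `region_annotation` with fields `er_signal`
#'   (interval or `NULL`), `gpi_omega`, `mature` (interval), `introns`,
#'   `provenance`.
#' @export
region_annotation <- function(er_end = NULL, gpi_omega = NULL, length = NA,
                              introns = list(),
                              provenance = c("imported", "heuristic")) {
  provenance <- match.arg(provenance)
  if (!is.null(er_end) && !is.null(gpi_omega) && er_end >= gpi_omega)
    stop("ER signal end (", er_end, ") must precede the omega site (",
         gpi_omega, ")")
  m_start <- if (is.null(er_end)) 1L else er_end + 1L
  m_end <- if (is.null(gpi_omega)) {
    if (is.na(length)) NA_integer_ else as.integer(length)
  } else {
    as.integer(gpi_omega) - 1L
  }
  structure(list(
    er_signal = if (is.null(er_end)) NULL else c(1L, as.integer(er_end)),
    gpi_omega = if (is.null(gpi_omega)) NULL else as.integer(gpi_omega),
    mature = c(m_start, m_end),
    introns = introns,
    provenance = provenance
  ), class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  er <- if (is.null(x$er_signal)) "absent" else
    sprintf("1..%d", x$er_signal[2])
  om <- if (is.null(x$gpi_omega)) "absent" else as.character(x$gpi_omega)
  cat(sprintf("<region_annotation> ER signal: %s; omega: %s; mature: %s..%s [%s]\n",
              er, om, x$mature[1], x$mature[2], x$provenance))
  invisible(x)
}
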