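#' Six-frame open reading frame scan
#'
#' Finds every maximal stop-free codon run in all six reading frames of a
#' DNA record and reports the translated peptides with their forward-strand
#' nucleotide coordinates. ORFs are stop-to-stop by default: a run need not
#' begin with ATG, because candidate transcripts are often truncated and
#' their predicted proteins may lack the initiator methionine. Runs at the
#' sequence ends may lack both start and stop context and are flagged as
#' partial.
#'
#' @param record A DNA [seq_record] (or plain DNA string).
#' @param min_aa Minimum peptide length in residues (default 50).
#' @param require_atg If `TRUE`, trim each run to its first internal
#'   methionine and discard Met-free runs (ATG-anchored mode).
#' @return Data frame with one row per ORF: `source_id`, `strand`, `frame`,
#'   `start`, `end` (1-based inclusive on the forward strand), `peptide`,
#'   `has_initiator_met`, `partial` (run touches a sequence end, i.e. is
#'   not bounded by stop codons on both sides).
#' @examples
#' find_orfs(seq_record("x", "ATGAAATAA", "DNA"), min_aa = 1)
#' @export
find_orfs <- function(record, min_aa = 50L, require_atg = FALSE) {
  if (is.character(record)) record <- seq_record("seq", record, "DNA")
  stopifnot(record$alphabet == "DNA")
  if (min_aa < 1L) stop("min_aa must be >= 1")
  L <- nchar(record$residues)
  out <- list()
  frames <- six_frame(record$residues)
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    if (!nzchar(pep)) next
    strand <- frames$strand[i]
    frame <- frames$frame[i]
    n_aa <- nchar(pep)
    runs <- stop_free_runs(pep)
    for (r in seq_len(nrow(runs))) {
      i0 <- runs$start[r]; i1 <- runs$end[r]
      p <- substr(pep, i0, i1)
      if (require_atg) {
        m <- regexpr("M", p, fixed = TRUE)
        if (m < 0) next
        i0 <- i0 + m - 1L
        p <- substr(pep, i0, i1)
      }
      if (nchar(p) < min_aa) next
      # aa positions i0..i1 of this frame's translation -> nt coordinates
      if (strand == "+") {
        nt_start <- frame + 3L * (i0 - 1L) + 1L
        nt_end <- frame + 3L * i1
      } else {
        nt_start <- L - (frame + 3L * i1) + 1L
        nt_end <- L - frame - 3L * (i0 - 1L)
      }
      partial <- (i0 == 1L) || (i1 == n_aa)
      out[[length(out) + 1L]] <- data.frame(
        source_id = record$id, strand = strand, frame = frame,
        start = nt_start, end = nt_end, peptide = p,
        has_initiator_met = startsWith(p, "M"), partial = partial,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_orf_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_orf_frame <- function() {
  data.frame(source_id = character(), strand = character(),
             frame = integer(), start = integer(), end = integer(),
             peptide = character(), has_initiator_met = logical(),
             partial = logical(), stringsAsFactors = FALSE)
}

# maximal '*'-free runs of a peptide as (start, end) aa positions
stop_free_runs <- function(pep) {
  chunks <- strsplit(pep, "*", fixed = TRUE)[[1]]
  starts <- integer(0); ends <- integer(0); pos <- 1L
  for (ch in chunks) {
    if (nzchar(ch)) {
      starts <- c(starts, pos)
      ends <- c(ends, pos + nchar(ch) - 1L)
    }
    pos <- pos + nchar(ch) + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Filter ORFs by combined proline + glycine content
#'
#' Retains ORFs whose peptide has strictly more than `threshold_pct`
#' percent P+G residues. This is the screen used to surface candidate
#' disordered-protein ORFs when homology search finds nothing: PG-rich,
#' low-complexity peptides are rare among random ORFs.
#'
#' @param orfs Data frame from [find_orfs()] (needs a `peptide` column).
#' @param threshold_pct Percentage threshold, strict `>` (default 20).
#' @return The retained rows of `orfs`.
#' @export
pg_filter <- function(orfs, threshold_pct = 20.0) {
  if (!nrow(orfs)) return(orfs)
  stopifnot(all(nzchar(orfs$peptide)))
  keep <- pg_percent(orfs$peptide) > threshold_pct
  orfs[keep, , drop = FALSE]
}

#' Percent P+G of peptides
#'
#' @param peptides Character vector of protein strings.
#' @return Numeric vector, `100 * (countP + countG) / length`.
#' @export
pg_percent <- function(peptides) {
  vapply(peptides, function(p) {
    n <- nchar(p)
    pg <- n - nchar(gsub("[PG]", "", p))
    100 * pg / n
  }, 0, USE.NAMES = FALSE)
}
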