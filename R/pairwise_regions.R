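#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment under an affine gap model in which
#' a gap run of length L costs `gap_open + L * gap_extend`. Defaults are
#' the conventional full-length DNA comparison settings: match +5,
#' mismatch -4, gap open 10, gap extend 0.5, with terminal gaps free
#' (appropriate when whole gene sequences of unequal extent are
#' compared). Tie-breaking is deterministic: diagonal, then vertical (gap
#' in `b`), then horizontal.
#'
#' @param a,b Sequence strings or [seq_record]s of the same alphabet.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param free_end_gaps Do not penalise terminal gap runs (default
#'   `TRUE`).
#' @return Object of class `global_alignment`: `gapped_a`, `gapped_b`
#'   (equal-length strings with `-` gaps, never gap opposite gap),
#'   `score`, and `params`.
#' @examples
#' aln <- global_align("ACGT", "ACGT")
#' aln$score  # 20
#' @export
global_align <- function(a, b, match = 5, mismatch = -4,
                         gap_open = 10, gap_extend = 0.5,
                         free_end_gaps = TRUE) {
  ab_a <- if (inherits(a, "seq_record")) a$alphabet else NULL
  ab_b <- if (inherits(b, "seq_record")) b$alphabet else NULL
  if (!is.null(ab_a) && !is.null(ab_b) && ab_a != ab_b)
    stop("cannot align mixed alphabets: ", ab_a, " vs ", ab_b)
  if (inherits(a, "seq_record")) a <- a$residues
  if (inherits(b, "seq_record")) b <- b$residues
  res <- nw_align_cpp(a, b, match, mismatch, gap_open, gap_extend,
                      free_end_gaps)
  structure(list(
    gapped_a = res$gapped_a, gapped_b = res$gapped_b, score = res$score,
    params = list(match = match, mismatch = mismatch, gap_open = gap_open,
                  gap_extend = gap_extend, free_end_gaps = free_end_gaps)
  ), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> %d columns, score %.1f, identity %.1f%%\n",
              nchar(x$gapped_a), x$score, alignment_identity(x)))
  w <- 60
  for (i in seq(1, nchar(x$gapped_a), by = w)) {
    cat(substr(x$gapped_a, i, i + w - 1), "\n")
    cat(substr(x$gapped_b, i, i + w - 1), "\n\n")
  }
  invisible(x)
}

#' Percent identity of an alignment over all columns
#'
#' @param aln A `global_alignment`.
#' @return `100 * identical columns / total columns`.
#' @export
alignment_identity <- function(aln) {
  ca <- strsplit(aln$gapped_a, "")[[1]]
  cb <- strsplit(aln$gapped_b, "")[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Region-partitioned identity of a global alignment
#'
#' Partitions the alignment columns by regions defined on the ungapped
#' coordinates of sequence `a` (e.g. ER signal, intron, mature coding,
#' GPI signal) and reports percent identity per region. A column where
#' `a` has a gap inherits the region of the last preceding `a` residue
#' (leading gap columns take the first region). Identity is
#' `100 * identical columns / columns assigned to the region`, gap
#' columns included in the denominator. A `full` row summarises the whole
#' alignment.
#'
#' @param aln A [global_align()] result.
#' @param regions_a Data frame with columns `label`, `start`, `end`
#'   (1-based inclusive on ungapped `a`). Positions not covered by any
#'   region are pooled under the label `"unassigned"`.
#' @return Data frame: `label`, `columns`, `identical`, `identity_pct`.
#' @export
region_identity <- function(aln, regions_a) {
  ca <- strsplit(aln$gapped_a, "")[[1]]
  cb <- strsplit(aln$gapped_b, "")[[1]]
  len_a <- sum(ca != "-")
  if (nrow(regions_a)) {
    if (any(regions_a$start < 1 | regions_a$end > len_a |
            regions_a$start > regions_a$end))
      stop("region outside sequence a (length ", len_a, ")")
  }
  pos_label <- rep("unassigned", len_a)
  for (r in seq_len(nrow(regions_a))) {
    pos_label[regions_a$start[r]:regions_a$end[r]] <- regions_a$label[r]
  }
  # a-position at each column; gap columns inherit the preceding position
  apos <- cumsum(ca != "-")
  apos[apos == 0L] <- 1L
  col_label <- pos_label[apos]
  ident <- ca == cb & ca != "-"
  labels <- unique(c(regions_a$label,
                     if ("unassigned" %in% col_label) "unassigned"))
  rows <- lapply(labels, function(lb) {
    sel <- col_label == lb
    data.frame(label = lb, columns = sum(sel), identical = sum(ident[sel]),
               identity_pct = if (any(sel)) 100 * sum(ident[sel]) / sum(sel)
                              else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    label = "full", columns = length(ca), identical = sum(ident),
    identity_pct = 100 * sum(ident) / length(ca), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frameshift-inducing gaps within coding regions
#'
#' Finds maximal gap runs (in either sequence) whose length is not a
#' multiple of three and which fall inside the given coding regions of
#' sequence `a`. Such gaps change the reading frame between otherwise
#' orthologous coding sequences.
#'
#' @param aln A [global_align()] result.
#' @param coding_regions Data frame with `start`, `end` on ungapped `a`
#'   coordinates (and optionally `label`).
#' @return Data frame: `position` (ungapped `a` coordinate of the last
#'   `a` residue before/at the run start), `length`, `in_a` (`TRUE` when
#'   the gap is in `a`), `frameshift` (`length %% 3 != 0`); only
#'   frameshift rows inside coding regions are returned.
#' @export
frameshift_gaps <- function(aln, coding_regions) {
  ca <- strsplit(aln$gapped_a, "")[[1]]
  cb <- strsplit(aln$gapped_b, "")[[1]]
  apos <- cumsum(ca != "-")
  runs <- function(isgap, in_a) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(col_start = starts[keep], length = r$lengths[keep],
               in_a = rep(in_a, sum(keep)))
  }
  g <- rbind(runs(ca == "-", TRUE), runs(cb == "-", FALSE))
  if (!nrow(g)) return(data.frame(position = integer(), length = integer(),
                                  in_a = logical()))
  g$position <- pmax(apos[g$col_start], 1L)
  in_coding <- vapply(g$position, function(p)
    any(p >= coding_regions$start & p <= coding_regions$end), TRUE)
  out <- g[in_coding & g$length %% 3L != 0L,
           c("position", "length", "in_a"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length of a genomic interval and its kilobase label
#'
#' 1-based inclusive convention: `length = end - start + 1`.
#'
#' @param start,end Interval bounds, `start <= end`.
#' @return List with `nt` (integer length) and `kb` (string, length/1000
#'   rounded to 1 decimal, e.g. `"10.7 kb"`).
#' @examples
#' genomic_span(527748, 538492)$kb  # "10.7 kb"
#' @export
genomic_span <- function(start, end) {
  if (start > end) stop("start (", start, ") exceeds end (", end, ")")
  nt <- as.integer(end - start + 1)
  list(nt = nt, kb = sprintf("%.1f kb", round(nt / 1000, 1)))
}
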