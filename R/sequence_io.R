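#' Read a FASTA file
#'
#' Reads (optionally gzip-compressed) FASTA into a list of [seq_record]s.
#' Wrapped sequence lines are joined and residues are uppercased. Record
#' ids (the header token before the first whitespace) must be unique
#' within one file.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param alphabet `"auto"` (default), `"DNA"` or `"PROTEIN"`. With
#'   `"auto"`, a record whose residues are all in `A,C,G,T,N` is typed DNA,
#'   otherwise protein.
#' @return Named list of [seq_record]s in file order.
#' @export
read_fasta <- function(path, alphabet = c("auto", "DNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- read_text_lines(path)
  validate_fasta_lines(lines, path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  desc <- ifelse(grepl("\\s", names(set)),
                 sub("^\\S+\\s+", "", names(set)), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ab <- if (alphabet == "auto") guess_alphabet(res[[i]]) else alphabet
    out[[i]] <- seq_record(ids[[i]], res[[i]], ab, desc[[i]])
  }
  names(out) <- ids
  out
}

read_text_lines <- function(path) {
  con <- gzfile(path, "rt")  # reads plain text transparently too
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

validate_fasta_lines <- function(lines, path) {
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop("empty FASTA file: ", path)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">"))
    stop("FASTA parse error at line ", first, " of ", path,
         ": expected a '>' header")
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    if (!nzchar(trimws(sub("^>", "", lines[h]))))
      stop("FASTA parse error at line ", h, " of ", path,
           ": empty header")
    nxt <- lines[seq(h + 1L, length.out = max(0L, length(lines) - h))]
    upto <- which(startsWith(nxt, ">"))
    body <- if (length(upto)) nxt[seq_len(upto[1] - 1L)] else nxt
    if (!any(nzchar(trimws(body))))
      stop("FASTA parse error at line ", h, " of ", path,
           ": record has no sequence lines")
  }
  invisible(TRUE)
}

guess_alphabet <- function(residues) {
  letters <- unique(strsplit(residues, "", fixed = TRUE)[[1]])
  if (all(letters %in% DNA_LETTERS)) "DNA" else "PROTEIN"
}

#' Write records to FASTA
#'
#' @param records List of [seq_record]s.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read FASTQ reads, optionally paired
#'
#' Reads one or two Sanger Phred+33 FASTQ files (plain or gzipped) into a
#' list of [read_pair]s. When a mate file is given the two files must hold
#' the same number of records in matching order; pairs are zipped by
#' position.
#'
#' @param path_r1 Forward-read FASTQ path.
#' @param path_r2 Optional mate FASTQ path.
#' @return List of [read_pair]s in file order.
#' @export
read_fastq <- function(path_r1, path_r2 = NULL) {
  r1 <- read_fastq_one(path_r1)
  if (is.null(path_r2)) {
    return(mapply(function(id, s, q) read_pair(id, s, q),
                  r1$id, r1$seq, r1$qual, SIMPLIFY = FALSE))
  }
  r2 <- read_fastq_one(path_r2)
  if (length(r1$id) != length(r2$id)) {
    stop("mate files differ in record count: ", length(r1$id), " vs ",
         length(r2$id))
  }
  mapply(function(id, s1, q1, s2, q2) read_pair(id, s1, q1, s2, q2),
         r1$id, r1$seq, r1$qual, r2$seq, r2$qual, SIMPLIFY = FALSE)
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- read_text_lines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error in ", path, ": line count ", length(lines),
         " is not a multiple of 4")
  n <- length(lines) %/% 4L
  at <- function(k) lines[seq.int(k, by = 4L, length.out = n)]
  hdr <- at(1L); seqs <- toupper(at(2L)); plus <- at(3L); qual <- at(4L)
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 1L, " of ",
         path, ": expected '@' header")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 3L, " of ",
         path, ": expected '+' separator")
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad))
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 4L, " of ",
         path, ": quality length differs from sequence length")
  list(id = sub("\\s.*$", "", sub("^@", "", hdr)), seq = seqs, qual = qual)
}

#' Write read pairs to FASTQ
#'
#' @param pairs List of [read_pair]s.
#' @param path_r1 Output path for forward reads.
#' @param path_r2 Output path for mates; required if any pair has a mate.
#' @return Invisibly, the output path(s).
#' @export
write_fastq <- function(pairs, path_r1, path_r2 = NULL) {
  fmt <- function(id, s, q) paste0("@", id, "\n", s, "\n+\n", q)
  writeLines(vapply(pairs, function(p) fmt(p$id, p$r1, p$q1), ""), path_r1)
  have_mate <- vapply(pairs, function(p) !is.null(p$r2), TRUE)
  if (any(have_mate)) {
    if (is.null(path_r2)) stop("pairs have mates but no path_r2 given")
    writeLines(vapply(pairs[have_mate],
                      function(p) fmt(p$id, p$r2, p$q2), ""), path_r2)
    return(invisible(c(path_r1, path_r2)))
  }
  invisible(path_r1)
}

#' Reverse complement of a DNA string
#'
#' An involution over `A,C,G,T,N`; `N` maps to `N`.
#'
#' @param dna DNA string (or [seq_record]).
#' @return Reverse-complemented string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(dna) {
  if (inherits(dna, "seq_record")) dna <- dna$residues
  dna <- toupper(dna)
  bad <- setdiff(unique(strsplit(dna, "", fixed = TRUE)[[1]]), DNA_LETTERS)
  if (length(bad))
    stop("not a DNA string; offending letter(s): ", paste(bad, collapse = ","))
  chartr("ACGTN", "TGCAN", str_reverse(dna))
}

str_reverse <- function(x) intToUtf8(rev(utf8ToInt(x)))

#' Translate DNA in a given frame and strand
#'
#' Standard genetic code; any codon containing `N` translates to `X`;
#' stops are `*`. A trailing partial codon is dropped, so the peptide has
#' `floor((len - frame) / 3)` residues. On the minus strand the frame is
#' counted from the 5' end of the reverse complement.
#'
#' @param dna DNA string (or [seq_record]).
#' @param frame 0, 1 or 2.
#' @param strand `"+"` or `"-"`.
#' @return Protein string (possibly containing `*`).
#' @examples
#' translate_dna("ATGGGT")        # "MG"
#' translate_dna("TAA")           # "*"
#' @export
translate_dna <- function(dna, frame = 0L, strand = "+") {
  if (inherits(dna, "seq_record")) dna <- dna$residues
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2; got ", frame)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "-") dna <- reverse_complement(dna)
  n_aa <- (nchar(dna) - frame) %/% 3L
  if (n_aa < 1L) return("")
  starts <- frame + 1L + 3L * (seq_len(n_aa) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # any codon touching an N
  paste(aa, collapse = "")
}

#' Translate all six reading frames
#'
#' @param dna DNA string (or [seq_record]).
#' @return Data frame with columns `strand`, `frame`, `peptide`.
#' @export
six_frame <- function(dna) {
  if (inherits(dna, "seq_record")) dna <- dna$residues
  grid <- expand.grid(frame = 0:2, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  grid$peptide <- mapply(function(f, s) translate_dna(dna, f, s),
                         grid$frame, grid$strand)
  grid[, c("strand", "frame", "peptide")]
}
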