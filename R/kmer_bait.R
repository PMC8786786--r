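#' Build a k-mer bait index
#'
#' Collects every canonical k-mer (the lexicographic minimum of a k-mer
#' and its reverse complement) of the bait sequences. Canonicalisation
#' collapses strands, since baits derive from coding sequences while
#' sequencing reads come from both strands. K-mers containing `N` are
#' skipped.
#'
#' @param baits List of DNA [seq_record]s (or character vector).
#' @param k K-mer length; must be odd and >= 11 (default 31, the
#'   conventional baiting default).
#' @param n_min Minimum number of matching k-mers for a read to be
#'   selected (default 1).
#' @return Object of class `bait_index` with fields `k`, `n_min`, `kmers`
#'   (character vector of unique canonical k-mers).
#' @export
build_bait_index <- function(baits, k = 31L, n_min = 1L) {
  if (inherits(baits, "seq_record")) baits <- list(baits)
  seqs <- vapply(baits, function(b)
    if (inherits(b, "seq_record")) b$residues else toupper(b), "")
  if (!length(seqs)) stop("no bait sequences given")
  if (k < 11L || k %% 2L == 0L) stop("k must be odd and >= 11; got ", k)
  if (all(nchar(seqs) < k))
    stop("all baits are shorter than k = ", k)
  kmers <- unlist(lapply(seqs, canonical_kmers, k = k), use.names = FALSE)
  structure(list(k = as.integer(k), n_min = as.integer(n_min),
                 kmers = unique(kmers)),
            class = "bait_index")
}

#' @export
print.bait_index <- function(x, ...) {
  cat(sprintf("<bait_index> k = %d, n_min = %d, %d canonical k-mers\n",
              x$k, x$n_min, length(x$kmers)))
  invisible(x)
}

# canonical k-mers of one sequence (N-containing k-mers dropped)
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- substring(seq, 1:(n - k + 1L), k:n)
  rc <- reverse_complement(seq)
  rev_ <- substring(rc, 1:(n - k + 1L), k:n)
  # k-mer i of the forward strand pairs with k-mer (n-k+2-i) of the rc
  rev_ <- rev(rev_)
  canon <- pmin(fwd, rev_)
  canon[!grepl("N", canon, fixed = TRUE)]
}

#' Select reads sharing k-mers with the bait index
#'
#' A read matches when at least `n_min` of its canonical k-mers are in
#' the index; reads shorter than k never match. Qualities are ignored.
#' Input order is preserved, so identical inputs give identical outputs.
#'
#' @param pairs List of [read_pair]s.
#' @param index A [build_bait_index()] result.
#' @param pair_policy `"either"` (default: keep the pair when either mate
#'   matches, the right policy when baited pairs feed a paired-end
#'   assembler), `"both"`, or `"ignore-pairing"` (judge the forward read
#'   only).
#' @return List with `selected` (the selected [read_pair]s, input order)
#'   and `log` (data frame: `id`, `kmers_r1`, `kmers_r2`, `selected`).
#' @export
bait_reads <- function(pairs, index,
                       pair_policy = c("either", "both", "ignore-pairing")) {
  pair_policy <- match.arg(pair_policy)
  stopifnot(inherits(index, "bait_index"))
  count_hits <- function(s) {
    if (is.null(s) || nchar(s) < index$k) return(0L)
    sum(canonical_kmers(s, index$k) %in% index$kmers)
  }
  n1 <- vapply(pairs, function(p) count_hits(p$r1), 0L)
  n2 <- vapply(pairs, function(p) count_hits(p$r2), 0L)
  m1 <- n1 >= index$n_min
  m2 <- n2 >= index$n_min & vapply(pairs, function(p) !is.null(p$r2), TRUE)
  sel <- switch(pair_policy,
                "either" = m1 | m2,
                "both" = m1 & m2,
                "ignore-pairing" = m1)
  list(selected = pairs[sel],
       log = data.frame(
         id = vapply(pairs, `[[`, "", "id"),
         kmers_r1 = n1, kmers_r2 = n2, selected = sel,
         stringsAsFactors = FALSE))
}
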