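# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately naive re-derivation of the quantity under test, sharing no
# code with the package implementation paths it checks.

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

random_protein_str <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), n,
               replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# --- six-frame ORF oracle (uses seqinr's codon translation) -----------------

oracle_orfs <- function(dna, min_aa) {
  L <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else oracle_revcomp(dna)
    for (frame in 0:2) {
      aa <- seqinr::translate(seqinr::s2c(s), frame = frame, sens = "F")
      n_aa <- length(aa)
      if (!n_aa) next
      i <- 1L
      while (i <= n_aa) {
        if (aa[i] == "*") { i <- i + 1L; next }
        j <- i
        while (j < n_aa && aa[j + 1L] != "*") j <- j + 1L
        if (j - i + 1L >= min_aa) {
          if (strand == "+") {
            nt_s <- frame + 3L * (i - 1L) + 1L; nt_e <- frame + 3L * j
          } else {
            nt_s <- L - (frame + 3L * j) + 1L
            nt_e <- L - frame - 3L * (i - 1L)
          }
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, frame = frame, start = nt_s, end = nt_e,
            peptide = paste(aa[i:j], collapse = ""),
            stringsAsFactors = FALSE)
        }
        i <- j + 2L
      }
    }
  }
  if (!length(out)) return(data.frame(strand = character(),
                                      frame = integer(), start = integer(),
                                      end = integer(), peptide = character()))
  res <- do.call(rbind, out)
  res[order(res$strand, res$frame, res$start), , drop = FALSE]
}

# --- alignment oracles ------------------------------------------------------

# score one explicit alignment under the affine model used by the package
# (gap run of length L costs open + L * ext; terminal runs free if asked)
score_alignment <- function(ga, gb, match, mismatch, open, ext,
                            free_end_gaps) {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  ncol_ <- length(ca)
  sub <- sum(ifelse(ca[ca != "-" & cb != "-"] ==
                    cb[ca != "-" & cb != "-"], match, mismatch))
  gap_cost <- 0
  for (cs in list(ca, cb)) {
    r <- rle(cs == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      terminal <- starts[k] == 1L || ends[k] == ncol_
      if (!(free_end_gaps && terminal))
        gap_cost <- gap_cost + open + r$lengths[k] * ext
    }
  }
  sub - gap_cost
}

# exhaustive enumeration of all alignments (tiny sequences only)
oracle_align_enum <- function(a, b, match = 5, mismatch = -4, open = 10,
                              ext = 0.5, free_end_gaps = TRUE) {
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > nchar(a) && j > nchar(b)) {
      best <<- max(best, score_alignment(ga, gb, match, mismatch, open,
                                         ext, free_end_gaps))
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b))
      rec(i + 1L, j + 1L, paste0(ga, substr(a, i, i)),
          paste0(gb, substr(b, j, j)))
    if (i <= nchar(a))
      rec(i + 1L, j, paste0(ga, substr(a, i, i)), paste0(gb, "-"))
    if (j <= nchar(b))
      rec(i, j + 1L, paste0(ga, "-"), paste0(gb, substr(b, j, j)))
    invisible()
  }
  rec(1L, 1L, "", "")
  best
}

# top-down memoised recursion over (i, j, state); independent of the
# package's bottom-up C++ implementation
oracle_align_memo <- function(a, b, match = 5, mismatch = -4, open = 10,
                              ext = 0.5, free_end_gaps = TRUE) {
  n <- nchar(a); m <- nchar(b)
  memo <- new.env(hash = TRUE)
  # f(i, j, state): best score of aligning a[1..i], b[1..j] where state is
  # how the alignment ends: 1 diag, 2 gap-in-b, 3 gap-in-a
  f <- function(i, j, state) {
    key <- paste(i, j, state)
    if (exists(key, envir = memo, inherits = FALSE)) return(memo[[key]])
    val <- if (state == 1) {
      if (i == 0 && j == 0) 0
      else if (i == 0 || j == 0) -Inf
      else {
        s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
        s + max(f(i - 1, j - 1, 1), f(i - 1, j - 1, 2), f(i - 1, j - 1, 3))
      }
    } else if (state == 2) {          # gap in b: consumed a[.. i]
      if (i == 0) -Inf
      else if (j == 0) {
        if (free_end_gaps) 0 else -(open + i * ext)
      } else {
        term <- free_end_gaps && j == m
        co <- if (term) 0 else open + ext
        ce <- if (term) 0 else ext
        max(f(i - 1, j, 1) - co, f(i - 1, j, 2) - ce, f(i - 1, j, 3) - co)
      }
    } else {                          # gap in a
      if (j == 0) -Inf
      else if (i == 0) {
        if (free_end_gaps) 0 else -(open + j * ext)
      } else {
        term <- free_end_gaps && i == n
        co <- if (term) 0 else open + ext
        ce <- if (term) 0 else ext
        max(f(i, j - 1, 1) - co, f(i, j - 1, 2) - co, f(i, j - 1, 3) - ce)
      }
    }
    memo[[key]] <- val
    val
  }
  max(f(n, m, 1), f(n, m, 2), f(n, m, 3))
}

# --- pI grid-scan oracle ----------------------------------------------------

oracle_pi_grid <- function(protein, step = 1e-4) {
  # independently restated Henderson-Hasselbalch net charge, Bjellqvist pKa
  ch <- strsplit(protein, "")[[1]]
  nK <- sum(ch == "K"); nR <- sum(ch == "R"); nH <- sum(ch == "H")
  nD <- sum(ch == "D"); nE <- sum(ch == "E"); nC <- sum(ch == "C")
  nY <- sum(ch == "Y")
  pH <- seq(0, 14, by = step)
  pos <- 1 / (1 + 10^(pH - 7.5)) +
    nK / (1 + 10^(pH - 10.0)) + nR / (1 + 10^(pH - 12.0)) +
    nH / (1 + 10^(pH - 5.98))
  neg <- 1 / (1 + 10^(3.55 - pH)) +
    nD / (1 + 10^(4.05 - pH)) + nE / (1 + 10^(4.45 - pH)) +
    nC / (1 + 10^(9.0 - pH)) + nY / (1 + 10^(10.0 - pH))
  pH[which.min(abs(pos - neg))]
}

# --- brute-force perfect-repeat scan ----------------------------------------

# all (start, period, copies) with >= min_copies exact adjacent copies
oracle_perfect_repeats <- function(s, min_copies = 2L, max_period = NULL) {
  n <- nchar(s)
  if (is.null(max_period)) max_period <- n %/% 2L
  hits <- list()
  for (p in seq_len(max_period)) {
    for (st in seq_len(n - 2L * p + 1L)) {
      unit <- substr(s, st, st + p - 1L)
      cp <- 1L
      while (st + (cp + 1L) * p - 1L <= n &&
             substr(s, st + cp * p, st + (cp + 1L) * p - 1L) == unit)
        cp <- cp + 1L
      if (cp >= min_copies)
        hits[[length(hits) + 1L]] <- c(start = st, period = p, copies = cp)
    }
  }
  hits
}

# --- baiting substring oracle -----------------------------------------------

oracle_read_matches <- function(read, baits, k) {
  if (nchar(read) < k) return(FALSE)
  targets <- c(baits, vapply(baits, oracle_revcomp, ""))
  kmers <- substring(read, 1:(nchar(read) - k + 1L), k:nchar(read))
  any(vapply(kmers, function(km)
    any(grepl(km, targets, fixed = TRUE)), TRUE))
}

# --- misc -------------------------------------------------------------------

mutate_dna_str <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  for (i in which(hit)) ch[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                                ch[i]), 1L)
  paste(ch, collapse = "")
}
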