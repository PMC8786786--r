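test_that("identical sequences align gap-free at full score", {
  aln <- global_align("ACGT", "ACGT")
  expect_equal(aln$score, 20)
  expect_equal(aln$gapped_a, "ACGT")
  expect_equal(aln$gapped_b, "ACGT")
  expect_equal(alignment_identity(aln), 100)
  set.seed(71)
  s <- random_dna_str(50)
  self <- global_align(s, s)
  expect_false(grepl("-", self$gapped_a, fixed = TRUE))
  expect_false(grepl("-", self$gapped_b, fixed = TRUE))
})

test_that("alignment recovers inputs and never stacks gap on gap", {
  set.seed(72)
  for (i in 1:10) {
    a <- random_dna_str(sample(10:40, 1))
    b <- random_dna_str(sample(10:40, 1))
    aln <- global_align(a, b)
    expect_equal(gsub("-", "", aln$gapped_a), a)
    expect_equal(gsub("-", "", aln$gapped_b), b)
    ca <- strsplit(aln$gapped_a, "")[[1]]
    cb <- strsplit(aln$gapped_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    expect_equal(global_align(b, a)$score, aln$score)
  }
})

test_that("scores equal the exhaustive-alignment oracle on short sequences", {
  set.seed(73)
  # full enumeration for tiny inputs, cross-checked against the memoised
  # recursion, which then covers lengths up to 12
  for (i in 1:6) {
    a <- random_dna_str(sample(2:6, 1)); b <- random_dna_str(sample(2:6, 1))
    enum <- oracle_align_enum(a, b)
    expect_equal(oracle_align_memo(a, b), enum)
    expect_equal(global_align(a, b)$score, enum)
  }
  for (i in 1:12) {
    a <- random_dna_str(sample(8:12, 1)); b <- random_dna_str(sample(8:12, 1))
    expect_equal(global_align(a, b)$score, oracle_align_memo(a, b))
  }
  # penalised end gaps too
  for (i in 1:6) {
    a <- random_dna_str(sample(4:10, 1)); b <- random_dna_str(sample(4:10, 1))
    expect_equal(global_align(a, b, free_end_gaps = FALSE)$score,
                 oracle_align_memo(a, b, free_end_gaps = FALSE))
  }
})

test_that("mixed alphabets are rejected", {
  expect_error(global_align(seq_record("a", "ACGT", "DNA"),
                            seq_record("b", "MKL", "PROTEIN")),
               "mixed")
})

test_that("region identity partitions columns and recombines", {
  s <- paste0(strrep("A", 10), strrep("C", 10), strrep("G", 10))
  regions <- data.frame(label = c("left", "mid", "right"),
                        start = c(1, 11, 21), end = c(10, 20, 30))
  self <- region_identity(global_align(s, s), regions)
  expect_true(all(self$identity_pct == 100))
  # recombination: per-region identical columns sum to the full count
  set.seed(74)
  b <- mutate_dna_str(s, 0.2)
  rep2 <- region_identity(global_align(s, b), regions)
  full <- rep2[rep2$label == "full", ]
  expect_equal(sum(rep2$identical[rep2$label != "full"]), full$identical)
  expect_error(region_identity(global_align(s, b),
                               data.frame(label = "x", start = 1, end = 99)),
               "outside")
})

test_that("a region aligned entirely opposite gaps scores zero identity", {
  a <- paste0("ACGTACGTAC", strrep("T", 12))
  b <- "ACGTACGTAC"
  aln <- global_align(a, b)
  rep_ <- region_identity(aln, data.frame(label = c("head", "tail"),
                                          start = c(1, 11), end = c(10, 22)))
  expect_equal(rep_$identity_pct[rep_$label == "tail"], 0)
  expect_equal(rep_$identity_pct[rep_$label == "head"], 100)
})

test_that("synthetic orthologues keep signal regions more conserved", {
  # conserved signal/ends, heavily mutated mature middle
  set.seed(75)
  g <- make_agl_gene(synth_spec(seed = 76))
  cds <- g$cds
  er_nt <- c(1, 60)                       # 20 aa ER signal
  om <- g$regions$gpi_omega
  mature_nt <- c(61, (om - 1) * 3)
  gpi_nt <- c((om - 1) * 3 + 1, nchar(cds))
  ortho <- paste0(mutate_dna_str(substr(cds, 1, 60), 0.05),
                  mutate_dna_str(substr(cds, 61, (om - 1) * 3), 0.35),
                  mutate_dna_str(substr(cds, gpi_nt[1], gpi_nt[2]), 0.05))
  regions <- data.frame(label = c("er_signal", "mature", "gpi_signal"),
                        start = c(er_nt[1], mature_nt[1], gpi_nt[1]),
                        end = c(er_nt[2], mature_nt[2], gpi_nt[2]))
  rep_ <- region_identity(global_align(cds, ortho), regions)
  id <- function(lb) rep_$identity_pct[rep_$label == lb]
  expect_gt(id("er_signal"), id("mature"))
  expect_gt(id("gpi_signal"), id("mature"))
})

test_that("frameshift gaps are gap runs with length not divisible by 3", {
  a <- "ATGGCTGCAGCTGCAGCTTAA"           # 21 nt
  coding <- data.frame(start = 1, end = 21)
  drop2 <- paste0(substr(a, 1, 8), substr(a, 11, 21))   # 2-nt deletion
  g2 <- frameshift_gaps(global_align(a, drop2), coding)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$length, 2)
  drop3 <- paste0(substr(a, 1, 8), substr(a, 12, 21))   # 3-nt deletion
  expect_equal(nrow(frameshift_gaps(global_align(a, drop3), coding)), 0)
  drop4 <- paste0(substr(a, 1, 8), substr(a, 13, 21))   # 4-nt deletion
  g4 <- frameshift_gaps(global_align(a, drop4), coding)
  expect_equal(g4$length, 4)
})

test_that("genomic spans use the 1-based inclusive convention", {
  expect_equal(genomic_span(527748, 538492),
               list(nt = 10745L, kb = "10.7 kb"))
  expect_equal(genomic_span(30068, 46636),
               list(nt = 16569L, kb = "16.6 kb"))
  expect_equal(genomic_span(5, 5)$nt, 1L)
  expect_error(genomic_span(10, 9), "exceeds")
})
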