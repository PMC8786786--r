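test_that("five-class scheme follows signals, chimera status and PGA", {
  # ER + GPI, small, PGA-rich: class 1 AGL
  c1 <- classify_candidate(TRUE, TRUE, 58, 150)
  expect_equal(c1$class_label, 1L)
  expect_true(c1$is_agl)
  # ER only, moderate PGA: class 2
  expect_equal(classify_candidate(TRUE, FALSE, 20, 150)$class_label, 2L)
  # neither signal: class 5, never an AGL
  c5 <- classify_candidate(FALSE, FALSE, 80, 100)
  expect_equal(c5$class_label, 5L)
  expect_false(c5$is_agl)
  # chimeric sequences take classes 3/4 from the imported domain table
  expect_equal(classify_candidate(TRUE, TRUE, 80, 100,
                                  "insignificant")$class_label, 3L)
  expect_equal(classify_candidate(TRUE, TRUE, 80, 100,
                                  "other")$class_label, 4L)
  # boundary: PGA exactly 40 is class 2 (class 1 is strict >40)
  expect_equal(classify_candidate(TRUE, TRUE, 40, 100)$class_label, 2L)
  # size gate: class 1 but mature > 200 aa is not called an AGL
  big <- classify_candidate(TRUE, TRUE, 58, 201)
  expect_equal(big$class_label, 1L)
  expect_false(big$is_agl)
  # GPI without ER escapes class 5 but cannot be an AGL
  noer <- classify_candidate(FALSE, TRUE, 58, 150)
  expect_equal(noer$class_label, 1L)
  expect_false(noer$is_agl)
})

test_that("class intervals are exhaustive and mutually exclusive", {
  for (pga in seq(15, 100, by = 0.5)) {
    cls <- classify_candidate(TRUE, TRUE, pga, 100)$class_label
    expect_true(cls %in% c(1L, 2L))
    expect_equal(cls, if (pga > 40) 1L else 2L)
  }
  expect_true(is.na(classify_candidate(TRUE, TRUE, 10, 100)$class_label))
})

test_that("classification is a pure function of its inputs", {
  args <- list(TRUE, FALSE, 33.3, 120, NA_character_)
  expect_identical(do.call(classify_candidate, args),
                   do.call(classify_candidate, args))
})

test_that("elimination retains only high-identity partials of ER peers", {
  set.seed(81)
  full <- random_protein_str(120)
  partial <- substr(full, 30, 120)      # truncated copy, ~100% identical
  peers <- list(list(peptide = full, has_er = TRUE))
  kept <- elimination_rule(list(peptide = partial, has_er = FALSE,
                                partial = TRUE), peers)
  expect_false(kept$eliminated)
  # unrelated no-ER candidate is eliminated
  gone <- elimination_rule(list(peptide = random_protein_str(90),
                                has_er = FALSE, partial = TRUE), peers)
  expect_true(gone$eliminated)
  # non-partial no-ER candidate is eliminated even when identical
  gone2 <- elimination_rule(list(peptide = partial, has_er = FALSE,
                                 partial = FALSE), peers)
  expect_true(gone2$eliminated)
  # ER-bearing candidates are never eliminated by this rule
  keep <- elimination_rule(list(peptide = random_protein_str(90),
                                has_er = TRUE, partial = TRUE), peers)
  expect_false(keep$eliminated)
})

test_that("BLAST tabular import validates the 12-column format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  row <- paste(c("q1", "s1", "97.5", "200", "5", "0", "1", "200", "11",
                 "210", "1e-50", "370"), collapse = "\t")
  writeLines(row, f)
  hits <- import_blast_tab(f)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pident, 97.5)
  expect_equal(hits$evalue, 1e-50)
  writeLines("q1\ts1\t97.5", f)
  expect_error(import_blast_tab(f), "line 1")
  writeLines(character(0), f)
  expect_equal(nrow(import_blast_tab(f)), 0)
})

test_that("the pipeline recovers planted candidates with truth signals", {
  co <- make_cohort(3, 7, seed = 91)
  rep_ <- run_pipeline(co$transcripts, signals = co$signals)
  agl <- rep_[rep_$is_agl, ]
  expect_equal(nrow(agl), 3)
  expect_setequal(agl$source_id, c("agl1", "agl2", "agl3"))
  expect_true(all(agl$class_label == 1))
  expect_true(all(agl$has_er & agl$has_gpi))
  expect_true(all(agl$provenance == "imported"))
  expect_true(all(agl$nterm_q))
  # planted repeat structure is recovered on the mature protein
  expect_true(all(agl$repeat_unit_length == 6))
  expect_true(all(agl$repeat_copies == 12))
  # non-secreted candidates are eliminated with a reason
  el <- rep_[rep_$eliminated, ]
  expect_true(all(grepl("not secreted", el$elimination_reason)))
  # determinism
  rep2 <- run_pipeline(co$transcripts, signals = co$signals)
  expect_identical(rep_, rep2)
})

test_that("protein input, domain hits and empty input are handled", {
  co <- make_cohort(1, 0, seed = 92)
  prot <- co$truth[[1]]$protein
  sig <- stats::setNames(list(co$signals[[1]]), prot$id)
  rep_ <- run_pipeline(list(prot), signals = sig)
  expect_equal(rep_$origin, "supplied")
  expect_true(rep_$is_agl)
  # a domain hit reroutes to the chimeric classes
  dh <- data.frame(id = prot$id, domain = "PF10342",
                   category = "insignificant", stringsAsFactors = FALSE)
  rep3 <- run_pipeline(list(prot), signals = sig, domain_hits = dh)
  expect_equal(rep3$class_label, 3L)
  expect_false(rep3$is_agl)
  # empty input -> empty report
  expect_equal(nrow(run_pipeline(list())), 0)
  # DNA with no qualifying ORF -> empty report
  short <- list(seq_record("tiny", "ATGAAATAA", "DNA"))
  expect_equal(nrow(run_pipeline(short)), 0)
})
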