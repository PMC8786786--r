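test_that("perfect arrays are reported once, at the smallest period", {
  r <- detect_repeats(strrep("GKAPAGGAAPGADA", 5), "protein", psim_min = 1.0)
  expect_equal(nrow(r), 1)
  expect_equal(r$unit_length, 14)
  expect_equal(r$copies, 5)
  expect_equal(r$psim, 1.0)
  expect_equal(r$consensus, "GKAPAGGAAPGADA")
  expect_equal(c(r$start, r$end), c(1, 70))

  r6 <- detect_repeats(strrep("APADGK", 5), "protein", psim_min = 1.0)
  expect_equal(r6$unit_length, 6)
  expect_equal(r6$copies, 5)

  # smallest-period rule: ABABABAB is 2 x 4, not 4 x 2
  ab <- detect_repeats("ABABABAB", "dna", psim_min = 1.0)
  expect_equal(ab$unit_length, 2)
  expect_equal(ab$copies, 4)

  # homopolymer runs report unit length 1
  hp <- detect_repeats(strrep("A", 12), "protein", psim_min = 1.0)
  expect_equal(hp$unit_length, 1)
  expect_equal(hp$copies, 12)
})

test_that("random peptides carry no sizeable perfect arrays (brute force)", {
  set.seed(41)
  for (i in 1:5) {
    s <- random_protein_str(60)
    want <- oracle_perfect_repeats(s, min_copies = 2)
    got <- detect_repeats(s, "protein", psim_min = 1.0)
    # soundness: anything detected is a genuine perfect array
    expect_true(all(vapply(seq_len(nrow(got)), function(k)
      any(vapply(want, function(h)
        h["period"] == got$unit_length[k] &&
        h["start"] == got$start[k] &&
        h["copies"] == got$copies[k], TRUE)), TRUE)))
    # a uniform-random peptide has no array spanning >= 12 residues, and
    # the detector agrees
    spans <- vapply(want, function(h) unname(h["period"] * h["copies"]), 0)
    expect_false(any(spans >= 12))
    expect_false(any(got$unit_length * got$copies >= 12))
  }
})

test_that("flanking sequence shifts coordinates but not the array", {
  set.seed(42)
  array <- strrep("PGKADA", 6)
  left <- random_protein_str(17); right <- random_protein_str(23)
  bare <- detect_repeats(array, "protein", psim_min = 1.0)
  flanked <- detect_repeats(paste0(left, array, right), "protein",
                            psim_min = 1.0)
  expect_equal(flanked$unit_length, bare$unit_length)
  expect_equal(flanked$copies, bare$copies)
  expect_equal(flanked$psim, bare$psim)
  expect_equal(flanked$start, bare$start + nchar(left))
})

test_that("substituting m residues lowers psim by exactly m/(N*L)", {
  unit <- "GCTAGGAT"  # DNA, L = 8
  N <- 6
  s <- strrep(unit, N)
  for (m in 1:3) {
    mutated <- s
    # mutate the first m positions of the third unit
    for (j in seq_len(m)) {
      pos <- 2 * nchar(unit) + j
      old <- substr(mutated, pos, pos)
      substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    r <- detect_repeats(mutated, "dna", psim_min = 0.6)
    r <- r[r$unit_length == nchar(unit), ]
    expect_equal(r$psim, 1 - m / (N * nchar(unit)), tolerance = 1e-12)
  }
})

test_that("partial terminal units extend the span but not the copy count", {
  r <- detect_repeats(paste0(strrep("APADGK", 4), "APA"), "protein",
                      psim_min = 1.0)
  expect_equal(r$copies, 4)
  expect_equal(r$end, 27)   # 24 full + 3 partial
})

test_that("overlap filtering keeps the strongest region", {
  s <- paste0(strrep("APADGK", 5), strrep("W", 5), strrep("NG", 4))
  all_r <- detect_repeats(s, "protein", psim_min = 1.0)
  expect_gte(nrow(all_r), 2)
  filt <- detect_repeats(s, "protein", psim_min = 1.0,
                         filter_overlaps = TRUE)
  expect_true(all(diff(sort(c(rbind(filt$start, filt$end)))) >= 0))
  expect_true(30 %in% (filt$copies * filt$unit_length * filt$psim))
})

test_that("repeat properties: composition and the zwitterionic rule", {
  mk_region <- function(unit, copies = 3) {
    detect_repeats(strrep(unit, copies), "protein", psim_min = 1.0)
  }
  pr <- repeat_properties(mk_region("PTGDAGGAAPKGGAA"))
  expect_true(pr$zwitterionic)      # has D and K
  pr2 <- repeat_properties(mk_region("APADGK"))
  expect_true(pr2$zwitterionic)
  expect_equal(round(pr2$p_pct, 1), 16.7)
  expect_equal(round(pr2$g_pct, 1), 16.7)
  pr3 <- repeat_properties(mk_region("AAAA"))
  expect_false(pr3$zwitterionic)
})

test_that("zone classification matches the calibrated exemplars", {
  expect_equal(classify_zone(0, 0), "amyloid")
  expect_equal(classify_zone(50, 50), "elastic")
  expect_equal(classify_zone(0, 14.3), "amyloid")       # G-only repeat
  expect_equal(classify_zone(16.7, 16.7), "intermediate")
  expect_equal(classify_zone(14.3, 28.6), "intermediate")  # GKAPAGGAAPGADA
  expect_equal(classify_zone(25, 12.5), "intermediate")
  expect_equal(classify_zone(20, 20), "elastic")
  expect_equal(classify_zone(30, 30), "elastic")
  expect_equal(classify_zone(12.5, 62.5), "elastic")    # P 12.5, G 62.5
  expect_equal(classify_zone(25, 63), "elastic")
})

test_that("zone boundaries load from JSON and reject crossings", {
  path <- system.file("extdata", "zones_default.json", package = "aglscan")
  z <- read_zones(path)
  expect_s3_class(z, "property_zones")
  expect_equal(classify_zone(16.7, 16.7, z), "intermediate")
  bad <- list(amyloid_intermediate = cbind(g_pct = c(0, 100),
                                           p_pct = c(50, 0)),
              intermediate_elastic = cbind(g_pct = c(0, 100),
                                           p_pct = c(10, 10)))
  expect_error(classify_zone(5, 5, bad), "cross")
})

test_that("zone labels never move toward amyloid as P%% or G%% grow", {
  grid <- seq(0, 100, by = 4)
  rank <- c(amyloid = 1, intermediate = 2, elastic = 3)
  lab <- outer(grid, grid, function(p, g) rank[classify_zone(p, g)])
  expect_true(all(apply(lab, 2, diff) >= 0))  # increasing P
  expect_true(all(apply(lab, 1, diff) >= 0))  # increasing G
})

test_that("codon usage counts and fractions per amino acid", {
  cu <- codon_usage("CCACCACCA")
  expect_equal(unname(cu$P$counts["CCA"]), 3L)
  expect_equal(unname(cu$P$fractions["CCA"]), 1.0)
  cu2 <- codon_usage("CCTCCACCA")
  expect_equal(unname(cu2$P$fractions[c("CCA", "CCT")]), c(2 / 3, 1 / 3))
  cu3 <- codon_usage("AAAGAC")
  expect_equal(unname(cu3$K$counts["AAA"]), 1L)
  expect_equal(unname(cu3$D$counts["GAC"]), 1L)
  # fractions sum to one per amino acid
  set.seed(43)
  s <- random_dna_str(300)
  cu4 <- codon_usage(s)
  for (aa in names(cu4)) expect_equal(sum(cu4[[aa]]$fractions), 1)
  # frame handling
  expect_error(codon_usage("ATGCCC", c(2, 6)), "frame")
  expect_equal(names(codon_usage("ATGCCC", c(2, 6), frame_offset = 2)),
               "P")
})
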