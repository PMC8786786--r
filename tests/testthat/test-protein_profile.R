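test_that("composition percentages match hand counts", {
  p <- composition("APADGK")
  expect_equal(round(unname(p$pct["P"]), 1), 16.7)
  expect_equal(round(unname(p$pct["G"]), 1), 16.7)
  expect_equal(round(unname(p$pct["A"]), 1), 33.3)   # 2/6
  expect_equal(round(unname(p$pct["D"]), 1), 16.7)   # 1/6
  expect_equal(round(unname(p$pct["K"]), 1), 16.7)   # 1/6
  q <- composition("APKDG")
  expect_equal(round(unname(q$pct["P"]), 1), 20.0)
  expect_equal(round(unname(q$pct["G"]), 1), 20.0)
  expect_error(composition(""), "empty")
  expect_error(composition("AP*DG"), "stop")
})

test_that("percentages sum to 100 and aggregates decompose", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_protein_str(sample(5:120, 1))
    p <- composition(s)
    expect_lt(abs(sum(p$pct) - 100), 0.05)
    expect_equal(p$pga_pct,
                 unname(p$pct["P"] + p$pct["G"] + p$pct["A"]))
    expect_equal(p$de_pct, unname(p$pct["D"] + p$pct["E"]))
    expect_equal(p$kr_pct, unname(p$pct["K"] + p$pct["R"]))
  }
  expect_true(composition("QAPA")$nterm_q)
  expect_false(composition("APQA")$nterm_q)
})

test_that("molecular weight uses average masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01 / 75.07)
  expect_equal(molecular_weight("GG"),
               2 * molecular_weight("G") - 18.02, tolerance = 1e-3)
  set.seed(32)
  a <- random_protein_str(15); b <- random_protein_str(22)
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - WATER_MASS)
  expect_error(molecular_weight("AXA"), "X")
  expect_equal(molecular_weight("AXA", x_mass = 110),
               2 * RESIDUE_MASS[["A"]] + 110 + WATER_MASS)
})

test_that("pI is monotone in charge and agrees with a grid-scan oracle", {
  expect_gt(isoelectric_point(strrep("K", 10)),
            isoelectric_point(strrep("D", 10)))
  set.seed(33)
  for (i in 1:10) {
    s <- random_protein_str(sample(5:60, 1))
    # non-decreasing up to the bisection tolerance
    expect_gte(isoelectric_point(paste0(s, "K")) + 0.01,
               isoelectric_point(s))
    expect_lt(abs(isoelectric_point(s) - oracle_pi_grid(s)), 0.01)
  }
})

test_that("profile flags honour the inclusive thresholds", {
  # N-rich profile flags N among high single residues
  p <- composition(paste0(strrep("N", 33), strrep("A", 67)))
  fl <- flag_profile(p)
  expect_true("N" %in% fl$high_single_aa)
  # boundary: PGA exactly 40 is flagged (>= 40)
  p40 <- composition(paste0(strrep("P", 40), strrep("L", 60)))
  expect_true(flag_profile(p40)$pga_ge_40)
  expect_equal(p40$pga_pct, 40)
  # all-L profile sets nothing except its (neutral-range) pI class
  pl <- flag_profile(composition(strrep("L", 30)))
  expect_false(pl$pga_ge_40 || pl$de_ge_8 || pl$kr_ge_8)
  expect_setequal(pl$high_single_aa, "L")   # homopolymer trivially >= 15%
})

test_that("signal stripping returns the mature interval", {
  prot <- random_protein_str(100)
  regions <- region_annotation(er_end = 20, gpi_omega = 81, length = 100)
  mature <- strip_signals(prot, regions)
  expect_equal(nchar(mature), 60)
  expect_equal(mature, substr(prot, 21, 80))
  # only ER annotated
  er_only <- region_annotation(er_end = 20, length = 100)
  expect_equal(strip_signals(prot, er_only), substr(prot, 21, 100))
  # composition of stripped equals composition of the manual slice
  expect_equal(composition(mature)$pct,
               composition(substr(prot, 21, 80))$pct)
  expect_error(region_annotation(er_end = 50, gpi_omega = 40), "precede")
})

test_that("predictor imports map rows to annotations by dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq1\t20\tYES", "seq2\t0\tNO"), f)
  er <- import_signal_predictions(f, "er")
  expect_equal(er$seq1$er_end, 20)
  expect_null(er$seq2$er_end)
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq1\t130\tYES\t0.92"), g)
  gpi <- import_signal_predictions(g, "gpi")
  expect_equal(gpi$seq1$gpi_omega, 130)
  expect_error(import_signal_predictions(g, "er"), "3 columns")
  ann <- merge_signal_annotations(er, gpi, lengths = c(seq1 = 160))
  expect_equal(ann$seq1$er_signal, c(1L, 20L))
  expect_equal(ann$seq1$gpi_omega, 130L)
  expect_equal(ann$seq1$mature, c(21L, 129L))
  expect_equal(ann$seq1$provenance, "imported")
})

test_that("ER cleavage heuristic needs an h-region and small -3/-1", {
  # classic 15-aa signal: MKFLAVLLLLAVVSA | Q...
  s <- paste0("MKFLAVLLLLAVVSA", "Q", random_protein_str(30))
  expect_equal(heuristic_er_signal(s), 15)
  # acidic N-terminus: no hydrophobic window, no call
  expect_null(heuristic_er_signal(paste0(strrep("D", 40),
                                         random_protein_str(20))))
  expect_null(heuristic_er_signal("MKFLAVLLLLAVVSAQ"))  # below length floor
})

test_that("GPI omega heuristic requires a hydrophobic tail", {
  g <- make_agl_gene(synth_spec(seed = 7))
  expect_equal(heuristic_gpi_signal(g$protein$residues),
               g$regions$gpi_omega)
  expect_equal(heuristic_er_signal(g$protein$residues),
               g$regions$er_signal[2])
  # hydrophilic C-terminus: no call
  set.seed(34)
  hydrophilic <- paste0(random_protein_str(60), strrep("DKE", 8))
  expect_null(heuristic_gpi_signal(hydrophilic))
  expect_null(heuristic_gpi_signal(random_protein_str(39)))
})
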