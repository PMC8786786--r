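## Physico-chemical constants ------------------------------------------------

# Average residue masses (Da), monoisotopic not used; one water is added per
# chain. X has no defined mass.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# pKa sets for the charge model. "bjellqvist" is the convention of the
# common protein-analysis toolkits; "emboss" is provided as an alternative.
PKA_SETS <- list(
  bjellqvist = list(
    nterm = 7.5, cterm = 3.55,
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)),
  emboss = list(
    nterm = 8.6, cterm = 3.6,
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)))

# Kyte-Doolittle hydropathy
KD_SCALE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,  E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5,  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,  X = 0)

aa_counts <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = c(PROTEIN_LETTERS, "X")))
  as.integer(tab) |> stats::setNames(names(tab))
}

## Composition ----------------------------------------------------------------

#' Amino-acid composition profile of a protein
#'
#' Computes per-residue percentages (`100 * count / length`), molecular
#' weight, isoelectric point, the aggregate percentages used to
#' characterise disordered candidates (PGA, PG, DE, KR), and whether the
#' first residue is glutamine (a hallmark of many mature secreted
#' disordered proteins after signal cleavage). `X` residues count toward
#' the length but never toward any named percentage.
#'
#' @param protein Protein string (no `*`).
#' @param pka Name of the pKa set for the pI ([PKA_SETS] entry):
#'   `"bjellqvist"` (default) or `"emboss"`.
#' @return Object of class `composition_profile`: a list with `length`,
#'   `mw` (Da, `NA` when the sequence contains `X`), `pI`, `pct` (named
#'   percentage vector over the 20 residues plus X), `pga_pct`, `pg_pct`,
#'   `de_pct`, `kr_pct`, `nterm_q`.
#' @examples
#' p <- composition("APADGK")
#' round(p$pct[c("P", "G")], 1)  # 16.7 16.7
#' @export
composition <- function(protein, pka = "bjellqvist") {
  if (inherits(protein, "seq_record")) protein <- protein$residues
  if (!nzchar(protein)) stop("empty protein sequence")
  if (grepl("*", protein, fixed = TRUE))
    stop("protein contains a stop character '*'")
  cnt <- aa_counts(protein)
  n <- nchar(protein)
  pct <- 100 * cnt / n
  has_x <- cnt[["X"]] > 0L
  structure(list(
    length = n,
    mw = if (has_x) NA_real_ else molecular_weight(protein),
    pI = isoelectric_point(protein, pka = pka),
    pct = pct,
    pga_pct = unname(pct["P"] + pct["G"] + pct["A"]),
    pg_pct = unname(pct["P"] + pct["G"]),
    de_pct = unname(pct["D"] + pct["E"]),
    kr_pct = unname(pct["K"] + pct["R"]),
    nterm_q = substr(protein, 1, 1) == "Q"
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "<composition_profile> %d aa, MW %s Da, pI %.1f\n  PGA %.1f%%  PG %.1f%%  DE %.1f%%  KR %.1f%%  N-terminal Q: %s\n",
    x$length, ifelse(is.na(x$mw), "NA", sprintf("%.1f", x$mw)), x$pI,
    x$pga_pct, x$pg_pct, x$de_pct, x$kr_pct, x$nterm_q))
  invisible(x)
}

#' Average molecular weight of a protein (Da)
#'
#' Sum of average residue masses plus one water.
#'
#' @param protein Protein string with standard residues. `X` is an error
#'   unless `x_mass` supplies a substitute mass (e.g. the mean residue
#'   mass).
#' @param x_mass Optional mass to use for `X` residues.
#' @return Molecular weight in Daltons.
#' @export
molecular_weight <- function(protein, x_mass = NULL) {
  cnt <- aa_counts(protein)
  if (cnt[["X"]] > 0L && is.null(x_mass))
    stop("sequence contains X; supply x_mass to allow a substitute mass")
  core <- sum(cnt[PROTEIN_LETTERS] * RESIDUE_MASS[PROTEIN_LETTERS])
  if (cnt[["X"]] > 0L) core <- core + cnt[["X"]] * x_mass
  core + WATER_MASS
}

## Isoelectric point ----------------------------------------------------------

protein_charge <- function(protein_counts, pH, pka) {
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  neg <- -1 / (1 + 10^(pka$cterm - pH))
  for (aa in names(pka$positive)) {
    k <- protein_counts[[aa]]
    if (k > 0) pos <- pos + k / (1 + 10^(pH - pka$positive[[aa]]))
  }
  for (aa in names(pka$negative)) {
    k <- protein_counts[[aa]]
    if (k > 0) neg <- neg - k / (1 + 10^(pka$negative[[aa]] - pH))
  }
  pos + neg
}

#' Isoelectric point by bisection of the Henderson-Hasselbalch net charge
#'
#' Net charge is modelled from the termini plus D, E, C, Y (acidic) and
#' H, K, R (basic) side chains under the chosen pKa set; the pI is the pH
#' in `[0, 14]` where the charge crosses zero, found by bisection to a
#' tolerance of 0.005.
#'
#' @param protein Protein string.
#' @param pka pKa set name (see [PKA_SETS]).
#' @param tol Bisection tolerance in pH units.
#' @return The pI (full precision; display convention is 1 decimal).
#' @export
isoelectric_point <- function(protein, pka = "bjellqvist", tol = 0.005) {
  if (!nzchar(protein)) stop("empty protein sequence")
  set <- PKA_SETS[[match.arg(pka, names(PKA_SETS))]]
  cnt <- aa_counts(protein)
  lo <- 0; hi <- 14
  # charge is monotone decreasing in pH
  if (protein_charge(cnt, lo, set) < 0) return(lo)
  if (protein_charge(cnt, hi, set) > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(cnt, mid, set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Flags ----------------------------------------------------------------------

#' Composition flags for candidate triage
#'
#' Applies the standard display thresholds to a [composition()] profile:
#' individual residues present at >= 15%, aggregate PGA >= 40%, acidic
#' DE >= 8%, basic KR >= 8% (all non-strict), plus a pI class.
#'
#' @param profile A `composition_profile`.
#' @param pi_acidic,pi_basic pI class cut points: acidic `< pi_acidic`,
#'   basic `> pi_basic`, neutral in between (defaults 6.0 and 7.5).
#' @return Object of class `profile_flags`: `high_single_aa` (character
#'   vector of residues at >= 15%), `pga_ge_40`, `de_ge_8`, `kr_ge_8`,
#'   `pi_class`.
#' @export
flag_profile <- function(profile, pi_acidic = 6.0, pi_basic = 7.5) {
  stopifnot(inherits(profile, "composition_profile"))
  pct20 <- profile$pct[PROTEIN_LETTERS]
  structure(list(
    high_single_aa = names(pct20)[pct20 >= 15],
    pga_ge_40 = profile$pga_pct >= 40,
    de_ge_8 = profile$de_pct >= 8,
    kr_ge_8 = profile$kr_pct >= 8,
    pi_class = if (profile$pI < pi_acidic) "acidic"
               else if (profile$pI > pi_basic) "basic" else "neutral"
  ), class = "profile_flags")
}

## Signal-region handling -----------------------------------------------------

#' Strip ER and GPI signal regions, returning the mature protein
#'
#' Removes the N-terminal ER signal peptide (everything up to and
#' including the cleavage position) and the GPI-anchor signal (the omega
#' residue and everything after it, i.e. the propeptide removed on anchor
#' attachment). If only one signal is annotated, only that one is trimmed.
#'
#' @param protein Protein string.
#' @param regions A [region_annotation()].
#' @return The mature protein string.
#' @export
strip_signals <- function(protein, regions) {
  if (inherits(protein, "seq_record")) protein <- protein$residues
  n <- nchar(protein)
  from <- if (is.null(regions$er_signal)) 1L else regions$er_signal[2] + 1L
  to <- if (is.null(regions$gpi_omega)) n else regions$gpi_omega - 1L
  if (!is.null(regions$er_signal) && regions$er_signal[2] >= n)
    stop("ER signal end at or beyond sequence end")
  if (!is.null(regions$gpi_omega) && regions$gpi_omega > n)
    stop("omega site beyond sequence end")
  if (from > to) stop("signal regions overlap or invert: mature interval ",
                      from, "..", to)
  substr(protein, from, to)
}

#' Import external signal-predictor summaries
#'
#' Parses tab-separated predictor summaries into per-sequence region
#' annotations with `provenance = "imported"`. Two dialects are supported:
#' \describe{
#'   \item{`"er"`}{3 columns: `id`, `er_cleavage_end`, `call` (YES/NO). A
#'     YES row annotates an ER signal ending at `er_cleavage_end`.}
#'   \item{`"gpi"`}{4 columns: `id`, `omega_pos`, `call` (YES/NO),
#'     `score`. A YES row annotates the omega site.}
#' }
#' Ids absent from the table are simply left unannotated.
#'
#' @param path TSV file path.
#' @param dialect `"er"` or `"gpi"`.
#' @return Named list: `id -> list(er_end = ..or NULL, gpi_omega = ..or NULL)`.
#' @export
import_signal_predictions <- function(path, dialect = c("er", "gpi")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- if (dialect == "er") 3L else 4L
  if (ncol(tab) != need)
    stop("dialect '", dialect, "' expects ", need, " columns, found ",
         ncol(tab), " in ", path)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    id <- as.character(tab[i, 1])
    yes <- toupper(as.character(tab[i, 3])) == "YES"
    if (!yes) { out[[id]] <- list(er_end = NULL, gpi_omega = NULL); next }
    pos <- as.integer(tab[i, 2])
    out[[id]] <- if (dialect == "er") list(er_end = pos, gpi_omega = NULL)
                 else list(er_end = NULL, gpi_omega = pos)
  }
  out
}

#' Merge imported ER and GPI predictor tables into region annotations
#'
#' @param er,gpi Maps from [import_signal_predictions()] (either may be
#'   `NULL`).
#' @param lengths Optional named integer vector of protein lengths, used
#'   to complete the mature interval.
#' @return Named list of [region_annotation()]s (provenance `"imported"`).
#' @export
merge_signal_annotations <- function(er = NULL, gpi = NULL, lengths = NULL) {
  ids <- union(names(er), names(gpi))
  out <- lapply(ids, function(id) {
    region_annotation(
      er_end = er[[id]]$er_end,
      gpi_omega = gpi[[id]]$gpi_omega,
      length = if (!is.null(lengths) && id %in% names(lengths))
        lengths[[id]] else NA,
      provenance = "imported")
  })
  names(out) <- ids
  out
}

kd_values <- function(protein) unname(KD_SCALE[strsplit(protein, "")[[1]]])

#' Heuristic ER signal-peptide call
#'
#' A deliberately simple approximation of secretion-signal predictors,
#' used only as a fallback when no imported predictions are available:
#' within the first 40 residues there must be a hydrophobic h-region (an
#' 8-residue window with mean Kyte-Doolittle hydropathy >= 1.6) followed
#' by a cleavage position in 15..35 satisfying the (-3, -1) small-residue
#' rule (both residues in A,G,S,C,T,V). The first qualifying position is
#' returned. Results carry `provenance = "heuristic"` downstream and are
#' never mixed silently with imported predictor calls.
#'
#' @param protein Protein string (length >= 25 required, else no call).
#' @return Integer cleavage position (signal = 1..pos) or `NULL`.
#' @export
heuristic_er_signal <- function(protein) {
  if (inherits(protein, "seq_record")) protein <- protein$residues
  n <- nchar(protein)
  if (n < 25L) return(NULL)
  head_len <- min(40L, n)
  kd <- kd_values(substr(protein, 1, head_len))
  win_means <- if (head_len >= 8L)
    vapply(seq_len(head_len - 7L),
           function(i) mean(kd[i:(i + 7L)]), 0) else numeric(0)
  h_starts <- which(win_means >= 1.6)
  if (!length(h_starts)) return(NULL)
  h_first_end <- min(h_starts) + 7L   # earliest h-region must precede cleavage
  small <- c("A", "G", "S", "C", "T", "V")
  for (pos in 15:35) {
    if (pos > n - 1L) break
    if (pos < h_first_end) next
    r1 <- substr(protein, pos, pos)        # -1 position
    r3 <- substr(protein, pos - 2L, pos - 2L)  # -3 position
    if (r1 %in% small && r3 %in% small) return(pos)
  }
  NULL
}

#' Heuristic GPI-anchor omega-site call
#'
#' Fallback approximation of GPI-signal predictors: requires a
#' hydrophobic C-terminal tail (mean Kyte-Doolittle >= 1.0 over the final
#' 12 residues) and a small residue (G,A,S,N,D,C) at a position 17 to 31
#' residues from the C-terminus with another small residue at omega+2.
#' Among qualifying positions the one closest to 25-from-end is returned
#' (ties resolved toward the C-terminus).
#'
#' @param protein Protein string (no call for length < 40).
#' @return Integer omega position or `NULL`.
#' @export
heuristic_gpi_signal <- function(protein) {
  if (inherits(protein, "seq_record")) protein <- protein$residues
  n <- nchar(protein)
  if (n < 40L) return(NULL)
  tail_kd <- mean(kd_values(substr(protein, n - 11L, n)))
  if (tail_kd < 1.0) return(NULL)
  small <- c("G", "A", "S", "N", "D", "C")
  cand <- integer(0)
  for (d in 17:31) {            # distance from C-terminus
    pos <- n - d + 1L
    if (pos < 1L || pos + 2L > n) next
    if (substr(protein, pos, pos) %in% small &&
        substr(protein, pos + 2L, pos + 2L) %in% small)
      cand <- c(cand, pos)
  }
  if (!length(cand)) return(NULL)
  target <- n - 25L + 1L
  cand[order(abs(cand - target), -cand)][1]
}
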