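## Candidate classification ---------------------------------------------------

#' Default pipeline thresholds
#'
#' @return Named list: `pg_min` (ORF screen, strict %PG), `pga_class1`
#'   (strict lower bound for class 1), `pga_class2_low` (inclusive lower
#'   bound for class 2), `max_len_agl` (maximum mature length, aa, for an
#'   AGL call), `peer_identity` (percent identity for the partial-sequence
#'   retention rule), `min_aa` (ORF minimum length), `psim_protein`
#'   (repeat similarity threshold for proteins).
#' @export
default_thresholds <- function() {
  list(pg_min = 20, pga_class1 = 40, pga_class2_low = 15,
       max_len_agl = 200, peer_identity = 90, min_aa = 50,
       psim_protein = 1.0)
}

#' Assign the five-class candidate label
#'
#' The scheme: class 5, no ER and no GPI signal (not a secreted,
#' anchored protein); classes 3/4, chimeric sequences flagged by an
#' external domain-hit table (3 when the hit is the configured
#' "insignificant" arabinogalactan-domain category, 4 otherwise); class
#' 1, PGA strictly above 40%; class 2, PGA in [15, 40]. Candidates below
#' 15% PGA with a signal are reported unclassified (`NA`). A candidate
#' is called an AGL when it is class 1, has an ER signal, and its mature
#' protein is at most 200 aa.
#'
#' @param has_er,has_gpi Signal presence.
#' @param pga_pct Mature-protein PGA percentage.
#' @param mature_len Mature protein length (aa).
#' @param domain_category `NA`, `"insignificant"` or `"other"` from the
#'   imported domain-hit table.
#' @param thresholds See [default_thresholds()].
#' @return List: `class_label` (integer or `NA`), `is_agl` (logical).
#' @export
classify_candidate <- function(has_er, has_gpi, pga_pct, mature_len,
                               domain_category = NA_character_,
                               thresholds = default_thresholds()) {
  cls <- if (!has_er && !has_gpi) {
    5L
  } else if (!is.na(domain_category)) {
    if (domain_category == "insignificant") 3L else 4L
  } else if (pga_pct > thresholds$pga_class1) {
    1L
  } else if (pga_pct >= thresholds$pga_class2_low) {
    2L
  } else {
    NA_integer_
  }
  list(class_label = cls,
       is_agl = isTRUE(cls == 1L) && has_er &&
                mature_len <= thresholds$max_len_agl)
}

#' Elimination rule for non-secreted candidates
#'
#' Candidates without an ER signal are eliminated (they cannot be
#' secreted), unless they are partial sequences with high global-alignment
#' identity to a peer that does carry an ER signal -- the situation of a
#' truncated assembly of a real gene. Identity is computed over the
#' candidate's own residues (identical columns / candidate length), so a
#' clean truncation of a full-length peer scores 100%.
#'
#' @param candidate List with `peptide`, `has_er`, `partial`.
#' @param peers List of peers, each with `peptide`, `has_er`.
#' @param identity_min Retention identity threshold in percent (default
#'   90).
#' @return List: `eliminated` (logical), `reason` (string or `NA`).
#' @export
elimination_rule <- function(candidate, peers, identity_min = 90) {
  if (isTRUE(candidate$has_er))
    return(list(eliminated = FALSE, reason = NA_character_))
  if (isTRUE(candidate$partial)) {
    for (p in peers) {
      if (!isTRUE(p$has_er)) next
      aln <- global_align(candidate$peptide, p$peptide,
                          match = 1, mismatch = 0, gap_open = 1,
                          gap_extend = 0.5)
      ca <- strsplit(aln$gapped_a, "")[[1]]
      cb <- strsplit(aln$gapped_b, "")[[1]]
      pid <- 100 * sum(ca == cb & ca != "-") / nchar(candidate$peptide)
      if (pid >= identity_min)
        return(list(eliminated = FALSE,
                    reason = "retained: partial with high identity to an ER-bearing peer"))
    }
  }
  list(eliminated = TRUE, reason = "no ER signal: not secreted")
}

#' Import a 12-column tabular BLAST hit file
#'
#' Standard tabular hit format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score). No filtering is applied at parse time.
#'
#' @param path File path.
#' @return Data frame of hits (possibly empty).
#' @export
import_blast_tab <- function(path) {
  cols <- c("query", "subject", "pident", "aln_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("BLAST tabular parse error at line ", bad[1], " of ", path,
         ": expected 12 columns, found ", lengths(fields)[bad[1]])
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- cols
  num <- c("pident", "aln_len", "mismatches", "gap_opens", "qstart",
           "qend", "sstart", "send", "evalue", "bitscore")
  out[num] <- lapply(out[num], as.numeric)
  out
}

## Pipeline -------------------------------------------------------------------

#' Run the discovery and characterisation pipeline
#'
#' End-to-end, deterministic orchestration: DNA inputs are six-frame ORF
#' scanned and screened at `pg_min` %PG; protein inputs are taken as
#' supplied. Each candidate is annotated with signal regions (imported
#' annotations preferred; the built-in heuristics used as a clearly
#' flagged fallback when enabled), stripped to its mature protein,
#' profiled, scanned for tandem repeats, classified into the five-class
#' scheme and passed through the elimination rule.
#'
#' Imported signal annotations are keyed by input sequence id. An
#' annotation that records the predicted protein's length is applied only
#' to candidate peptides of exactly that length; an annotation without a
#' length is applied to the longest ORF of its source only. Either way,
#' ORFs from other frames of the same input are never mis-annotated with
#' a prediction made for a different protein.
#'
#' @param input List of [seq_record]s, or a FASTA path.
#' @param signals Optional named map `id -> list(er_end, gpi_omega,
#'   length)` (e.g. truth annotations or merged predictor imports).
#' @param domain_hits Optional data frame `id`, `domain`, `category`
#'   (`"insignificant"`/`"other"`) marking chimeric candidates.
#' @param thresholds See [default_thresholds()].
#' @param use_heuristics Fall back to [heuristic_er_signal()] /
#'   [heuristic_gpi_signal()] for candidates with no imported annotation
#'   (default `TRUE`).
#' @return Data frame (class `candidate_report`), one row per candidate:
#'   id, origin, source_id, peptide and mature lengths, signal calls and
#'   provenance, mature composition (pga/pg/de/kr percentages, pI,
#'   N-terminal Q), repeat summary (count, and for the longest-spanning
#'   repeat: unit length, copies, psim, P%, G%, zwitterionic, zone),
#'   class label, AGL call, elimination status and reason. Empty input
#'   yields an empty report.
#' @export
run_pipeline <- function(input, signals = NULL, domain_hits = NULL,
                         thresholds = default_thresholds(),
                         use_heuristics = TRUE) {
  if (is.character(input) && length(input) == 1L) input <- read_fasta(input)
  if (!length(input)) return(empty_candidate_report())
  candidates <- list()
  for (rec in input) {
    if (rec$alphabet == "DNA") {
      orfs <- pg_filter(find_orfs(rec, min_aa = thresholds$min_aa),
                        thresholds$pg_min)
      for (i in seq_len(nrow(orfs))) {
        candidates[[length(candidates) + 1L]] <- list(
          id = sprintf("%s|%s%d|%d-%d", orfs$source_id[i], orfs$strand[i],
                       orfs$frame[i], orfs$start[i], orfs$end[i]),
          source_id = orfs$source_id[i], origin = "orf_scan",
          peptide = orfs$peptide[i], partial = orfs$partial[i])
      }
    } else {
      candidates[[length(candidates) + 1L]] <- list(
        id = rec$id, source_id = rec$id, origin = "supplied",
        peptide = rec$residues, partial = FALSE)
    }
  }
  if (!length(candidates)) return(empty_candidate_report())

  # longest candidate per source: target of length-free source-keyed
  # annotations
  pep_len <- vapply(candidates, function(c) nchar(c$peptide), 0L)
  src <- vapply(candidates, `[[`, "", "source_id")
  longest_of <- tapply(pep_len, src, max)

  rows <- lapply(candidates, function(cand) {
    n_aa <- nchar(cand$peptide)
    ann <- signals[[cand$id]]
    if (is.null(ann)) {
      ann <- signals[[cand$source_id]]
      if (!is.null(ann)) {
        if (!is.null(ann$length)) {
          if (ann$length != n_aa) ann <- NULL
        } else if (n_aa != longest_of[[cand$source_id]]) {
          ann <- NULL
        }
      }
    }
    if (!is.null(ann)) {
      regions <- region_annotation(er_end = ann$er_end,
                                   gpi_omega = ann$gpi_omega,
                                   length = n_aa, provenance = "imported")
    } else if (use_heuristics) {
      regions <- region_annotation(er_end = heuristic_er_signal(cand$peptide),
                                   gpi_omega = heuristic_gpi_signal(cand$peptide),
                                   length = n_aa, provenance = "heuristic")
    } else {
      regions <- region_annotation(length = n_aa, provenance = "imported")
    }
    mature <- strip_signals(cand$peptide, regions)
    prof <- composition(mature)
    flags <- flag_profile(prof)
    reps <- detect_repeats(mature, "protein",
                           psim_min = thresholds$psim_protein)
    has_er <- !is.null(regions$er_signal)
    has_gpi <- !is.null(regions$gpi_omega)
    dc <- NA_character_
    if (!is.null(domain_hits) && cand$source_id %in% domain_hits$id)
      dc <- domain_hits$category[match(cand$source_id, domain_hits$id)]
    cls <- classify_candidate(has_er, has_gpi, prof$pga_pct, prof$length,
                              dc, thresholds)
    top <- if (nrow(reps)) which.max(reps$end - reps$start) else NA_integer_
    top_props <- if (!is.na(top))
      repeat_properties(reps[top, , drop = FALSE]) else NULL
    data.frame(
      id = cand$id, origin = cand$origin, source_id = cand$source_id,
      length_aa = n_aa,
      has_er = has_er, er_end = if (has_er) regions$er_signal[2] else NA,
      has_gpi = has_gpi, gpi_omega = if (has_gpi) regions$gpi_omega else NA,
      provenance = regions$provenance,
      mature_len = prof$length,
      pga_pct = prof$pga_pct, pg_pct = prof$pg_pct,
      de_pct = prof$de_pct, kr_pct = prof$kr_pct,
      pI = prof$pI, nterm_q = prof$nterm_q, pi_class = flags$pi_class,
      n_repeats = nrow(reps),
      repeat_unit_length = if (!is.na(top)) reps$unit_length[top] else NA,
      repeat_copies = if (!is.na(top)) reps$copies[top] else NA,
      repeat_psim = if (!is.na(top)) reps$psim[top] else NA,
      repeat_p_pct = if (!is.na(top)) top_props$p_pct else NA,
      repeat_g_pct = if (!is.na(top)) top_props$g_pct else NA,
      repeat_zwitterionic = if (!is.na(top)) top_props$zwitterionic else NA,
      repeat_zone = if (!is.na(top)) top_props$zone else NA_character_,
      class_label = cls$class_label, is_agl = cls$is_agl,
      partial = cand$partial,
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  # elimination pass: peers are all other candidates
  peers_all <- lapply(seq_len(nrow(report)), function(i)
    list(peptide = candidates[[i]]$peptide, has_er = report$has_er[i]))
  elim <- lapply(seq_len(nrow(report)), function(i) {
    elimination_rule(
      list(peptide = candidates[[i]]$peptide,
           has_er = report$has_er[i], partial = report$partial[i]),
      peers_all[-i], identity_min = thresholds$peer_identity)
  })
  report$eliminated <- vapply(elim, `[[`, TRUE, "eliminated")
  report$elimination_reason <- vapply(elim, `[[`, "", "reason")
  report$is_agl <- report$is_agl & !report$eliminated
  class(report) <- c("candidate_report", class(report))
  report
}

empty_candidate_report <- function() {
  out <- data.frame(id = character(), origin = character(),
                    source_id = character(), length_aa = integer(),
                    has_er = logical(), er_end = integer(),
                    has_gpi = logical(), gpi_omega = integer(),
                    provenance = character(), mature_len = integer(),
                    pga_pct = numeric(), pg_pct = numeric(),
                    de_pct = numeric(), kr_pct = numeric(), pI = numeric(),
                    nterm_q = logical(), pi_class = character(),
                    n_repeats = integer(), repeat_unit_length = integer(),
                    repeat_copies = integer(), repeat_psim = numeric(),
                    repeat_p_pct = numeric(), repeat_g_pct = numeric(),
                    repeat_zwitterionic = logical(),
                    repeat_zone = character(), class_label = integer(),
                    is_agl = logical(), partial = logical(),
                    eliminated = logical(),
                    elimination_reason = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_report", class(out))
  out
}

#' Write a candidate report to TSV and JSON
#'
#' @param report A [run_pipeline()] result.
#' @param tsv,json Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_candidate_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", digits = NA)
  invisible(c(tsv, json))
}
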