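## Tandem repeat detection ----------------------------------------------------

#' Detect tandem repeat arrays in a protein or DNA sequence
#'
#' Period discovery is seeded by exact k-mer recurrence (k = 3 for
#' protein, k = 5 for DNA): candidate unit lengths are the pairwise
#' occurrence distances of recurring k-mers, restricted to distances that
#' are observed at least twice and can fit two copies in the sequence.
#' For each candidate period, in ascending order, arrays are grown from
#' left to right: starting from a seed window, consecutive period-length
#' units are appended while each new unit matches the running
#' column-majority consensus at identity >= `psim_min`. The similarity of
#' a finished array, `psim`, is the mean over full units of the fraction
#' of positions matching the final consensus; a trailing partial unit that
#' matches the consensus prefix extends the reported span but is not
#' counted as a copy. Regions whose span is identical but whose period is
#' a multiple of a smaller qualifying period at at-least-equal psim are
#' suppressed, so a perfect array is reported once, at its smallest
#' period. Unit comparison is positional (substitutions are tolerated up
#' to `psim_min`; unit-internal indels are not chased).
#'
#' @param seq Sequence string or [seq_record].
#' @param alphabet `"protein"` or `"dna"` (chooses the seeding k).
#' @param psim_min Minimum unit-to-consensus similarity in (0, 1]. The
#'   conventional settings are 1.0 for proteins and 0.7 for DNA, where
#'   codon degeneracy blurs the repeat.
#' @param min_copies Minimum number of full copies (default 2).
#' @param filter_overlaps If `TRUE`, greedily keep the
#'   highest-`copies * unit_length * psim` regions and drop any region
#'   overlapping an already-accepted one (the conventional setting is
#'   off).
#' @return Data frame with one row per region: `seq_id`, `start`, `end`
#'   (1-based inclusive), `unit_length`, `copies`, `consensus`, `psim`,
#'   and a list column `units` of the full unit strings.
#' @examples
#' detect_repeats(strrep("APADGK", 5), "protein", psim_min = 1.0)
#' @export
detect_repeats <- function(seq, alphabet = c("protein", "dna"),
                           psim_min = 1.0, min_copies = 2L,
                           filter_overlaps = FALSE) {
  alphabet <- match.arg(alphabet)
  id <- "seq"
  if (inherits(seq, "seq_record")) { id <- seq$id; seq <- seq$residues }
  stopifnot(psim_min > 0, psim_min <= 1, min_copies >= 2L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  k <- if (alphabet == "protein") 3L else 5L
  periods <- candidate_periods(seq, k, max_period = n %/% 2L)
  regions <- list()
  for (p in periods) {
    for (reg in grow_arrays(chars, p, psim_min, min_copies)) {
      regions[[length(regions) + 1L]] <- reg
    }
  }
  regions <- suppress_harmonics(regions)
  if (filter_overlaps) regions <- greedy_filter_overlaps(regions)
  if (!length(regions)) return(empty_repeat_frame())
  res <- data.frame(
    seq_id = id,
    start = vapply(regions, `[[`, 0L, "start"),
    end = vapply(regions, `[[`, 0L, "end"),
    unit_length = vapply(regions, `[[`, 0L, "unit_length"),
    copies = vapply(regions, `[[`, 0L, "copies"),
    consensus = vapply(regions, `[[`, "", "consensus"),
    psim = vapply(regions, `[[`, 0, "psim"),
    stringsAsFactors = FALSE)
  res$units <- I(lapply(regions, `[[`, "units"))
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_repeat_frame <- function() {
  out <- data.frame(seq_id = character(), start = integer(),
                    end = integer(), unit_length = integer(),
                    copies = integer(), consensus = character(),
                    psim = numeric(), stringsAsFactors = FALSE)
  out$units <- I(list())
  out
}

# candidate periods: pairwise distances between occurrences of recurring
# k-mers, kept when the same distance is seen >= 2 times
candidate_periods <- function(seq, k, max_period) {
  n <- nchar(seq)
  if (n < k || max_period < 1L) return(integer(0))
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  occ <- split(seq_along(kmers), kmers)
  dist_count <- integer(0)
  dists <- unlist(lapply(occ, function(pos) {
    if (length(pos) < 2L) return(integer(0))
    d <- outer(pos, pos, "-")
    d[d > 0]
  }), use.names = FALSE)
  if (!length(dists)) return(integer(0))
  tab <- table(dists)
  cand <- as.integer(names(tab)[tab >= 2L])
  # homopolymer and very short periods arise naturally as distance 1, 2, ...
  sort(cand[cand >= 1L & cand <= max_period])
}

# grow maximal arrays of period p scanning left to right
grow_arrays <- function(chars, p, psim_min, min_copies) {
  n <- length(chars)
  out <- list()
  s <- 1L
  while (s + 2L * p - 1L <= n) {
    units <- list(chars[s:(s + p - 1L)])
    cons <- units[[1]]
    e <- s + p - 1L
    repeat {
      nxt_start <- e + 1L
      if (nxt_start + p - 1L > n) break
      u <- chars[nxt_start:(nxt_start + p - 1L)]
      if (mean(u == cons) < psim_min) break
      units[[length(units) + 1L]] <- u
      cons <- column_majority(units)
      e <- e + p
    }
    if (length(units) >= min_copies) {
      psim <- mean(vapply(units, function(u) mean(u == cons), 0))
      if (psim >= psim_min) {
        # partial terminal unit: extends span, not copies
        tail_len <- min(p - 1L, n - e)
        end <- e
        if (tail_len > 0L) {
          tail_chars <- chars[(e + 1L):(e + tail_len)]
          if (mean(tail_chars == cons[seq_len(tail_len)]) >= psim_min)
            end <- e + tail_len
        }
        out[[length(out) + 1L]] <- list(
          start = s, end = end, unit_length = p,
          copies = length(units),
          consensus = paste(cons, collapse = ""),
          units = vapply(units, paste, "", collapse = ""),
          psim = psim)
        s <- end + 1L
        next
      }
    }
    s <- s + 1L
  }
  out
}

# column-majority consensus over equal-length units; ties go to the
# residue seen in the earliest unit
column_majority <- function(units) {
  p <- length(units[[1]])
  vapply(seq_len(p), function(j) {
    col <- vapply(units, `[`, "", j)
    counts <- table(factor(col, levels = unique(col)))  # first-seen order
    names(counts)[which.max(counts)]
  }, "")
}

# drop regions whose span is also explained by a smaller qualifying period
# at >= psim (the smallest period owns the span)
suppress_harmonics <- function(regions) {
  if (length(regions) < 2L) return(regions)
  keep <- rep(TRUE, length(regions))
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i == j || !keep[i]) next
      a <- regions[[i]]; b <- regions[[j]]
      if (b$unit_length < a$unit_length &&
          a$unit_length %% b$unit_length == 0L &&
          b$start == a$start && b$end >= a$end &&
          b$psim >= a$psim) {
        keep[i] <- FALSE
      }
    }
  }
  regions[keep]
}

greedy_filter_overlaps <- function(regions) {
  if (length(regions) < 2L) return(regions)
  score <- vapply(regions, function(r) r$copies * r$unit_length * r$psim, 0)
  ord <- order(-score,
               vapply(regions, `[[`, 0L, "start"),
               vapply(regions, `[[`, 0L, "unit_length"))
  accepted <- list()
  for (i in ord) {
    r <- regions[[i]]
    clash <- any(vapply(accepted, function(a)
      r$start <= a$end && a$start <= r$end, TRUE))
    if (!clash) accepted[[length(accepted) + 1L]] <- r
  }
  accepted
}

## Repeat properties ----------------------------------------------------------

#' Biophysical properties of a repeat region
#'
#' Computes the proline and glycine percentages of the repeat (on the
#' consensus unit by default, the level at which repeat composition is
#' conventionally quoted), whether the unit is zwitterionic (contains at
#' least one acidic D/E and one basic K/R residue), and the predicted
#' mechanical zone from [classify_zone()].
#'
#' @param region One row of a [detect_repeats()] result (or a list with
#'   `consensus`, `start`, `end`, `units`).
#' @param zones Zone boundaries (default [default_zones()]).
#' @param on `"unit"` (default) computes percentages on the consensus
#'   unit; `"region"` on the concatenated full units.
#' @return List of class `repeat_properties`: `p_pct`, `g_pct`,
#'   `zwitterionic`, `zone`.
#' @export
repeat_properties <- function(region, zones = default_zones(), on = "unit") {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region[1L, ])
    if (is.list(region$units)) region$units <- region$units[[1]]
  }
  basis <- if (on == "unit") region$consensus
           else paste(region$units, collapse = "")
  n <- nchar(basis)
  cnt <- function(re) n - nchar(gsub(re, "", basis))
  p_pct <- 100 * cnt("P") / n
  g_pct <- 100 * cnt("G") / n
  structure(list(
    p_pct = p_pct, g_pct = g_pct,
    zwitterionic = grepl("[DE]", region$consensus) &&
                   grepl("[KR]", region$consensus),
    zone = classify_zone(p_pct, g_pct, zones)
  ), class = "repeat_properties")
}

## Zone classification --------------------------------------------------------

#' Default mechanical-property zone boundaries
#'
#' Two non-crossing piecewise-linear curves in the (G%, P%) plane
#' separating amyloid, intermediate ("interchangeable") and elastic
#' repeat compositions. Repeat polypeptides rich in both P and G behave
#' elastically (elastin, flagelliform silk), P/G-poor ones form amyloid,
#' and a band between is interchangeable; proline weighs more heavily
#' than glycine toward elasticity, so the elastic boundary drops steeply
#' at low G% and flattens at high G%. The shipped vertices are a
#' calibration chosen so that well-characterised exemplar repeat
#' compositions, written as (G%, P%), fall in their expected zones:
#' (14.3, 0) amyloid; (16.7, 16.7), (12.5, 25) and (28.6, 14.3)
#' intermediate; (20, 20), (30, 30), (40, 40), (62.5, 12.5) and (63, 25)
#' elastic. They are not a universal constant and can be replaced via
#' [read_zones()].
#'
#' @return Object of class `property_zones`: a list with
#'   `amyloid_intermediate` and `intermediate_elastic`, each a matrix of
#'   `(g_pct, p_pct)` vertices.
#' @export
default_zones <- function() {
  zones <- list(
    amyloid_intermediate = cbind(g_pct = c(0, 25, 100),
                                 p_pct = c(25, 0, 0)),
    intermediate_elastic = cbind(g_pct = c(0, 12.5, 20, 35, 50, 100),
                                 p_pct = c(39, 26, 19.5, 15, 12, 12)))
  validate_zones(zones)
}

#' Read zone boundaries from a JSON config
#'
#' The file holds an object with keys `amyloid_intermediate` and
#' `intermediate_elastic`, each a list of `[g_pct, p_pct]` vertex pairs
#' ordered by increasing G%.
#'
#' @param path JSON file path.
#' @return A `property_zones` object.
#' @export
read_zones <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  zones <- lapply(raw[c("amyloid_intermediate", "intermediate_elastic")],
                  function(m) {
                    m <- as.matrix(m)
                    colnames(m) <- c("g_pct", "p_pct")
                    m
                  })
  validate_zones(zones)
}

validate_zones <- function(zones) {
  for (nm in c("amyloid_intermediate", "intermediate_elastic")) {
    v <- zones[[nm]]
    if (is.unsorted(v[, "g_pct"], strictly = TRUE))
      stop("zone boundary '", nm, "': vertices must have increasing G%")
    if (is.unsorted(rev(v[, "p_pct"])))
      stop("zone boundary '", nm, "': boundary P% must be non-increasing ",
           "in G% (zone labels must be monotone)")
  }
  g_grid <- sort(unique(c(zones[[1]][, "g_pct"], zones[[2]][, "g_pct"],
                          seq(0, 100, by = 1))))
  lo <- boundary_p(zones$amyloid_intermediate, g_grid)
  hi <- boundary_p(zones$intermediate_elastic, g_grid)
  if (any(hi <= lo))
    stop("zone boundaries cross or touch; the intermediate band must have ",
         "positive width everywhere")
  structure(zones, class = "property_zones")
}

# piecewise-linear boundary value P(g); flat extension beyond the vertices
boundary_p <- function(vertices, g) {
  stats::approx(vertices[, "g_pct"], vertices[, "p_pct"], xout = g,
                rule = 2)$y
}

#' Classify a repeat composition into a mechanical-property zone
#'
#' Point-in-band test in the (G%, P%) plane: compositions below the lower
#' boundary are `"amyloid"`, at or above the upper boundary `"elastic"`,
#' and in between `"intermediate"`. Because both boundaries are
#' non-increasing in G%, increasing either percentage can never move the
#' label toward amyloid.
#'
#' @param p_pct,g_pct Proline and glycine percentages in `[0, 100]`.
#' @param zones A `property_zones` object (default [default_zones()]).
#' @return `"amyloid"`, `"intermediate"` or `"elastic"` (vectorised).
#' @examples
#' classify_zone(0, 0)      # amyloid
#' classify_zone(50, 50)    # elastic
#' @export
classify_zone <- function(p_pct, g_pct, zones = default_zones()) {
  stopifnot(all(p_pct >= 0 & p_pct <= 100), all(g_pct >= 0 & g_pct <= 100))
  if (!inherits(zones, "property_zones")) zones <- validate_zones(zones)
  lo <- boundary_p(zones$amyloid_intermediate, g_pct)
  hi <- boundary_p(zones$intermediate_elastic, g_pct)
  ifelse(p_pct < lo, "amyloid",
         ifelse(p_pct >= hi, "elastic", "intermediate"))
}

## Codon usage ----------------------------------------------------------------

#' Codon usage within an interval of a coding sequence
#'
#' Counts the codons used within a stated nucleotide interval of a CDS
#' (typically a tandem-repeat region) and reports, per encoded amino
#' acid, each codon's count and within-amino-acid fraction. Repeat arrays
#' typically show strongly restricted usage -- often a single codon per
#' amino acid -- consistent with expansion by recent DNA-level
#' duplication.
#'
#' @param cds DNA string or [seq_record] (a coding sequence read in frame
#'   from position 1).
#' @param interval_nt `c(start, end)`, 1-based inclusive, or `NULL` for
#'   the whole CDS.
#' @param frame_offset Offset 0..2 applied inside the interval when the
#'   interval does not start on a codon boundary of the CDS. By default
#'   the interval must be in frame with the CDS and have length divisible
#'   by 3; otherwise an explicit `frame_offset` is required.
#' @return Object of class `codon_usage_table`: named list per amino acid
#'   with `counts` and `fractions` (each named by codon), plus attributes
#'   `interval` and `n_codons`.
#' @examples
#' codon_usage("CCTCCACCA")  # P: CCA 2/3, CCT 1/3
#' @export
codon_usage <- function(cds, interval_nt = NULL, frame_offset = NULL) {
  if (inherits(cds, "seq_record")) cds <- cds$residues
  n <- nchar(cds)
  if (is.null(interval_nt)) interval_nt <- c(1L, n)
  s <- interval_nt[1]; e <- interval_nt[2]
  stopifnot(s >= 1L, e <= n, s <= e)
  in_frame <- (s - 1L) %% 3L == 0L && (e - s + 1L) %% 3L == 0L
  if (is.null(frame_offset)) {
    if (!in_frame)
      stop("interval ", s, "..", e, " is not in frame with the CDS; ",
           "supply frame_offset explicitly")
    frame_offset <- 0L
  }
  s2 <- s + frame_offset
  len <- ((e - s2 + 1L) %/% 3L) * 3L
  if (len < 3L) stop("interval too short to contain a codon")
  starts <- seq.int(s2, s2 + len - 3L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  out <- lapply(split(codons, aa), function(cv) {
    counts <- sort(table(cv), decreasing = TRUE)
    counts <- stats::setNames(as.integer(counts), names(counts))
    list(counts = counts, fractions = counts / sum(counts))
  })
  structure(out, class = "codon_usage_table",
            interval = c(s, e), n_codons = length(codons))
}

#' @export
print.codon_usage_table <- function(x, ...) {
  iv <- attr(x, "interval")
  cat(sprintf("<codon_usage_table> interval %d..%d, %d codons\n",
              iv[1], iv[2], attr(x, "n_codons")))
  for (aa in names(x)) {
    fr <- x[[aa]]$fractions
    cat(sprintf("  %s: %s\n", aa,
                paste(sprintf("%s %d (%.3f)", names(fr),
                              x[[aa]]$counts, fr), collapse = ", ")))
  }
  invisible(x)
}
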