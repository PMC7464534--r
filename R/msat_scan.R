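#' Default scan parameters for perfect microsatellite detection
#'
#' Minimum complete-copy thresholds by motif length (period): dinucleotide
#' repeats require 6 copies, trinucleotides 4, and tetra- through
#' hexanucleotides 3 copies.  These are the field-standard defaults for
#' perfect-repeat genome scans of 2-6 bp motifs.
#'
#' @param min_copies named numeric vector mapping period (as name, "2".."6")
#'   to the minimum number of complete motif copies a run must contain to be
#'   reported.  All thresholds must be >= 2 and all periods within 2..6.
#' @return an object of class `scan_params`: a list with `periods` (integer
#'   vector) and `min_copies` (integer vector, parallel to `periods`).
#' @examples
#' scan_params()                      # defaults
#' scan_params(c(`2` = 8, `3` = 5))   # stricter 2-/3-mer thresholds
#' @export
scan_params <- function(min_copies = c(`2` = 6, `3` = 4, `4` = 3, `5` = 3,
                                       `6` = 3)) {
  if (is.null(names(min_copies)) || any(!nzchar(names(min_copies))))
    stop("min_copies must be a named vector with period names")
  periods <- as.integer(names(min_copies))
  if (anyNA(periods) || any(periods < 2L) || any(periods > 6L))
    stop("periods must be integers in 2..6")
  if (anyDuplicated(periods)) stop("duplicated periods in min_copies")
  mc <- as.integer(min_copies)
  if (anyNA(mc) || any(mc < 2L)) stop("all copy thresholds must be >= 2")
  o <- order(periods)
  structure(list(periods = periods[o], min_copies = mc[o]),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat("Microsatellite scan parameters (perfect repeats):\n")
  cat(sprintf("  period %d: >= %d copies\n", x$periods, x$min_copies), sep = "")
  invisible(x)
}

#' Lexicographically smallest rotation of a motif
#'
#' Canonical representative of a motif's rotation class, used as a stable
#' reporting key so e.g. runs of "CA" and "AC" tally together.  Strands are
#' not folded: "AC" and "GT" remain distinct (see [scan_sequence()]'s
#' `fold_strands`).
#'
#' @param motif character vector of DNA motifs (1-6 bp, A/C/G/T only).
#' @return character vector of canonical rotations; idempotent.
#' @examples
#' canonical_motif(c("CA", "GAT"))  # "AC", "ATG"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (any(nchar(motif) < 1L | nchar(motif) > 6L))
    stop("motif length must be in 1..6")
  if (any(grepl("[^ACGT]", motif)))
    stop("invalid motif: characters outside {A,C,G,T}")
  vapply(motif, function(m) {
    p <- nchar(m)
    if (p == 1L) return(m)
    rots <- vapply(seq_len(p), function(i)
      paste0(substr(m, i, p), substr(m, 1, i - 1L)), character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

## reverse complement of an ACGT motif (helper for strand folding)
revcomp_motif <- function(motif) {
  vapply(motif, function(m) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(m, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## tail-run lengths: T[i] = number of consecutive TRUE values of m starting
## at i (0 where m[i] is FALSE); vectorised via rle + sequence()
tail_run_lengths <- function(m) {
  if (length(m) == 0L) return(integer(0))
  r <- rle(m)
  out <- sequence(r$lengths, from = r$lengths, by = -1L)
  out[rep.int(!r$values, r$lengths)] <- 0L
  out
}

empty_loci <- function() {
  data.frame(sequence_id = character(0), start = integer(0), end = integer(0),
             period = integer(0), motif = character(0),
             canonical_motif = character(0), copies = integer(0),
             stringsAsFactors = FALSE)
}

#' Scan a DNA sequence for perfect 2-6-mer tandem repeats
#'
#' Finds maximal perfect runs of a 2-6 bp motif meeting the per-period
#' minimum complete-copy threshold.  The scan is strictly left-to-right: at
#' each position the longest qualifying run over all allowed periods is
#' emitted (smallest period wins ties), and scanning resumes after its end,
#' so reported loci never overlap.  A run's extent is maximal under the
#' perfectness condition `s[i] == s[i + period]` and therefore may include a
#' partial trailing copy; the copy threshold applies to complete copies
#' (`floor(length/period)`).  Each locus is classed by the primitive
#' (smallest) period of its motif, so `ATATATAT...` is always a 2-mer, never
#' a 4- or 6-mer, and mononucleotide runs are never reported.  Lowercase is
#' folded to uppercase before scanning; any character outside A/C/G/T
#' (including IUPAC ambiguity codes and `N`) terminates a run.
#'
#' Scanning the reverse complement yields loci with mirrored coordinates and
#' identical total bp per period class; per-motif tallies are strand-specific
#' unless `fold_strands = TRUE`, which additionally folds
#' `canonical_motif` over reverse complements.
#'
#' @param sequence_id identifier carried into the output's `sequence_id`.
#' @param seq a single DNA string.
#' @param params a [scan_params()] object.
#' @param fold_strands also canonicalise motifs across strands (the bp
#'   totals used by the comparative analyses are strand-invariant either
#'   way).
#' @return data.frame with columns `sequence_id`, `start`, `end` (0-based
#'   half-open, BED convention), `period`, `motif` (first `period` bases of
#'   the run), `canonical_motif`, `copies`; sorted by `start`.
#' @examples
#' scan_sequence("s", "ACACACACACAC")        # one 2-mer locus, 6 copies
#' scan_sequence("s", "ACACACACAC")          # empty: 5 copies < threshold
#' @export
scan_sequence <- function(sequence_id, seq, params = scan_params(),
                          fold_strands = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!inherits(params, "scan_params")) stop("params must be a scan_params object")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) return(empty_loci())
  x <- charToRaw(seq)
  valid <- x == charToRaw("A") | x == charToRaw("C") |
    x == charToRaw("G") | x == charToRaw("T")

  ## tail-run lengths per offset d: matches of s[i] == s[i+d] between valid chars
  need_d <- sort(unique(c(params$periods, 1L, 2L, 3L)))
  Td <- vector("list", max(need_d))
  for (d in need_d) {
    if (n <= d) { Td[[d]] <- integer(0); next }
    m <- x[seq_len(n - d)] == x[(d + 1L):n] &
      valid[seq_len(n - d)] & valid[(d + 1L):n]
    Td[[d]] <- tail_run_lengths(m)
  }

  ## candidate qualifying starts per period, with primitivity pre-filtered
  cand_start <- integer(0); cand_len <- integer(0); cand_p <- integer(0)
  for (k in seq_along(params$periods)) {
    p <- params$periods[k]
    minc <- params$min_copies[k]
    Tp <- Td[[p]]
    if (length(Tp) == 0L) next
    idx <- which(Tp >= p * (minc - 1L))
    if (length(idx) == 0L) next
    ## drop candidates whose motif has a smaller period (non-primitive)
    prim <- rep(TRUE, length(idx))
    for (d in seq_len(p - 1L)) {
      if (p %% d != 0L) next
      Tdd <- Td[[d]]
      sub <- idx[idx <= length(Tdd)]
      periodic <- logical(length(idx))
      periodic[idx <= length(Tdd)] <- Tdd[sub] >= (p - d)
      prim <- prim & !periodic
    }
    idx <- idx[prim]
    if (length(idx) == 0L) next
    cand_start <- c(cand_start, idx)
    cand_len <- c(cand_len, p + Tp[idx])
    cand_p <- c(cand_p, rep.int(p, length(idx)))
  }
  if (length(cand_start) == 0L) return(empty_loci())

  ## greedy left-to-right selection: longest run, smallest period on ties
  o <- order(cand_start, -cand_len, cand_p)
  cs <- cand_start[o]; cl <- cand_len[o]; cp <- cand_p[o]
  sel <- integer(0)
  i <- 1L
  nc <- length(cs)
  while (i <= nc) {
    s0 <- cs[i]
    ## candidates are sorted so the first at each start is the best there
    sel <- c(sel, i)
    nxt <- s0 + cl[i]
    ## advance to first candidate starting at or after the run's end
    i <- i + 1L
    while (i <= nc && cs[i] < nxt) i <- i + 1L
  }
  st <- cs[sel]; ln <- cl[sel]; pp <- cp[sel]
  motif <- substring(seq, st, st + pp - 1L)
  canon <- canonical_motif(motif)
  if (fold_strands) canon <- pmin(canon, canonical_motif(revcomp_motif(canon)))
  data.frame(sequence_id = rep_len(as.character(sequence_id), length(st)),
             start = st - 1L, end = st - 1L + ln, period = pp,
             motif = motif, canonical_motif = canon,
             copies = ln %/% pp, stringsAsFactors = FALSE)
}

#' Reference scanner (direct character comparison)
#'
#' Transparent re-derivation of [scan_sequence()]: at every position and
#' every allowed period the maximal perfect run is extended by direct
#' character comparison, and the same greedy selection policy is applied.
#' Orders of magnitude slower in spirit (per-position work) but written
#' independently; used to validate the vectorised scanner and to finalise
#' ground-truth locus tables for synthetic genomes.
#'
#' @inheritParams scan_sequence
#' @return same layout as [scan_sequence()].
#' @export
scan_sequence_ref <- function(sequence_id, seq, params = scan_params(),
                              fold_strands = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  res <- .scan_oracle_cpp(seq, params$periods, params$min_copies)
  if (nrow(res) == 0L) return(empty_loci())
  seq <- toupper(seq)
  motif <- substring(seq, res$start + 1L, res$start + res$period)
  canon <- canonical_motif(motif)
  if (fold_strands) canon <- pmin(canon, canonical_motif(revcomp_motif(canon)))
  data.frame(sequence_id = rep_len(as.character(sequence_id), nrow(res)),
             start = res$start, end = res$end, period = res$period,
             motif = motif, canonical_motif = canon, copies = res$copies,
             stringsAsFactors = FALSE)
}

#' Summarise per-genome microsatellite content
#'
#' Aggregates a locus table into the per-genome quantities the comparative
#' analyses consume: bp per period class, total microsatellite bp, content
#' per Mbp of assembly, and the proportion of the assembly that is
#' microsatellite.
#'
#' @param species species or assembly label.
#' @param loci locus table from [scan_sequence()]/[scan_fasta()] (may span
#'   multiple records); loci must not overlap within a record.
#' @param assembly_length total assembly length in bp (> 0), including
#'   ambiguous bases.
#' @param periods period classes to tally (absent classes report 0 bp).
#' @return an object of class `msat_profile`: list with `species`,
#'   `assembly_length`, `bp_by_period` (named numeric), `total_bp`,
#'   `content_per_mbp` (bp per Mbp), `proportion`.
#' @export
summarize_genome <- function(species, loci, assembly_length,
                             periods = 2:6) {
  if (!is.numeric(assembly_length) || length(assembly_length) != 1L ||
      is.na(assembly_length) || assembly_length <= 0)
    stop("assembly_length must be a single positive number")
  bp <- stats::setNames(numeric(length(periods)), as.character(periods))
  if (nrow(loci) > 0L) {
    w <- tapply(loci$end - loci$start, factor(loci$period, levels = periods),
                sum)
    w[is.na(w)] <- 0
    bp[] <- as.numeric(w)
  }
  total <- sum(bp)
  structure(list(species = as.character(species),
                 assembly_length = as.numeric(assembly_length),
                 bp_by_period = bp,
                 total_bp = total,
                 content_per_mbp = total / (assembly_length / 1e6),
                 proportion = total / assembly_length),
            class = "msat_profile")
}

#' @export
print.msat_profile <- function(x, ...) {
  cat(sprintf("Microsatellite profile for %s (assembly %.0f bp)\n",
              x$species, x$assembly_length))
  cat(sprintf("  %smer: %.0f bp\n", names(x$bp_by_period), x$bp_by_period),
      sep = "")
  cat(sprintf("  total: %.0f bp  (%.2f bp/Mbp, proportion %.3g)\n",
              x$total_bp, x$content_per_mbp, x$proportion))
  invisible(x)
}

#' Convert a genome profile to a one-row data.frame
#'
#' @param x an `msat_profile`.
#' @return one-row data.frame with columns `species`, `assembly_length`,
#'   `bp_2mer`..`bp_6mer`, `total_bp`, `content_per_mbp`, `proportion`.
#' @export
profile_row <- function(x) {
  stopifnot(inherits(x, "msat_profile"))
  row <- data.frame(species = x$species, assembly_length = x$assembly_length,
                    stringsAsFactors = FALSE)
  for (p in names(x$bp_by_period))
    row[[paste0("bp_", p, "mer")]] <- unname(x$bp_by_period[p])
  row$total_bp <- x$total_bp
  row$content_per_mbp <- x$content_per_mbp
  row$proportion <- x$proportion
  row
}

#' Scan a FASTA assembly for microsatellites
#'
#' Reads a (optionally gzip-compressed) FASTA file, scans every record with
#' [scan_sequence()], and summarises per-genome content.  Assembly length is
#' the sum of record lengths including ambiguous bases.
#'
#' @param path FASTA file path (plain or gzip).
#' @param params a [scan_params()] object.
#' @param species label for the profile; defaults to the file name without
#'   extensions.
#' @param fold_strands see [scan_sequence()].
#' @return list with `profile` (an `msat_profile`) and `loci` (combined
#'   locus table, record ids in `sequence_id`).
#' @export
scan_fasta <- function(path, params = scan_params(), species = NULL,
                       fold_strands = FALSE) {
  recs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     stop(sprintf("failed to read FASTA '%s': %s", path,
                                  conditionMessage(e)), call. = FALSE))
  if (is.null(species))
    species <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  ids <- sub("\\s.*$", "", names(recs))
  loci <- do.call(rbind, lapply(seq_along(recs), function(i)
    scan_sequence(ids[i], as.character(recs[[i]]), params,
                  fold_strands = fold_strands)))
  if (is.null(loci)) loci <- empty_loci()
  list(profile = summarize_genome(species, loci, sum(Biostrings::width(recs)),
                                  periods = params$periods),
       loci = loci)
}

#' Write a locus table as BED-like TSV
#'
#' Columns: `sequence_id`, `start`, `end` (0-based half-open), `period`,
#' `motif`, `canonical_motif`, `copies`.
#'
#' @param loci locus table.
#' @param path output file.
#' @export
write_loci_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
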