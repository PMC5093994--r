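# Parsers for the standard output dialects of the external detectors.
# All parsers accept either a file path or a character vector of lines,
# return a domain-hit data.frame (see domain_hits), and support two
# row-error policies: "strict" (default) stops at the first malformed row,
# naming its line number; "skip" drops malformed rows with a warning.

as_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1 && grepl("\n", x, fixed = TRUE))
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

row_error <- function(policy, lineno, msg, bad) {
  full <- sprintf("line %d: %s", lineno, msg)
  if (identical(policy, "strict")) stop(full, call. = FALSE)
  bad$msgs <- c(bad$msgs, full)
  NULL
}

flush_row_errors <- function(bad, what) {
  if (length(bad$msgs) > 0)
    warning("skipped ", length(bad$msgs), " malformed ", what, " row(s); ",
            "first: ", bad$msgs[[1]], call. = FALSE)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))
int_or_na <- function(x) suppressWarnings(as.integer(x))

# InterProScan writes member-database names in varying case across versions.
normalize_ipr_source <- function(analysis) {
  key <- c(pfam = "Pfam", gene3d = "Gene3D", smart = "SMART",
           superfamily = "Superfamily", panther = "Panther")
  out <- key[tolower(analysis)]
  ifelse(is.na(out), NA_character_, out)
}

#' Parse InterProScan TSV output
#'
#' Reads the tab-separated InterProScan format (protein accession, md5,
#' length, analysis, signature accession, signature description, start,
#' stop, score, status, date, ...; at least 11 columns) into domain hits.
#' The analysis column becomes the evidence source and the signature
#' accession is mapped to a canonical motif via the signature map; rows from
#' member databases the classifier never consults (anything outside Pfam,
#' Gene3D, SMART, Superfamily, Panther) are dropped, since the evidence
#' vocabulary is closed over those five. Source filtering by analysis mode
#' is *not* done here — that is [mode_filter()]'s job.
#'
#' @param x File path, single string with embedded newlines, or character
#'   vector of lines.
#' @param map Signature map, see [load_signature_map()].
#' @param on_error `"strict"` (stop at first malformed row, with its line
#'   number) or `"skip"` (drop malformed rows with a warning).
#' @return A domain-hit data.frame.
#' @export
parse_interproscan_tsv <- function(x, map = load_signature_map(),
                                   on_error = c("strict", "skip")) {
  on_error <- match.arg(on_error)
  lines <- as_lines(x)
  bad <- new.env(parent = emptyenv()); bad$msgs <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      row_error(on_error, i, sprintf("expected >= 11 tab-separated columns, got %d",
                                     length(f)), bad)
      next
    }
    start <- int_or_na(f[7]); end <- int_or_na(f[8])
    if (is.na(start) || is.na(end)) {
      row_error(on_error, i, "non-numeric start/stop coordinate", bad)
      next
    }
    src <- normalize_ipr_source(f[4])
    if (is.na(src)) next  # member database outside the closed vocabulary
    rows[[i]] <- data.frame(protein_id = f[1], source = src,
                            signature_id = strip_version(f[5]),
                            start = start, end = end,
                            score = num_or_na(f[9]),
                            stringsAsFactors = FALSE)
  }
  flush_row_errors(bad, "InterProScan")
  finish_parse(rows, map)
}

finish_parse <- function(rows, map) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(domain_hits())
  d <- do.call(rbind, rows)
  h <- domain_hits(d$protein_id,
                   map_motif(d$signature_id, d$source, map),
                   d$source, d$signature_id, d$start, d$end, d$score)
  h <- sort_hits(h)
  rownames(h) <- NULL
  h
}

#' Parse pfam_scan output
#'
#' Reads the whitespace-delimited pfam_scan dialect (comment lines start
#' with `#`): seq id, alignment start/end, envelope start/end, hmm acc, hmm
#' name, type, hmm start/end/length, bit score, E-value, significance, clan.
#' Alignment coordinates are used; the hmm accession's version suffix is
#' stripped before signature-map lookup (Pfam-release independence); score is
#' the row's E-value; source is `pfam_scan`.
#'
#' @inheritParams parse_interproscan_tsv
#' @return A domain-hit data.frame, ordered by (protein, start).
#' @export
parse_pfamscan <- function(x, map = load_signature_map(),
                           on_error = c("strict", "skip")) {
  on_error <- match.arg(on_error)
  lines <- as_lines(x)
  bad <- new.env(parent = emptyenv()); bad$msgs <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 13) {
      row_error(on_error, i, sprintf("expected >= 13 columns, got %d", length(f)),
                bad)
      next
    }
    start <- int_or_na(f[2]); end <- int_or_na(f[3]); ev <- num_or_na(f[13])
    if (is.na(start) || is.na(end) || is.na(ev)) {
      row_error(on_error, i, "non-numeric coordinate or E-value", bad)
      next
    }
    rows[[i]] <- data.frame(protein_id = f[1], source = "pfam_scan",
                            signature_id = strip_version(f[6]),
                            start = start, end = end, score = ev,
                            stringsAsFactors = FALSE)
  }
  flush_row_errors(bad, "pfam_scan")
  finish_parse(rows, map)
}

#' Parse Phobius output (short or long format)
#'
#' The dialect is auto-detected per file. Short format is the one-line-per-
#' protein table (id, TM helix count, SP flag, topology string); each
#' `<start>-<end>` membrane segment of the topology becomes one TM hit. Long
#' format uses `FT TRANSMEM <start> <end>` feature lines under an `ID` line.
#' Signal peptides (SP = Y, or `FT SIGNAL` lines) are retained as `UNMAPPED`
#' hits spanning the signal peptide — reported in the domain table but never
#' consulted by classification.
#'
#' @inheritParams parse_interproscan_tsv
#' @return A domain-hit data.frame (motif `TM`, source `phobius`, plus
#'   `UNMAPPED` signal-peptide rows).
#' @export
parse_phobius <- function(x, on_error = c("strict", "skip")) {
  on_error <- match.arg(on_error)
  lines <- as_lines(x)
  long <- any(grepl("^(ID[[:space:]]|FT[[:space:]])", lines))
  if (long) parse_phobius_long(lines, on_error)
  else parse_phobius_short(lines, on_error)
}

parse_phobius_short <- function(lines, on_error) {
  bad <- new.env(parent = emptyenv()); bad$msgs <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    # header line of the short format ("SEQENCE ID ..." in phobius itself)
    if (i == 1 && is.na(int_or_na(f[2]))) next
    if (length(f) < 4) {
      row_error(on_error, i, "expected 4 columns (id, TM, SP, topology)", bad)
      next
    }
    id <- f[1]; ntm <- int_or_na(f[2]); sp <- f[3]; topo <- f[4]
    if (is.na(ntm)) {
      row_error(on_error, i, "non-numeric TM count", bad)
      next
    }
    body <- topo
    sig <- NULL
    if (sp %in% c("Y", "1")) {
      m <- regmatches(topo, regexec("^n[^/]*?([0-9]+)/([0-9]+)", topo))[[1]]
      if (length(m) == 0) {
        row_error(on_error, i, "signal-peptide topology cannot be tokenized", bad)
        next
      }
      cut <- as.integer(m[2])
      sig <- data.frame(protein_id = id, motif = "UNMAPPED",
                        source = "phobius", signature_id = "SIGNAL",
                        start = 1L, end = cut, score = NA_real_,
                        stringsAsFactors = FALSE)
      body <- sub("^n[^/]*?[0-9]+/[0-9]+", "", topo)
    }
    spans <- regmatches(body, gregexpr("[0-9]+-[0-9]+", body))[[1]]
    if (length(spans) != ntm) {
      row_error(on_error, i,
                sprintf("topology has %d membrane segments but TM column says %d",
                        length(spans), ntm), bad)
      next
    }
    tm <- NULL
    if (ntm > 0) {
      se <- do.call(rbind, strsplit(spans, "-", fixed = TRUE))
      tm <- data.frame(protein_id = id, motif = "TM", source = "phobius",
                       signature_id = "TRANSMEM",
                       start = as.integer(se[, 1]), end = as.integer(se[, 2]),
                       score = NA_real_, stringsAsFactors = FALSE)
    }
    rows[[i]] <- rbind(sig, tm)
  }
  flush_row_errors(bad, "Phobius")
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(domain_hits())
  h <- do.call(rbind, rows)
  h <- sort_hits(validate_hits(h))
  rownames(h) <- NULL
  h
}

parse_phobius_long <- function(lines, on_error) {
  bad <- new.env(parent = emptyenv()); bad$msgs <- character(0)
  cur <- NA_character_
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "ID")) {
      cur <- strsplit(ln, "[[:space:]]+")[[1]][2]
    } else if (startsWith(ln, "FT")) {
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(f) < 4 || !f[2] %in% c("TRANSMEM", "SIGNAL")) next
      start <- int_or_na(f[3]); end <- int_or_na(f[4])
      if (is.na(start) || is.na(end) || is.na(cur)) {
        row_error(on_error, i, "malformed feature line", bad)
        next
      }
      motif <- if (f[2] == "TRANSMEM") "TM" else "UNMAPPED"
      rows[[i]] <- data.frame(protein_id = cur, motif = motif,
                              source = "phobius", signature_id = f[2],
                              start = start, end = end, score = NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  flush_row_errors(bad, "Phobius")
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(domain_hits())
  h <- do.call(rbind, rows)
  h <- sort_hits(validate_hits(h))
  rownames(h) <- NULL
  h
}

#' Parse a coiled-coil segment table
#'
#' Reads the 4-column whitespace-delimited segment table (protein id, start,
#' end, maximum probability) written by [detect_cc_segments()] /
#' [write_cc_segments()] or by an external coiled-coil scanner exported in
#' the same dialect. Each segment becomes one CC hit with the segment's
#' probability as its score.
#'
#' @inheritParams parse_interproscan_tsv
#' @return A domain-hit data.frame (motif `CC`, source `coils`).
#' @export
parse_coils_segments <- function(x, on_error = c("strict", "skip")) {
  on_error <- match.arg(on_error)
  lines <- as_lines(x)
  bad <- new.env(parent = emptyenv()); bad$msgs <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 4) {
      row_error(on_error, i, "expected 4 columns (id, start, end, probability)",
                bad)
      next
    }
    start <- int_or_na(f[2]); end <- int_or_na(f[3]); p <- num_or_na(f[4])
    if (is.na(start) || is.na(end) || is.na(p)) {
      row_error(on_error, i, "non-numeric coordinate or probability", bad)
      next
    }
    if (p < 0 || p > 1) {
      row_error(on_error, i, sprintf("probability %g outside [0, 1]", p), bad)
      next
    }
    rows[[i]] <- data.frame(protein_id = f[1], motif = "CC", source = "coils",
                            signature_id = "COILS", start = start, end = end,
                            score = p, stringsAsFactors = FALSE)
  }
  flush_row_errors(bad, "coiled-coil segment")
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(domain_hits())
  h <- do.call(rbind, rows)
  h <- sort_hits(validate_hits(h))
  rownames(h) <- NULL
  h
}
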