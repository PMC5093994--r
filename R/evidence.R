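#' Construct a table of domain hits
#'
#' A domain hit is one detected domain/motif instance on a protein. Hits are
#' kept as a plain data.frame with one row per hit; coordinates are 1-based
#' inclusive protein positions, the convention of InterProScan and pfam_scan
#' output, used throughout the package.
#'
#' @param protein_id Character vector.
#' @param motif Canonical motif labels, from [RGA_MOTIFS].
#' @param source Evidence sources, from [RGA_SOURCES].
#' @param signature_id Raw signature accessions (version suffix already
#'   stripped where applicable).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param score E-value or probability; `NA` when the source reports none.
#' @return A data.frame with the seven columns above.
#' @export
domain_hits <- function(protein_id = character(0), motif = character(0),
                        source = character(0), signature_id = character(0),
                        start = integer(0), end = integer(0),
                        score = rep(NA_real_, length(protein_id))) {
  h <- data.frame(protein_id = as.character(protein_id),
                  motif = as.character(motif),
                  source = as.character(source),
                  signature_id = as.character(signature_id),
                  start = as.integer(start), end = as.integer(end),
                  score = as.numeric(score),
                  stringsAsFactors = FALSE)
  validate_hits(h)
  h
}

validate_hits <- function(h) {
  stopifnot(is.data.frame(h))
  need <- c("protein_id", "motif", "source", "signature_id", "start", "end",
            "score")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0)
    stop("hit table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(h$motif), RGA_MOTIFS)
  if (length(bad) > 0)
    stop("unknown motif label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(h$source), RGA_SOURCES)
  if (length(bad) > 0)
    stop("unknown evidence source(s): ", paste(bad, collapse = ", "))
  if (nrow(h) > 0 && any(h$start < 1 | h$end < h$start))
    stop("invalid coordinates: need 1 <= start <= end")
  invisible(h)
}

sort_hits <- function(h) {
  h[order(h$protein_id, h$start, h$end, h$source, h$signature_id,
          method = "radix"), , drop = FALSE]
}

#' Merge domain-hit lists into an evidence set
#'
#' Groups hits from any number of parses by protein, deduplicates identical
#' hits (same protein, motif, source, start, end — the first occurrence is
#' kept), and fixes a deterministic within-protein order
#' (start, end, source). Proteins present in `lengths` but without hits are
#' retained with an empty hit list, so downstream classification sees the
#' whole input proteome.
#'
#' Hits extending beyond a known protein length are retained but flagged
#' (`clamped` column), with a warning.
#'
#' @param ... Hit data.frames (as produced by the parsers), or a single list
#'   of them.
#' @param lengths Named integer vector, protein id -> length. Optional
#'   (`NULL` means unknown lengths; protein universe is then taken from the
#'   hits alone). The order of `lengths` defines the protein order of the
#'   set, matching input FASTA order in the pipeline.
#' @return An `evidence_set`: list with elements `proteins` (ordered id
#'   vector), `lengths` (named integer, `NA` when unknown) and `hits` (one
#'   data.frame, sorted, with a logical `clamped` column).
#' @examples
#' h <- domain_hits("p1", "NB-ARC", "Pfam", "PF00931", 10L, 200L)
#' es <- merge_evidence(h, h, lengths = c(p1 = 400L, p2 = 120L))
#' nrow(es$hits)        # 1 — duplicates collapsed
#' es$proteins          # "p1" "p2"
#' @export
merge_evidence <- function(..., lengths = NULL) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]]))
    lists <- lists[[1]]
  lists <- Filter(function(x) !is.null(x), lists)
  hits <- if (length(lists) == 0) domain_hits() else do.call(rbind, lists)
  validate_hits(hits)

  key <- paste(hits$protein_id, hits$motif, hits$source, hits$start, hits$end,
               sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- sort_hits(hits)
  rownames(hits) <- NULL

  prot <- unique(c(names(lengths), hits$protein_id))
  len <- rep(NA_integer_, length(prot))
  names(len) <- prot
  if (!is.null(lengths)) len[names(lengths)] <- as.integer(lengths)

  known <- len[hits$protein_id]
  hits$clamped <- !is.na(known) & hits$end > known
  if (any(hits$clamped))
    warning(sum(hits$clamped), " hit(s) extend beyond the known protein ",
            "length; retained and flagged as clamped")

  structure(list(proteins = prot, lengths = len, hits = hits),
            class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat("evidence_set: ", length(x$proteins), " protein(s), ",
      nrow(x$hits), " domain hit(s)\n", sep = "")
  if (nrow(x$hits) > 0) {
    tab <- table(x$hits$motif)
    cat("  motifs:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read the unified domain table
#'
#' The pipeline's plain-text export of all domain evidence: tab-separated
#' with columns protein_id, motif, source, signature_id, start, end, score.
#' Writing then re-reading (with the same lengths) reproduces an identical
#' evidence set.
#'
#' @param evidence An `evidence_set`.
#' @param path Output (or input) file path.
#' @return `write_domain_table` returns `path` invisibly;
#'   `read_domain_table` returns a hit data.frame suitable for
#'   [merge_evidence()].
#' @export
write_domain_table <- function(evidence, path) {
  h <- evidence$hits
  out <- h[, c("protein_id", "motif", "source", "signature_id", "start",
               "end", "score")]
  out$score <- ifelse(is.na(out$score), "NA", format(out$score, digits = 15,
                                                     scientific = TRUE,
                                                     trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_domain_table
#' @export
read_domain_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "character",
                                        "character", "integer", "integer",
                                        "character"),
                         quote = "", stringsAsFactors = FALSE)
  d$score <- suppressWarnings(as.numeric(d$score))
  domain_hits(d$protein_id, d$motif, d$source, d$signature_id, d$start,
              d$end, d$score)
}
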