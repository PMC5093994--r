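# Initial similarity-based filtering: most proteins of a proteome are not
# RGAs, so aligning against a curated resistance-protein reference set and
# keeping only queries with a sub-cutoff BLASTP hit removes the bulk of the
# input before the (expensive) domain-detection stage.

#' Construct annotation records
#'
#' A minimal record for reference-set curation: an id, a free-text
#' description line, and an amino-acid sequence.
#'
#' @param record_id,description,sequence Character vectors of equal length.
#' @return A data.frame with those three columns.
#' @export
annotation_records <- function(record_id, description, sequence) {
  data.frame(record_id = as.character(record_id),
             description = as.character(description),
             sequence = as.character(sequence),
             stringsAsFactors = FALSE)
}

#' Read / write annotation records as FASTA
#'
#' The description is everything after the first whitespace of the header
#' line; the id is the first token.
#'
#' @param path FASTA file path.
#' @param records A record data.frame, see [annotation_records()].
#' @export
read_annotation_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- names(aa)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  annotation_records(id, desc, as.character(aa))
}

#' @rdname read_annotation_fasta
#' @export
write_annotation_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$record_id, records$description),
                      records$record_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Curate a resistance-protein reference set by keyword
#'
#' Applies the reference-database curation rules: records without any
#' annotation (empty description) are removed; a record is retained only if
#' its description contains at least one include keyword and none of the
#' exclude keywords (case-insensitive substring match); exact duplicate
#' sequences are collapsed, keeping the first-seen record. The defaults
#' retrieve disease-resistance entries while discarding resistance to
#' abiotic stresses (aluminum, drought, cold, DNA damage, herbicide, UVB)
#' that the keywords would otherwise sweep in.
#'
#' The operation is idempotent: curating an already-curated set changes
#' nothing.
#'
#' @param records A record data.frame ([annotation_records()]).
#' @param include Keywords, at least one of which must occur. Must be
#'   non-empty.
#' @param exclude Keywords, none of which may occur.
#' @return The retained records, original order preserved.
#' @examples
#' r <- annotation_records(c("a", "b"),
#'                         c("TIR-NBS-LRR disease resistance protein",
#'                           "aluminum resistance protein ALS3"),
#'                         c("MKV", "MLA"))
#' curate_reference(r)$record_id   # "a"
#' @export
curate_reference <- function(records,
                             include = c("resistance", "disease"),
                             exclude = c("aluminum", "aluminium", "drought",
                                         "cold", "DNA-damage", "herbicide",
                                         "UVB")) {
  if (length(include) == 0)
    stop("include keyword list must not be empty")
  desc <- tolower(records$description)
  keep <- nzchar(trimws(records$description))
  has_any <- function(d, kw) {
    m <- rep(FALSE, length(d))
    for (k in tolower(kw)) m <- m | grepl(k, d, fixed = TRUE)
    m
  }
  keep <- keep & has_any(desc, include)
  if (length(exclude) > 0) keep <- keep & !has_any(desc, exclude)
  out <- records[keep, , drop = FALSE]
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge curated reference sets
#'
#' Concatenates already-curated sets in order and removes exact duplicate
#' sequences globally, keeping the first occurrence (set order, then
#' within-set order). Colliding record ids on distinct sequences are made
#' unique.
#'
#' @param sets A list of record data.frames.
#' @return One merged record data.frame.
#' @export
merge_reference_sets <- function(sets) {
  if (length(sets) == 0)
    return(annotation_records(character(0), character(0), character(0)))
  out <- do.call(rbind, sets)
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  out$record_id <- make.unique(out$record_id, sep = "_")
  rownames(out) <- NULL
  out
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the 12-column tab-separated BLAST dialect: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' E-values in scientific notation ("3e-42") and "0.0" parse exactly.
#'
#' @inheritParams parse_interproscan_tsv
#' @return A data.frame of alignment hits with those 12 columns.
#' @export
parse_blast_tabular <- function(x, on_error = c("strict", "skip")) {
  on_error <- match.arg(on_error)
  lines <- as_lines(x)
  bad <- new.env(parent = emptyenv()); bad$msgs <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 12) {
      row_error(on_error, i, sprintf("expected 12 tab-separated columns, got %d",
                                     length(f)), bad)
      next
    }
    nums <- num_or_na(f[3:12])
    if (anyNA(nums)) {
      row_error(on_error, i, "non-numeric field", bad)
      next
    }
    rows[[i]] <- data.frame(query_id = f[1], subject_id = f[2],
                            pct_identity = nums[1], aln_len = as.integer(nums[2]),
                            mismatches = as.integer(nums[3]),
                            gap_opens = as.integer(nums[4]),
                            q_start = as.integer(nums[5]),
                            q_end = as.integer(nums[6]),
                            s_start = as.integer(nums[7]),
                            s_end = as.integer(nums[8]),
                            evalue = nums[9], bitscore = nums[10],
                            stringsAsFactors = FALSE)
  }
  flush_row_errors(bad, "BLAST tabular")
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), aln_len = integer(0),
                      mismatches = integer(0), gap_opens = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (any(out$evalue < 0)) stop("negative E-value in BLAST tabular input")
  rownames(out) <- NULL
  out
}

#' Retain RGA candidates by E-value prefilter
#'
#' A query is retained iff it has at least one alignment with
#' `evalue <= cutoff` (inclusive comparison, the BLAST community norm; any
#' hit qualifies, not only the best one, since the filter operates on
#' proteins, not alignments). The default cutoff of 1e-5 may be adjusted per
#' species.
#'
#' @param hits BLAST hit data.frame from [parse_blast_tabular()].
#' @param cutoff E-value cutoff, > 0. Default `1e-5`.
#' @param total Optional total number of input queries (the proteome size),
#'   used to report the retained fraction.
#' @return A list with `retained` (unique query ids, in first-appearance
#'   order) and `retained_fraction` (`NA` when `total` is not given).
#' @examples
#' h <- parse_blast_tabular(c("q1\ts1\t40\t200\t100\t2\t1\t200\t1\t200\t1e-30\t150",
#'                            "q2\ts1\t30\t150\t90\t3\t1\t150\t1\t150\t0.1\t40"))
#' filter_candidates(h, total = 10)$retained   # "q1"
#' @export
filter_candidates <- function(hits, cutoff = 1e-5, total = NULL) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  keep <- hits$query_id[hits$evalue <= cutoff]
  retained <- unique(keep)
  frac <- if (is.null(total)) NA_real_ else length(retained) / total
  list(retained = retained, retained_fraction = frac)
}

#' Write a retained-id list
#'
#' One id per line, plain text.
#' @param ids Character vector.
#' @param path Output path.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
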