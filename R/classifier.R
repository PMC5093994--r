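# Domain-architecture classification: reduce a protein's evidence to seven
# presence flags (NB-ARC, TIR, CC, LRR, LysM, kinase, TM) and run an ordered
# decision tree. The NBS branch (anything with NB-ARC or TIR) is evaluated
# before the membrane branch, so a protein with NB-ARC or TIR is never
# assigned RLP/RLK/TM-CC regardless of a TM helix.

#' Evidence-source modes
#'
#' Which annotation databases contribute domain hits. `quick` uses Pfam and
#' Gene3D through InterProScan; `deep` additionally consults SMART and
#' Superfamily; `free` is a user-chosen source set. The three dedicated
#' channels — pfam_scan (NB-ARC), phobius (TM) and coils (CC) — are always
#' active in quick and deep: they sit outside the InterProScan database
#' choice.
#'
#' @param name `"quick"`, `"deep"` or `"free"`.
#' @param sources For `free` mode only: a non-empty subset of
#'   [RGA_SOURCES].
#' @return A list of class `rga_mode` with `name` and `active_sources`.
#' @examples
#' rga_mode("quick")$active_sources
#' rga_mode("free", sources = c("Pfam", "Panther", "phobius"))
#' @export
rga_mode <- function(name = c("quick", "deep", "free"), sources = NULL) {
  name <- match.arg(name)
  dedicated <- c("pfam_scan", "phobius", "coils")
  active <- switch(name,
    quick = c("Pfam", "Gene3D", dedicated),
    deep  = c("Pfam", "Gene3D", "SMART", "Superfamily", dedicated),
    free  = {
      if (is.null(sources) || length(sources) == 0)
        stop("free mode requires a non-empty source set")
      bad <- setdiff(sources, RGA_SOURCES)
      if (length(bad) > 0)
        stop("unknown source(s) in free mode: ", paste(bad, collapse = ", "))
      unique(sources)
    })
  structure(list(name = name, active_sources = active), class = "rga_mode")
}

#' Filter an evidence set by mode
#'
#' Only hits whose source is in the mode's active set survive; protein keys
#' and lengths are untouched, so proteins whose every hit is filtered away
#' remain (with an empty hit list) and classify as non-RGA.
#'
#' @param evidence An `evidence_set` from [merge_evidence()].
#' @param mode An [rga_mode()].
#' @return The filtered `evidence_set`.
#' @export
mode_filter <- function(evidence, mode = rga_mode("quick")) {
  stopifnot(inherits(evidence, "evidence_set"), inherits(mode, "rga_mode"))
  evidence$hits <- evidence$hits[evidence$hits$source %in% mode$active_sources,
                                 , drop = FALSE]
  rownames(evidence$hits) <- NULL
  evidence
}

#' Summarize hits into the seven presence flags
#'
#' Each flag is true iff at least one hit carries that canonical motif;
#' `UNMAPPED` hits set no flag. Counting and coordinates play no role.
#'
#' @param hits A domain-hit data.frame for one protein (already
#'   mode-filtered).
#' @return A named logical vector
#'   `c(nb, tir, cc, lrr, lysm, kinase, tm)`.
#' @export
flags_from_evidence <- function(hits) {
  m <- unique(hits$motif)
  c(nb = "NB-ARC" %in% m, tir = "TIR" %in% m, cc = "CC" %in% m,
    lrr = "LRR" %in% m, lysm = "LysM" %in% m, kinase = "KINASE" %in% m,
    tm = "TM" %in% m)
}

#' Classify domain-architecture flags into an RGA class
#'
#' The ordered decision tree; the first matching rule wins:
#'
#' 1. TIR and CC -> `OTHER` (chimeric architecture, worth manual review)
#' 2. TIR, NB-ARC and LRR -> `TNL`
#' 3. TIR and NB-ARC -> `TN`
#' 4. TIR -> `TX` (TIR with unknown companions)
#' 5. NB-ARC, CC and LRR -> `CNL`
#' 6. NB-ARC and CC -> `CN`
#' 7. NB-ARC and LRR -> `NL`
#' 8. NB-ARC -> `NBS`
#' 9. TM, kinase and an ectodomain (LRR or LysM) -> `RLK`
#' 10. TM and an ectodomain -> `RLP`
#' 11. TM and CC -> `TMCC`
#' 12. otherwise -> `NONRGA` (no NB-ARC, TIR or qualifying TM: discarded)
#'
#' The function is total and deterministic over all 128 flag combinations,
#' and vectorized: all arguments recycle to a common length.
#'
#' With `strict_rlk = TRUE` (default), RLK demands an extracellular sensing
#' domain in addition to TM + kinase, mirroring the receptor-like kinase
#' architecture (ectodomain, transmembrane region, intracellular kinase);
#' this is stricter than some genome annotations. With `strict_rlk = FALSE`
#' TM + kinase alone qualifies.
#'
#' @param nb,tir,cc,lrr,lysm,kinase,tm Logical vectors (recycled).
#' @param strict_rlk Require an LRR/LysM ectodomain for RLK.
#' @return Character vector of labels from [RGA_CLASSES].
#' @examples
#' classify_flags(nb = TRUE, cc = TRUE, lrr = TRUE)        # "CNL"
#' classify_flags(tir = TRUE, cc = TRUE)                   # "OTHER"
#' classify_flags(tm = TRUE, kinase = TRUE, lrr = TRUE)    # "RLK"
#' classify_flags()                                        # "NONRGA"
#' @export
classify_flags <- function(nb = FALSE, tir = FALSE, cc = FALSE, lrr = FALSE,
                           lysm = FALSE, kinase = FALSE, tm = FALSE,
                           strict_rlk = TRUE) {
  n <- max(length(nb), length(tir), length(cc), length(lrr), length(lysm),
           length(kinase), length(tm))
  nb <- rep_len(as.logical(nb), n); tir <- rep_len(as.logical(tir), n)
  cc <- rep_len(as.logical(cc), n); lrr <- rep_len(as.logical(lrr), n)
  lysm <- rep_len(as.logical(lysm), n)
  kinase <- rep_len(as.logical(kinase), n)
  tm <- rep_len(as.logical(tm), n)

  ecto <- lrr | lysm
  rlk_ok <- if (strict_rlk) kinase & ecto else kinase
  out <- rep("NONRGA", n)
  rules <- list(
    list(tir & cc,          "OTHER"),
    list(tir & nb & lrr,    "TNL"),
    list(tir & nb,          "TN"),
    list(tir,               "TX"),
    list(nb & cc & lrr,     "CNL"),
    list(nb & cc,           "CN"),
    list(nb & lrr,          "NL"),
    list(nb,                "NBS"),
    list(tm & rlk_ok,       "RLK"),
    list(tm & ecto,         "RLP"),
    list(tm & cc,           "TMCC"))
  assigned <- rep(FALSE, n)
  for (r in rules) {
    fire <- r[[1]] & !assigned
    out[fire] <- r[[2]]
    assigned <- assigned | fire
  }
  out
}

#' Classify every protein of an evidence set
#'
#' Applies [mode_filter()], reduces each protein's hits to presence flags
#' and runs the decision tree. Row order follows the evidence set's protein
#' order (input FASTA order in the pipeline).
#'
#' @param evidence An `evidence_set`.
#' @param mode An [rga_mode()]; default quick.
#' @param strict_rlk See [classify_flags()].
#' @return A data.frame with columns `protein_id`, `class`, `family`,
#'   `domains` (present motifs joined by `;` in canonical order), and the
#'   seven logical flag columns.
#' @export
classify_all <- function(evidence, mode = rga_mode("quick"),
                         strict_rlk = TRUE) {
  ev <- mode_filter(evidence, mode)
  prot <- ev$proteins
  if (length(prot) == 0)
    return(data.frame(protein_id = character(0), class = character(0),
                      family = character(0), domains = character(0),
                      nb = logical(0), tir = logical(0), cc = logical(0),
                      lrr = logical(0), lysm = logical(0),
                      kinase = logical(0), tm = logical(0),
                      stringsAsFactors = FALSE))
  byprot <- split(ev$hits$motif, factor(ev$hits$protein_id, levels = prot))
  flagmat <- t(vapply(prot, function(p) {
    m <- byprot[[p]]
    c(nb = "NB-ARC" %in% m, tir = "TIR" %in% m, cc = "CC" %in% m,
      lrr = "LRR" %in% m, lysm = "LysM" %in% m, kinase = "KINASE" %in% m,
      tm = "TM" %in% m)
  }, logical(7)))
  cls <- classify_flags(flagmat[, "nb"], flagmat[, "tir"], flagmat[, "cc"],
                        flagmat[, "lrr"], flagmat[, "lysm"],
                        flagmat[, "kinase"], flagmat[, "tm"],
                        strict_rlk = strict_rlk)
  canon <- c("CC", "TIR", "NB-ARC", "LRR", "LysM", "KINASE", "TM")
  flagcanon <- c("cc", "tir", "nb", "lrr", "lysm", "kinase", "tm")
  domains <- apply(flagmat[, flagcanon, drop = FALSE], 1,
                   function(f) paste(canon[f], collapse = ";"))
  out <- data.frame(protein_id = prot, class = cls, family = rga_family(cls),
                    domains = domains, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flagmat))
  rownames(out) <- NULL
  out
}
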