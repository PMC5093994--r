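# Built-in coiled-coil detection by sliding-window heptad scoring.
#
# Coiled coils show a seven-residue (heptad) periodicity, positions labelled
# a..g, with hydrophobic residues at a and d. The scorer slides a window
# along the sequence; for each placement and each of the 7 possible heptad
# frames the window score is the (weighted) geometric mean of per-position
# residue propensities; a residue's score is the best window score over all
# windows covering it and all frames. Scores are converted to coiled-coil
# probabilities via the ratio of two Gaussian score densities (coiled-coil
# vs globular), and maximal above-threshold runs become CC segments.

#' Load the default (synthetic) coiled-coil propensity table
#'
#' The shipped table is a synthetic stand-in constructed from heptad
#' biology, not a published matrix; see the file header of
#' `extdata/coils_propensities_synthetic.tsv`. Any table with rows named by
#' residue and 7 columns (heptad positions a..g) can be supplied to
#' [coils_params()] instead.
#'
#' @param path Path to a tab-separated table, first column residue letters,
#'   then 7 propensity columns.
#' @return A numeric matrix, rownames = residues, 7 columns `a`..`g`.
#' @export
load_coils_propensities <- function(path = system.file(
    "extdata", "coils_propensities_synthetic.tsv", package = "rgascan")) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[, 1]
  colnames(m) <- letters[1:7]
  storage.mode(m) <- "double"
  m
}

#' Coiled-coil detection parameters
#'
#' @param propensity_table Numeric matrix, rows named by residue, 7 columns
#'   (heptad positions a..g), all entries > 0. Default: the shipped
#'   synthetic table ([load_coils_propensities()]).
#' @param window Window length in residues, >= 14 (two heptads).
#'   Default 21, the conventional three-heptad window.
#' @param position_weights Multiplicative weights per heptad position
#'   (length 7). Default all 1; a common alternative up-weights the core
#'   positions a and d (e.g. 2.5).
#' @param gaussian_cc,gaussian_gl `c(mean, sd)` of window scores in coiled
#'   coils resp. globular proteins; the probability is the ratio of the two
#'   normal densities. Defaults are calibrated to the shipped synthetic
#'   table (ideal heptads ~2.4, random sequence ~0.8).
#' @param prob_threshold Per-residue probability needed to call a coil,
#'   in \[0, 1\]. Default 0.9, the community convention.
#' @param min_segment_len Minimum segment length in residues. Default 7,
#'   one heptad.
#' @return A list of class `coils_params`.
#' @export
coils_params <- function(propensity_table = load_coils_propensities(),
                         window = 21L,
                         position_weights = rep(1, 7),
                         gaussian_cc = c(mean = 2.4, sd = 0.3),
                         gaussian_gl = c(mean = 0.8, sd = 0.25),
                         prob_threshold = 0.9,
                         min_segment_len = 7L) {
  stopifnot(is.matrix(propensity_table), ncol(propensity_table) == 7,
            all(propensity_table > 0), !is.null(rownames(propensity_table)))
  window <- as.integer(window)
  if (window < 14) stop("window must be >= 14 residues (two heptads)")
  stopifnot(length(position_weights) == 7, all(position_weights > 0),
            length(gaussian_cc) == 2, length(gaussian_gl) == 2,
            gaussian_cc[2] > 0, gaussian_gl[2] > 0,
            prob_threshold >= 0, prob_threshold <= 1, min_segment_len >= 1)
  structure(list(propensity_table = propensity_table, window = window,
                 position_weights = as.numeric(position_weights),
                 gaussian_cc = as.numeric(gaussian_cc),
                 gaussian_gl = as.numeric(gaussian_gl),
                 prob_threshold = prob_threshold,
                 min_segment_len = as.integer(min_segment_len)),
            class = "coils_params")
}

#' Score a protein for coiled-coil propensity
#'
#' For every window placement and every heptad frame, the window score is
#' the weighted geometric mean of per-position propensities; each residue's
#' score is the maximum window score over all windows covering it and all 7
#' frames. Proteins shorter than the window score 0 everywhere.
#'
#' Residue `X` is neutral (propensity 1 at every position, even if absent
#' from the table); any other residue missing from the table is an error
#' naming its position.
#'
#' @param sequence Amino-acid string (or anything `as.character` turns into
#'   one).
#' @param params A [coils_params()] object.
#' @param protein_id Identifier carried into the profile.
#' @return A `coils_profile`: list with `protein_id`, `length`, `score`
#'   (per-residue numeric) and `probability` (filled by
#'   [coils_probability()], `NULL` until then).
#' @export
coils_score <- function(sequence, params = coils_params(),
                        protein_id = "protein") {
  seq <- toupper(as.character(sequence)[1])
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(res)
  prof <- structure(list(protein_id = protein_id, length = L,
                         score = numeric(L), probability = NULL),
                    class = "coils_profile")
  if (L == 0) return(prof)

  tab <- params$propensity_table
  ridx <- match(res, rownames(tab))
  miss <- which(is.na(ridx) & res != "X")
  if (length(miss) > 0)
    stop(sprintf("illegal residue '%s' at position %d", res[miss[1]],
                 miss[1]))
  W <- params$window
  if (L < W) return(prof)  # too short: all-zero scores by convention

  # log-propensity per residue for each of the 7 frames; X is neutral (log 1)
  logtab <- log(tab)
  best <- rep(-Inf, L)
  w <- params$position_weights
  for (f in 0:6) {
    hp <- ((f + seq_len(L) - 1L) %% 7L) + 1L          # heptad position/residue
    v <- ifelse(is.na(ridx), 0, logtab[cbind(ridx, hp)])
    wi <- w[hp]
    cnum <- cumsum(c(0, v * wi))
    cden <- cumsum(c(0, wi))
    s <- seq_len(L - W + 1L)
    wscore <- (cnum[s + W] - cnum[s]) / (cden[s + W] - cden[s])
    # residue max over covering windows: running max over W shifted copies
    for (off in 0:(W - 1L)) {
      idx <- s + off                                   # residues covered
      best[idx] <- pmax(best[idx], wscore)
    }
  }
  prof$score <- exp(best)
  prof
}

#' Convert coiled-coil scores to probabilities
#'
#' Per-residue probability `P = Gcc / (Gcc + Ggl)` where `Gcc` and `Ggl`
#' are the normal densities of the residue's score under the coiled-coil
#' and globular score models. Proteins shorter than the window get
#' probability 0 everywhere.
#'
#' @param profile A `coils_profile` from [coils_score()].
#' @param params A [coils_params()] object.
#' @return The profile with its `probability` field filled.
#' @export
coils_probability <- function(profile, params = coils_params()) {
  s <- profile$score
  if (profile$length == 0 || all(s == 0)) {
    profile$probability <- numeric(profile$length)
    return(profile)
  }
  lcc <- stats::dnorm(s, params$gaussian_cc[1], params$gaussian_cc[2],
                      log = TRUE)
  lgl <- stats::dnorm(s, params$gaussian_gl[1], params$gaussian_gl[2],
                      log = TRUE)
  profile$probability <- 1 / (1 + exp(lgl - lcc))
  profile
}

#' Call coiled-coil segments from a probability profile
#'
#' Maximal runs of residues with probability >= `prob_threshold` and length
#' >= `min_segment_len`, each emitted as one CC domain hit whose score is
#' the run's maximum probability.
#'
#' @inheritParams coils_probability
#' @return A domain-hit data.frame (motif `CC`, source `coils`).
#' @export
detect_cc_segments <- function(profile, params = coils_params()) {
  if (is.null(profile$probability))
    profile <- coils_probability(profile, params)
  p <- profile$probability
  if (length(p) == 0) return(domain_hits())
  r <- rle(p >= params$prob_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_segment_len
  if (!any(keep)) return(domain_hits())
  starts <- starts[keep]; ends <- ends[keep]
  score <- vapply(seq_along(starts),
                  function(i) max(p[starts[i]:ends[i]]), numeric(1))
  domain_hits(rep(profile$protein_id, length(starts)), "CC", "coils",
              "COILS", starts, ends, score)
}

#' Scan a set of proteins for coiled-coil segments
#'
#' Convenience wrapper: score, convert to probability and call segments for
#' every sequence.
#'
#' @param sequences An `AAStringSet` or named character vector.
#' @param params A [coils_params()] object.
#' @return A domain-hit data.frame with all CC segments.
#' @export
scan_coils <- function(sequences, params = coils_params()) {
  ids <- names(sequences)
  seqs <- as.character(sequences)
  if (is.null(ids)) ids <- paste0("protein", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)
  hits <- lapply(seq_along(seqs), function(i) {
    prof <- coils_score(seqs[[i]], params, protein_id = ids[[i]])
    detect_cc_segments(coils_probability(prof, params), params)
  })
  out <- do.call(rbind, c(hits, list(domain_hits())))
  rownames(out) <- NULL
  out
}

#' Write coiled-coil segments as the 4-column segment table
#'
#' The dialect read back by [parse_coils_segments()]: protein id, start,
#' end, maximum probability, whitespace-delimited.
#'
#' @param hits A domain-hit data.frame of CC hits.
#' @param path Output path.
#' @export
write_cc_segments <- function(hits, path) {
  cc <- hits[hits$motif == "CC", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", cc$protein_id, cc$start, cc$end,
                   format(cc$score, digits = 6, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
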