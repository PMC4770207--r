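#' Build the off-target search query for a cut-site
#'
#' The target region around the cut-site covering the maximal possible
#' arm-binding sites: `arm_max + 3 + arm_max` nt centered on the NUH
#' triplet, clipped at the sequence ends (a 23-nt query at the default
#' maximal arm length of 10).
#'
#' @param target a [target_transcript()].
#' @param site one row of [find_cut_sites()] output.
#' @param params a [design_params()] (supplies `arm_max`).
#' @return list with `query` (RNA string, always containing the triplet)
#'   and `site_offset` (0-based offset of the N of the triplet within the
#'   query).
#' @export
build_query <- function(target, site, params = design_params()) {
  w <- site_window(target, site, params$arm_max)
  list(query = substr(target$sequence, w$start + 1L, w$end),
       site_offset = as.integer(site$index) - w$start)
}

.read_reference <- function(transcriptome) {
  if (inherits(transcriptome, "XStringSet")) {
    seqs <- as.character(transcriptome)
  } else if (is.character(transcriptome) && length(transcriptome) == 1L &&
             is.null(names(transcriptome))) {
    if (!file.exists(transcriptome)) {
      stop("transcriptome file not found: ", transcriptome)
    }
    set <- Biostrings::readBStringSet(transcriptome)
    seqs <- as.character(set)
    names(seqs) <- names(set)
  } else if (is.character(transcriptome)) {
    seqs <- transcriptome
  } else stop("unsupported transcriptome input")
  if (length(seqs) && is.null(names(seqs))) {
    names(seqs) <- paste0("record", seq_along(seqs))
  }
  if (!length(seqs)) return(setNames(character(0), character(0)))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  vapply(seqs, as_rna, "", USE.NAMES = TRUE)
}

#' Off-target specificity of a cut-site query
#'
#' Scans every record of a reference transcriptome for ungapped local
#' matches to the query, weighting each hit by its matched-pair fraction
#' (a perfect match weighs 1). Hits on predicted records (accessions
#' starting `XM`/`XR`) are reported but excluded from the score, as are
#' hits that could not be cleaved when `mode = "cleavage_only"` (no U at
#' the aligned U-position or G at the aligned H-position). The score is
#' the sum of counted weights: 1 is optimal (the intended site only);
#' larger values flag potential off-target activity. Transcripts are
#' directional, so only the sense strand is searched.
#'
#' @param query RNA string from [build_query()].
#' @param site_offset 0-based offset of the triplet N within `query`.
#' @param transcriptome FASTA path, named character vector or
#'   `XStringSet` of reference transcripts.
#' @param mode `"cleavage_only"` or `"annealing_and_cleavage"`.
#' @param min_weight minimal matched-pair fraction for a hit to be
#'   reported/counted (default 0.75).
#' @return list with `score` and `hits` (data.frame: `accession`,
#'   `position` 0-based, `matched_pairs`, `weight`, `cleavable`,
#'   `predicted_record`, `counted`).
#' @export
specificity_score <- function(query, site_offset, transcriptome,
                              mode = c("cleavage_only",
                                       "annealing_and_cleavage"),
                              min_weight = 0.75) {
  mode <- match.arg(mode)
  stopifnot(min_weight > 0, min_weight <= 1)
  query <- as_rna(query)
  qlen <- nchar(query)
  refs <- .read_reference(transcriptome)
  hits <- list()
  if (!length(refs)) warning("empty reference transcriptome; score is 0")
  max_mm <- floor((1 - min_weight) * qlen)
  qpat <- Biostrings::RNAString(query)
  for (acc in names(refs)) {
    subject <- Biostrings::RNAString(refs[[acc]])
    if (length(subject) < qlen) next
    m <- Biostrings::matchPattern(qpat, subject, max.mismatch = max_mm,
                                  with.indels = FALSE)
    if (!length(m)) next
    starts <- IRanges::start(m)
    for (s in starts) {
      mm <- Biostrings::neditStartingAt(qpat, subject, starting.at = s,
                                        with.indels = FALSE)
      matched <- qlen - mm
      weight <- matched / qlen
      if (weight < min_weight) next
      u_at <- s + site_offset + 1L
      h_at <- s + site_offset + 2L
      cleav <- h_at <= length(subject) &&
        substr(refs[[acc]], u_at, u_at) == "U" &&
        substr(refs[[acc]], h_at, h_at) %in% c("A", "C", "U")
      hits <- c(hits, list(data.frame(
        accession = acc, position = s - 1L, matched_pairs = matched,
        weight = weight, cleavable = cleav,
        predicted_record = grepl("^(XM|XR)", acc, ignore.case = TRUE),
        stringsAsFactors = FALSE
      )))
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else data.frame(
    accession = character(0), position = integer(0),
    matched_pairs = integer(0), weight = numeric(0),
    cleavable = logical(0), predicted_record = logical(0),
    stringsAsFactors = FALSE
  )
  hits$counted <- !hits$predicted_record &
    (mode == "annealing_and_cleavage" | hits$cleavable)
  list(score = sum(hits$weight[hits$counted]), hits = hits)
}

#' Write off-target hits as a TSV side file
#'
#' @param hits `hits` data.frame from [specificity_score()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
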