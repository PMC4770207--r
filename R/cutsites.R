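#' Find NUH cleavage sites in a target
#'
#' Scans the target for every occurrence of the requested cleavage triplets.
#' Overlapping occurrences are all reported. Coordinates are 0-based:
#' `index` is the position of the N of the NUH triplet and cleavage occurs
#' immediately 3' of the H, i.e. between `cut_pos - 1` and `cut_pos` with
#' `cut_pos = index + 3`.
#'
#' @param target a [target_transcript()].
#' @param triplets character vector of NUH triplets (defaults to `"GUC"`).
#' @return data.frame with one row per site, sorted by `index`: `site_id`
#'   (0-based, in target order), `index`, `triplet`, `cut_pos`.
#' @examples
#' find_cut_sites(target_transcript("GUCGUC"), "GUC")
#' @export
find_cut_sites <- function(target, triplets = "GUC") {
  stopifnot(inherits(target, "target_transcript"))
  triplets <- toupper(chartr("Tt", "Uu", triplets))
  if (!all(.valid_triplet(triplets))) stop("invalid NUH triplet(s)")
  ch <- strsplit(target$sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  idx <- integer(0); trp <- character(0)
  if (n >= 3L) {
    for (t in unique(triplets)) {
      p <- strsplit(t, "", fixed = TRUE)[[1]]
      hit <- which(ch[seq_len(n - 2L)] == p[1L] &
                   ch[seq_len(n - 2L) + 1L] == p[2L] &
                   ch[seq_len(n - 2L) + 2L] == p[3L])
      idx <- c(idx, hit - 1L)
      trp <- c(trp, rep(t, length(hit)))
    }
  }
  o <- order(idx)
  data.frame(site_id = seq_along(idx) - 1L, index = idx[o], triplet = trp[o],
             cut_pos = idx[o] + 3L, stringsAsFactors = FALSE)
}

# arm fitting rules, 0-based coordinates:
#  arm 1 (helix I side) binds target[cut_pos .. cut_pos + arm1_len - 1]
#  arm 3 (helix III side) binds target[index - arm3_len + 1 .. index],
#  leaving the U and H of the NUH unpaired.
.arm1_fits <- function(cut_pos, arm1_len, n) cut_pos + arm1_len <= n
.arm3_fits <- function(index, arm3_len) arm3_len <= index + 1L

#' Assemble a ribozyme sequence for one cut-site
#'
#' The ribozyme reads 5' to 3': reverse complement of the target segment
#' 3' of the cleavage position (arm 1, helix I), the constant catalytic
#' core, then the reverse complement of the target segment ending at the N
#' of the NUH triplet (arm 3, helix III). The U and H of the triplet are
#' left unpaired, as in the catalytically active fold.
#'
#' @param target a [target_transcript()].
#' @param site one row of [find_cut_sites()] output (or a list with
#'   `index` and `cut_pos`).
#' @param arm1_len,arm3_len arm lengths in nt. Zero-length arms yield the
#'   bare core.
#' @param core a [core_template()].
#' @return RNA string of the assembled ribozyme.
#' @export
assemble_ribozyme <- function(target, site, arm1_len, arm3_len,
                              core = core_template()) {
  stopifnot(inherits(target, "target_transcript"),
            inherits(core, "core_template"))
  n <- nchar(target$sequence)
  index <- as.integer(site$index); cut_pos <- as.integer(site$cut_pos)
  if (!.arm1_fits(cut_pos, arm1_len, n) || !.arm3_fits(index, arm3_len)) {
    stop("arms would extend past the target sequence ends")
  }
  seg1 <- if (arm1_len > 0) {
    substr(target$sequence, cut_pos + 1L, cut_pos + arm1_len)
  } else ""
  seg3 <- if (arm3_len > 0) {
    substr(target$sequence, index - arm3_len + 2L, index + 1L)
  } else ""
  paste0(if (nzchar(seg1)) rna_revcomp(seg1) else "",
         core$core_seq,
         if (nzchar(seg3)) rna_revcomp(seg3) else "")
}

#' Enumerate all candidate ribozymes
#'
#' One candidate per (cut-site, arm 1 length, arm 3 length) combination
#' whose arms fit inside the target. For sites far from both sequence ends
#' this yields `(arm_max - arm_min + 1)^2` candidates per site; sites near
#' an end keep only the combinations that fit.
#'
#' @param target a [target_transcript()].
#' @param sites output of [find_cut_sites()].
#' @param params a [design_params()].
#' @param core a [core_template()]; defaults to the model named in `params`.
#' @return data.frame with columns `site_id`, `index`, `triplet`, `cut_pos`,
#'   `arm1_len`, `arm3_len`, `arm1_seq`, `arm3_seq` (the arm sequences as
#'   they appear in the ribozyme) and `ribozyme`.
#' @export
enumerate_candidates <- function(target, sites, params = design_params(),
                                 core = core_template(params$model)) {
  stopifnot(inherits(target, "target_transcript"),
            inherits(params, "design_params"))
  n <- nchar(target$sequence)
  lens <- seq(params$arm_min, params$arm_max)
  rows <- vector("list", nrow(sites))
  for (r in seq_len(nrow(sites))) {
    s <- sites[r, ]
    a1 <- lens[.arm1_fits(s$cut_pos, lens, n)]
    a3 <- lens[.arm3_fits(s$index, lens)]
    if (!length(a1) || !length(a3)) next
    g <- expand.grid(arm1_len = a1, arm3_len = a3, KEEP.OUT.ATTRS = FALSE)
    g$site_id <- s$site_id; g$index <- s$index
    g$triplet <- s$triplet; g$cut_pos <- s$cut_pos
    rows[[r]] <- g
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(site_id = integer(0), index = integer(0),
                      triplet = character(0), cut_pos = integer(0),
                      arm1_len = integer(0), arm3_len = integer(0),
                      arm1_seq = character(0), arm3_seq = character(0),
                      ribozyme = character(0), stringsAsFactors = FALSE))
  }
  seq <- target$sequence
  out$arm1_seq <- rna_revcomp(substr(rep(seq, nrow(out)),
                                     out$cut_pos + 1L,
                                     out$cut_pos + out$arm1_len))
  out$arm3_seq <- rna_revcomp(substr(rep(seq, nrow(out)),
                                     out$index - out$arm3_len + 2L,
                                     out$index + 1L))
  out$ribozyme <- paste0(out$arm1_seq, core$core_seq, out$arm3_seq)
  rownames(out) <- NULL
  out[, c("site_id", "index", "triplet", "cut_pos", "arm1_len", "arm3_len",
          "arm1_seq", "arm3_seq", "ribozyme")]
}

#' T7 transcription template for a ribozyme
#'
#' Prepends the T7 promoter (with its GCG leader, so transcription starts
#' on G) to the DNA form of the ribozyme and returns both strands of the
#' double-stranded template.
#'
#' @param ribozyme_seq RNA string of the ribozyme (may be empty).
#' @return named character vector with `sense` (promoter + ribozyme, DNA)
#'   and `antisense` (its reverse complement).
#' @export
emit_t7_template <- function(ribozyme_seq) {
  promoter <- "TAATACGACTCACTATAGCG"
  sense <- paste0(promoter,
                  if (nzchar(ribozyme_seq)) rna_to_dna(as_rna(ribozyme_seq)) else "")
  anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sense)))
  c(sense = sense, antisense = anti)
}
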