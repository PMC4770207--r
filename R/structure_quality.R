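#' Decompose a structure into continuous double-stranded stretches
#'
#' A stretch is a run of stacked base pairs `(i, j), (i+1, j-1), ...`;
#' two helices separated by a single 1x1 internal mismatch (one unpaired
#' base on each strand) are merged into one stretch, with at most one such
#' mismatch per stretch. Larger loops end the stretch. An optional set of
#' pairs (e.g. the designed stem II of the catalytic core) is removed
#' before decomposition.
#'
#' @param pt integer pair table from [db_pairs()].
#' @param exclude_pairs optional two-column matrix of pairs `(i, j)` to
#'   drop before decomposition.
#' @return list of stretches; each a two-column matrix of pairs, ordered
#'   5' to 3' on the i-strand.
#' @export
ds_stretches <- function(pt, exclude_pairs = NULL) {
  pairs <- .pt_pairs(pt)
  if (!is.null(exclude_pairs) && nrow(pairs)) {
    key <- paste(pairs[, 1], pairs[, 2])
    ex <- paste(pmin(exclude_pairs[, 1], exclude_pairs[, 2]),
                pmax(exclude_pairs[, 1], exclude_pairs[, 2]))
    pairs <- pairs[!key %in% ex, , drop = FALSE]
  }
  if (!nrow(pairs)) return(list())
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  out <- list()
  cur <- pairs[1, , drop = FALSE]
  mism <- FALSE
  for (r in seq_len(nrow(pairs))[-1]) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pi <- cur[nrow(cur), 1]; pj <- cur[nrow(cur), 2]
    if (i == pi + 1L && j == pj - 1L) {
      cur <- rbind(cur, pairs[r, ])
    } else if (i == pi + 2L && j == pj - 2L && !mism) {
      cur <- rbind(cur, pairs[r, ])
      mism <- TRUE
    } else {
      out <- c(out, list(cur))
      cur <- pairs[r, , drop = FALSE]
      mism <- FALSE
    }
  }
  c(out, list(cur))
}

# melting temperature (Kelvin) of one stretch: NN Tm of the concatenated
# paired bases on the i-strand; single pairs carry no stacking information
# and contribute 0.
.stretch_tm_K <- function(stretch, seq, env, nn) {
  bases <- paste(substring(seq, stretch[, 1], stretch[, 1]), collapse = "")
  if (nchar(bases) < 2L) return(0)
  max(0, duplex_tm(bases, env, nn) + 273.15)
}

# designed stem II pairs in ribozyme coordinates (arm 1 precedes the core)
.core_pairs_abs <- function(arm1_len, core) {
  core$stem2_pairs + as.integer(arm1_len)
}

#' Is the catalytic core intact in a structure?
#'
#' The core is intact when the structure, restricted to the core positions,
#' equals the designed fold: every stem II pair is present and every other
#' core position (the conserved CUGAUGA and GAAA boxes and the stem II
#' loop) is unpaired. A fully unpaired core fails (helix II not formed), as
#' does any core base pairing with an arm.
#'
#' @param db dot-bracket structure of the whole ribozyme (or its pair
#'   table).
#' @param arm1_len length of arm 1 (the core starts at `arm1_len + 1`).
#' @param core a [core_template()].
#' @return logical.
#' @export
core_intact <- function(db, arm1_len, core = core_template()) {
  pt <- if (is.character(db)) db_pairs(db) else db
  off <- as.integer(arm1_len)
  ncore <- nchar(core$core_seq)
  if (off + ncore > length(pt)) stop("structure shorter than arm 1 + core")
  want <- integer(ncore)
  want[core$stem2_pairs[, 1]] <- core$stem2_pairs[, 2] + off
  want[core$stem2_pairs[, 2]] <- core$stem2_pairs[, 1] + off
  identical(pt[off + seq_len(ncore)], want)
}

#' Structure quality of a ribozyme over an ensemble
#'
#' Per structure, the score `Q_s` is the sum of the Kelvin melting
#' temperatures of all continuous double-stranded stretches other than the
#' designed stem II (which is meant to be there), plus a penalty of 50
#' (same Kelvin-sum scale) when the catalytic core is not intact. The
#' ensemble score is the probability-weighted sum `Q_f = sum(f_s * Q_s)`.
#' Lower is better: 0 means both arms are fully open in every structure
#' and the core always folds as designed.
#'
#' @param ribozyme RNA string of the ribozyme.
#' @param ensemble data.frame from [fold_ensemble()].
#' @param arm1_len length of arm 1.
#' @param core a [core_template()].
#' @param env a [design_env()].
#' @param nn parameter table from [nn_table()].
#' @return list with `Q_s` (numeric vector), `core_intact` (logical
#'   vector) and `Q_f` (scalar).
#' @export
structure_quality <- function(ribozyme, ensemble, arm1_len,
                              core = core_template(), env = design_env(),
                              nn = nn_table()) {
  stopifnot(nrow(ensemble) >= 1L)
  ex <- .core_pairs_abs(arm1_len, core)
  qs <- numeric(nrow(ensemble))
  ok <- logical(nrow(ensemble))
  for (k in seq_len(nrow(ensemble))) {
    pt <- db_pairs(ensemble$dotbracket[k])
    if (length(pt) != nchar(ribozyme)) {
      stop("structure length differs from ribozyme length")
    }
    st <- ds_stretches(pt, exclude_pairs = ex)
    qs[k] <- sum(vapply(st, .stretch_tm_K, numeric(1), seq = ribozyme,
                        env = env, nn = nn))
    ok[k] <- core_intact(pt, arm1_len, core)
    if (!ok[k]) qs[k] <- qs[k] + 50
  }
  list(Q_s = qs, core_intact = ok, Q_f = sum(ensemble$f_s * qs))
}

#' Designed (reference) fold of an assembled ribozyme
#'
#' Helper producing the dot-bracket in which both arms are fully open and
#' the core folds exactly as designed (stem II paired, conserved boxes
#' unpaired). Useful for constructing fixture ensembles.
#'
#' @param arm1_len,arm3_len arm lengths.
#' @param core a [core_template()].
#' @return dot-bracket string of length `arm1_len + nchar(core) + arm3_len`.
#' @export
designed_fold <- function(arm1_len, arm3_len, core = core_template()) {
  n <- arm1_len + nchar(core$core_seq) + arm3_len
  pt <- integer(n)
  abs <- .core_pairs_abs(arm1_len, core)
  pt[abs[, 1]] <- abs[, 2]
  pt[abs[, 2]] <- abs[, 1]
  pairs_db(pt)
}
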