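#' Generate a synthetic transcript with planted cut-sites
#'
#' Builds a random background sequence carrying the requested NUH triplets
#' at exact 0-based positions and *no* accidental occurrence of any of the
#' requested triplet types elsewhere: accidental occurrences are removed by
#' re-randomizing their (background) uridine position, iterating until the
#' scan is clean. Deterministic for a given seed.
#'
#' @param length transcript length, nt.
#' @param planted data.frame with columns `triplet` and `position`
#'   (0-based index of the N); positions must be non-overlapping and at
#'   least `margin` nt from either end.
#' @param seed RNG seed.
#' @param margin minimal distance of a planted N from either sequence end
#'   (use `arm_max` to guarantee interior sites for enumeration).
#' @param id transcript identifier.
#' @param gc_bias probability of drawing G or C for background positions
#'   (0.5 = uniform over the four bases).
#' @return a [target_transcript()].
#' @examples
#' tgt <- make_transcript(100, data.frame(triplet = "GUC",
#'                                        position = c(20, 60)), seed = 1)
#' find_cut_sites(tgt, "GUC")
#' @export
make_transcript <- function(length, planted = NULL, seed = 1L, margin = 0L,
                            id = "synthetic_target", gc_bias = 0.5) {
  stopifnot(length >= 3L, gc_bias > 0, gc_bias < 1)
  if (is.null(planted)) {
    planted <- data.frame(triplet = character(0), position = integer(0))
  }
  planted$triplet <- toupper(chartr("Tt", "Uu", planted$triplet))
  if (nrow(planted) && !all(.valid_triplet(planted$triplet))) {
    stop("planted triplets must be valid NUH")
  }
  pos <- as.integer(planted$position)
  if (any(pos < margin) || any(pos > length - 3L - margin)) {
    stop("planted positions violate the requested end margin")
  }
  if (nrow(planted) > 1L && min(diff(sort(pos))) < 3L) {
    stop("planted positions overlap")
  }
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
  })
  set.seed(seed)
  prob <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2, G = gc_bias / 2,
            U = (1 - gc_bias) / 2)
  ch <- sample(names(prob), length, replace = TRUE, prob = prob)
  fixed <- logical(length)
  for (r in seq_len(nrow(planted))) {
    at <- pos[r] + 1L
    ch[at:(at + 2L)] <- strsplit(planted$triplet[r], "")[[1]]
    fixed[at:(at + 2L)] <- TRUE
  }
  types <- unique(planted$triplet)
  scan <- function(ch) {
    n <- base::length(ch)
    hit <- integer(0)
    for (t in types) {
      p <- strsplit(t, "")[[1]]
      hit <- c(hit, which(ch[seq_len(n - 2L)] == p[1L] &
                          ch[seq_len(n - 2L) + 1L] == p[2L] &
                          ch[seq_len(n - 2L) + 2L] == p[3L]) - 1L)
    }
    sort(unique(hit))
  }
  if (base::length(types)) {
    for (iter in seq_len(100L)) {
      bad <- setdiff(scan(ch), pos)
      if (!base::length(bad)) break
      for (b in bad) {
        u_at <- b + 2L   # 1-based position of the accidental U
        if (fixed[u_at]) {
          # the U belongs to a planted triplet; mutate a flanking
          # background base of the accidental occurrence instead
          cand <- (b + 1L):(b + 3L)
          u_at <- cand[!fixed[cand]][1L]
          if (is.na(u_at)) stop("cannot break accidental site at ", b,
                                ": all bases are planted")
        }
        ch[u_at] <- sample(setdiff(c("A", "C", "G"), ch[u_at]), 1L)
      }
      if (iter == 100L) stop("could not remove accidental cut-sites; ",
                             "constraints appear unsatisfiable")
    }
    if (!identical(scan(ch), sort(pos))) {
      stop("planted-site constraint could not be satisfied")
    }
  }
  target_transcript(paste(ch, collapse = ""), id = id)
}

#' Experimentally validated ribozyme fixture set
#'
#' The four anti-PABPN1 hammerhead ribozymes whose printed sequences pin
#' the arm/core decomposition used by [assemble_ribozyme()]: each sequence
#' splits into arm 1 + the 28-nt minimal core + arm 3. The target context
#' of each is reconstructed from the reverse complements of its arms; the
#' unpaired H of the NUH triplet is not recoverable from the arms and is
#' set to `C` in these synthetic contexts (yielding AUC/AUC/AUC/CUC
#' triplets).
#'
#' @return data.frame with one row per ribozyme: `name`, `ribozyme` (RNA),
#'   `arm1`, `arm3` (as they appear in the ribozyme), `arm1_len`,
#'   `arm3_len`, `target_context` (synthetic, RNA), `site_index` (0-based
#'   N position within the context) and `triplet`.
#' @export
yz_fixture_set <- function() {
  core <- core_template("minimal")$core_seq
  rz <- c(
    Yz144 = "CAGGCUCCAGUUUAACCUCACUGAUGAGUCGCUGAAAUGCGACGAAACUCCAGGCC",
    Yz363 = "UCUUCCUCCAUCUAAUCCCUCUGAUGAGUCGCUGAAAUGCGACGAAACUCGAGCUUUGAUA",
    Yz437 = "GCAUUGCCUGGUAAAGGUGCUGAUGAGUCGCUGAAAUGCGACGAAACUCAUAUUCAUCU",
    Yz867 = "CCGGCCCUAACUGUACUGAUGAGUCGCUGAAAUGCGACGAAACGCGACCC"
  )
  out <- lapply(names(rz), function(nm) {
    s <- rz[[nm]]
    at <- regexpr(core, s, fixed = TRUE)
    stopifnot(at > 0)
    arm1 <- substr(s, 1L, at - 1L)
    arm3 <- substr(s, at + nchar(core), nchar(s))
    seg1 <- rna_revcomp(arm1)
    seg3 <- rna_revcomp(arm3)
    ctx <- paste0(seg3, "U", "C", seg1)   # synthetic H = C
    data.frame(
      name = nm, ribozyme = s, arm1 = arm1, arm3 = arm3,
      arm1_len = nchar(arm1), arm3_len = nchar(arm3),
      target_context = ctx, site_index = nchar(seg3) - 1L,
      triplet = substr(ctx, nchar(seg3), nchar(seg3) + 2L),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
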