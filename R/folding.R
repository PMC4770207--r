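#' Deterministic mock folding backend
#'
#' An offline, bit-reproducible stand-in for an external partition-function
#' folder. The optimal structure is computed by maximum base pairing
#' (Watson-Crick + GU wobble, minimum hairpin loop of 3); alternative
#' ensemble members are generated by forbidding pairs of the optimum (in a
#' seed-determined order) and re-folding, de-duplicated. Ensemble weights
#' are Boltzmann-like in the pair count and normalized to sum to 1.
#'
#' Named fixture ensembles (see [write_ensemble_fixture()]) take precedence
#' over the algorithmic fold for their exact sequence, which lets tests pin
#' ensembles precisely.
#'
#' @param n_structures maximum ensemble size (default 10, mirroring the
#'   10-structure ensembles the scoring model was built around).
#' @param fixtures optional list of fixture ensembles, named by sequence;
#'   each a data.frame with columns `dotbracket`, `f_s`, or a path readable
#'   by [read_ensemble_fixture()].
#' @return object of class `folding_backend`.
#' @export
mock_backend <- function(n_structures = 10L, fixtures = NULL) {
  if (!is.null(fixtures)) {
    fixtures <- lapply(fixtures, function(f) {
      if (is.character(f)) read_ensemble_fixture(f)$ensemble else f
    })
  }
  structure(
    list(name = "mock", n_structures = as.integer(n_structures),
         fixtures = fixtures),
    class = "folding_backend"
  )
}

#' ViennaRNA folding backend adapter
#'
#' Uses the `RNAsubopt` command-line program (if installed) as an external
#' ensemble provider: structures within `e_range` kcal/mol of the minimum
#' free energy, sorted by energy, truncated to `n_structures`, with weights
#' proportional to their Boltzmann factors at 37 degrees C (normalized to
#' sum to 1). Deterministic: no stochastic backtracking is used.
#'
#' @param n_structures maximum ensemble size.
#' @param e_range suboptimal energy range passed to `RNAsubopt -e`, kcal/mol.
#' @return object of class `folding_backend`.
#' @export
vienna_backend <- function(n_structures = 10L, e_range = 5) {
  if (Sys.which("RNAsubopt") == "") {
    stop("folding backend unavailable: RNAsubopt not found on PATH; ",
         "use mock_backend()")
  }
  structure(
    list(name = "vienna", n_structures = as.integer(n_structures),
         e_range = e_range),
    class = "folding_backend"
  )
}

#' Fold a sequence into a weighted structure ensemble
#'
#' @param seq RNA string.
#' @param backend a [mock_backend()] or [vienna_backend()].
#' @param seed integer; the same sequence, backend and seed always return
#'   the identical ensemble (reproducibility contract).
#' @return data.frame with columns `dotbracket` and `f_s` (weights in
#'   `[0, 1]`, summing to 1).
#' @examples
#' fold_ensemble("GGGGAAAACCCC", mock_backend(), seed = 1)
#' @export
fold_ensemble <- function(seq, backend = mock_backend(), seed = 1L) {
  stopifnot(inherits(backend, "folding_backend"))
  seq <- as_rna(seq)
  if (!nzchar(seq)) stop("cannot fold an empty sequence")
  if (backend$name == "mock") {
    fx <- backend$fixtures[[seq]]
    if (!is.null(fx)) {
      .validate_ensemble(seq, fx)
      return(fx)
    }
    .mock_ensemble(seq, backend$n_structures, seed)
  } else {
    .vienna_ensemble(seq, backend)
  }
}

.mock_ensemble <- function(seq, n_structures, seed) {
  opt <- .nussinov_pairs(seq)
  structs <- list(opt)
  base_pairs <- .pt_pairs(opt)
  if (nrow(base_pairs)) {
    ord <- .seeded_perm(nrow(base_pairs), seed)
    # singles: forbid one pair of the optimum at a time
    ban_sets <- lapply(ord, function(k) base_pairs[k, , drop = FALSE])
    # cumulative: forbid growing prefixes of pairs
    if (nrow(base_pairs) > 1L) {
      ban_sets <- c(ban_sets, lapply(2:nrow(base_pairs), function(k) {
        base_pairs[ord[seq_len(k)], , drop = FALSE]
      }))
    }
    # position bans: open up each paired position entirely
    ban_pos <- lapply(ord, function(k) base_pairs[k, ])
    for (bs in ban_sets) {
      if (length(structs) >= n_structures) break
      structs <- c(structs, list(.nussinov_pairs(seq, banned_pairs = bs)))
      structs <- structs[!duplicated(vapply(structs, paste, "", collapse = ","))]
    }
    if (length(structs) < n_structures) {
      for (bp in ban_pos) {
        if (length(structs) >= n_structures) break
        structs <- c(structs, list(.nussinov_pairs(seq, banned_pos = bp)))
        structs <- structs[!duplicated(vapply(structs, paste, "", collapse = ","))]
      }
    }
  }
  structs <- structs[seq_len(min(length(structs), n_structures))]
  npairs <- vapply(structs, function(pt) sum(pt > 0) / 2, numeric(1))
  w <- exp(0.5 * (npairs - max(npairs)))
  w <- w / sum(w)
  data.frame(dotbracket = vapply(structs, pairs_db, ""), f_s = w,
             stringsAsFactors = FALSE)
}

# deterministic seeded permutation without touching the caller's RNG state
.seeded_perm <- function(n, seed) {
  if (n == 1L) return(1L)
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  sample.int(n)
}

.vienna_ensemble <- function(seq, backend) {
  out <- suppressWarnings(
    system2("RNAsubopt", c("-e", format(backend$e_range), "--sorted"),
            input = seq, stdout = TRUE, stderr = FALSE)
  )
  lines <- grep("^[().]+\\s+-?[0-9.]+", out, value = TRUE)
  if (!length(lines)) stop("RNAsubopt returned no structures")
  parts <- strsplit(trimws(lines), "\\s+")
  db <- vapply(parts, `[`, "", 1L)
  en <- as.numeric(vapply(parts, `[`, "", 2L))
  keep <- seq_len(min(length(db), backend$n_structures))
  db <- db[keep]; en <- en[keep]
  rt <- 0.0019872 * 310.15   # kcal/mol at 37 C
  w <- exp(-(en - min(en)) / rt)
  w <- w / sum(w)
  data.frame(dotbracket = db, f_s = w, stringsAsFactors = FALSE)
}

.validate_ensemble <- function(seq, ens) {
  stopifnot(is.data.frame(ens), all(c("dotbracket", "f_s") %in% names(ens)))
  if (any(nchar(ens$dotbracket) != nchar(seq))) {
    stop("ensemble structure length differs from sequence length")
  }
  lapply(ens$dotbracket, db_pairs)   # errors on malformed strings
  if (any(ens$f_s < 0 | ens$f_s > 1)) stop("weights must lie in [0, 1]")
  if (sum(ens$f_s) > 1 + 1e-6) stop("ensemble weights sum to more than 1")
  invisible(TRUE)
}

#' Write a mock-backend ensemble fixture file
#'
#' Plain-text format: a `# sequence: <seq>` header line followed by one
#' `structure<TAB>weight` line per ensemble member.
#'
#' @param seq RNA string the structures belong to.
#' @param structures data.frame with columns `dotbracket`, `f_s`, or a list
#'   of `(dotbracket, weight)` pairs.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_fixture <- function(seq, structures, path) {
  if (!is.data.frame(structures)) {
    structures <- data.frame(
      dotbracket = vapply(structures, `[[`, "", 1L),
      f_s = as.numeric(vapply(structures, function(x) as.numeric(x[[2L]]),
                              numeric(1))),
      stringsAsFactors = FALSE
    )
  }
  seq <- as_rna(seq)
  .validate_ensemble(seq, structures)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sequence: ", seq), con)
  writeLines(paste(structures$dotbracket, format(structures$f_s, digits = 15),
                   sep = "\t"), con)
  invisible(path)
}

#' Read an ensemble fixture file
#'
#' @param path file written by [write_ensemble_fixture()].
#' @return list with `sequence` and `ensemble` (data.frame `dotbracket`,
#'   `f_s`).
#' @export
read_ensemble_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqline <- grep("^# sequence:", lines, value = TRUE)
  if (!length(seqline)) stop("missing '# sequence:' header in ", path)
  seq <- trimws(sub("^# sequence:", "", seqline[1L]))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ens <- data.frame(dotbracket = vapply(parts, `[`, "", 1L),
                    f_s = as.numeric(vapply(parts, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  .validate_ensemble(seq, ens)
  list(sequence = seq, ensemble = ens)
}
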