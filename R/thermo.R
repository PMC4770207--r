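#' Nearest-neighbor parameter table
#'
#' Loads (and caches) the RNA/RNA dinucleotide stacking table shipped with
#' the package: dH (kcal/mol) and dS (cal/mol/K) for all 16 stacks at the
#' 1 M NaCl reference state, plus duplex initiation and terminal A-U terms.
#' A different table (e.g. a DNA/RNA hybrid set) can be supplied as a
#' tab-delimited file with columns `stack`, `dH`, `dS`.
#'
#' @param path optional path to an alternative table.
#' @return data.frame with rownames = stack labels and columns `dH`, `dS`.
#' @export
nn_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.hh_cache$nn)) return(.hh_cache$nn)
    path <- system.file("extdata", "nn_rna_xia1998.tsv",
                        package = "hammerhead")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("stack", "dH", "dS") %in% names(tab)))
  rownames(tab) <- tab$stack
  dinucs <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                            paste0))
  missing <- setdiff(c(dinucs, "init", "term_AU"), rownames(tab))
  if (length(missing)) stop("NN table missing entries: ",
                            paste(missing, collapse = ", "))
  if (any(!is.finite(tab$dH)) || any(!is.finite(tab$dS))) {
    stop("NN table contains non-finite values")
  }
  tab <- tab[, c("dH", "dS")]
  if (cache) .hh_cache$nn <- tab
  tab
}

# effective monovalent cation concentration (molar); Mg2+ folded in as an
# equivalent monovalent contribution
.na_effective <- function(env) {
  (env$na_mM + 120 * sqrt(env$mg_mM)) / 1000
}

#' Duplex melting temperature of an RNA oligomer with its perfect complement
#'
#' Nearest-neighbor base-stacking model:
#' `Tm(K) = 1000 * dH / (dS + R * ln(CT/4))`, with the stack, initiation and
#' terminal A-U terms summed from the parameter table, followed by a
#' monovalent-salt correction `+16.6 * log10([Na+]eff)` where the effective
#' monovalent concentration folds Mg2+ in as `120 * sqrt(mg_mM)` mM.
#' Sequences shorter than 2 nt, for which the stacking model is undefined,
#' return `-Inf` (they are always rejected by the temperature filter).
#'
#' @param seq RNA string (the strand whose duplex with its perfect
#'   complement is melted).
#' @param env a [design_env()] (supplies salt and oligomer concentrations).
#' @param nn parameter table from [nn_table()].
#' @return melting temperature in degrees Celsius.
#' @examples
#' duplex_tm("GCGCGCGC", design_env())
#' @export
duplex_tm <- function(seq, env = design_env(), nn = nn_table()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  s <- as_rna(seq)
  n <- nchar(s)
  if (n < 2L) return(-Inf)
  stacks <- substring(s, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  dH <- nn["init", "dH"] + sum(nn[stacks, "dH"])
  dS <- nn["init", "dS"] + sum(nn[stacks, "dS"])
  ends <- substr(s, 1, 1)
  ends <- c(ends, substr(s, n, n))
  n_au <- sum(ends %in% c("A", "U"))
  dH <- dH + n_au * nn["term_AU", "dH"]
  dS <- dS + n_au * nn["term_AU", "dS"]
  R <- 1.9872          # cal / (mol K)
  ct <- env$oligo_nM * 1e-9
  tm_k <- 1000 * dH / (dS + R * log(ct / 4))
  tm_k <- tm_k + 16.6 * log10(.na_effective(env))
  tm_k - 273.15
}

#' Per-arm annealing temperatures of candidates
#'
#' Computes the melting temperature of each arm annealed to its
#' perfect-complement target segment and appends `tm_arm1`/`tm_arm3`
#' columns.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param env a [design_env()].
#' @param nn parameter table from [nn_table()].
#' @return `candidates` with numeric columns `tm_arm1` and `tm_arm3`.
#' @export
candidate_tm <- function(candidates, env = design_env(), nn = nn_table()) {
  tm_of <- function(seqs) {
    vapply(seqs, function(s) duplex_tm(s, env, nn), numeric(1),
           USE.NAMES = FALSE)
  }
  # memoize over unique arm sequences; arm Tm only depends on the sequence
  u <- unique(c(candidates$arm1_seq, candidates$arm3_seq))
  tm_u <- setNames(tm_of(u), u)
  candidates$tm_arm1 <- unname(tm_u[candidates$arm1_seq])
  candidates$tm_arm3 <- unname(tm_u[candidates$arm3_seq])
  candidates
}

#' Annealing-temperature filter
#'
#' A candidate is kept when each arm's Tm lies within `-5` to `+60` degrees
#' C of the environment temperature. Unless `strict = TRUE`, a candidate
#' with one arm outside the window is rescued when the mean of the two arm
#' Tms still lies inside it (one arm "making up" for the other).
#'
#' @param candidates data.frame with `tm_arm1`/`tm_arm3` columns (see
#'   [candidate_tm()]).
#' @param env a [design_env()].
#' @param strict disable the compensation rule.
#' @return logical vector, `TRUE` for candidates to keep.
#' @export
tm_filter <- function(candidates, env = design_env(), strict = FALSE) {
  lo <- env$temperature - 5
  hi <- env$temperature + 60
  in_win <- function(x) x >= lo & x <= hi
  both <- in_win(candidates$tm_arm1) & in_win(candidates$tm_arm3)
  if (strict) return(both)
  both | in_win((candidates$tm_arm1 + candidates$tm_arm3) / 2)
}
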