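#' Min-max normalize and adjust quality measures
#'
#' For each named measure, adds `<measure>_normalized` (min-max scaled over
#' the candidate set, so the best-observed value maps to 0 and the worst to
#' 1 for detrimental measures) and `<measure>_adjusted = 1 - normalized`
#' (1 = best). When all candidates share the same value the measure carries
#' no discriminating information: normalized is set to 0 (adjusted 1) for
#' all.
#'
#' @param candidates data.frame of scored candidates.
#' @param measures character vector of column names to normalize (all
#'   treated as detrimental, i.e. larger raw = worse).
#' @return `candidates` with the extra columns.
#' @export
normalize_measures <- function(candidates,
                               measures = c("q_f", "inaccessibility",
                                            "dG_disruption")) {
  stopifnot(nrow(candidates) >= 1L)
  for (m in measures) {
    x <- candidates[[m]]
    if (is.null(x)) stop("no such measure column: ", m)
    lo <- min(x); hi <- max(x)
    z <- if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
    candidates[[paste0(m, "_normalized")]] <- z
    candidates[[paste0(m, "_adjusted")]] <- 1 - z
  }
  candidates
}

#' Pareto-front ranking (successive non-dominated sorting)
#'
#' Candidate `a` dominates `b` when `a` is no worse than `b` on every
#' objective and strictly better on at least one. Rank 1 is the set of
#' candidates dominated by nobody; removing it, rank 2 is the
#' non-dominated set among the remainder, and so on until all candidates
#' are ranked. Candidates with identical objective vectors do not dominate
#' one another and share a rank.
#'
#' @param objectives numeric matrix (rows = candidates, columns =
#'   objectives) or data.frame of numeric columns. All values must be
#'   finite.
#' @param minimize logical scalar or vector (per column): `TRUE` if
#'   smaller is better (default for every objective).
#' @return integer vector of ranks (1 = Pareto-optimal front).
#' @examples
#' pareto_rank(cbind(c(1, 2, 2), c(1, 1, 2)))
#' @export
pareto_rank <- function(objectives, minimize = TRUE) {
  obj <- as.matrix(objectives)
  storage.mode(obj) <- "double"
  if (!all(is.finite(obj))) stop("objective values must be finite")
  minimize <- rep_len(minimize, ncol(obj))
  obj[, !minimize] <- -obj[, !minimize]   # flip so everything is minimized
  n <- nrow(obj)
  rank <- integer(n)
  left <- seq_len(n)
  r <- 0L
  while (length(left)) {
    r <- r + 1L
    sub <- obj[left, , drop = FALSE]
    dominated <- vapply(seq_along(left), function(i) {
      le <- sub <= matrix(sub[i, ], nrow(sub), ncol(sub), byrow = TRUE)
      lt <- sub < matrix(sub[i, ], nrow(sub), ncol(sub), byrow = TRUE)
      any(rowSums(le) == ncol(sub) & rowSums(lt) > 0)
    }, logical(1))
    front <- left[!dominated]
    rank[front] <- r
    left <- left[dominated]
  }
  rank
}

#' Assemble the ranked design report
#'
#' Builds the final design table: one row per surviving candidate with its
#' cut-site number (0-based, in target order), position, triplet, arm
#' lengths and sequence, both arm Tms, the raw and adjusted structure
#' ("ribozyme shape") and accessibility measures, the specificity score
#' (off-target hit weight; `NA` for in vitro runs) and the Pareto rank.
#' Rows are ordered by rank, then deterministically by position and arm
#' lengths.
#'
#' @param candidates scored, normalized and ranked candidate data.frame
#'   (needs a `rank` column).
#' @param meta named list of run parameters recorded in the report header.
#' @return object of class `design_report`: list with `table` and `meta`.
#' @export
build_report <- function(candidates, meta = list()) {
  if (!nrow(candidates)) {
    warning("empty candidate set: report contains a header only")
    tab <- data.frame(
      cutsite = integer(0), position = integer(0), triplet = character(0),
      arm1_len = integer(0), arm3_len = integer(0), ribozyme = character(0),
      tm_arm1 = numeric(0), tm_arm3 = numeric(0),
      structure_raw = numeric(0), ribozyme_shape = numeric(0),
      accessibility1_raw = numeric(0), accessibility1 = numeric(0),
      accessibility2_raw = numeric(0), accessibility2 = numeric(0),
      specificity = numeric(0), rank = integer(0), stringsAsFactors = FALSE
    )
    return(structure(list(table = tab, meta = meta),
                     class = "design_report"))
  }
  spec <- if (!is.null(candidates$specificity)) candidates$specificity else
    rep(NA_real_, nrow(candidates))
  tab <- data.frame(
    cutsite = candidates$site_id,
    position = candidates$index,
    triplet = candidates$triplet,
    arm1_len = candidates$arm1_len,
    arm3_len = candidates$arm3_len,
    ribozyme = candidates$ribozyme,
    tm_arm1 = candidates$tm_arm1,
    tm_arm3 = candidates$tm_arm3,
    structure_raw = candidates$q_f,
    ribozyme_shape = candidates$q_f_adjusted,
    accessibility1_raw = candidates$inaccessibility,
    accessibility1 = candidates$inaccessibility_adjusted,
    accessibility2_raw = candidates$dG_disruption,
    accessibility2 = candidates$dG_disruption_adjusted,
    specificity = spec,
    rank = candidates$rank,
    stringsAsFactors = FALSE
  )
  o <- order(tab$rank, tab$position, tab$arm1_len, tab$arm3_len)
  tab <- tab[o, ]
  rownames(tab) <- NULL
  structure(list(table = tab, meta = meta), class = "design_report")
}

#' @export
print.design_report <- function(x, n = 10L, ...) {
  cat(sprintf("<design_report> %d candidates, %d Pareto front(s)\n",
              nrow(x$table),
              if (nrow(x$table)) max(x$table$rank) else 0L))
  print(utils::head(x$table, n))
  invisible(x)
}

#' Serialize a design report to TSV
#'
#' Tab-delimited UTF-8 with a `#`-prefixed metadata header capturing the
#' run parameters, so a report is self-describing and reruns are
#' comparable byte for byte.
#'
#' @param report a [build_report()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- report$meta
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = ",")),
               con)
  }
  tab <- report$table
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
  })
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
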