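#' Disruption-energy window around a cut-site
#'
#' The fixed-width target window used for the disruption-energy term:
#' `arm_max + 3 + arm_max` nt (23 nt at the default maximum arm length of
#' 10) covering both arms' maximal binding sites with the NUH triplet
#' interior, clipped at the sequence ends.
#'
#' @param target a [target_transcript()].
#' @param site one row of [find_cut_sites()] output.
#' @param arm_max maximal arm length (default 10).
#' @return list with 0-based half-open `start`, `end` and `width`.
#' @export
site_window <- function(target, site, arm_max = 10L) {
  n <- nchar(target$sequence)
  start <- max(0L, as.integer(site$index) - as.integer(arm_max))
  end <- min(n, as.integer(site$index) + 3L + as.integer(arm_max))
  list(start = start, end = end, width = end - start)
}

# 0-based half-open window actually bound by a candidate's arms
# (arm 3 segment + the unpaired U and H + arm 1 segment)
.binding_window <- function(site, arm1_len, arm3_len, n) {
  start <- max(0L, as.integer(site$index) - as.integer(arm3_len) + 1L)
  end <- min(n, as.integer(site$cut_pos) + as.integer(arm1_len))
  c(start = start, end = end)
}

# does a pair (i, j) [1-based] touch a 0-based half-open window?
.in_window0 <- function(pos1, start, end) pos1 - 1L >= start & pos1 - 1L < end

#' Cut-site inaccessibility of a candidate
#'
#' Ensemble-weighted sum, over the target's secondary structures, of the
#' Kelvin melting temperatures of double-stranded stretches that intersect
#' the candidate's arm-binding window. The computation mirrors the
#' ribozyme-structure score: 0 means the binding region is open in every
#' structure; larger values flag self-structure the arms must displace.
#'
#' @param target a [target_transcript()].
#' @param cand one candidate row (needs `index`, `cut_pos`, `arm1_len`,
#'   `arm3_len`).
#' @param ensemble target ensemble from [fold_ensemble()] (folded once per
#'   run and shared by all candidates).
#' @param env a [design_env()].
#' @param nn parameter table from [nn_table()].
#' @return non-negative scalar (Kelvin-sum units).
#' @export
cutsite_inaccessibility <- function(target, cand, ensemble,
                                    env = design_env(), nn = nn_table()) {
  n <- nchar(target$sequence)
  win <- .binding_window(cand, cand$arm1_len, cand$arm3_len, n)
  total <- 0
  for (k in seq_len(nrow(ensemble))) {
    pt <- db_pairs(ensemble$dotbracket[k])
    st <- ds_stretches(pt)
    if (!length(st)) next
    hit <- vapply(st, function(s) {
      any(.in_window0(c(s[, 1], s[, 2]), win["start"], win["end"]))
    }, logical(1))
    if (!any(hit)) next
    tm <- sum(vapply(st[hit], .stretch_tm_K, numeric(1),
                     seq = target$sequence, env = env, nn = nn))
    total <- total + ensemble$f_s[k] * tm
  }
  total
}

# free-energy change (kcal/mol) of one dinucleotide stack at temperature T
.stack_dG <- function(stack, temp_c, nn) {
  nn[stack, "dH"] - (temp_c + 273.15) * nn[stack, "dS"] / 1000
}

#' Disruption energy of a cut-site
#'
#' The free-energy cost (kcal/mol) to melt local target structure across
#' the fixed 23-nt window around a cut-site: per ensemble structure, the
#' stabilizing free energies of all base-pair stacks with at least one
#' partner inside the window are summed and sign-flipped (floored at 0),
#' then combined as an ensemble-weighted sum. Computed once per cut-site.
#'
#' @param target a [target_transcript()].
#' @param site one row of [find_cut_sites()] output.
#' @param ensemble target ensemble from [fold_ensemble()].
#' @param env a [design_env()] (supplies the temperature for dG = dH - T dS).
#' @param nn parameter table from [nn_table()].
#' @param arm_max maximal arm length defining the window (default 10,
#'   i.e. a 23-nt window).
#' @return non-negative scalar, kcal/mol.
#' @export
disruption_energy <- function(target, site, ensemble, env = design_env(),
                              nn = nn_table(), arm_max = 10L) {
  win <- site_window(target, site, arm_max)
  seq <- target$sequence
  total <- 0
  for (k in seq_len(nrow(ensemble))) {
    pt <- db_pairs(ensemble$dotbracket[k])
    pairs <- .pt_pairs(pt)
    if (!nrow(pairs)) next
    dg <- 0
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      # stack formed by (i, j) on (i+1, j-1)
      if (i + 1L <= length(pt) && pt[i + 1L] == j - 1L) {
        if (any(.in_window0(c(i, i + 1L, j - 1L, j),
                            win$start, win$end))) {
          g <- .stack_dG(substr(seq, i, i + 1L), env$temperature, nn)
          if (g < 0) dg <- dg + g
        }
      }
    }
    total <- total + ensemble$f_s[k] * max(0, -dg)
  }
  total
}
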