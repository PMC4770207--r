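#' End-to-end ribozyme design
#'
#' Runs the full design procedure: cut-site discovery, candidate
#' enumeration and assembly, annealing-temperature filtering, ribozyme
#' structure scoring over a folding ensemble, target accessibility
#' (cut-site inaccessibility per candidate, disruption energy per site),
#' off-target specificity (in vivo runs only), min-max
#' normalization/adjustment and Pareto-front ranking. Per-stage candidate
#' counts are logged via `message()` and recorded in the result.
#'
#' The target is folded once and its ensemble shared by all candidates;
#' each candidate's ribozyme is folded individually (memoized per unique
#' sequence). With the mock backend the whole run is deterministic given
#' `seed`.
#'
#' @param target a [target_transcript()] (or a FASTA/text path).
#' @param params a [design_params()].
#' @param env a [design_env()].
#' @param backend a folding backend from [mock_backend()] or
#'   [vienna_backend()].
#' @param seed integer seed controlling every stochastic choice.
#' @param core a [core_template()]; defaults to the model named in
#'   `params`.
#' @return a `design_report` (see [build_report()]) with an extra
#'   `stage_counts` element; if `params$t7` is set, a `t7_templates`
#'   element maps each reported ribozyme to its transcription template.
#' @examples
#' tgt <- make_transcript(60, planted = data.frame(triplet = "GUC",
#'                                                 position = 30), seed = 7)
#' rep <- run_design(tgt, design_params(arm_min = 4, arm_max = 5),
#'                   design_env(), mock_backend(), seed = 1)
#' rep$table
#' @export
run_design <- function(target, params = design_params(), env = design_env(),
                       backend = mock_backend(), seed = 1L,
                       core = core_template(params$model)) {
  if (is.character(target)) target <- read_target_fasta(target)
  stopifnot(inherits(target, "target_transcript"),
            inherits(params, "design_params"),
            inherits(env, "design_env"))
  counts <- list()
  log <- function(stage, n) {
    counts[[stage]] <<- n
    message(sprintf("[%s] %d candidates", stage, n))
  }

  sites <- find_cut_sites(target, params$cut_triplets)
  log("cut_sites", nrow(sites))

  cands <- enumerate_candidates(target, sites, params, core)
  log("enumerated", nrow(cands))

  cands <- candidate_tm(cands, env)
  cands <- cands[tm_filter(cands, env), , drop = FALSE]
  log("tm_filtered", nrow(cands))

  if (nrow(cands)) {
    # ribozyme structure, memoized per unique sequence + arm split
    key <- paste(cands$ribozyme, cands$arm1_len)
    qf <- setNames(rep(NA_real_, length(unique(key))), unique(key))
    for (k in unique(key)) {
      row <- cands[match(k, key), ]
      ens <- fold_ensemble(row$ribozyme, backend, seed)
      qf[k] <- structure_quality(row$ribozyme, ens, row$arm1_len, core,
                                 env)$Q_f
    }
    cands$q_f <- unname(qf[key])
    log("structure_scored", nrow(cands))

    # target folded once per run
    tens <- fold_ensemble(target$sequence, backend, seed)
    cands$inaccessibility <- vapply(seq_len(nrow(cands)), function(r) {
      cutsite_inaccessibility(target, cands[r, ], tens, env)
    }, numeric(1))
    used <- sites[sites$site_id %in% cands$site_id, , drop = FALSE]
    dg <- vapply(seq_len(nrow(used)), function(r) {
      disruption_energy(target, used[r, ], tens, env,
                        arm_max = params$arm_max)
    }, numeric(1))
    cands$dG_disruption <- dg[match(cands$site_id, used$site_id)]
    log("accessibility_scored", nrow(cands))

    if (env$context == "in_vivo") {
      sp <- vapply(seq_len(nrow(used)), function(r) {
        q <- build_query(target, used[r, ], params)
        specificity_score(q$query, q$site_offset, env$transcriptome_path,
                          mode = params$specificity_mode)$score
      }, numeric(1))
      cands$specificity <- sp[match(cands$site_id, used$site_id)]
      log("specificity_scored", nrow(cands))
    } else {
      message("[specificity] skipped (in vitro run)")
      cands$specificity <- NA_real_
    }

    cands <- normalize_measures(cands)
    objectives <- cands[, c("q_f", "inaccessibility", "dG_disruption"),
                        drop = FALSE]
    if (env$context == "in_vivo") objectives$specificity <- cands$specificity
    cands$rank <- pareto_rank(objectives)
    log("ranked", nrow(cands))
  }

  meta <- list(
    target_id = target$id, target_length = nchar(target$sequence),
    cut_triplets = paste(params$cut_triplets, collapse = ","),
    arm_min = params$arm_min, arm_max = params$arm_max,
    model = params$model, t7 = params$t7,
    specificity_mode = params$specificity_mode,
    temperature_C = env$temperature, na_mM = env$na_mM, mg_mM = env$mg_mM,
    oligo_nM = env$oligo_nM, context = env$context,
    backend = backend$name, n_structures = backend$n_structures,
    seed = seed
  )
  report <- build_report(cands, meta)
  report$stage_counts <- counts
  if (params$t7 && nrow(report$table)) {
    report$t7_templates <- lapply(setNames(nm = unique(report$table$ribozyme)),
                                  emit_t7_template)
  }
  report
}
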