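#' Environment conditions for a design run
#'
#' Physico-chemical conditions of the intended application. Defaults follow
#' a typical mammalian-cell assay buffer: 37 degrees C, 100 mM Na+, 0.1 mM
#' Mg2+, 500 nM oligomer.
#'
#' @param temperature environment temperature, degrees Celsius.
#' @param na_mM monovalent sodium concentration, mM.
#' @param mg_mM magnesium concentration, mM.
#' @param oligo_nM oligomer (ribozyme) concentration, nM.
#' @param context `"in_vitro"` or `"in_vivo"`. In vivo runs require a
#'   reference transcriptome for the specificity stage.
#' @param transcriptome_path path to a (multi-)FASTA reference transcriptome;
#'   required iff `context == "in_vivo"`.
#' @return object of class `design_env`.
#' @export
design_env <- function(temperature = 37, na_mM = 100, mg_mM = 0.1,
                       oligo_nM = 500, context = c("in_vitro", "in_vivo"),
                       transcriptome_path = NULL) {
  context <- match.arg(context)
  stopifnot(is.finite(temperature), na_mM >= 0, mg_mM >= 0, oligo_nM > 0)
  if (context == "in_vivo" && is.null(transcriptome_path)) {
    stop("in_vivo designs require a reference transcriptome (transcriptome_path)")
  }
  structure(
    list(temperature = temperature, na_mM = na_mM, mg_mM = mg_mM,
         oligo_nM = oligo_nM, context = context,
         transcriptome_path = transcriptome_path),
    class = "design_env"
  )
}

.valid_triplet <- function(t) {
  nchar(t) == 3L & substr(t, 2, 2) == "U" &
    substr(t, 3, 3) %in% c("A", "C", "U") &
    !grepl("[^ACGU]", t)
}

#' Design parameters
#'
#' @param cut_triplets character vector of NUH cleavage triplets (RNA
#'   alphabet; `N` any base, `U` fixed, `H` one of A/C/U). Default `"GUC"`,
#'   the most cleavage-susceptible triplet.
#' @param arm_min,arm_max inclusive range of lengths (nt) for both
#'   substrate-binding arms (helices I and III).
#' @param model `"minimal"` or `"extended"` catalytic-core model; see
#'   [core_template()].
#' @param t7 logical; also emit a T7 transcription template for each design.
#' @param specificity_mode `"cleavage_only"` counts only off-target hits the
#'   ribozyme could cleave; `"annealing_and_cleavage"` counts all
#'   annealing-competent hits.
#' @return object of class `design_params`.
#' @export
design_params <- function(cut_triplets = "GUC", arm_min = 3L, arm_max = 10L,
                          model = c("minimal", "extended"), t7 = FALSE,
                          specificity_mode = c("cleavage_only",
                                               "annealing_and_cleavage")) {
  model <- match.arg(model)
  specificity_mode <- match.arg(specificity_mode)
  cut_triplets <- toupper(chartr("Tt", "Uu", cut_triplets))
  if (!length(cut_triplets) || !all(.valid_triplet(cut_triplets))) {
    stop("cut_triplets must be NUH triplets: U at position 2, ",
         "position 3 one of A/C/U")
  }
  arm_min <- as.integer(arm_min); arm_max <- as.integer(arm_max)
  if (!(arm_min >= 1L && arm_min <= arm_max)) {
    stop("need 1 <= arm_min <= arm_max")
  }
  structure(
    list(cut_triplets = unique(cut_triplets), arm_min = arm_min,
         arm_max = arm_max, model = model, t7 = isTRUE(t7),
         specificity_mode = specificity_mode),
    class = "design_params"
  )
}

#' Catalytic core template
#'
#' The constant central segment placed between the two target-binding arms:
#' the conserved CUGAUGA and GAAA boxes around a stem II hairpin. The
#' minimal-model core is the 28-nt constant shared by experimentally
#' validated designs (`CUGAUGA` + stem II + loop + stem II' + `GAAAC`);
#' the extended model adds one stem II pair by default and is intended to be
#' overridden with a scaffold of the user's choice via `stem2`/`loop2`.
#'
#' @param model `"minimal"` or `"extended"`.
#' @param stem2 5' strand of the stem II helix (paired with its reverse
#'   complement on the 3' side).
#' @param loop2 loop closing stem II.
#' @return object of class `core_template` with fields `model`, `core_seq`,
#'   `stem2_pairs` (two-column matrix of 1-based positions within the core)
#'   and `unpaired` (core positions that must stay unpaired in the designed
#'   fold).
#' @examples
#' core_template()$core_seq
#' @export
core_template <- function(model = c("minimal", "extended"),
                          stem2 = NULL, loop2 = "UGAAAU") {
  model <- match.arg(model)
  if (is.null(stem2)) stem2 <- if (model == "minimal") "GUCGC" else "GGUCGC"
  stem2 <- as_rna(stem2); loop2 <- as_rna(loop2)
  if (nchar(stem2) < 3L) stop("stem II must have at least 3 pairs")
  if (nchar(loop2) < 3L) stop("stem II loop must have at least 3 nt")
  box1 <- "CUGAUGA"; box2 <- "GAAAC"
  core <- paste0(box1, stem2, loop2, rna_revcomp(stem2), box2)
  n1 <- nchar(box1); ns <- nchar(stem2); nl <- nchar(loop2)
  # pair k: stem II 5' position n1+k with 3' position n1+ns+nl+(ns-k+1)
  pairs <- cbind(n1 + seq_len(ns), n1 + ns + nl + (ns - seq_len(ns) + 1L))
  colnames(pairs) <- c("i", "j")
  unpaired <- setdiff(seq_len(nchar(core)), c(pairs))
  if (!grepl("CUGAUGA", core, fixed = TRUE) || !grepl("GAAA", core, fixed = TRUE)) {
    stop("core template lost a conserved box")  # defensive; cannot happen here
  }
  structure(
    list(model = model, core_seq = core, stem2_pairs = pairs,
         unpaired = unpaired),
    class = "core_template"
  )
}

#' @export
print.core_template <- function(x, ...) {
  cat(sprintf("<core_template> %s model, %d nt: %s\n  stem II: %d pairs\n",
              x$model, nchar(x$core_seq), x$core_seq, nrow(x$stem2_pairs)))
  invisible(x)
}
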