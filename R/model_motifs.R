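#' Generic miRNA network-motif models
#'
#' Canonical 3-5 species transcription-factor/miRNA/target mass-action
#' networks illustrating the characteristic dynamics of the four motif
#' classes through which miRNAs act:
#'
#' \describe{
#'   \item{positive_feedback}{double-negative loop: the TF represses miRNA
#'     transcription (by binding the miRNA gene) while the miRNA enhances
#'     degradation of the TF mRNA. Mutual repression plus molecular
#'     titration makes the circuit bistable: started from opposite initial
#'     conditions it settles into distinct long-run states (TF on / miRNA
#'     off, or the reverse).}
#'   \item{negative_feedback}{the TF activates miRNA transcription and the
#'     miRNA removes TF mRNA; the three-stage loop (mRNA -> protein ->
#'     miRNA) has enough phase lag that the deterministic response rings,
#'     i.e. shows damped oscillations.}
#'   \item{coherent_ffl}{double-negative chain: the signal represses the
#'     miRNA and the miRNA represses the target, so the signal activates
#'     the target both directly and indirectly. The depleted miRNA takes a
#'     long time to recover after the signal decays, prolonging target
#'     expression (sign-sensitive delay).}
#'   \item{incoherent_ffl}{the signal activates the target and also a miRNA
#'     that removes the target, producing an accelerated, pulse-like
#'     response.}
#' }
#'
#' @param kind one of \code{"positive_feedback"}, \code{"negative_feedback"},
#'   \code{"coherent_ffl"}, \code{"incoherent_ffl"}.
#' @param initialState for \code{positive_feedback} only: \code{"TF_high"}
#'   or \code{"miRNA_high"}, selecting the basin the simulation starts in.
#' @return a [KineticModel-class].
#' @export
buildGenericMotif <- function(kind = c("positive_feedback",
                                       "negative_feedback",
                                       "coherent_ffl", "incoherent_ffl"),
                              initialState = c("TF_high", "miRNA_high")) {
  kind <- match.arg(kind)
  initialState <- match.arg(initialState)
  switch(kind,
    positive_feedback = {
      tfHigh <- initialState == "TF_high"
      species <- rbind(
        speciesSpec("TF_mRNA", if (tfHigh) 100 else 0, "mRNA"),
        speciesSpec("TF", if (tfHigh) 2000 else 0, "TF"),
        speciesSpec("miRNA", if (tfHigh) 0 else 300, "miRNA"),
        speciesSpec("miRNA_gene", if (tfHigh) 0 else 2, "gene"),
        speciesSpec("miRNA_gene_TF", if (tfHigh) 2 else 0, "gene")
      )
      rates <- c(
        k_synTFmRNA = 0.01, k_degTFmRNA = 1e-4,
        k_remTFmRNA = 1e-4,           # mutual miRNA/mRNA destruction
        k_synTF = 2e-3, k_degTF = 1e-4,
        k_synmiRNA = 0.015,           # per free gene copy
        k_degmiRNA = 1e-4,
        k_bindGene = 2e-5, k_relGene = 2e-3
      )
      reactions <- list(
        .rx(character(0), "TF_mRNA", "k_synTFmRNA"),
        .rx("TF_mRNA", character(0), "k_degTFmRNA"),
        .rx(c("miRNA", "TF_mRNA"), character(0), "k_remTFmRNA"),
        .rx("TF_mRNA", c("TF_mRNA", "TF"), "k_synTF"),
        .rx("TF", character(0), "k_degTF"),
        .rx("miRNA_gene", c("miRNA_gene", "miRNA"), "k_synmiRNA"),
        .rx("miRNA", character(0), "k_degmiRNA"),
        .rx(c("TF", "miRNA_gene"), "miRNA_gene_TF", "k_bindGene"),
        .rx("miRNA_gene_TF", c("TF", "miRNA_gene"), "k_relGene")
      )
      buildModel("generic_positive_feedback", species, reactions, rates,
                 notes = "double-negative TF/miRNA loop (bistable)")
    },
    negative_feedback = {
      species <- rbind(
        speciesSpec("TF_mRNA", 500, "mRNA"),
        speciesSpec("TF", 0, "TF"),
        speciesSpec("miRNA", 0, "miRNA")
      )
      rates <- c(
        k_synTFmRNA = 0.05, k_degTFmRNA = 1e-4,
        k_remTFmRNA = 2e-6,           # miRNA-catalysed mRNA removal
        k_synTF = 1e-4, k_degTF = 1e-4,
        k_synmiRNA = 1e-4,            # TF-driven transcription
        k_degmiRNA = 1e-4
      )
      reactions <- list(
        .rx(character(0), "TF_mRNA", "k_synTFmRNA"),
        .rx("TF_mRNA", character(0), "k_degTFmRNA"),
        .rx(c("miRNA", "TF_mRNA"), "miRNA", "k_remTFmRNA"),
        .rx("TF_mRNA", c("TF_mRNA", "TF"), "k_synTF"),
        .rx("TF", character(0), "k_degTF"),
        .rx("TF", c("TF", "miRNA"), "k_synmiRNA"),
        .rx("miRNA", character(0), "k_degmiRNA")
      )
      buildModel("generic_negative_feedback", species, reactions, rates,
                 notes = "TF-activates-miRNA / miRNA-inhibits-TF loop")
    },
    coherent_ffl = {
      species <- rbind(
        speciesSpec("S", 500, "signal"),
        speciesSpec("miRNA", 200, "miRNA"),
        speciesSpec("Target", 0, "mRNA")
      )
      rates <- c(
        k_degS = 2.57e-4,
        k_synmiRNA = 4e-4, k_degmiRNA = 2e-6,
        k_remmiRNA = 1e-6,            # signal-enhanced miRNA degradation
        k_synTarget = 1e-4,           # signal-driven transcription
        k_degTarget = 1e-5,
        k_remTarget = 2e-6            # miRNA-catalysed target removal
      )
      reactions <- list(
        .rx("S", character(0), "k_degS"),
        .rx(character(0), "miRNA", "k_synmiRNA"),
        .rx("miRNA", character(0), "k_degmiRNA"),
        .rx(c("S", "miRNA"), "S", "k_remmiRNA"),
        .rx("S", c("S", "Target"), "k_synTarget"),
        .rx("Target", character(0), "k_degTarget"),
        .rx(c("miRNA", "Target"), "miRNA", "k_remTarget")
      )
      buildModel("generic_coherent_ffl", species, reactions, rates,
                 notes = "double-negative coherent feedforward loop")
    },
    incoherent_ffl = {
      species <- rbind(
        speciesSpec("S", 500, "signal"),
        speciesSpec("miRNA", 0, "miRNA"),
        speciesSpec("Target", 0, "mRNA")
      )
      rates <- c(
        k_degS = 1e-5,
        k_synmiRNA = 2e-6,            # signal-driven transcription
        k_degmiRNA = 7.2e-6,
        k_synTarget = 1e-4,
        k_degTarget = 1e-5,
        k_remTarget = 1e-6
      )
      reactions <- list(
        .rx("S", character(0), "k_degS"),
        .rx("S", c("S", "miRNA"), "k_synmiRNA"),
        .rx("miRNA", character(0), "k_degmiRNA"),
        .rx("S", c("S", "Target"), "k_synTarget"),
        .rx("Target", character(0), "k_degTarget"),
        .rx(c("miRNA", "Target"), "miRNA", "k_remTarget")
      )
      buildModel("generic_incoherent_ffl", species, reactions, rates,
                 notes = "incoherent feedforward loop (pulse-like response)")
    })
}

#' Model registry
#'
#' Resolve a (model name, variant label) pair to a concrete
#' [KineticModel-class]. Available models: the four generic motifs
#' (variant = initial state for the positive feedback, ignored otherwise),
#' the five single-pathway models with their intervention presets, and the
#' integrated model (variant \code{"anti_miR140_<dose>"}).
#'
#' @param modelName one of \code{"generic_positive_feedback"},
#'   \code{"generic_negative_feedback"}, \code{"generic_coherent_ffl"},
#'   \code{"generic_incoherent_ffl"}, \code{"tgfb_smad3"},
#'   \code{"sox9_runx2"}, \code{"il1_adamts5"}, \code{"il1_mmp13"},
#'   \code{"tnfa_igfbp5"}, \code{"integrated"}.
#' @param variant preset label; see the individual builders. For
#'   \code{"tnfa_igfbp5"} use \code{"<miR140 preset>/<tnfa condition>"}
#'   (e.g. \code{"miR140_low/tnfa_chronic"}).
#' @return a [KineticModel-class].
#' @examples
#' getModel("tgfb_smad3", "with_miR140")
#' getModel("tnfa_igfbp5", "miR140_basal/tnfa_500")
#' @export
getModel <- function(modelName, variant = NULL) {
  switch(modelName,
    generic_positive_feedback =
      buildGenericMotif("positive_feedback",
                        initialState = if (is.null(variant)) "TF_high" else variant),
    generic_negative_feedback = buildGenericMotif("negative_feedback"),
    generic_coherent_ffl = buildGenericMotif("coherent_ffl"),
    generic_incoherent_ffl = buildGenericMotif("incoherent_ffl"),
    tgfb_smad3 = buildTgfbSmad3Model(if (is.null(variant)) "with_miR140" else variant),
    sox9_runx2 = buildSox9Runx2Model(if (is.null(variant)) "with_miR140" else variant),
    il1_adamts5 = buildIl1Adamts5Model(if (is.null(variant)) "with_miR140" else variant),
    il1_mmp13 = buildIl1Mmp13Model(if (is.null(variant)) "with_miR140" else variant),
    tnfa_igfbp5 = {
      parts <- strsplit(if (is.null(variant)) "miR140_basal/tnfa_500" else variant,
                        "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("tnfa_igfbp5 variant must be '<miR140 preset>/<tnfa condition>'")
      buildTnfaIgfbp5Model(parts[1], parts[2])
    },
    integrated = {
      dose <- if (is.null(variant)) 0 else
        as.numeric(sub("^anti_miR140_", "", variant))
      if (is.na(dose)) stop("integrated variant must be 'anti_miR140_<dose>'")
      buildIntegratedModel(dose)
    },
    stop("unknown model: ", modelName))
}

#' @rdname getModel
#' @export
listModels <- function() {
  c("generic_positive_feedback", "generic_negative_feedback",
    "generic_coherent_ffl", "generic_incoherent_ffl",
    "tgfb_smad3", "sox9_runx2", "il1_adamts5", "il1_mmp13",
    "tnfa_igfbp5", "integrated")
}
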