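#' Integrated cartilage-degradation model
#'
#' Union of the five single-pathway networks over a single shared miR-140
#' pool and a shared NF-kB pool, with the additional reactions that couple
#' the pathways to the matrix readouts: translation of ADAMTS5 and MMP13
#' mRNAs to proteins, ADAMTS-5-catalysed conversion of Aggrecan to AggFrag,
#' MMP-13-catalysed conversion of Collagen2 to ColFrag, and irreversible
#' binding of an anti-miR-140 oligonucleotide to miR-140 (inert complex).
#'
#' miR-140 is transcribed from its gene (2 copies, repressed by
#' phospho-SMAD3), by active NF-kB, and by SOX9. MMP13 mRNA is produced by
#' both active NF-kB and RUNX2; phospho-SMAD3 additionally promotes RUNX2
#' turnover (TGF-beta/SMAD3 signalling antagonises the hypertrophy factor
#' RUNX2), which is what makes TGF-beta protective against collagen
#' degradation in the combined network. Several shared constants are
#' re-calibrated relative to the single-pathway models so that the combined
#' stimulus behaves sensibly on the week-long horizon (see the methods
#' vignette); figure-legend values retained where printed.
#'
#' The default simulation scenario applies the combined stimulus
#' (IL1, Tnfa, TGFb_A all nonzero) at t = 0.
#'
#' @param antiMir140Dose initial anti-miR-140 count (0 = no inhibition;
#'   500 = moderate; 3000 = high).
#' @param il1,tnfa,tgfb initial stimulus amounts (defaults 500 each).
#' @return a [KineticModel-class] exposing readouts ADAMTS5, MMP13 (protein
#'   pools), AggFrag and ColFrag.
#' @export
buildIntegratedModel <- function(antiMir140Dose = 0, il1 = 500, tnfa = 500,
                                 tgfb = 500) {
  if (antiMir140Dose < 0) stop("anti-miR-140 dose must be >= 0")
  antiMir140Dose <- round(antiMir140Dose)
  il1 <- round(il1); tnfa <- round(tnfa); tgfb <- round(tgfb)
  species <- rbind(
    # stimuli
    speciesSpec("IL1", 0, "cytokine"),
    speciesSpec("Tnfa", 0, "cytokine"),
    speciesSpec("TGFb_A", 0, "ligand"),
    speciesSpec("TGFb_I", 0, "ligand"),
    # shared pools
    speciesSpec("NFkB", 0, "TF"),
    speciesSpec("miR140", 500, "miRNA"),
    speciesSpec("miR140_gene", 2, "gene"),
    speciesSpec("miR140_gene_pSMAD3", 0, "gene"),
    speciesSpec("antimiR140", 0, "oligonucleotide"),
    speciesSpec("miR140_antimiR140", 0, "complex"),
    # TGF-beta/SMAD3 arm
    speciesSpec("SMAD3", 100, "mRNA"),
    speciesSpec("SMAD3_P", 200, "protein"),
    speciesSpec("pSMAD3", 0, "protein"),
    speciesSpec("SMAD7", 0, "protein"),
    speciesSpec("miR140_SMAD3mRNA", 0, "complex"),
    # SOX9/HDAC4/RUNX2 arm
    speciesSpec("SOX9", 1, "TF"),
    speciesSpec("HDAC4_mRNA", 50, "mRNA"),
    speciesSpec("miR140_HDAC4mRNA", 0, "complex"),
    speciesSpec("HDAC4", 50, "protein"),
    speciesSpec("RUNX2", 40, "TF"),
    speciesSpec("HDAC4_RUNX2", 0, "complex"),
    speciesSpec("RUNX2_gene", 2, "gene"),
    speciesSpec("RUNX2_gene_HDAC4", 0, "gene"),
    # catabolic enzymes and matrix
    speciesSpec("ADAMTS5_mRNA", 0, "mRNA"),
    speciesSpec("ADAMTS5", 0, "protein"),
    speciesSpec("MMP13_mRNA", 0, "mRNA"),
    speciesSpec("MMP13", 0, "protein"),
    speciesSpec("Aggrecan", 10000, "matrix"),
    speciesSpec("AggFrag", 0, "readout"),
    speciesSpec("Collagen2", 10000, "matrix"),
    speciesSpec("ColFrag", 0, "readout"),
    # TNF-alpha/IGFBP5/IGF-1 arm
    speciesSpec("JNK", 0, "kinase"),
    speciesSpec("IGFBP5_mRNA", 80, "mRNA"),
    speciesSpec("miR140_IGFBP5mRNA", 0, "complex"),
    speciesSpec("IGFBP5", 0, "protein"),
    speciesSpec("IGF1", 0, "growth factor"),
    speciesSpec("AKT", 0, "kinase"),
    speciesSpec("ACAN", 0, "readout")
  )
  rates <- c(
    # stimuli
    k_degIL1 = 2.57e-4,
    k_degTnfa = 1e-4,
    # shared NF-kB (low-copy active pool)
    k_actNFkB = 9e-6,             # IL1-driven activation
    k_actNFkBTnfa = 1.3e-6,       # Tnfa-driven activation
    k_inactNFkB = 5e-5,
    # shared miR-140
    k_synmiR140 = 0.0018,         # per gene copy
    k_synmiR140NFkB = 1e-3,
    k_synmiR140SOX9 = 1e-4,
    k_degmiR140 = 7.2e-6,
    k_degmiR140IL1 = 1e-7,
    k_bindantimiR140 = 1e-5,      # irreversible sequestration
    # TGF-beta arm (slow SMAD7 inactivation: dose-dependent persistence)
    k_synSMAD3mRNA = 2e-4,
    k_degSMAD3mRNA = 1e-5,
    k_synSMAD3 = 3e-4,
    k_degSMAD3 = 1e-5,
    k_phosSMAD3 = 2e-6,
    k_dephosSMAD3 = 1e-4,
    k_synSMAD7 = 1e-4,
    k_degSMAD7 = 5e-5,
    k_inactTGFb = 1e-8,
    k_bindmiR140gene = 5e-7,
    k_relmiR140gene = 1e-4,
    k_bindmiR140SMAD3 = 1e-6,
    k_relmiR140SMAD3 = 2.5e-4,
    # SOX9 arm
    k_synHDAC4mRNA = 5e-4,
    k_degHDAC4mRNA = 1e-5,
    k_bindmiR140HDAC4 = 1e-5,
    k_relmiR140HDAC4 = 1e-4,
    k_synHDAC4 = 4e-5,
    k_degHDAC4 = 1e-5,
    k_bindHDAC4RUNX2 = 1e-6,
    k_relHDAC4RUNX2 = 1e-4,
    k_bindRUNX2gene = 5e-6,
    k_relRUNX2gene = 1e-4,
    k_synRUNX2 = 0.01,
    k_degRUNX2 = 1e-5,
    k_degRUNX2SOX9 = 5e-4,
    k_degRUNX2pSMAD3 = 5e-5,      # TGF-beta/SMAD3 antagonism of RUNX2
    # catabolic enzyme expression
    k_synADAMTS5 = 2e-4,          # IL1-driven transcription
    k_degADAMTS5mRNA = 1e-6,
    k_degADAMTS5miR140 = 2e-7,
    k_synADAMTS5prot = 1e-5,
    k_degADAMTS5prot = 1e-5,
    k_synMMP13NFkB = 2e-3,
    k_synMMP13RUNX2 = 1e-4,
    k_degMMP13mRNA = 1e-6,
    k_degMMP13miR140 = 4e-7,
    k_synMMP13prot = 1e-5,
    k_degMMP13prot = 1e-5,
    k_cleaveAgg = 1e-9,
    k_cleaveCol = 1e-9,
    # TNF-alpha/IGFBP5 arm
    k_actJNK = 2e-5,
    k_inactJNK = 2e-5,
    k_synIGFBP5 = 7e-3,
    k_synIGFBP5JNK = 2.7e-4,
    k_degIGFBP5mRNA = 1e-5,
    k_bindmiR140IGFBP5 = 1e-6,
    k_relmiR140IGFBP5 = 1e-6,
    k_degIGFBP5mRNAmiR140 = 1e-4,
    k_synIGFBP5prot = 1e-5,
    k_degIGFBP5 = 1.5e-5,
    k_synIGF1 = 1e-5,
    k_degIGF1 = 1e-4,
    k_actAKT = 1e-6,
    k_inactAKT = 1e-4,
    k_synACAN = 1e-3,
    k_degACAN = 1e-5
  )
  reactions <- c(list(
    # stimulus decay
    .rx("IL1", character(0), "k_degIL1"),
    .rx("Tnfa", character(0), "k_degTnfa"),
    # shared NF-kB
    .rx("IL1", c("IL1", "NFkB"), "k_actNFkB"),
    .rx("Tnfa", c("Tnfa", "NFkB"), "k_actNFkBTnfa"),
    .rx("NFkB", character(0), "k_inactNFkB"),
    # shared miR-140 synthesis/decay and anti-miR
    .rx("miR140_gene", c("miR140_gene", "miR140"), "k_synmiR140"),
    .rx("NFkB", c("NFkB", "miR140"), "k_synmiR140NFkB"),
    .rx("SOX9", c("SOX9", "miR140"), "k_synmiR140SOX9"),
    .rx("miR140", character(0), "k_degmiR140"),
    .rx(c("IL1", "miR140"), "IL1", "k_degmiR140IL1"),
    .rx(c("antimiR140", "miR140"), "miR140_antimiR140", "k_bindantimiR140"),
    # TGF-beta/SMAD3 arm
    .rx(character(0), "SMAD3", "k_synSMAD3mRNA"),
    .rx("SMAD3", character(0), "k_degSMAD3mRNA"),
    .rx("SMAD3", c("SMAD3", "SMAD3_P"), "k_synSMAD3"),
    .rx("SMAD3_P", character(0), "k_degSMAD3"),
    .rx("pSMAD3", character(0), "k_degSMAD3"),
    .rx(c("TGFb_A", "SMAD3_P"), c("TGFb_A", "pSMAD3"), "k_phosSMAD3"),
    .rx("pSMAD3", "SMAD3_P", "k_dephosSMAD3"),
    .rx("pSMAD3", c("pSMAD3", "SMAD7"), "k_synSMAD7"),
    .rx("SMAD7", character(0), "k_degSMAD7"),
    .rx(c("SMAD7", "TGFb_A"), c("SMAD7", "TGFb_I"), "k_inactTGFb"),
    .rx(c("pSMAD3", "miR140_gene"), "miR140_gene_pSMAD3", "k_bindmiR140gene"),
    .rx("miR140_gene_pSMAD3", c("pSMAD3", "miR140_gene"), "k_relmiR140gene"),
    # SOX9 arm
    .rx(character(0), "HDAC4_mRNA", "k_synHDAC4mRNA"),
    .rx("HDAC4_mRNA", character(0), "k_degHDAC4mRNA"),
    .rx("HDAC4_mRNA", c("HDAC4_mRNA", "HDAC4"), "k_synHDAC4"),
    .rx("HDAC4", character(0), "k_degHDAC4"),
    .rx(c("HDAC4", "RUNX2"), "HDAC4_RUNX2", "k_bindHDAC4RUNX2"),
    .rx("HDAC4_RUNX2", c("HDAC4", "RUNX2"), "k_relHDAC4RUNX2"),
    .rx("HDAC4_RUNX2", "HDAC4", "k_degRUNX2"),
    .rx(c("HDAC4", "RUNX2_gene"), "RUNX2_gene_HDAC4", "k_bindRUNX2gene"),
    .rx("RUNX2_gene_HDAC4", c("HDAC4", "RUNX2_gene"), "k_relRUNX2gene"),
    .rx("RUNX2_gene", c("RUNX2_gene", "RUNX2"), "k_synRUNX2"),
    .rx("RUNX2", character(0), "k_degRUNX2"),
    .rx(c("SOX9", "RUNX2"), "SOX9", "k_degRUNX2SOX9"),
    .rx(c("pSMAD3", "RUNX2"), "pSMAD3", "k_degRUNX2pSMAD3"),
    # ADAMTS5 arm and aggrecan cleavage
    .rx("IL1", c("IL1", "ADAMTS5_mRNA"), "k_synADAMTS5"),
    .rx("ADAMTS5_mRNA", character(0), "k_degADAMTS5mRNA"),
    .rx(c("miR140", "ADAMTS5_mRNA"), "miR140", "k_degADAMTS5miR140"),
    .rx("ADAMTS5_mRNA", c("ADAMTS5_mRNA", "ADAMTS5"), "k_synADAMTS5prot"),
    .rx("ADAMTS5", character(0), "k_degADAMTS5prot"),
    .rx(c("ADAMTS5", "Aggrecan"), c("ADAMTS5", "AggFrag"), "k_cleaveAgg"),
    # MMP13 arm and collagen cleavage
    .rx("NFkB", c("NFkB", "MMP13_mRNA"), "k_synMMP13NFkB"),
    .rx("RUNX2", c("RUNX2", "MMP13_mRNA"), "k_synMMP13RUNX2"),
    .rx("MMP13_mRNA", character(0), "k_degMMP13mRNA"),
    .rx(c("miR140", "MMP13_mRNA"), "miR140", "k_degMMP13miR140"),
    .rx("MMP13_mRNA", c("MMP13_mRNA", "MMP13"), "k_synMMP13prot"),
    .rx("MMP13", character(0), "k_degMMP13prot"),
    .rx(c("MMP13", "Collagen2"), c("MMP13", "ColFrag"), "k_cleaveCol"),
    # TNF-alpha/IGFBP5/IGF-1 arm
    .rx("Tnfa", c("Tnfa", "JNK"), "k_actJNK"),
    .rx("JNK", character(0), "k_inactJNK"),
    .rx(character(0), "IGFBP5_mRNA", "k_synIGFBP5"),
    .rx("JNK", c("JNK", "IGFBP5_mRNA"), "k_synIGFBP5JNK"),
    .rx("IGFBP5_mRNA", character(0), "k_degIGFBP5mRNA"),
    .rx(c("miR140", "IGFBP5_mRNA"), "miR140_IGFBP5mRNA", "k_bindmiR140IGFBP5"),
    .rx("miR140_IGFBP5mRNA", c("miR140", "IGFBP5_mRNA"), "k_relmiR140IGFBP5"),
    .rx("miR140_IGFBP5mRNA", "miR140", "k_degIGFBP5mRNAmiR140"),
    .rx("miR140_IGFBP5mRNA", "IGFBP5_mRNA", "k_degmiR140"),
    .rx("IGFBP5_mRNA", c("IGFBP5_mRNA", "IGFBP5"), "k_synIGFBP5prot"),
    .rx("IGFBP5", character(0), "k_degIGFBP5"),
    .rx("IGFBP5", c("IGFBP5", "IGF1"), "k_synIGF1"),
    .rx("IGF1", character(0), "k_degIGF1"),
    .rx("IGF1", c("IGF1", "AKT"), "k_actAKT"),
    .rx("AKT", character(0), "k_inactAKT"),
    .rx("AKT", c("AKT", "ACAN"), "k_synACAN"),
    .rx("ACAN", character(0), "k_degACAN")
  ),
  .sequestrationReactions("miR140", "SMAD3", "miR140_SMAD3mRNA",
                          "k_bindmiR140SMAD3", "k_relmiR140SMAD3",
                          "k_degSMAD3mRNA", "k_degmiR140"),
  .sequestrationReactions("miR140", "HDAC4_mRNA", "miR140_HDAC4mRNA",
                          "k_bindmiR140HDAC4", "k_relmiR140HDAC4",
                          "k_degHDAC4mRNA", "k_degmiR140"))
  m <- buildModel("integrated", species, reactions, rates,
                  notes = "integrated cartilage-degradation model")
  m <- .atBasalSteadyState(m, freeze = c("Aggrecan", "Collagen2",
                                         "AggFrag", "ColFrag"))
  applyIntervention(m, intervention(
    sprintf("combined stimulus, anti-miR140 = %g", antiMir140Dose),
    initialOverrides = c(IL1 = il1, Tnfa = tnfa, TGFb_A = tgfb,
                         antimiR140 = antiMir140Dose)))
}
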