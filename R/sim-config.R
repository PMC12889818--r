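#' Default 16-marker mouse lung panel
#'
#' A marker panel typical of multiplexed immunofluorescence of metastatic
#' mouse lung: a nuclear tumor reporter (GFP), a proliferation marker (Ki67,
#' declared sign "any" so it never participates in gating), and 14 membrane
#' lineage markers resolving 11 immune cell types plus the tumor type. Each
#' type's expected sign vector is pairwise distinct, and the marker count
#' exceeds the type count by more than one so the regression-mixture stage
#' of phenotyping is identifiable.
#'
#' @param excludeTypes cell types to drop from downstream analysis after
#'   phenotyping (default none).
#' @return a \linkS4class{MarkerPanel}
#' @examples
#' p <- defaultPanel()
#' cellTypes(p)
#' @export
defaultPanel <- function(excludeTypes = character()) {
    markers <- c("GFP", "Ki67", "CD45", "EpCAM", "CD3", "CD4", "CD8",
                 "CD19", "B220", "CD11b", "CD11c", "CD103", "NKp46",
                 "Ly6G", "Ly6C", "F480", "CD68", "SiglecF", "MHCII",
                 "CD64")
    nuclear <- markers %in% c("GFP", "Ki67")
    names(nuclear) <- markers
    types <- c("Tumor", "CD4_T", "CD8_T", "B", "NK", "NKT", "Neutrophil",
               "Monocyte", "Macrophage", "AlvMac", "cDC", "CD103_DC")
    signs <- matrix(-1, length(types), length(markers),
                    dimnames = list(types, markers))
    signs[, "Ki67"] <- 0
    pos <- list(
        Tumor = c("GFP", "EpCAM"),
        CD4_T = c("CD45", "CD3", "CD4"),
        CD8_T = c("CD45", "CD3", "CD8"),
        B = c("CD45", "CD19", "B220", "MHCII"),
        NK = c("CD45", "NKp46"),
        NKT = c("CD45", "CD3", "NKp46"),
        Neutrophil = c("CD45", "CD11b", "Ly6G"),
        Monocyte = c("CD45", "CD11b", "Ly6C"),
        Macrophage = c("CD45", "CD11b", "F480", "CD68", "CD64", "MHCII"),
        AlvMac = c("CD45", "SiglecF", "F480", "CD68", "CD11c", "CD64",
                   "MHCII"),
        cDC = c("CD45", "CD11c", "MHCII"),
        CD103_DC = c("CD45", "CD11c", "CD103", "MHCII"))
    for (t in names(pos)) signs[t, pos[[t]]] <- 1
    new("MarkerPanel", markers = markers, signs = signs, nuclear = nuclear,
        tumorType = "Tumor", excludeTypes = excludeTypes,
        profiles = matrix(numeric(), 0, length(markers),
                          dimnames = list(NULL, markers)))
}

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: two
#' genotypes with the knockout producing small, mostly dormant lesions
#' (zero-truncated negative binomial means 16.8 vs 3.8 tumor cells),
#' per-mouse random intercepts on the log scale, size-linked immune niches
#' (lesions of at most 8 tumor cells draw their immune composition from the
#' dormancy-associated niche-2 profile, larger lesions from the niche-1
#' profile), and an 8-fold separation between positive and negative marker
#' intensities.
#'
#' @param nSamplesPerGenotype mice per genotype.
#' @param genotypes two genotype labels; the first is the reference level.
#' @param lesionsPerSample lesions planted per mouse.
#' @param ztnbMu named (by genotype) NB mean before zero truncation.
#' @param ztnbTheta NB dispersion.
#' @param sampleRandomSD SD of the per-sample intercept on the log scale.
#' @param nicheProfiles 2 x types probability matrix (rows: niche1, niche2).
#' @param nicheSizeCutoff lesion size at or below which the niche-2 profile
#'   is used when \code{nicheSizeLinked}.
#' @param nicheSizeLinked if \code{FALSE}, niches are assigned independently
#'   of size (coin flip) — the null configuration.
#' @param immuneCellsPerLesion Poisson mean of immune cells per lesion.
#' @param lesionSpatialSD isotropic Gaussian scatter of tumor cells around
#'   the lesion center, micrometres.
#' @param minLesionSeparation minimum distance between lesion centers,
#'   micrometres; 450 guarantees a 1:1 match between planted lesions and
#'   recovered proximity-graph components at the 200 um radius.
#' @param fieldSize c(width, height) of the imaged field, micrometres.
#' @param backgroundImmuneDensity unclustered immune cells per mm^2.
#' @param pixelSize x-y pixel size in micrometres.
#' @param foldSeparation fold change between positive and negative marker
#'   mean MFI.
#' @param mfiSdLog log-scale SD of the type-conditional log-normal MFIs.
#' @param noisePoissonScale Poisson noise scale for rendered images
#'   (0 disables noise).
#' @param spillover channel spillover mixing matrix (identity = none).
#' @param panel a \linkS4class{MarkerPanel}.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a validated \linkS4class{SimConfig}
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nSamplesPerGenotype = 4,
                      genotypes = c("control", "knockout"),
                      lesionsPerSample = 15,
                      ztnbMu = c(control = 16.8, knockout = 3.8),
                      ztnbTheta = 2,
                      sampleRandomSD = 0.5,
                      nicheProfiles = NULL,
                      nicheSizeCutoff = 8,
                      nicheSizeLinked = TRUE,
                      immuneCellsPerLesion = 40,
                      lesionSpatialSD = 30,
                      minLesionSeparation = 450,
                      fieldSize = c(3000, 3000),
                      backgroundImmuneDensity = 50,
                      pixelSize = 0.284,
                      foldSeparation = 8,
                      mfiSdLog = 0.45,
                      noisePoissonScale = 0,
                      spillover = NULL,
                      panel = defaultPanel(),
                      seed = 1) {
    imm <- immuneTypes(panel)
    if (is.null(nicheProfiles)) {
        nicheProfiles <- matrix(0, 2, length(imm),
                                dimnames = list(c("niche1", "niche2"), imm))
        n1 <- c(CD4_T = 0.18, CD8_T = 0.22, B = 0.04, NK = 0.02, NKT = 0.02,
                Neutrophil = 0.02, Monocyte = 0.02, Macrophage = 0.18,
                AlvMac = 0.14, cDC = 0.14, CD103_DC = 0.02)
        n2 <- c(CD4_T = 0.02, CD8_T = 0.02, B = 0.02, NK = 0.20, NKT = 0.10,
                Neutrophil = 0.18, Monocyte = 0.18, Macrophage = 0.02,
                AlvMac = 0.02, cDC = 0.02, CD103_DC = 0.22)
        nicheProfiles["niche1", names(n1)] <- n1
        nicheProfiles["niche2", names(n2)] <- n2
    }
    if (is.null(spillover)) {
        spillover <- diag(length(markerNames(panel)))
        dimnames(spillover) <- list(markerNames(panel), markerNames(panel))
    }
    cfg <- new("SimConfig",
        nSamplesPerGenotype = as.integer(nSamplesPerGenotype),
        genotypes = genotypes,
        lesionsPerSample = as.integer(lesionsPerSample),
        ztnbMu = ztnbMu, ztnbTheta = ztnbTheta,
        sampleRandomSD = sampleRandomSD,
        nicheProfiles = nicheProfiles,
        nicheSizeCutoff = nicheSizeCutoff,
        nicheSizeLinked = nicheSizeLinked,
        immuneCellsPerLesion = immuneCellsPerLesion,
        lesionSpatialSD = lesionSpatialSD,
        minLesionSeparation = minLesionSeparation,
        fieldSize = fieldSize,
        backgroundImmuneDensity = backgroundImmuneDensity,
        pixelSize = pixelSize,
        foldSeparation = foldSeparation,
        mfiSdLog = mfiSdLog,
        noisePoissonScale = noisePoissonScale,
        spillover = spillover,
        panel = panel,
        seed = as.integer(seed))
    validObject(cfg)
    cfg
}
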