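#' @include AllClasses.R
NULL

# 27 bilateral volumetric ROIs + cerebellum + brainstem = 56 regions,
# matching a whole-brain probabilistic atlas parcellation. Lobe assignment
# drives the regional contribution aggregation.
.GM_VOLUME_REGIONS <- data.frame(
  region = c("Sup Fron Gy", "Mid Fron Gy", "Inf Fron Gy", "PreCen Gy",
             "Mid OrbFron Gy", "Lat OrbFron Gy", "Gy Rectus",
             "PostCen Gy", "Sup Parie Gy", "SupraMar Gy", "Angular Gy",
             "Precuneus",
             "Sup Occi Gy", "Mid Occi Gy", "Inf Occi Gy", "Cuneus",
             "Lingual Gy",
             "Sup Temp Gy", "Mid Temp Gy", "Inf Temp Gy", "ParaHip Gy",
             "Fusiform Gy",
             "Insula", "Cing Gy", "Caudate", "Putamen", "Hippocampus"),
  lobe = c(rep("frontal", 7), rep("parietal", 5), rep("occipital", 5),
           rep("temporal", 5), rep("other", 5)),
  stringsAsFactors = FALSE)

# 34 bilateral cortical-surface ROIs (Desikan-Killiany-style) = 68 regions
.GM_THICKNESS_REGIONS <- data.frame(
  region = c("Caud Mid Fron Gy", "Lat OrbFron Gy", "Med OrbFron Gy",
             "ParaCen Gy", "Pars Oper Gy", "Pars Orbit Gy", "Pars Tri Gy",
             "PreCen Gy", "Rost Mid Fron Gy", "Sup Fron Gy", "Fron Pole",
             "Inf Parie Gy", "PostCen Gy", "Precuneus", "Sup Parie Gy",
             "SupraMar Gy",
             "Bank SupTemp Sul", "Entorhinal Gy", "Fusiform Gy",
             "Inf Temp Gy", "Mid Temp Gy", "ParaHip Gy", "Sup Temp Gy",
             "Temp Pole", "Trans Temp Gy",
             "Cuneus", "Lat Occi Gy", "Lingual Gy", "PeriCal Gy",
             "Caud Ant Cing Gy", "Isthmus Cing Gy", "Post Cing Gy",
             "Rost Ant Cing Gy", "Insula"),
  lobe = c(rep("frontal", 11), rep("parietal", 5), rep("temporal", 9),
           rep("occipital", 4), rep("other", 5)),
  stringsAsFactors = FALSE)

# 45 major fiber-tract bundles: 7 callosal segments (midline), 10 bilateral
# association pairs, 9 bilateral projection pairs
.WM_CALLOSAL <- c("CC Genu", "CC PreMotor", "CC Motor", "CC Sensory",
                  "CC Parie", "CC Temp", "CC Occi")
.WM_ASSOCIATION <- c("AF", "UF", "ILF", "IFOF", "SLF I", "SLF II",
                     "SLF III", "Cingulum", "Fornix", "MdLF")
.WM_PROJECTION <- c("TR PreFron", "TR SM", "TR Parie", "TR Opt", "TR Aud",
                    "CST", "CBT", "SCP", "ICP")

.bilateral <- function(regions, lobes = NULL) {
  data.frame(
    region = as.vector(t(outer(c("L", "R"), regions, paste))),
    base = rep(regions, each = 2),
    hemisphere = rep(c("left", "right"), times = length(regions)),
    lobe = if (is.null(lobes)) NA_character_ else rep(lobes, each = 2),
    stringsAsFactors = FALSE)
}

#' Feature descriptors for the gray-matter panel
#'
#' The 124-feature gray-matter panel: 56 regional volumes (27 bilateral
#' ROIs plus cerebellum and brainstem) and 68 cortical thicknesses (34
#' bilateral surface ROIs). Names are prefixed with the feature type
#' (`Vol`/`CT`) followed by hemisphere and region, e.g.
#' `"Vol L Mid OrbFron Gy"`.
#'
#' @return data.frame with columns `name`, `modality`, `region_group`
#'   (lobe), `hemisphere`.
#' @examples
#' table(gmFeatureDescriptors()$modality)
#' @export
gmFeatureDescriptors <- function() {
  vol <- .bilateral(.GM_VOLUME_REGIONS$region, .GM_VOLUME_REGIONS$lobe)
  vol <- rbind(vol,
               data.frame(region = c("Cerebellum", "Brainstem"),
                          base = c("Cerebellum", "Brainstem"),
                          hemisphere = "midline", lobe = "other"))
  thk <- .bilateral(.GM_THICKNESS_REGIONS$region, .GM_THICKNESS_REGIONS$lobe)
  rbind(
    data.frame(name = paste("Vol", vol$region), modality = "GM_volume",
               region_group = vol$lobe, hemisphere = vol$hemisphere,
               stringsAsFactors = FALSE),
    data.frame(name = paste("CT", thk$region), modality = "GM_thickness",
               region_group = thk$lobe, hemisphere = thk$hemisphere,
               stringsAsFactors = FALSE))
}

#' Feature descriptors for the white-matter panel
#'
#' The 90-feature white-matter panel: generalized fractional anisotropy
#' (GFA) and mean diffusivity (MD) averaged over each of 45 major fiber
#' tract bundles (7 callosal segments, 10 bilateral association pairs, 9
#' bilateral projection pairs). Names follow the `"<type> <hemi> <tract>"`
#' convention, e.g. `"GFA R UF"` for the GFA of the right uncinate
#' fasciculus or `"MD CC Parie"` for the parietal callosal segment.
#'
#' @return data.frame with columns `name`, `modality`, `region_group`
#'   (fiber system), `hemisphere`.
#' @examples
#' table(wmFeatureDescriptors()$region_group)
#' @export
wmFeatureDescriptors <- function() {
  assoc <- .bilateral(.WM_ASSOCIATION)
  proj <- .bilateral(.WM_PROJECTION)
  tracts <- rbind(
    data.frame(region = .WM_CALLOSAL, hemisphere = "midline",
               system = "callosal", stringsAsFactors = FALSE),
    data.frame(region = assoc$region, hemisphere = assoc$hemisphere,
               system = "association", stringsAsFactors = FALSE),
    data.frame(region = proj$region, hemisphere = proj$hemisphere,
               system = "projection", stringsAsFactors = FALSE))
  rbind(
    data.frame(name = paste("GFA", tracts$region), modality = "WM_GFA",
               region_group = tracts$system, hemisphere = tracts$hemisphere,
               stringsAsFactors = FALSE),
    data.frame(name = paste("MD", tracts$region), modality = "WM_MD",
               region_group = tracts$system, hemisphere = tracts$hemisphere,
               stringsAsFactors = FALSE))
}
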