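# The 120-region anatomical parcellation (AAL2-style nomenclature):
# 56 bilateral cortical/subcortical/cerebellar structures plus 8 unpaired
# vermis subdivisions. Names follow the conventional <Structure>_<L|R>
# labelling so that reports read like the field's region tables.

aal2_paired <- c(
  "Precentral", "Frontal_Sup_2", "Frontal_Mid_2", "Frontal_Inf_Oper",
  "Frontal_Inf_Tri", "Frontal_Inf_Orb_2", "Rolandic_Oper", "Supp_Motor_Area",
  "Olfactory", "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus",
  "OFCmed", "OFCant", "OFCpost", "OFClat", "Insula",
  "Cingulate_Ant", "Cingulate_Mid", "Cingulate_Post",
  "Hippocampus", "ParaHippocampal", "Amygdala",
  "Calcarine", "Cuneus", "Lingual",
  "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
  "Postcentral", "Parietal_Sup", "Parietal_Inf", "Supramarginal",
  "Angular", "Precuneus", "Paracentral_Lobule",
  "Caudate", "Putamen", "Pallidum", "Thalamus", "Heschl",
  "Temporal_Sup", "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
  "Temporal_Inf",
  "Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3", "Cerebelum_4_5",
  "Cerebelum_6", "Cerebelum_7b", "Cerebelum_8", "Cerebelum_9", "Cerebelum_10"
)

aal2_vermis <- c(
  "Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6",
  "Vermis_7", "Vermis_8", "Vermis_9", "Vermis_10"
)

#' Atlas region names
#'
#' Returns the default region naming used across the package: the 120
#' cortical, subcortical and cerebellar labels of the AAL2-style
#' parcellation (56 paired structures suffixed `_L`/`_R`, interleaved, then
#' 8 vermis subdivisions). When `n` differs from 120 the first `n` labels
#' are returned, padded with `Region_<i>` if `n > 120`.
#'
#' @param n number of region names wanted (default 120).
#' @return character vector of length `n`.
#' @export
#' @examples
#' head(region_names(), 4)
region_names <- function(n = 120L) {
  check_number(n, "n", lower = 1)
  full <- c(as.vector(rbind(paste0(aal2_paired, "_L"), paste0(aal2_paired, "_R"))),
            aal2_vermis)
  if (n <= length(full)) return(full[seq_len(n)])
  c(full, paste0("Region_", seq.int(length(full) + 1L, n)))
}
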