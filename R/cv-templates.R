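# Ideal beta-sheet reference templates for the beta-RMSD collective
# variable: two 3-residue backbone segments (atoms N, CA, CB, C, O per
# residue; segment A rows 1-15, segment B rows 16-30), in Angstrom.
# Constructed from ideal beta-strand torsions (phi = -139, psi = 135)
# with the inter-segment placement solved for canonical 2.91 A
# N-H...O=C hydrogen-bond geometry in the antiparallel and parallel
# registers. Both segments are stored in N-to-C residue order.

TEMPLATE_ANTIPARALLEL <- matrix(c(
-4.9362, -0.9219, -2.2823,
-3.4782, -0.9219, -2.2823,
-2.9455, -1.6998, -3.4758,
-2.9267, 0.4999, -2.2823,
-3.4000, 1.3537, -3.0323,
-1.9284, 0.7421, -1.4391,
-1.3114, 2.0594, -1.3403,
-1.8945, 2.8341, -0.1685,
0.2038, 1.9502, -1.2072,
0.7060, 1.1332, -0.4353,
0.9203, 2.7762, -1.9626,
2.3779, 2.7740, -1.9305,
2.9349, 1.9543, -3.0844,
2.9325, 4.1940, -1.9676,
2.4778, 5.0220, -2.7570,
5.4072, -0.7213, 0.7939,
4.0811, -1.1840, 0.4026,
4.1696, -2.5425, -0.2757,
3.1424, -1.2465, 1.6028,
3.5202, -1.7375, 2.6665,
1.9242, -0.7473, 1.4215,
0.9304, -0.7455, 2.4884,
0.8949, 0.6083, 3.1808,
-0.4514, -1.1092, 1.9555,
-0.8729, -0.6037, 0.9152,
-1.1457, -1.9850, 2.6746,
-2.4798, -2.4174, 2.2759,
-2.4117, -3.7494, 1.5447,
-3.4104, -2.5161, 3.4799,
-3.0306, -3.0522, 4.5209), ncol = 3, byrow = TRUE)

TEMPLATE_PARALLEL <- matrix(c(
-5.3756, -1.3831, -1.9594,
-3.9176, -1.3831, -1.9594,
-3.3849, -2.1610, -3.1529,
-3.3661, 0.0387, -1.9594,
-3.8394, 0.8924, -2.7094,
-2.3678, 0.2808, -1.1162,
-1.7508, 1.5982, -1.0174,
-2.3340, 2.3729, 0.1545,
-0.2356, 1.4889, -0.8843,
0.2665, 0.6720, -0.1123,
0.4809, 2.3150, -1.6397,
1.9385, 2.3127, -1.6076,
2.4955, 1.4930, -2.7614,
2.4931, 3.7328, -1.6447,
2.0384, 4.5607, -2.4341,
-2.9058, -3.9851, 1.7566,
-1.4828, -3.8328, 1.4779,
-1.1512, -4.3665, 0.0928,
-1.0482, -2.3768, 1.6074,
-1.7263, -1.4760, 1.1132,
0.0816, -2.1585, 2.2723,
0.6080, -0.8130, 2.4676,
0.2229, -0.2845, 3.8409,
2.1221, -0.7818, 2.2887,
2.8302, -1.6465, 2.8046,
2.6060, 0.2168, 1.5573,
4.0354, 0.3621, 1.3093,
4.4019, -0.2160, -0.0490,
4.4656, 1.8222, 1.4020,
3.7994, 2.7053, 0.8619), ncol = 3, byrow = TRUE)


#' Ideal beta-sheet segment-pair template
#'
#' Returns the 30-atom reference coordinates (two 3-residue backbone
#' segments, atoms N, CA, CB, C, O) that the beta-RMSD collective
#' variable compares segment pairs against.
#'
#' @param mode "antiparallel" or "parallel".
#' @return Numeric 30 x 3 matrix (Angstrom).
#' @export
beta_template <- function(mode = c("antiparallel", "parallel")) {
  mode <- match.arg(mode)
  if (mode == "antiparallel") TEMPLATE_ANTIPARALLEL else TEMPLATE_PARALLEL
}
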