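# Curated backbone templates for the synthetic hairpin motifs (strands of
# four flanking the loop).
#
# The beta-turn (loop 4) is a dihedral template over ideal internal
# coordinates, found by numerical optimisation of the Kabsch-Sander
# energies of its blueprint bonds.
#
# The type-1 (loop 5) and type-2 (loop 6) bulge-loop motifs are stored as
# backbone coordinate templates (N/CA/C/O rows per residue): rigidly ideal
# internal coordinates cannot robustly realise the bulge bond pattern
# together with the sheet register, so these were derived once by
# restrained coordinate-space minimisation (near-ideal covalent geometry;
# blueprint hydrogen bonds; penalties against incidental ladder-extending
# bonds; bond-survival margins over a fixed set of coordinate-noise
# draws), seeded from a real kinase beta-hairpin backbone. See the methods
# vignette. All templates are validated by the package classifier at zero
# noise in the test-suite.
HAIRPIN_TEMPLATES <- list(
  `4` = list(
    phi = c(-139, -139, -139, -139, -65.188, -30.484, -78.855, 57.064, -157.507, -139, -139, -139),
    psi = c(135, 135, 135, 88.839, -86.43, -46.382, -5.142, 66.601, 135, 135, 135, 135)
  ),
  `5` = list(
    coords = list(
      N = matrix(c(
      -3.8739, -27.4219, 16.8846,
      -2.4196, -24.2516, 15.7379,
      -3.2693, -20.9850, 15.4543,
      -2.5056, -17.7565, 14.6681,
      -0.7526, -14.9948, 13.9947,
      1.2275, -12.8256, 12.3711,
      2.8982, -10.1286, 11.9503,
      0.4306, -9.7986, 11.5815,
      -0.9827, -12.3192, 11.7476,
      -0.7219, -15.9323, 11.9722,
      -0.5935, -19.1761, 11.2666,
      -0.4764, -22.2818, 12.6297,
      -0.2467, -25.7085, 12.2741), ncol = 3, byrow = TRUE),
      CA = matrix(c(
      -3.2970, -26.5071, 15.9072,
      -2.0430, -22.9291, 16.2227,
      -3.6176, -19.9046, 14.5395,
      -2.2211, -16.4379, 15.2212,
      -0.3634, -13.5826, 14.0081,
      2.5397, -12.5195, 11.8133,
      2.5896, -8.7600, 11.5690,
      -1.0173, -9.9100, 11.4704,
      -1.2975, -13.7064, 11.4269,
      0.2115, -17.0548, 12.1064,
      -1.3221, -20.4390, 11.3070,
      0.3456, -23.4493, 12.9220,
      -0.9935, -26.9601, 12.3326), ncol = 3, byrow = TRUE),
      C = matrix(c(
      -2.9545, -25.1638, 16.5435,
      -2.3080, -21.8579, 15.1710,
      -3.4352, -18.5426, 15.2001,
      -2.0173, -15.3912, 14.1187,
      1.0813, -13.3991, 13.5578,
      2.5082, -11.1367, 11.1803,
      1.0814, -8.6531, 11.3895,
      -1.4316, -11.3058, 11.0103,
      -0.3459, -14.6738, 12.1586,
      -0.5494, -18.3589, 12.3147,
      -0.3769, -21.6243, 11.4794,
      -0.5138, -24.6972, 13.0945,
      -0.3823, -27.9179, 13.3503), ncol = 3, byrow = TRUE),
      O = matrix(c(
      -3.2184, -24.9411, 17.7252,
      -1.6164, -21.7872, 14.1541,
      -4.2447, -18.1379, 16.0348,
      -2.7557, -15.5161, 13.1169,
      1.9700, -14.0914, 14.0607,
      2.1926, -10.9923, 9.9987,
      0.5824, -7.6911, 10.8060,
      -2.3468, -11.4292, 10.1902,
      0.8870, -14.3953, 12.2107,
      -1.2805, -18.4983, 13.2978,
      0.2680, -22.0540, 10.5201,
      -1.4697, -24.6997, 13.8713,
      -0.7483, -29.0920, 13.4097), ncol = 3, byrow = TRUE)
    )
  ),
  `6` = list(
    coords = list(
      N = matrix(c(
      -5.6241, -24.6962, 20.1038,
      -3.4521, -22.6473, 18.0210,
      -3.6100, -19.4351, 17.3746,
      -2.6394, -16.5624, 15.5560,
      -0.6341, -14.6248, 13.6605,
      1.5543, -14.8901, 12.0228,
      4.2281, -13.7358, 11.3832,
      3.5433, -10.9767, 10.4653,
      1.6887, -12.0479, 8.9478,
      -0.8803, -12.8816, 10.0495,
      -1.6697, -15.6242, 12.0172,
      -2.5210, -19.0166, 12.1923,
      -2.3620, -21.6297, 14.1664,
      -3.0770, -24.9254, 14.7015), ncol = 3, byrow = TRUE),
      CA = matrix(c(
      -5.1560, -24.1736, 18.8257,
      -2.5588, -21.4959, 18.0817,
      -3.9860, -18.3729, 16.4497,
      -1.7774, -15.3876, 15.6331,
      0.0894, -13.4203, 13.2529,
      2.4470, -15.3056, 10.9470,
      5.1642, -12.6572, 11.0907,
      2.8505, -10.0669, 9.5626,
      0.7011, -12.8773, 8.2903,
      -1.6081, -13.4039, 11.2008,
      -1.1846, -17.0080, 12.0245,
      -3.4581, -19.9475, 12.8093,
      -1.7406, -22.9213, 14.4342,
      -3.9525, -25.8626, 15.3951), ncol = 3, byrow = TRUE),
      C = matrix(c(
      -4.2772, -22.9424, 19.0205,
      -2.8875, -20.4826, 16.9888,
      -3.1213, -17.1343, 16.6559,
      -1.7876, -14.5766, 14.3297,
      0.9693, -13.6949, 12.0372,
      3.3404, -14.1565, 10.4869,
      4.5832, -11.6976, 10.0605,
      2.0581, -10.8443, 8.5186,
      -0.0030, -13.6358, 9.3989,
      -0.8547, -14.5980, 11.8203,
      -2.1421, -17.9000, 12.8052,
      -2.8437, -21.3341, 12.9628,
      -2.6517, -23.8059, 15.2782,
      -3.1970, -26.6287, 16.4761), ncol = 3, byrow = TRUE),
      O = matrix(c(
      -4.4054, -22.2285, 20.0155,
      -2.3374, -20.5492, 15.8808,
      -2.9663, -16.6525, 17.7806,
      -2.8920, -14.5065, 13.7393,
      0.8161, -13.0157, 11.0020,
      3.4428, -13.8949, 9.2841,
      5.1806, -11.4753, 9.0057,
      2.3261, -10.6172, 7.3283,
      0.6627, -14.4784, 10.0120,
      0.3410, -14.8165, 11.4664,
      -2.7270, -17.4559, 13.7941,
      -2.9986, -22.1862, 12.0833,
      -3.0471, -23.4290, 16.3822,
      -2.6182, -27.6831, 16.2140), ncol = 3, byrow = TRUE)
    )
  )
)

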