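# Physical constants and residue tables used across the package.

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# data.table is used (not inherited) for the heavy keyed aggregations
.datatable.aware <- TRUE

# Monoisotopic residue masses (Da) for the 20 standard amino acids, i.e. the
# mass each residue contributes inside a peptide chain (free water excluded).
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Monoisotopic mass of water added to every free peptide (N-terminal H,
# C-terminal OH).
WATER_MONO_MASS <- 18.0105646863

AA_ALPHABET <- names(AA_MONO_MASS)

# Swiss-Prot amino-acid background frequencies (fractions), used by the
# sequence simulator to draw realistic protein composition.
AA_FREQ <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
)

# Collapse isoleucine to leucine: the two are isobaric and indistinguishable
# by MS, so all peptide matching and uniqueness calls use this key.
il_collapse <- function(x) chartr("I", "L", x)
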